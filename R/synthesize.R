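#' Class-conditioned generator profile
#'
#' A `class_profile` states the morphology/texture regime a lesion class is
#' simulated under: how many regions appear, how large they are, how
#' irregular their outline is (`circularity_target`), how bright they are
#' (`intensity_mean`) and how rough their internal texture is
#' (`contrast_level`, the within-region intensity noise s.d. that drives
#' GLCM contrast monotonically).
#'
#' @param class_name class label string.
#' @param area_range length-2 positive integer vector `(min, max)` pixel
#'   count per region.
#' @param n_regions_range length-2 positive integer vector `(min, max)`.
#' @param contrast_level within-region intensity noise s.d. (in `[0,1]`
#'   intensity units).
#' @param circularity_target target outline circularity in `(0, 1]`;
#'   lower values produce more irregular blobs.
#' @param intensity_mean mean region intensity in `(0, 1)`.
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(class_name, area_range, n_regions_range,
                          contrast_level, circularity_target, intensity_mean) {
  stopifnot(length(area_range) == 2, length(n_regions_range) == 2)
  if (any(area_range <= 0) || area_range[1] > area_range[2] ||
      any(n_regions_range <= 0) || n_regions_range[1] > n_regions_range[2]) {
    cg_stop("cg_profile_error", "area_range and n_regions_range must be positive and ordered")
  }
  stopifnot(contrast_level >= 0, circularity_target > 0, circularity_target <= 1,
            intensity_mean > 0, intensity_mean < 1)
  structure(list(class_name = as.character(class_name),
                 area_range = as.numeric(area_range),
                 n_regions_range = as.integer(n_regions_range),
                 contrast_level = contrast_level,
                 circularity_target = circularity_target,
                 intensity_mean = intensity_mean),
            class = "class_profile")
}

#' Default five-class lesion profiles
#'
#' Profiles for normal, CIN1, CIN2, CIN3 and carcinoma emulating the
#' reported morphology/texture *trends*: region area dips at CIN1 and grows
#' back toward carcinoma, texture contrast increases monotonically with
#' severity, outline circularity decreases, and region intensity follows
#' the reported per-class means. The absolute values are generator
#' parameters, not clinical measurements.
#'
#' @return Named list of [class_profile()] objects.
#' @export
default_class_profiles <- function() {
  list(
    normal    = class_profile("normal",    c(1400, 2200), c(1, 2), 0.05, 0.90, 0.65),
    CIN1      = class_profile("CIN1",      c(700, 1100),  c(2, 4), 0.08, 0.80, 0.68),
    CIN2      = class_profile("CIN2",      c(900, 1300),  c(2, 3), 0.11, 0.70, 0.55),
    CIN3      = class_profile("CIN3",      c(1000, 1500), c(2, 3), 0.14, 0.62, 0.58),
    carcinoma = class_profile("carcinoma", c(1300, 2000), c(1, 2), 0.18, 0.52, 0.50)
  )
}

# Irregular closed blob outline: base radius modulated by random low-order
# harmonics; amplitude grows as circularity_target drops.
blob_polygon <- function(cx, cy, r0, circ_target, n_vert = 28) {
  amp <- 0.65 * (1 - circ_target)
  theta <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  mod <- rep(0, n_vert)
  for (k in 2:4) {
    mod <- mod + stats::runif(1, 0, 1) * cos(k * theta + stats::runif(1, 0, 2 * pi))
  }
  if (max(abs(mod)) > 0) mod <- mod / max(abs(mod))
  r <- r0 * pmax(1 + amp * mod, 0.2)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

#' Generate one synthetic image + mask pair
#'
#' Draws `n` non-overlapping irregular regions on a blank canvas (region
#' count and pixel areas within the profile's stated ranges), fills the
#' image with a dark noisy background and brighter textured regions whose
#' internal noise s.d. equals `contrast_level`. Deterministic for a fixed
#' seed.
#'
#' @param profile a [class_profile()].
#' @param rng_seed integer seed.
#' @param size canvas `c(height, width)`, default `c(128, 128)` (the
#'   pipeline's working resolution).
#' @return List with elements `image` ([gray_image()]) and `mask`
#'   ([label_mask()]).
#' @export
generate_synthetic_case <- function(profile, rng_seed, size = c(128, 128)) {
  stopifnot(inherits(profile, "class_profile"))
  h <- size[1]; w <- size[2]
  r_hi <- sqrt(profile$area_range[2] / pi) * (1 + 0.65 * (1 - profile$circularity_target))
  if (2 * (r_hi + 3) >= min(h, w)) {
    cg_stop("cg_generation_error",
            "profile regions (radius ~%.1f) cannot fit a %dx%d canvas", r_hi, h, w)
  }
  # placement is rejection-sampled; retry whole cases on a derived seed so a
  # crowded draw never aborts generation (deterministic for a fixed rng_seed)
  for (attempt in 1:25) {
    polys <- with_seed(derive_seed(rng_seed, "case", attempt),
                       try_place_case(profile, h, w))
    if (!is.null(polys)) break
  }
  if (is.null(polys)) {
    cg_stop("cg_generation_error",
            "could not place regions for class %s on a %dx%d canvas",
            profile$class_name, h, w)
  }
  with_seed(derive_seed(rng_seed, "paint"), {
    n <- length(polys)
    mask <- rasterize_polygons(polys, c(h, w))
    px <- matrix(clip01(0.22 + stats::rnorm(h * w, 0, 0.02)), h, w)
    for (k in seq_len(n)) {
      sel <- mask$labels == k
      px[sel] <- clip01(profile$intensity_mean +
                          stats::rnorm(sum(sel), 0, profile$contrast_level))
    }
    list(image = gray_image(px), mask = mask)
  })
}

# one seeded attempt at drawing and placing all region outlines;
# returns NULL when rejection sampling runs out of tries
try_place_case <- function(profile, h, w) {
  n <- if (profile$n_regions_range[1] == profile$n_regions_range[2]) {
    profile$n_regions_range[1]
  } else {
    sample(profile$n_regions_range[1]:profile$n_regions_range[2], 1)
  }
  lo <- profile$area_range[1]; hi <- profile$area_range[2]
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:300) {
      a_target <- stats::runif(1, lo + 0.2 * (hi - lo), hi - 0.2 * (hi - lo))
      r0 <- sqrt(a_target / pi)
      r_max <- r0 * (1 + 0.65 * (1 - profile$circularity_target)) + 1
      cx <- stats::runif(1, r_max + 2, w - r_max - 1)
      cy <- stats::runif(1, r_max + 2, h - r_max - 1)
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(d < radii + r_max + 2)) next
      }
      # iterate the radius until the rasterized pixel count is in range
      ok <- FALSE
      for (adj in 1:6) {
        poly <- blob_polygon(cx, cy, r0, profile$circularity_target)
        cnt <- sum(polygon_interior(poly, h, w))
        if (cnt >= lo && cnt <= hi) { ok <- TRUE; break }
        if (cnt <= 0) break
        r0 <- r0 * sqrt(a_target / cnt)
        if (r0 > r_max) r0 <- r_max - 1
      }
      if (!ok) next
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r_max)
      polys[[i]] <- polygon_annotation(poly, profile$class_name)
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  polys
}

# one clockwise quarter turn
rot_quarter <- function(m) {
  t(m[nrow(m):1, , drop = FALSE])
}

# uniform rescale about the canvas center back onto the same canvas;
# bilinear for images, nearest neighbor for masks, 0-padded.
rescale_canvas <- function(m, s, nearest) {
  h <- nrow(m); w <- ncol(m)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ro <- rep(seq_len(h), times = w); co <- rep(seq_len(w), each = h)
  rs <- cy + (ro - cy) / s
  cs <- cx + (co - cx) / s
  out <- numeric(h * w)
  if (nearest) {
    ri <- round(rs); ci <- round(cs)
    valid <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out[valid] <- m[cbind(ri[valid], ci[valid])]
  } else {
    r0 <- floor(rs); c0 <- floor(cs)
    fr <- rs - r0; fc <- cs - c0
    g <- function(ri, ci) {
      v <- numeric(length(ri))
      valid <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v[valid] <- m[cbind(ri[valid], ci[valid])]
      v
    }
    out <- (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c0 + 1) +
      fr * (1 - fc) * g(r0 + 1, c0) + fr * fc * g(r0 + 1, c0 + 1)
  }
  matrix(out, h, w)
}

#' Paired image/mask augmentation
#'
#' Applies the same geometric transform (quarter-turn rotations, horizontal
#' and vertical flips, uniform scaling) to both members of a pair; masks use
#' nearest-neighbor resampling so labels stay integral, and photometric
#' adjustments (brightness shift, contrast gain about 0.5) touch the image
#' only, clipped back to `[0, 1]`.
#'
#' @param image a [gray_image()].
#' @param mask the paired [label_mask()].
#' @param ops either the string `"random"` or a list with any of
#'   `rotate` (0/90/180/270 degrees), `hflip`, `vflip` (logicals),
#'   `scale` (factor), `brightness` (additive shift), `contrast`
#'   (multiplicative gain about 0.5).
#' @param rng_seed integer seed (used only when `ops = "random"`).
#' @return List with transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask, ops = "random", rng_seed = 1L) {
  check_pair(image, mask)
  if (identical(ops, "random")) {
    ops <- with_seed(rng_seed, list(
      rotate = sample(c(0, 90, 180, 270), 1),
      hflip = stats::runif(1) < 0.5,
      vflip = stats::runif(1) < 0.5,
      scale = stats::runif(1, 0.9, 1.1),
      brightness = stats::runif(1, -0.15, 0.15),
      contrast = stats::runif(1, 0.85, 1.15)
    ))
  }
  img <- image$pixels
  msk <- mask$labels
  s <- ops$scale %||% 1
  if (s != 1) {
    img <- rescale_canvas(img, s, nearest = FALSE)
    msk <- rescale_canvas(msk, s, nearest = TRUE)
  }
  k <- ((ops$rotate %||% 0) / 90) %% 4
  for (i in seq_len(k)) {
    img <- rot_quarter(img)
    msk <- rot_quarter(msk)
  }
  if (isTRUE(ops$hflip)) {
    img <- img[, ncol(img):1, drop = FALSE]
    msk <- msk[, ncol(msk):1, drop = FALSE]
  }
  if (isTRUE(ops$vflip)) {
    img <- img[nrow(img):1, , drop = FALSE]
    msk <- msk[nrow(msk):1, , drop = FALSE]
  }
  img <- clip01((img - 0.5) * (ops$contrast %||% 1) + 0.5 + (ops$brightness %||% 0))
  list(image = gray_image(img), mask = label_mask(msk))
}

#' Generate a class-per-directory synthetic dataset on disk
#'
#' Writes `n_per_class` image+mask pairs for each profile into
#' `out_dir/<class>/` (8-bit PNGs) along with a `manifest.csv`
#' (columns: class, image_path, mask_path, seed). Pair generation and the
#' optional random augmentation are both seeded per item so the layout is
#' fully reproducible.
#'
#' @param profiles list of [class_profile()] objects.
#' @param n_per_class pairs per class (>= 1).
#' @param rng_seed global integer seed.
#' @param out_dir output directory (created if missing).
#' @param size canvas size.
#' @param augment apply a random augmentation to every generated pair.
#' @return The manifest as a data.frame, invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(profiles, n_per_class, rng_seed, out_dir,
                             size = c(128, 128), augment = TRUE) {
  stopifnot(n_per_class >= 1, length(profiles) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    cg_stop("cg_io_error", "cannot create output directory %s", out_dir)
  }
  rows <- vector("list", length(profiles) * n_per_class)
  ri <- 0
  for (pf in profiles) {
    cls_dir <- file.path(out_dir, pf$class_name)
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      seed_i <- derive_seed(rng_seed, pf$class_name, i)
      case <- generate_synthetic_case(pf, seed_i, size = size)
      if (augment) {
        case <- augment_pair(case$image, case$mask, "random",
                             rng_seed = derive_seed(seed_i, "aug"))
      }
      ip <- file.path(pf$class_name, sprintf("img_%04d.png", i))
      mp <- file.path(pf$class_name, sprintf("mask_%04d.png", i))
      write_gray_png(case$image, file.path(out_dir, ip))
      write_mask_png(case$mask, file.path(out_dir, mp))
      ri <- ri + 1
      rows[[ri]] <- data.frame(class = pf$class_name, image_path = ip,
                               mask_path = mp, seed = seed_i,
                               stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
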