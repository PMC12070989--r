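# Per-region geometric, GLCM texture and intensity features.

#' Canonical feature names
#'
#' The 14 per-region features, in the fixed order used by feature tables,
#' CSV files, graph node attributes and the GCN input layer.
#' @export
cg_feature_names <- c(
  "area", "perimeter", "eccentricity", "solidity", "major_axis", "minor_axis",
  "aspect_ratio", "compactness", "circularity",
  "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity",
  "mean_intensity"
)

#' GLCM configuration
#'
#' Controls gray-level co-occurrence matrix estimation: intensities in
#' `[0, 1]` are quantized to `levels` bins, pairs are accumulated at each
#' `distances` x `angles` offset for pixel pairs that both fall inside the
#' region, then (optionally) symmetrized and normalized before the four
#' Haralick statistics are computed and averaged over offsets.
#'
#' @param levels number of quantization bins (>= 2).
#' @param distances positive integer offsets.
#' @param angles offsets in degrees, each one of 0, 45, 90, 135.
#' @param symmetric accumulate pairs in both directions.
#' @param normalize divide counts by their total.
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(levels = 32L, distances = 1L,
                        angles = c(0, 45, 90, 135),
                        symmetric = TRUE, normalize = TRUE) {
  stopifnot(levels >= 2, all(distances >= 1), all(angles %in% c(0, 45, 90, 135)))
  structure(list(levels = as.integer(levels), distances = as.integer(distances),
                 angles = angles, symmetric = symmetric, normalize = normalize),
            class = "glcm_config")
}

#' Extract connected regions from a label mask
#'
#' One region per 8-connected component of each positive label, ordered by
#' ascending label and then by the scanline (row-major) position of the
#' component's first pixel. Background (label 0) is excluded.
#'
#' @param mask a [label_mask()].
#' @return List of regions; each has `region_id`, `label` and `pixels`
#'   (a 2-column matrix of `(row, col)` coordinates).
#' @export
extract_regions <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  h <- nrow(lab); w <- ncol(lab)
  fg <- which(lab > 0)
  if (length(fg) == 0) {
    cg_stop("cg_empty_mask_error", "mask has no foreground regions")
  }
  # linear (column-major) indices of 8-neighbor same-label pairs
  edges <- integer(0)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (sh in shifts) {
    dr <- sh[1]; dc <- sh[2]
    if (max(1, 1 - dr) > min(h, h - dr) ||
        max(1, 1 - dc) > min(w, w - dc)) next
    r1 <- max(1, 1 - dr):min(h, h - dr)
    c1 <- max(1, 1 - dc):min(w, w - dc)
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + dr, c1 + dc, drop = FALSE]
    hit <- which(a > 0 & a == b)
    if (length(hit) > 0) {
      rr <- ((hit - 1) %% length(r1)) + 1
      cc <- ((hit - 1) %/% length(r1)) + 1
      i1 <- (c1[cc] - 1) * h + r1[rr]
      i2 <- (c1[cc] + dc - 1) * h + r1[rr] + dr
      edges <- c(edges, rbind(match(i1, fg), match(i2, fg)))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  rows <- ((fg - 1) %% h) + 1
  cols <- ((fg - 1) %/% h) + 1
  regions <- lapply(seq_len(max(comp)), function(k) {
    sel <- comp == k
    list(label = lab[fg[sel][1]],
         pixels = cbind(row = rows[sel], col = cols[sel]))
  })
  # order by label, then scanline position of first pixel
  first_pos <- vapply(regions, function(r) {
    min((r$pixels[, "row"] - 1) * w + r$pixels[, "col"])
  }, numeric(1))
  labs <- vapply(regions, `[[`, numeric(1), "label")
  ord <- order(labs, first_pos)
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$region_id <- i
  regions
}

# Moore-neighbor boundary tracing; chain length with sqrt(2) diagonal weight.
# `inside` is a logical matrix holding one 8-connected component.
chain_perimeter <- function(inside) {
  if (sum(inside) == 1) return(4) # unit-square boundary convention
  nr <- nrow(inside); nc <- ncol(inside)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- inside
  idx <- which(pad, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  start <- idx[1, ]
  offs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1)) # clockwise from W
  cur <- start; backtrack <- 1
  chain <- 0; first <- TRUE
  limit <- 8 * sum(inside) + 16
  steps <- 0
  repeat {
    found <- FALSE
    for (k in 0:7) {
      j <- ((backtrack - 1 + k) %% 8) + 1
      cand <- cur + offs[j, ]
      if (pad[cand[1], cand[2]]) {
        step <- cand - cur
        chain <- chain + if (all(abs(step) == 1)) sqrt(2) else 1
        bo <- cur - cand
        bidx <- which(offs[, 1] == bo[1] & offs[, 2] == bo[2])
        backtrack <- (bidx %% 8) + 1
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) return(4) # isolated pixel (cannot happen for connected sets)
    if (all(cur == start) && !first) break
    first <- FALSE
    steps <- steps + 1
    if (steps > limit) break # safety; degenerate thin shapes
  }
  chain
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Geometric features of a single region
#'
#' Area is the pixel count; perimeter is the Moore-boundary chain length
#' (diagonal steps weighted `sqrt(2)`); axes and eccentricity come from the
#' second-order central moments of the pixel set (each pixel contributes a
#' 1/12 unit-square term, which also floors the minor axis for degenerate
#' one-pixel-wide regions); solidity is area over the convex-hull area of
#' the pixel corner points; circularity is `4*pi*A/P^2` and compactness its
#' reciprocal.
#'
#' @param region a region as returned by [extract_regions()].
#' @return Named numeric vector of the 9 geometric features.
#' @export
geometric_features <- function(region) {
  px <- region$pixels
  if (is.null(px) || nrow(px) == 0) {
    cg_stop("cg_region_error", "empty region")
  }
  a <- nrow(px)
  r <- px[, "row"]; cc <- px[, "col"]
  # perimeter on the region's own bounding box
  rr <- r - min(r) + 1; ccc <- cc - min(cc) + 1
  sub <- matrix(FALSE, max(rr), max(ccc))
  sub[cbind(rr, ccc)] <- TRUE
  per <- chain_perimeter(sub)
  # moments (pixel-extent corrected)
  mu20 <- (if (a > 1) stats::var(r) * (a - 1) / a else 0) + 1 / 12
  mu02 <- (if (a > 1) stats::var(cc) * (a - 1) / a else 0) + 1 / 12
  mu11 <- if (a > 1) sum((r - mean(r)) * (cc - mean(cc))) / a else 0
  tr <- mu20 + mu02
  det_b <- sqrt(4 * mu11^2 + (mu20 - mu02)^2)
  l1 <- (tr + det_b) / 2
  l2 <- (tr - det_b) / 2
  l2 <- max(l2, 1 / 12) # unit pixel floor
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- sqrt(max(0, 1 - l2 / l1))
  # convex hull of pixel corners
  corners <- rbind(cbind(cc - 0.5, r - 0.5), cbind(cc + 0.5, r - 0.5),
                   cbind(cc - 0.5, r + 0.5), cbind(cc + 0.5, r + 0.5))
  hull <- grDevices::chull(corners)
  hull_area <- shoelace_area(corners[hull, 1], corners[hull, 2])
  solidity <- min(a / hull_area, 1)
  circ <- 4 * pi * a / per^2
  c(area = a, perimeter = per, eccentricity = ecc, solidity = solidity,
    major_axis = major, minor_axis = minor, aspect_ratio = major / minor,
    compactness = per^2 / (4 * pi * a), circularity = circ)
}

#' GLCM texture features of a region
#'
#' Quantizes the image to `cfg$levels` equal-width bins over `[0, 1]`,
#' accumulates co-occurrence counts for pixel pairs that are *both* inside
#' the region at each configured offset, symmetrizes and normalizes the
#' matrix, computes contrast, correlation, energy and homogeneity, and
#' averages the statistics over offsets that contributed at least one pair.
#' Correlation of a constant region is reported as 0 by convention.
#'
#' @param image a [gray_image()].
#' @param region a region from [extract_regions()].
#' @param cfg a [glcm_config()].
#' @return Named numeric vector `(glcm_contrast, glcm_correlation,
#'   glcm_energy, glcm_homogeneity)`.
#' @export
glcm_features <- function(image, region, cfg = glcm_config()) {
  stopifnot(inherits(image, "gray_image"), inherits(cfg, "glcm_config"))
  px <- region$pixels
  L <- cfg$levels
  q <- pmin(floor(image$pixels * L), L - 1) + 1 # 1..L
  # region bounding box with membership
  r0 <- min(px[, "row"]); c0 <- min(px[, "col"])
  rr <- px[, "row"] - r0 + 1; ccc <- px[, "col"] - c0 + 1
  hh <- max(rr); ww <- max(ccc)
  inr <- matrix(FALSE, hh, ww)
  inr[cbind(rr, ccc)] <- TRUE
  sub <- matrix(0L, hh, ww)
  sub[cbind(rr, ccc)] <- q[cbind(px[, "row"], px[, "col"])]
  stats_list <- list()
  total_pairs <- 0
  for (d in cfg$distances) {
    for (ang in cfg$angles) {
      off <- switch(as.character(ang),
                    "0" = c(0L, d), "45" = c(-d, d),
                    "90" = c(-d, 0L), "135" = c(-d, -d))
      dr <- off[1]; dc <- off[2]
      if (max(1, 1 - dr) > min(hh, hh - dr) ||
          max(1, 1 - dc) > min(ww, ww - dc)) next
      r1 <- max(1, 1 - dr):min(hh, hh - dr)
      c1 <- max(1, 1 - dc):min(ww, ww - dc)
      a_in <- inr[r1, c1, drop = FALSE] & inr[r1 + dr, c1 + dc, drop = FALSE]
      if (!any(a_in)) next
      va <- sub[r1, c1, drop = FALSE][a_in]
      vb <- sub[r1 + dr, c1 + dc, drop = FALSE][a_in]
      total_pairs <- total_pairs + length(va)
      P <- matrix(0, L, L)
      tab <- table(factor(va, levels = 1:L), factor(vb, levels = 1:L))
      P <- P + unclass(tab)
      if (cfg$symmetric) P <- P + t(P)
      if (cfg$normalize) P <- P / sum(P)
      stats_list[[length(stats_list) + 1]] <- haralick_stats(P)
    }
  }
  if (total_pairs < 2) {
    cg_stop("cg_texture_error",
            "region too small for texture: %d co-occurring pair(s)", total_pairs)
  }
  m <- do.call(rbind, stats_list)
  colMeans(m)
}

# contrast, correlation, energy, homogeneity from a normalized GLCM
haralick_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(rep(1:L, L), L)
  j <- t(i)
  contrast <- sum(P * (i - j)^2)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  pi_m <- rowSums(P); pj_m <- colSums(P)
  mu_i <- sum((1:L) * pi_m); mu_j <- sum((1:L) * pj_m)
  s_i <- sqrt(sum((1:L - mu_i)^2 * pi_m))
  s_j <- sqrt(sum((1:L - mu_j)^2 * pj_m))
  correlation <- if (s_i * s_j == 0) 0 else {
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
  }
  c(glcm_contrast = contrast, glcm_correlation = correlation,
    glcm_energy = energy, glcm_homogeneity = homogeneity)
}

#' Feature table for one image + mask pair
#'
#' One row per connected region combining geometric, GLCM and mean-intensity
#' features, in deterministic region order.
#'
#' @param image a [gray_image()].
#' @param mask the paired [label_mask()].
#' @param class_label class string attached to the table.
#' @param cfg a [glcm_config()].
#' @param image_path,mask_path optional provenance strings.
#' @param min_area drop connected components smaller than this pixel count
#'   (default 0: keep every region). Pipeline stages use a small positive
#'   value to discard satellite fragments created by mask resampling, which
#'   are too small to carry texture.
#' @return An object of class `feature_table`: list with `class_label`,
#'   `features` (data.frame `region_id` + the 14 features) and source paths.
#' @export
extract_feature_table <- function(image, mask, class_label,
                                  cfg = glcm_config(),
                                  image_path = NA_character_,
                                  mask_path = NA_character_,
                                  min_area = 0L) {
  check_pair(image, mask)
  regions <- extract_regions(mask)
  if (min_area > 0) {
    regions <- Filter(function(r) nrow(r$pixels) >= min_area, regions)
    if (length(regions) == 0) {
      cg_stop("cg_empty_mask_error", "no region of at least %d px", min_area)
    }
  }
  rows <- lapply(regions, function(reg) {
    geo <- geometric_features(reg)
    tex <- glcm_features(image, reg, cfg)
    mi <- mean(image$pixels[reg$pixels])
    c(region_id = reg$region_id, geo, tex, mean_intensity = mi)
  })
  df <- as.data.frame(do.call(rbind, rows))
  feature_table(df, class_label, image_path, mask_path)
}

#' @rdname extract_feature_table
#' @param features data.frame with `region_id` plus the 14 feature columns.
#' @export
feature_table <- function(features, class_label,
                          image_path = NA_character_, mask_path = NA_character_) {
  need <- c("region_id", cg_feature_names)
  if (!all(need %in% names(features))) {
    cg_stop("cg_table_error", "feature table misses columns: %s",
            paste(setdiff(need, names(features)), collapse = ", "))
  }
  if (nrow(features) < 1) {
    cg_stop("cg_table_error", "feature table must have at least one row")
  }
  if (anyDuplicated(features$region_id)) {
    cg_stop("cg_table_error", "duplicate region_ids in feature table")
  }
  structure(list(class_label = as.character(class_label),
                 features = features[, need],
                 image_path = image_path, mask_path = mask_path),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table class=%s, %d region(s) x %d features>\n",
              x$class_label, nrow(x$features), length(cg_feature_names)))
  invisible(x)
}

# feature matrix (rows = regions, cols = the 14 features)
feature_matrix <- function(table) {
  as.matrix(table$features[, cg_feature_names])
}

#' Read and write feature tables as CSV
#'
#' Fixed schema, in order: `class, region_id,` then the 14 feature columns.
#' Numbers are written with 10 significant digits so a round trip is
#' lossless at that precision.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `read_feature_csv` returns a [feature_table()].
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- table$features
  out <- data.frame(class = table$class_label, df, stringsAsFactors = FALSE)
  num_cols <- setdiff(names(out), "class")
  for (nm in num_cols) out[[nm]] <- sprintf("%.10g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("class", "region_id", cg_feature_names)
  if (!identical(names(df), need)) {
    cg_stop("cg_format_error", "unexpected feature CSV header in %s", path)
  }
  feature_table(df[, -1], class_label = df$class[1])
}
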