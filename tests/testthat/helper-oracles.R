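# Independent brute-force oracles. These deliberately reimplement the
# operations with scalar loops and different algorithmic formulations so
# they share no code path with the package implementation.

# Even-odd point-in-polygon, scalar per pixel: parametric edge crossings of
# a rightward ray, plus explicit on-segment check.
pip_oracle <- function(vertices, h, w) {
  xs <- vertices[, 1]; ys <- vertices[, 2]
  n <- length(xs)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      px <- c; py <- r
      crossings <- 0
      on_b <- FALSE
      for (e in seq_len(n)) {
        x1 <- xs[e]; y1 <- ys[e]
        x2 <- xs[e %% n + 1]; y2 <- ys[e %% n + 1]
        # on-segment
        if (abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) < 1e-9 *
              max(1, sqrt((x2 - x1)^2 + (y2 - y1)^2)) &&
            px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
            py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9) {
          on_b <- TRUE
          break
        }
        if ((y1 > py) != (y2 > py)) {
          t <- (py - y1) / (y2 - y1)
          xi <- x1 + t * (x2 - x1)
          if (px < xi) crossings <- crossings + 1
        }
      }
      out[r, c] <- on_b || (crossings %% 2 == 1)
    }
  }
  out
}

# GLCM statistics by naive per-pixel pair enumeration.
glcm_oracle <- function(pixels, region_logical, levels,
                        angles = c(0, 45, 90, 135), d = 1) {
  q <- pmin(floor(pixels * levels), levels - 1) + 1
  h <- nrow(pixels); w <- ncol(pixels)
  per_angle <- list()
  for (ang in angles) {
    off <- switch(as.character(ang), "0" = c(0, d), "45" = c(-d, d),
                  "90" = c(-d, 0), "135" = c(-d, -d))
    P <- matrix(0, levels, levels)
    npairs <- 0
    for (r in seq_len(h)) {
      for (c in seq_len(w)) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            region_logical[r, c] && region_logical[r2, c2]) {
          P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
          npairs <- npairs + 1
        }
      }
    }
    if (npairs == 0) next
    P <- P + t(P)
    P <- P / sum(P)
    i <- row(P); j <- col(P)
    mu_i <- sum(i * P); mu_j <- sum(j * P)
    s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
    per_angle[[length(per_angle) + 1]] <- c(
      glcm_contrast = sum(P * (i - j)^2),
      glcm_correlation = if (s_i * s_j == 0) 0 else
        sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j),
      glcm_energy = sum(P^2),
      glcm_homogeneity = sum(P / (1 + abs(i - j))))
  }
  colMeans(do.call(rbind, per_angle))
}

# Dense two-layer GCN forward with explicit scalar sums.
forward_oracle <- function(params, graph, X = NULL) {
  nodes <- graph$nodes
  n <- nrow(nodes)
  if (is.null(X)) X <- as.matrix(nodes[, cg_feature_names])
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[e]; j <- graph$edges$j[e]
    A[i, j] <- graph$edges$weight[e]; A[j, i] <- graph$edges$weight[e]
  }
  At <- A + diag(n)
  deg <- rowSums(At)
  Ahat <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) Ahat[i, j] <- At[i, j] / sqrt(deg[i] * deg[j])
  matmul <- function(P, Q) {
    R <- matrix(0, nrow(P), ncol(Q))
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(Q)))
      R[i, j] <- sum(P[i, ] * Q[, j])
    R
  }
  H1 <- matmul(matmul(Ahat, X), params$W1); H1[H1 < 0] <- 0
  H2 <- matmul(matmul(Ahat, H1), params$W2); H2[H2 < 0] <- 0
  hg <- apply(H2, 2, mean)
  logits <- as.numeric(t(params$Wc) %*% hg) + params$bc
  e <- exp(logits - max(logits))
  list(logits = logits, probs = e / sum(e))
}

# AUC as the Mann-Whitney concordant-pair statistic.
auc_pair_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small random feature table (positive-ish values, fixed seed)
random_table <- function(n, seed, class_label = "x") {
  set.seed(seed)
  df <- data.frame(region_id = seq_len(n),
                   matrix(abs(rnorm(n * 14)), n,
                          dimnames = list(NULL, cg_feature_names)))
  feature_table(df, class_label)
}

# separable 2-class graph items: class feature means far apart
separable_items <- function(n_per_class, seed, gap = 3) {
  items <- list()
  for (cls in 0:1) {
    for (i in seq_len(n_per_class)) {
      set.seed(seed + 1000 * cls + i)
      df <- data.frame(region_id = 1:4,
                       matrix(abs(rnorm(4 * 14, mean = 1 + gap * cls)), 4,
                              dimnames = list(NULL, cg_feature_names)))
      items[[length(items) + 1]] <-
        list(graph = build_full_graph(feature_table(df, paste0("c", cls))),
             label = cls)
    }
  }
  items
}

# cached five-class synthetic feature tables (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

five_class_tables <- function(images_per_class = 4, seed = 2024) {
  key <- sprintf("tabs_%d_%d", images_per_class, seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  profiles <- default_class_profiles()
  tabs <- lapply(profiles, function(pf) {
    parts <- lapply(seq_len(images_per_class), function(i) {
      case <- generate_synthetic_case(pf, cervigraph:::derive_seed(seed, pf$class_name, i))
      extract_feature_table(case$image, case$mask, pf$class_name)$features
    })
    pooled <- do.call(rbind, parts)
    pooled$region_id <- seq_len(nrow(pooled))
    feature_table(pooled, pf$class_name)
  })
  .fixture_env[[key]] <- tabs
  tabs
}
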