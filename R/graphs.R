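# Inverse-distance weighted lesion graphs built from feature tables.

#' Lesion graph container
#'
#' Undirected weighted graph whose nodes carry the 14-dimensional region
#' feature vectors. Edges are stored once per unordered pair (`i < j`), with
#' strictly positive finite weights; self-loops are never stored.
#'
#' @param nodes data.frame with `node_id` plus the 14 feature columns.
#' @param edges data.frame with columns `i`, `j`, `weight` (may have 0 rows).
#' @param class_label class string.
#' @param provenance list with at least `kind` (`"original"` or
#'   `"augmented"`); augmented graphs also record `seed` and the threshold
#'   fraction `u`.
#' @return An object of class `lesion_graph`.
#' @export
lesion_graph <- function(nodes, edges, class_label,
                         provenance = list(kind = "original")) {
  stopifnot(is.data.frame(nodes), all(c("node_id", cg_feature_names) %in% names(nodes)))
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("i", "j", "weight") %in% names(edges)))
    if (any(edges$i >= edges$j)) {
      cg_stop("cg_graph_error", "edges must satisfy i < j (undirected, no self-loops)")
    }
    if (anyDuplicated(edges[, c("i", "j")])) {
      cg_stop("cg_graph_error", "duplicate edges")
    }
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
      cg_stop("cg_graph_error", "edge weights must be positive and finite")
    }
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  }
  nodes <- nodes[, c("node_id", cg_feature_names)]
  edges <- edges[, c("i", "j", "weight")]
  nodes$node_id <- as.integer(nodes$node_id)
  edges$i <- as.integer(edges$i)
  edges$j <- as.integer(edges$j)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes,
                 edges = edges,
                 class_label = as.character(class_label),
                 provenance = provenance),
            class = "lesion_graph")
}

#' @export
print.lesion_graph <- function(x, ...) {
  cat(sprintf("<lesion_graph class=%s (%s): %d nodes, %d edges>\n",
              x$class_label, x$provenance$kind, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Inverse-distance edge weight
#'
#' `w = 1 / (||f_i - f_j|| + epsilon)` with Euclidean distance; `epsilon`
#' guards the zero-distance case.
#'
#' @param f_i,f_j equal-length finite numeric vectors.
#' @param epsilon small positive constant (default `1e-8`).
#' @return Positive finite weight.
#' @export
edge_weight <- function(f_i, f_j, epsilon = 1e-8) {
  stopifnot(length(f_i) == length(f_j), epsilon > 0)
  if (any(!is.finite(f_i)) || any(!is.finite(f_j))) {
    cg_stop("cg_numeric_error", "non-finite feature values in edge_weight")
  }
  1 / (sqrt(sum((f_i - f_j)^2)) + epsilon)
}

pairwise_dist <- function(X) {
  as.matrix(stats::dist(X, method = "euclidean"))
}

#' Fully connected lesion graph from a feature table
#'
#' One node per table row; every unordered pair is connected with the
#' inverse-distance weight computed on the feature vectors.
#'
#' @param table a [feature_table()].
#' @param epsilon weight regularizer.
#' @param standardize compute the distances on per-table z-scored features
#'   (node attributes stay raw). Off by default: weights then follow the
#'   literal inverse-distance formula on raw feature values.
#' @return A [lesion_graph()] with `n*(n-1)/2` edges.
#' @export
build_full_graph <- function(table, epsilon = 1e-8, standardize = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  X <- feature_matrix(table)
  n <- nrow(X)
  D <- if (n > 1) pairwise_dist(zscore_if(X, standardize)) else matrix(0, 1, 1)
  edges <- if (n > 1) {
    idx <- which(upper.tri(D), arr.ind = TRUE)
    data.frame(i = idx[, 1], j = idx[, 2], weight = 1 / (D[idx] + epsilon))
  } else {
    data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  }
  nodes <- data.frame(node_id = seq_len(n), X)
  lesion_graph(nodes, edges, table$class_label, list(kind = "original"))
}

zscore_if <- function(X, standardize) {
  if (!standardize) return(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Graph augmentation configuration
#'
#' States the stochastic regime for augmented graph generation: Gaussian
#' feature noise (s.d. = `noise_fraction` of each feature's per-table s.d.,
#' applied to `noisy_features` only) and an edge-creation threshold drawn
#' uniformly from `threshold_range` (as a fraction of the maximum pairwise
#' feature-space distance).
#'
#' @param n_graphs_per_class graphs generated per class (default 500).
#' @param noise_fraction fraction of the per-feature s.d. (default 0.05).
#' @param noisy_features features that receive noise.
#' @param threshold_range `(low, high)` fractions in `(0, 1]`.
#' @param epsilon edge-weight regularizer.
#' @param rng_seed master seed for [generate_augmented_set()].
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(n_graphs_per_class = 500L, noise_fraction = 0.05,
                           noisy_features = c("area", "perimeter", "eccentricity",
                                              "mean_intensity", "glcm_contrast"),
                           threshold_range = c(0.30, 0.60),
                           epsilon = 1e-8, rng_seed = 1L) {
  stopifnot(noise_fraction >= 0, length(threshold_range) == 2,
            threshold_range[1] > 0, threshold_range[1] < threshold_range[2],
            threshold_range[2] <= 1,
            all(noisy_features %in% cg_feature_names))
  structure(list(n_graphs_per_class = as.integer(n_graphs_per_class),
                 noise_fraction = noise_fraction,
                 noisy_features = noisy_features,
                 threshold_range = threshold_range,
                 epsilon = epsilon, rng_seed = as.integer(rng_seed)),
            class = "augment_config")
}

# valid range per feature, re-applied after noise injection (only to the
# features that actually received noise, so untouched columns stay
# bit-identical)
feature_ranges <- list(
  area = c(1, Inf), perimeter = c(1e-6, Inf),
  eccentricity = c(0, 1 - 1e-9), solidity = c(1e-9, 1),
  major_axis = c(1e-6, Inf), minor_axis = c(1e-6, Inf),
  aspect_ratio = c(1, Inf), compactness = c(1e-9, Inf),
  circularity = c(1e-9, Inf), glcm_contrast = c(0, Inf),
  glcm_correlation = c(-1, 1), glcm_energy = c(1e-9, 1),
  glcm_homogeneity = c(1e-9, 1), mean_intensity = c(0, 1)
)

feature_floors <- function(df, cols) {
  for (nm in cols) {
    rg <- feature_ranges[[nm]]
    df[[nm]] <- pmin(pmax(df[[nm]], rg[1]), rg[2])
  }
  df
}

#' Add Gaussian noise to selected features
#'
#' Each feature named in `cfg$noisy_features` receives independent
#' `N(0, (noise_fraction * sigma_feature)^2)` noise, where `sigma_feature`
#' is the sample s.d. across the table's rows. Other features are untouched
#' and valid ranges are re-clipped. A single-row table has undefined sigma:
#' noise is skipped with a warning.
#'
#' @param table a [feature_table()].
#' @param cfg an [augment_config()].
#' @param draw_seed integer seed for this draw.
#' @return A perturbed [feature_table()].
#' @export
perturb_features <- function(table, cfg, draw_seed) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "augment_config"))
  df <- table$features
  if (nrow(df) < 2) {
    warning("single-row table: feature s.d. undefined, noise skipped")
    return(table)
  }
  if (cfg$noise_fraction > 0) {
    df <- with_seed(draw_seed, {
      for (nm in cfg$noisy_features) {
        sigma <- stats::sd(df[[nm]])
        if (is.finite(sigma) && sigma > 0) {
          df[[nm]] <- df[[nm]] + stats::rnorm(nrow(df), 0, cfg$noise_fraction * sigma)
        }
      }
      df
    })
    df <- feature_floors(df, cfg$noisy_features)
  }
  feature_table(df, table$class_label, table$image_path, table$mask_path)
}

#' Noise-augmented, threshold-pruned lesion graph
#'
#' Perturbs the table's features, draws a threshold fraction
#' `u ~ Uniform(threshold_range)`, and connects node pairs whose Euclidean
#' feature distance is at most `u` times the maximum pairwise distance,
#' weighted by the inverse-distance formula. The drawn `u` and the seed are
#' recorded in the graph's provenance.
#'
#' @param table a [feature_table()] with at least 2 rows.
#' @param cfg an [augment_config()].
#' @param draw_seed integer seed for this graph.
#' @param standardize compute distances on per-table z-scored features.
#' @return A [lesion_graph()] with provenance `kind = "augmented"`.
#' @export
build_augmented_graph <- function(table, cfg, draw_seed, standardize = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "augment_config"))
  if (nrow(table$features) < 2) {
    cg_stop("cg_augment_error", "augmented graphs need at least 2 regions")
  }
  pert <- perturb_features(table, cfg, derive_seed(draw_seed, "perturb"))
  u <- with_seed(derive_seed(draw_seed, "threshold"),
                 stats::runif(1, cfg$threshold_range[1], cfg$threshold_range[2]))
  X <- feature_matrix(pert)
  D <- pairwise_dist(zscore_if(X, standardize))
  d_max <- max(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  keep <- D[idx] <= u * d_max
  edges <- data.frame(i = idx[keep, 1], j = idx[keep, 2],
                      weight = 1 / (D[idx][keep] + cfg$epsilon))
  nodes <- data.frame(node_id = seq_len(nrow(X)), X)
  lesion_graph(nodes, edges, table$class_label,
               list(kind = "augmented", seed = draw_seed, u = u))
}

#' Generate the augmented graph collection
#'
#' Exactly `cfg$n_graphs_per_class` graphs per class table, with per-graph
#' seeds derived deterministically from `cfg$rng_seed`, the class name and
#' the graph index. If `out_dir` is given, graphs are written as GML under
#' `out_dir/<class>/` with a `manifest.csv` (class, path, provenance, u,
#' seed).
#'
#' @param tables named list of per-class [feature_table()] objects.
#' @param cfg an [augment_config()].
#' @param out_dir optional output directory.
#' @param standardize passed through to [build_augmented_graph()].
#' @return List with `graphs` (list of [lesion_graph()]) and `manifest`
#'   (data.frame).
#' @export
generate_augmented_set <- function(tables, cfg, out_dir = NULL, standardize = FALSE) {
  stopifnot(length(tables) >= 1)
  graphs <- list()
  rows <- list()
  for (tb in tables) {
    cls <- tb$class_label
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, cls), recursive = TRUE, showWarnings = FALSE)
    }
    for (g in seq_len(cfg$n_graphs_per_class)) {
      seed_g <- derive_seed(cfg$rng_seed, cls, g)
      gr <- build_augmented_graph(tb, cfg, seed_g, standardize = standardize)
      graphs[[length(graphs) + 1]] <- gr
      path <- file.path(cls, sprintf("graph_%04d.gml", g))
      if (!is.null(out_dir)) write_gml(gr, file.path(out_dir, path))
      rows[[length(rows) + 1]] <- data.frame(
        class = cls, path = path, provenance = "augmented",
        u = gr$provenance$u, seed = seed_g, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(graphs = graphs, manifest = manifest)
}
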