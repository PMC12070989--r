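# Graph construction, feature perturbation, augmentation, GML round trips.

test_that("edge_weight follows the inverse-distance formula", {
  expect_equal(edge_weight(c(1, 2), c(1, 2), 1e-8), 1e8)
  expect_equal(edge_weight(c(0, 0), c(3, 4), 1e-8), 1 / (5 + 1e-8))
  set.seed(1)
  for (rep in 1:10) {
    a <- rnorm(14); b <- rnorm(14)
    expect_identical(edge_weight(a, b), edge_weight(b, a)) # symmetry
  }
  expect_error(edge_weight(c(1, NA), c(1, 2)), class = "cg_numeric_error")
})

test_that("full graphs are complete with oracle-checked weights", {
  expect_equal(nrow(build_full_graph(random_table(1, 3))$edges), 0)
  g5 <- build_full_graph(random_table(5, 4))
  expect_equal(nrow(g5$edges), 10) # n(n-1)/2
  # brute-force recomputation from a CSV round trip
  tb <- random_table(7, 5)
  f <- tempfile(fileext = ".csv")
  write_feature_csv(tb, f)
  tb2 <- read_feature_csv(f)
  g <- build_full_graph(tb2)
  X <- as.matrix(tb2$features[, cg_feature_names])
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges$i[e]; j <- g$edges$j[e]
    expect_equal(g$edges$weight[e],
                 1 / (sqrt(sum((X[i, ] - X[j, ])^2)) + 1e-8),
                 tolerance = 1e-9)
  }
})

test_that("perturb_features adds the stated noise and nothing else", {
  tb <- random_table(6, 12)
  cfg0 <- augment_config(noise_fraction = 0)
  expect_equal(perturb_features(tb, cfg0, 5)$features, tb$features)
  cfg <- augment_config(noise_fraction = 0.05)
  pert <- perturb_features(tb, cfg, 5)
  quiet <- setdiff(cg_feature_names, cfg$noisy_features)
  expect_identical(pert$features[, quiet], tb$features[, quiet])
  expect_false(identical(pert$features$area, tb$features$area))
  # single-row table: noise skipped with a warning
  expect_warning(perturb_features(random_table(1, 2), cfg, 1), "skipped")
})

test_that("perturbation noise recovers its configured standard deviation", {
  # 10,000 noise draws on 'area': 2000 seeded perturbations x 5 rows
  tb <- random_table(5, 77)
  cfg <- augment_config(noise_fraction = 0.05,
                        noisy_features = "glcm_homogeneity")
  # use a feature whose floors never clip under small noise
  tb$features$glcm_homogeneity <- c(0.41, 0.52, 0.63, 0.44, 0.55)
  sigma <- sd(tb$features$glcm_homogeneity)
  draws <- unlist(lapply(1:2000, function(s) {
    perturb_features(tb, cfg, s)$features$glcm_homogeneity -
      tb$features$glcm_homogeneity
  }))
  expect_length(draws, 10000)
  expect_lt(abs(sd(draws) / (cfg$noise_fraction * sigma) - 1), 0.05)
})

test_that("augmented graphs obey the threshold contract", {
  tabs <- five_class_tables()
  tb <- tabs$CIN1
  cfg <- augment_config(rng_seed = 5)
  us <- numeric(60)
  for (s in 1:60) {
    g <- build_augmented_graph(tb, cfg, s)
    us[s] <- g$provenance$u
    expect_true(all(g$edges$weight > 0 & is.finite(g$edges$weight)))
  }
  expect_true(all(us >= 0.30 & us <= 0.60))
  expect_gt(diff(range(us)), 0.05) # actually random, not constant

  # edge set equals the brute-force re-threshold at the recorded u * Dmax
  g <- build_augmented_graph(tb, cfg, 123)
  pert <- perturb_features(tb, cfg, cervigraph:::derive_seed(123, "perturb"))
  X <- as.matrix(pert$features[, cg_feature_names])
  D <- as.matrix(dist(X))
  want <- which(upper.tri(D) & D <= g$provenance$u * max(D), arr.ind = TRUE)
  got <- as.matrix(g$edges[, c("i", "j")])
  dimnames(got) <- NULL; dimnames(want) <- NULL
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               want[order(want[, 1], want[, 2]), , drop = FALSE])
  # closest pair is connected whenever min dist < 0.3 * max dist
  dmin_pair <- which(D == min(D[upper.tri(D)]), arr.ind = TRUE)[1, ]
  if (min(D[upper.tri(D)]) < 0.3 * max(D)) {
    expect_true(any(g$edges$i == min(dmin_pair) & g$edges$j == max(dmin_pair)))
  }
  # |E| is non-decreasing in u for the fixed perturbed table
  sizes <- vapply(seq(0.3, 0.6, by = 0.05), function(u) {
    sum(D[upper.tri(D)] <= u * max(D))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(build_augmented_graph(random_table(1, 1), cfg, 1),
               class = "cg_augment_error")
})

test_that("generate_augmented_set produces exact counts deterministically", {
  tabs <- five_class_tables()[c("normal", "CIN1")]
  cfg <- augment_config(n_graphs_per_class = 3, rng_seed = 31)
  d1 <- file.path(tempdir(), "ag1"); d2 <- file.path(tempdir(), "ag2")
  unlink(c(d1, d2), recursive = TRUE)
  s1 <- generate_augmented_set(tabs, cfg, out_dir = d1)
  s2 <- generate_augmented_set(tabs, cfg, out_dir = d2)
  expect_length(s1$graphs, 6) # 2 classes x 3
  expect_equal(nrow(s1$manifest), 6)
  for (p in s1$manifest$path) { # identical GML bytes under the same seed
    expect_identical(readLines(file.path(d1, p)), readLines(file.path(d2, p)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("GML round trip is lossless and validates its schema", {
  tabs <- five_class_tables()
  g <- build_full_graph(tabs$CIN2)
  f <- tempfile(fileext = ".gml")
  write_gml(g, f)
  g2 <- read_gml(f)
  expect_equal(g$nodes, g2$nodes, tolerance = 1e-9)
  expect_equal(g$edges, g2$edges, tolerance = 1e-9)
  expect_identical(g$class_label, g2$class_label)
  expect_identical(g$nodes$node_id, g2$nodes$node_id) # order preserved
  # augmented provenance round trip
  ga <- build_augmented_graph(tabs$CIN2, augment_config(), 9)
  fa <- tempfile(fileext = ".gml")
  write_gml(ga, fa)
  ga2 <- read_gml(fa)
  expect_equal(ga$provenance$u, ga2$provenance$u, tolerance = 1e-9)
  # missing classLabel -> format error
  lines <- readLines(f)
  writeLines(lines[!grepl("classLabel", lines)], f)
  expect_error(read_gml(f), class = "cg_format_error")
  # missing weight -> format error
  write_gml(g, f)
  lines <- readLines(f)
  writeLines(lines[!grepl("weight", lines)], f)
  expect_error(read_gml(f), class = "cg_format_error")
})

test_that("stored graphs reject invalid shapes", {
  nodes <- data.frame(node_id = 1:2,
                      matrix(1, 2, 14, dimnames = list(NULL, cg_feature_names)))
  expect_error(lesion_graph(nodes, data.frame(i = 2, j = 1, weight = 1), "x"),
               class = "cg_graph_error")
  expect_error(lesion_graph(nodes, data.frame(i = 1, j = 2, weight = -1), "x"),
               class = "cg_graph_error")
  expect_error(lesion_graph(nodes, data.frame(i = c(1, 1), j = c(2, 2),
                                              weight = c(1, 2)), "x"),
               class = "cg_graph_error")
})
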