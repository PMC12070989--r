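# Region extraction, geometric features, GLCM, CSV serialization.

test_that("extract_regions follows connectivity and ordering contracts", {
  m <- matrix(0L, 8, 8)
  m[2:4, 2:4] <- 1L
  regs <- extract_regions(label_mask(m))
  expect_length(regs, 1)
  expect_equal(nrow(regs[[1]]$pixels), 9)
  # diagonal-touching pixels join under 8-connectivity
  d <- matrix(0L, 8, 8); d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_length(extract_regions(label_mask(d)), 1)
  # two labels -> two regions ordered by label
  two <- matrix(0L, 8, 8); two[2, 2:3] <- 2L; two[6, 6:7] <- 1L
  regs2 <- extract_regions(label_mask(two))
  expect_equal(vapply(regs2, `[[`, numeric(1), "label"), c(1, 2))
  expect_equal(vapply(regs2, `[[`, integer(1), "region_id"), 1:2)
  # same label, two components -> two regions, scanline order
  sp <- matrix(0L, 8, 8); sp[6, 6] <- 1L; sp[2, 2] <- 1L
  regs3 <- extract_regions(label_mask(sp))
  expect_length(regs3, 2)
  expect_equal(unname(regs3[[1]]$pixels[1, ]), c(2, 2))
  expect_error(extract_regions(label_mask(matrix(0L, 8, 8))),
               class = "cg_empty_mask_error")
})

test_that("geometric features match closed forms on canonical shapes", {
  # 10x10 square
  m <- matrix(0L, 16, 16); m[4:13, 4:13] <- 1L
  g <- geometric_features(extract_regions(label_mask(m))[[1]])
  expect_equal(unname(g["area"]), 100)
  expect_equal(unname(g["perimeter"]), 36) # chain around the boundary ring
  expect_equal(unname(g["eccentricity"]), 0)
  expect_equal(unname(g["aspect_ratio"]), 1)
  expect_equal(unname(g["solidity"]), 1)
  expect_equal(unname(g["compactness"]), 1 / unname(g["circularity"]))

  # rasterized disk radius 20: area via pixel enumeration, circularity near 1
  xy <- expand.grid(r = 1:64, c = 1:64)
  disk <- matrix(as.integer((xy$r - 32)^2 + (xy$c - 32)^2 <= 400), 64, 64)
  gd <- geometric_features(extract_regions(label_mask(disk))[[1]])
  expect_equal(unname(gd["area"]), sum(disk))
  expect_gte(unname(gd["circularity"]), 0.9)
  expect_lte(unname(gd["circularity"]), 1.1)
  expect_lt(unname(gd["eccentricity"]), 0.2)

  # 1x20 line: elongated, eccentric; moment formulas by hand
  ln <- matrix(0L, 8, 24); ln[4, 3:22] <- 1L
  gl <- geometric_features(extract_regions(label_mask(ln))[[1]])
  expect_gt(unname(gl["aspect_ratio"]), 10)
  expect_gt(unname(gl["eccentricity"]), 0.95)
  # hand-computed: lambda1 = var(0:19)*19/20 + 1/12, lambda2 = 1/12
  l1 <- var(0:19) * 19 / 20 + 1 / 12
  expect_equal(unname(gl["major_axis"]), 4 * sqrt(l1))
  expect_equal(unname(gl["minor_axis"]), 4 * sqrt(1 / 12))

  # single pixel: degenerate moments handled, not fatal
  px1 <- matrix(0L, 8, 8); px1[4, 4] <- 1L
  g1 <- geometric_features(extract_regions(label_mask(px1))[[1]])
  expect_equal(unname(g1["eccentricity"]), 0)
  expect_equal(unname(g1["area"]), 1)
})

test_that("GLCM statistics match hand-enumerated pair counts", {
  # 2x2 block [[0,0],[1,1]] at 2 levels (embedded in the 8x8 minimum canvas);
  # the region is restricted to the block
  full <- matrix(0, 8, 8)
  full[1:2, 1:2] <- matrix(c(0, 1, 0, 1), 2, 2) # rows: (0,0),(1,1)
  img <- gray_image(full)
  reg <- list(pixels = cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2)))
  horiz <- glcm_features(img, reg, glcm_config(levels = 2, angles = 0))
  expect_equal(unname(horiz["glcm_contrast"]), 0)
  expect_equal(unname(horiz["glcm_energy"]), 0.5)
  expect_equal(unname(horiz["glcm_homogeneity"]), 1)
  expect_equal(unname(horiz["glcm_correlation"]), 1)
  vert <- glcm_features(img, reg, glcm_config(levels = 2, angles = 90))
  expect_equal(unname(vert["glcm_contrast"]), 1)
  expect_equal(unname(vert["glcm_energy"]), 0.5)
  expect_equal(unname(vert["glcm_homogeneity"]), 0.5)
  expect_equal(unname(vert["glcm_correlation"]), -1)
  # constant region: energy 1, correlation 0 by convention
  cimg <- gray_image(matrix(0.4, 8, 8))
  creg <- list(pixels = as.matrix(expand.grid(row = 2:5, col = 2:5)))
  colnames(creg$pixels) <- c("row", "col")
  cst <- glcm_features(cimg, creg, glcm_config(levels = 8))
  expect_equal(unname(cst["glcm_contrast"]), 0)
  expect_equal(unname(cst["glcm_energy"]), 1)
  expect_equal(unname(cst["glcm_homogeneity"]), 1)
  expect_equal(unname(cst["glcm_correlation"]), 0)
  # too-small region
  tiny <- list(pixels = cbind(row = 2, col = 2))
  expect_error(glcm_features(cimg, tiny, glcm_config()),
               class = "cg_texture_error")
})

test_that("GLCM agrees with the brute-force oracle on random small images", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(3:4, 1)
    px <- matrix(runif(n * n), n, n)
    # pad image up to the 8x8 minimum but restrict the region to the n x n block
    full <- matrix(0, 8, 8); full[1:n, 1:n] <- px
    img <- gray_image(full)
    sel <- as.matrix(expand.grid(row = 1:n, col = 1:n))
    colnames(sel) <- c("row", "col")
    lv <- sample(c(4, 8), 1)
    got <- glcm_features(img, list(pixels = sel), glcm_config(levels = lv))
    want <- glcm_oracle(full, full * 0 + (row(full) <= n & col(full) <= n),
                        lv)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("feature tables are translation invariant and 14-dimensional", {
  pf <- default_class_profiles()
  case <- generate_synthetic_case(pf$CIN1, 31, c(96, 96))
  tb <- extract_feature_table(case$image, case$mask, "CIN1")
  expect_equal(ncol(tb$features), 15) # region_id + 14 features
  expect_identical(colnames(tb$features)[-1], cg_feature_names)
  # translate both arrays by (5, 7)
  sh_img <- matrix(0.0, 96, 96); sh_msk <- matrix(0L, 96, 96)
  sh_img[6:96, 8:96] <- case$image$pixels[1:91, 1:89]
  sh_msk[6:96, 8:96] <- case$mask$labels[1:91, 1:89]
  # translation keeps all regions intact here (margins are generous)
  tb2 <- extract_feature_table(gray_image(sh_img), label_mask(sh_msk), "CIN1")
  expect_equal(tb$features[, -1], tb2$features[, -1], tolerance = 1e-9)
})

test_that("feature CSV round trip is lossless and schema-checked", {
  tb <- random_table(5, seed = 8, class_label = "CIN3")
  f <- tempfile(fileext = ".csv")
  write_feature_csv(tb, f)
  tb2 <- read_feature_csv(f)
  expect_equal(tb$features, tb2$features, tolerance = 1e-9)
  expect_identical(tb2$class_label, "CIN3")
  # header mismatch
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3"), bad)
  expect_error(read_feature_csv(bad), class = "cg_format_error")
  # empty table construction violates the >= 1 row invariant
  expect_error(feature_table(tb$features[0, ], "x"), class = "cg_table_error")
  # duplicate region ids
  dup <- tb$features; dup$region_id <- c(1, 1, 2, 3, 4)
  expect_error(feature_table(dup, "x"), class = "cg_table_error")
})
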