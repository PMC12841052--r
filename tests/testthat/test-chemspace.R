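# KDE/occupancy tests are pure R + compiled code (fast); the UMAP tests at
# the bottom share one fitted model to keep worker start-up cost low.

test_that("kde_map matches the scipy gaussian_kde oracle on a frozen fixture", {
  # 10 fixed points; expected densities computed once with
  # scipy.stats.gaussian_kde (Scott's rule) on a 5 x 5 lattice
  pts <- matrix(c(
    -1.1836820255, -0.4942293212, 2.2318878919, -0.0448204647,
     1.6803463495,  0.2616830330, -0.6546954696, 0.2335617763,
    -0.1748931767, -0.4579112929,  0.4457509780, -1.4207443252,
     2.0882491562, -0.7368717401,  1.8004041295, -0.0909431009,
     2.5980496194, -0.7279755310, -0.1676922847, 0.0702153012),
    ncol = 2, byrow = TRUE)
  grid <- list(gx = seq(-3, 3, length.out = 5),
               gy = seq(-2.5, 2.5, length.out = 5),
               cell_area = 1.5 * 1.25)
  class(grid) <- "cddap_grid"
  m <- kde_map(pts, grid)
  oracle <- matrix(c(
    2.52158e-07, 0.000658681631, 0.005349402519, 6.2094078e-05, 1.4e-11,
    3.8466822e-05, 0.010999765554, 0.067632414618, 0.000805204669, 1.19e-10,
    0.000428893646, 0.046964471224, 0.121998829349, 0.001124529527, 1.5e-10,
    0.000349101302, 0.043656475876, 0.139237463364, 0.001294333267, 2.05e-10,
    2.1212122e-05, 0.028643032582, 0.075664953226, 0.000363918339, 3.8e-11),
    nrow = 5, byrow = TRUE)
  expect_equal(m$density, oracle, tolerance = 1e-6)
})

test_that("kde_map area approximates the analytic superlevel set", {
  # standard bivariate normal: {f > t} is a disc of area -2*pi*log(2*pi*t)
  xy <- rnorm2d(10000, seed = 42)
  m <- kde_map(xy, build_grid(xy, resolution = 256))
  analytic <- pi * (-2 * log(2 * pi * 0.01))  # pi * r^2 with r^2 = 5.534
  expect_equal(m$area, analytic, tolerance = 0.10)
  # normalisation: grid integral of the density is ~1
  expect_equal(sum(m$density) * m$grid$cell_area, 1, tolerance = 0.02)
})

test_that("kde_map is duplication-invariant at fixed bandwidth and rejects degenerate input", {
  xy <- rnorm2d(400, seed = 7)
  g <- build_grid(xy, resolution = 64)
  m1 <- kde_map(xy, g, bw_factor = 0.4)
  m2 <- kde_map(rbind(xy, xy), g, bw_factor = 0.4)
  expect_equal(m1$density, m2$density, tolerance = 1e-12)

  line <- cbind(1:10, 2 * (1:10))
  expect_error(kde_map(line), "collinear")
  expect_error(kde_map(xy[1:2, ]), "at least 3")
})

test_that("occupied area never shrinks when a far cluster is added (fixed bandwidth)", {
  a <- rnorm2d(2000, seed = 1)
  b <- rbind(a, a, rnorm2d(1000, seed = 2, mean = c(12, 0)))
  g <- build_grid(list(a, b), resolution = 256)
  m_a <- kde_map(a, g, bw_factor = 0.3)
  m_b <- kde_map(b, g, bw_factor = 0.3)
  expect_gte(m_b$area, m_a$area)
})

test_that("occupancy identities, translation invariance, and lattice guard", {
  a <- rnorm2d(3000, seed = 3)
  b <- rnorm2d(3000, seed = 4, mean = c(30, 0))
  g <- build_grid(list(a, b), resolution = 256)
  ma <- kde_map(a, g)
  mb <- kde_map(b, g)
  expect_equal(occupancy(ma, ma)$occupancy_rate, 1.0)
  expect_equal(occupancy(mb, ma)$occupancy_rate, 0.0)

  # shared-lattice translation of both sets leaves the rate unchanged
  shift <- c(5, -3)
  a2 <- sweep(a, 2, shift, "+")
  b2 <- sweep(b, 2, shift, "+")
  g2 <- build_grid(list(a2, b2), resolution = 256)
  rate1 <- occupancy(kde_map(b, g), kde_map(a, g))$occupancy_rate
  rate2 <- occupancy(kde_map(b2, g2), kde_map(a2, g2))$occupancy_rate
  expect_equal(rate1, rate2, tolerance = 1e-12)

  g_other <- build_grid(a, resolution = 128)
  expect_error(occupancy(kde_map(a, g_other), ma), "different lattices")
})

test_that("overlapping Gaussians give a fractional, grid-stable occupancy", {
  ref <- rnorm2d(4000, seed = 5)
  lib <- rnorm2d(4000, seed = 6, mean = c(2, 0))
  g <- build_grid(list(ref, lib), resolution = 128)
  rate <- occupancy(kde_map(lib, g), kde_map(ref, g))$occupancy_rate
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.95)
  # brute-force recount on a 4x finer lattice agrees within 5%
  g4 <- build_grid(list(ref, lib), resolution = 512)
  rate4 <- occupancy(kde_map(lib, g4), kde_map(ref, g4))$occupancy_rate
  expect_equal(rate, rate4, tolerance = 0.05)
})

test_that("grids span the union bounding box with padding", {
  a <- cbind(c(0, 1), c(0, 1))
  b <- cbind(c(9, 10), c(9, 10))
  g <- build_grid(list(a, b), resolution = 11, pad = 0.05)
  expect_equal(range(g$gx), c(-0.5, 10.5))
  expect_equal(range(g$gy), c(-0.5, 10.5))
  expect_equal(g$cell_area, 1.1 * 1.1)
})

## --- embedding (one fitted model shared across assertions) -------------

test_that("embedding is deterministic, projective, and separates families", {
  ref <- gen_reference(260, seed = 21, fraction_heavy_tail = 0.3)
  fps <- fcfp_fp(ref$smiles)
  expect_equal(ncol(fps), 1024L)

  emb1 <- embed_sets(fps, queries = list(train_head = fps[1:20, ]),
                     n_neighbors = 15L, seed = 42L)
  # refit with the same seed reproduces identical coordinates
  emb2 <- fit_embedding(fps, n_neighbors = 15L, seed = 42L)
  expect_equal(emb1$reference, emb2$coords, tolerance = 1e-6)

  # two constructed families (drug-like vs oligo-amide) separate: mean
  # silhouette over the known labels is positive
  lab <- ref$component
  xy <- emb1$reference
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    d <- sqrt(colSums((t(xy) - xy[i, ])^2))
    own <- setdiff(which(lab == lab[i]), i)
    a <- mean(d[own])
    b <- mean(d[lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)

  # project(): duplicates map to duplicate coordinates; order preserved;
  # empty input allowed; unsanitizable rows skipped
  model <- emb2
  dup <- project(model, c(ref$smiles[1], ref$smiles[1], "bad("))
  expect_equal(nrow(dup), 2L)
  expect_equal(dup[1, ], dup[2, ], tolerance = 1e-9)
  expect_equal(attr(dup, "skipped"), 3L)
  expect_equal(nrow(project(model, character())), 0L)

  # transform of the training head stays close to the fitted coordinates
  span <- sqrt(diff(range(xy[, 1]))^2 + diff(range(xy[, 2]))^2)
  d_train <- sqrt(rowSums((emb1$queries$train_head - xy[1:20, ])^2))
  expect_lt(stats::median(d_train), 0.35 * span)
})

test_that("embedding rejects n_neighbors larger than the reference", {
  smi <- gen_reference(120, seed = 22)$smiles[1:40]
  expect_error(fit_embedding(smi, n_neighbors = 50L), "n_neighbors")
})
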