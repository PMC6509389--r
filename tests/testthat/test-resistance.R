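test_that("surface parameterization produces valid resistances", {
  set.seed(2)
  cover <- landscape_raster(matrix(sample(1:3, 100, TRUE, c(0.3, 0.4, 0.3)),
                                   10, 10))
  uni <- parameterize(cover, "uniform")
  expect_true(all(uni$values == 1))

  bin <- parameterize(cover, "binary_cover", class_value = 1)
  expect_setequal(unique(as.vector(bin$values)), c(1, 2))
  expect_equal(sum(bin$values == 2), sum(cover$values == 1))
  expect_error(parameterize(cover, "binary_cover", class_value = 99),
               "absent")

  raw <- landscape_raster(matrix(seq(-3, 6, length.out = 100), 10, 10))
  shifted <- parameterize(raw, "raw")
  expect_gt(min(shifted$values), 0)
  expect_equal(min(shifted$values), 1)  # offset lands the minimum at +1
})

test_that("graph conductances follow the average-resistance rule", {
  # 1x3 chain of unit resistance, rook moves: both conductances 1
  g <- build_graph(landscape_raster(matrix(1, 1, 3)), 4)
  A <- Matrix::Diagonal(x = Matrix::diag(g$laplacian)) - g$laplacian
  expect_equal(A[1, 2], 1)
  expect_equal(A[2, 3], 1)
  expect_equal(A[1, 3], 0)
  expect_equal(max(abs(Matrix::rowSums(g$laplacian))), 0, tolerance = 1e-12)

  # neighbours with r = 1 and r = 3 -> conductance 2/4
  g2 <- build_graph(landscape_raster(matrix(c(1, 3), 1, 2)), 4)
  A2 <- Matrix::Diagonal(x = Matrix::diag(g2$laplacian)) - g2$laplacian
  expect_equal(A2[1, 2], 0.5)

  # diagonal conductance scaled by 1/sqrt(2)
  g3 <- build_graph(landscape_raster(matrix(1, 2, 2)), 8)
  A3 <- Matrix::Diagonal(x = Matrix::diag(g3$laplacian)) - g3$laplacian
  # nodes are column-major: (1,1),(2,1),(1,2),(2,2); diagonal pair 1-4
  expect_equal(A3[1, 4], 1 / sqrt(2))
  expect_equal(A3[1, 2], 1)
})

test_that("effective resistance solves hand-built circuits exactly", {
  # series: 1x3 unit chain end to end -> R = 2
  g <- build_graph(landscape_raster(matrix(1, 1, 3)), 4)
  R <- effective_resistance(
    g, data.frame(site = c("a", "b"), row = c(1, 1), col = c(1, 3))
  )
  expect_equal(R["a", "b"], 2, tolerance = 1e-10)

  # triangle of three unit resistors -> 2/3 between any pair
  L <- matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3, 3)
  tri <- list(laplacian = Matrix::Matrix(L, sparse = TRUE),
              cells = data.frame(row = c(1, 1, 1), col = 1:3),
              nrow = 1, ncol = 3, connectivity = 4)
  Rt <- effective_resistance(
    tri, data.frame(site = c("a", "b", "c"), row = 1, col = 1:3)
  )
  expect_equal(Rt["a", "b"], 2 / 3, tolerance = 1e-10)
  expect_equal(Rt["b", "c"], 2 / 3, tolerance = 1e-10)
  expect_equal(Rt["a", "c"], 2 / 3, tolerance = 1e-10)
})

test_that("effective resistance matches the dense pseudoinverse oracle", {
  skip_if_not_installed("MASS")
  set.seed(5)
  for (rep in 1:10) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    conn <- sample(c(4, 8), 1)
    ras <- landscape_raster(matrix(runif(nr * nc, 0.5, 4), nr, nc))
    g <- build_graph(ras, conn)
    picks <- sample(nrow(g$cells), 3)
    nodes <- data.frame(site = c("a", "b", "c"),
                        row = g$cells$row[picks], col = g$cells$col[picks])
    R <- effective_resistance(g, nodes)
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      expect_equal(
        R[pair[1], pair[2]],
        resistance_oracle(g$laplacian, picks[pair[1]], picks[pair[2]]),
        tolerance = 1e-8
      )
    }
    # metric properties
    expect_true(all(lower_triangle(R) > 0))
    expect_lte(R[1, 3], R[1, 2] + R[2, 3] + 1e-10)
  }
})

test_that("raising a cell's resistance never lowers any pairwise resistance", {
  set.seed(6)
  for (rep in 1:5) {
    m <- matrix(runif(36, 0.5, 3), 6, 6)
    ras <- landscape_raster(m)
    nodes <- data.frame(site = c("a", "b"), row = c(1, 6), col = c(1, 6))
    R0 <- effective_resistance(build_graph(ras, 8), nodes)["a", "b"]
    cell <- c(sample(6, 1), sample(6, 1))
    m2 <- m; m2[cell[1], cell[2]] <- m2[cell[1], cell[2]] * 5
    R1 <- effective_resistance(build_graph(landscape_raster(m2), 8),
                               nodes)["a", "b"]
    expect_gte(R1, R0 - 1e-10)
  }
})

test_that("the uniform layer gives a distance-like predictor", {
  ras <- landscape_raster(matrix(runif(40, 1, 9), 2, 20))
  nodes <- data.frame(site = c("a", "b", "c"), row = 1, col = c(1, 6, 16))
  R <- uniform_ibd_predictor(ras, nodes, 4)
  # farther pair has larger resistance on the uniform strip
  expect_gt(R["a", "c"], R["a", "b"])
  # identical to resistance on an explicitly uniform raster
  R2 <- effective_resistance(
    build_graph(parameterize(ras, "uniform"), 4), nodes
  )
  expect_equal(unclass(R), unclass(R2), tolerance = 1e-12)

  # 1xn strip: resistance proportional to cell separation (series circuit)
  strip <- landscape_raster(matrix(1, 1, 30))
  nodes2 <- data.frame(site = c("a", "b", "c"), row = 1, col = c(1, 11, 21))
  Rs <- uniform_ibd_predictor(strip, nodes2, 4)
  expect_equal(Rs["a", "b"], 10, tolerance = 1e-8)
  expect_equal(Rs["a", "c"], 20, tolerance = 1e-8)
})

test_that("disconnected node sets are rejected", {
  m <- matrix(1, 3, 5)
  m[, 3] <- NA  # wall of nodata
  g <- build_graph(landscape_raster(m), 4)
  nodes <- data.frame(site = c("a", "b"), row = c(1, 1), col = c(1, 5))
  expect_error(effective_resistance(g, nodes), "disconnected")
})

test_that("the VIF screen removes collinear predictors in order", {
  set.seed(9)
  P <- 10
  n <- P * (P - 1) / 2
  v1 <- rnorm(n); v2 <- rnorm(n); v3 <- rnorm(n)
  mk <- function(v) dist_matrix(sym_from_lower(v - min(v) + 1, P))
  # near-orthogonal set: nothing removed, VIF near 1
  scr <- vif_screen(list(a = mk(v1), b = mk(v2), c = mk(v3)), threshold = 4)
  expect_length(scr$removed, 0)
  expect_true(all(scr$vif < 2))

  # two predictors with exact sample r = 0.9 -> VIF = 1/(1-0.81) = 5.263
  z1 <- scale(v1)[, 1]
  e2 <- stats::residuals(stats::lm(v2 ~ v1))
  v2c <- 0.9 * z1 + sqrt(1 - 0.81) * scale(e2)[, 1]
  expect_equal(stats::cor(z1, v2c), 0.9, tolerance = 1e-10)
  scr2 <- vif_screen(list(a = mk(z1), b = mk(v2c)), threshold = 4)
  expect_length(scr2$removed, 1)
  scr2b <- vif_screen(list(a = mk(z1), b = mk(v2c)), threshold = 6)
  expect_length(scr2b$removed, 0)
  expect_equal(unname(scr2b$vif["a"]), 1 / (1 - 0.81), tolerance = 1e-8)

  # exact duplicate: infinite VIF handled, exactly one of the pair removed
  scr3 <- vif_screen(list(a = mk(v1), dup = mk(v1), c = mk(v3)),
                     threshold = 4)
  expect_length(intersect(scr3$removed, c("a", "dup")), 1)
  expect_false("c" %in% scr3$removed)
})

test_that("ESRI ASCII grids round-trip including nodata", {
  m <- matrix(runif(20, 0, 5), 4, 5)
  m[2, 3] <- NA
  ras <- landscape_raster(m, cellsize = 15, xll = 100, yll = 200)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(ras, f)
  back <- read_ascii_grid(f)
  expect_equal(back$values, m, tolerance = 1e-8)
  expect_equal(back$cellsize, 15)
  expect_equal(back$xll, 100)
  expect_equal(back$yll, 200)
})
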