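test_that("hexagonal grid has unit nearest-neighbour distances", {
  g <- hex_grid(4L, 4L)
  expect_identical(nrow(g), 16L)
  expect_identical(g$unit, 1:16)
  xy <- as.matrix(g[, c("x", "y")])
  d <- function(a, b) sqrt(sum((xy[a, ] - xy[b, ])^2))
  expect_equal(d(1L, 2L), 1)          # same row
  expect_equal(d(1L, 5L), 1)          # adjacent row, offset
  expect_equal(d(1L, 4L), 3)          # across the first row
  expect_equal(d(1L, 5L), sqrt(0.25 + 0.75))
  # every unit's closest other unit is at distance exactly 1
  dm <- as.matrix(dist(xy))
  diag(dm) <- Inf
  expect_equal(unname(apply(dm, 1L, min)), rep(1, 16), tolerance = 1e-12)
})

test_that("identical rows collapse the codebook to a fixed point", {
  x <- matrix(0.3, 20L, 7L)
  rownames(x) <- paste0("p", 1:20)
  m <- train_som(x, seed = 1L)
  expect_lt(max(abs(m$codebook - 0.3)), 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(77)
  x <- matrix(runif(300, -0.5, 0.5), 60L)
  rownames(x) <- paste0("p", 1:60)
  m1 <- train_som(x, seed = 4L)
  set.seed(1234)  # global RNG state must not leak in
  m2 <- train_som(x, seed = 4L)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$qe_trace, m2$qe_trace)
  m3 <- train_som(x, seed = 5L)
  expect_false(identical(m1$codebook, m3$codebook))
})

test_that("two well-separated clusters map to disjoint unit sets", {
  for (s in 1:10) {
    set.seed(500 + s)
    x <- rbind(matrix(rnorm(15 * 4, mean = -0.5, sd = 0.01), 15L),
               matrix(rnorm(15 * 4, mean = 0.5, sd = 0.01), 15L))
    rownames(x) <- paste0("p", 1:30)
    m <- train_som(x, seed = s)
    u <- assign_bmu(m, x)$unit
    expect_length(intersect(u[1:15], u[16:30]), 0L)
  }
})

test_that("BMU assignment matches the brute-force distance argmin", {
  set.seed(83)
  for (i in seq_len(200)) {
    x <- matrix(runif(50 * 4, -1, 1), 50L)
    rownames(x) <- paste0("p", 1:50)
    codebook <- matrix(runif(16 * 4, -1, 1), 16L)
    m <- make_som_model(codebook)
    a <- assign_bmu(m, x)
    expect_identical(unname(a$unit), brute_bmu(codebook, x))
  }
})

test_that("BMU ties break toward the lowest unit index", {
  codebook <- matrix(0, 16L, 3L)
  codebook[5L, ] <- c(1, 0, 0)
  codebook[9L, ] <- c(-1, 0, 0)
  m <- make_som_model(codebook)
  # equidistant from units 5 and 9 (and from all-zero units)
  x <- matrix(c(0, 5, 0), 1L, dimnames = list("p1", NULL))
  expect_identical(unname(assign_bmu(m, x)$unit), 1L)
  x2 <- matrix(c(1, 0, 0), 1L, dimnames = list("p1", NULL))
  expect_identical(unname(assign_bmu(m, x2)$unit), 5L)
})

test_that("quantization error equals the brute-force row-minima mean", {
  set.seed(89)
  for (i in seq_len(50)) {
    x <- matrix(runif(20 * 5), 20L)
    rownames(x) <- paste0("p", 1:20)
    codebook <- matrix(runif(16 * 5), 16L)
    m <- make_som_model(codebook)
    expect_equal(quantization_error(m, x), brute_qe(codebook, x),
                 tolerance = 1e-12)
  }
  # rows identical to codebook vectors: QE = 0 (rows widely spaced)
  cb <- matrix(rep(10 * seq_len(16), 3L), 16L)
  m <- make_som_model(cb)
  x <- cb[c(2L, 7L, 16L), , drop = FALSE]
  rownames(x) <- paste0("p", 1:3)
  expect_equal(quantization_error(m, x), 0)
  # single row at distance 2
  x1 <- cb[1L, , drop = FALSE] + c(2, 0, 0)
  rownames(x1) <- "p1"
  expect_equal(quantization_error(m, x1), 2)
})

test_that("training lowers quantization error when rows outnumber units", {
  for (s in 1:5) {
    set.seed(600 + s)
    centers <- rbind(rep(-0.4, 7), rep(0.4, 7), rep(0, 7),
                     c(0, 0, 0.4, 0.4, 0.4, 0.4, 0.4))
    x <- centers[rep(1:4, each = 50), ] +
      matrix(rnorm(200 * 7, sd = 0.05), 200L)
    rownames(x) <- sprintf("p%03d", 1:200)
    m <- train_som(x, seed = s)
    expect_lte(m$qe_trace[length(m$qe_trace)], m$qe_trace[1L])
  }
})

test_that("unit counts sum to the number of pathways", {
  set.seed(97)
  x <- matrix(runif(45 * 7, -0.5, 0.5), 45L)
  rownames(x) <- paste0("p", 1:45)
  m <- train_som(x, seed = 2L)
  a <- assign_bmu(m, x)
  expect_identical(sum(a$units$n), 45L)
  expect_identical(length(a$unit), 45L)
  # occupied units carry a band derived from their member median
  occ <- a$units[a$units$n > 0L, ]
  expect_identical(occ$band, classify_band(occ$median_ne))
})

test_that("SOM model JSON round-trips", {
  set.seed(7)
  x <- matrix(runif(80, -0.5, 0.5), 20L,
              dimnames = list(paste0("p", 1:20), LETTERS[1:4]))
  m <- train_som(x, epochs = 10L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_som_model(m, path)
  back <- read_som_model(path)
  expect_equal(back$codebook, m$codebook, tolerance = 1e-12)
  expect_equal(back$qe_trace, m$qe_trace, tolerance = 1e-12)
  expect_identical(back$epochs, m$epochs)
})

test_that("degenerate SOM inputs are rejected", {
  expect_error(train_som(matrix(numeric(0), 0L, 3L)), "empty")
  x <- matrix(c(1, NA), 1L)
  expect_error(train_som(x), "missing")
  m <- make_som_model(matrix(0, 16L, 3L))
  expect_error(assign_bmu(m, matrix(0, 2L, 5L)), "mismatch")
})
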