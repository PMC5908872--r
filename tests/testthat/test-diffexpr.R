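test_that("median-of-ratios size factors match hand computation", {
  cm <- make_cm(rbind(c(2L, 4L), c(4L, 8L), c(6L, 12L)))
  sf <- estimate_size_factors(cm)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)

  # identical samples
  cm2 <- make_cm(cbind(c(5L, 9L), c(5L, 9L)))
  expect_equal(unname(estimate_size_factors(cm2)), c(1, 1))

  # scale equivariance: doubling one sample's counts doubles its factor
  # relative to the others
  set.seed(2)
  counts <- matrix(rpois(40, 30) + 1L, 10L)
  cm3 <- make_cm(counts)
  doubled <- counts
  doubled[, 2L] <- doubled[, 2L] * 2L
  s_raw <- estimate_size_factors(cm3, rescale = FALSE)
  s_dbl <- estimate_size_factors(make_cm(doubled), rescale = FALSE)
  expect_equal(unname((s_dbl[2L] / s_dbl[1L]) / (s_raw[2L] / s_raw[1L])),
               2, tolerance = 1e-12)

  # no gene expressed everywhere
  expect_error(estimate_size_factors(make_cm(rbind(c(0L, 1L), c(1L, 0L)))),
               "total-count")
})

test_that("moderated log transform evaluates as documented", {
  cm <- make_cm(matrix(c(0L, 7L, 100L), 3L, 1L))
  expect_equal(unname(moderated_log(cm, 1)[, 1L]),
               c(0, 3, log2(101)))
  cm2 <- make_cm(matrix(100L, 1L, 1L))
  expect_equal(unname(moderated_log(cm2, 2, pseudocount = 0.5)[1L, 1L]),
               log2(50.5), tolerance = 1e-12)
  # monotone in count
  cm3 <- make_cm(matrix(0:20, 21L, 1L))
  expect_true(all(diff(moderated_log(cm3, 1)[, 1L]) > 0))
})

test_that("dispersion estimator recovers Poisson and NB simulations", {
  set.seed(31)
  design <- make_design(c(rep("a", 10), rep("control", 10)))
  # Poisson: alpha ~ 0 (500 replicate genes)
  cm <- make_cm(matrix(rpois(500 * 20, 100), 500L))
  a_pois <- estimate_dispersion(cm, rep(1, 20), design, shrink = 0)
  expect_lt(abs(mean(a_pois)), 0.02)

  # NB alpha = 0.2, mu = 100, n = 40: mean estimate within 25%
  design2 <- make_design(c(rep("a", 20), rep("control", 20)))
  cm2 <- make_cm(matrix(rnbinom(500 * 40, mu = 100, size = 5), 500L))
  a_nb <- estimate_dispersion(cm2, rep(1, 40), design2, shrink = 0)
  expect_lt(abs(mean(a_nb) - 0.2) / 0.2, 0.25)

  # constant gene clamps to zero
  cm3 <- make_cm(matrix(50L, 1L, 20L))
  expect_identical(unname(estimate_dispersion(cm3, rep(1, 20), design,
                                              shrink = 0)), 0)

  # all-singleton design requires pooled mode
  d_single <- make_design(c("a", "b", "control"),
                          allow_single_control = TRUE)
  cm4 <- make_cm(matrix(rpois(30, 50), 10L))
  expect_error(estimate_dispersion(cm4, rep(1, 3), d_single), "pooled")
  expect_silent(estimate_dispersion(cm4, rep(1, 3), d_single, pooled = TRUE))
})

test_that("one-sided trend shrinkage never lowers the raw estimate", {
  set.seed(8)
  design <- make_design(c(rep("a", 6), rep("control", 6)))
  cm <- make_cm(matrix(rnbinom(200 * 12, mu = 60, size = 4), 200L))
  raw <- estimate_dispersion(cm, rep(1, 12), design, shrink = 0)
  shr <- estimate_dispersion(cm, rep(1, 12), design, shrink = 0.5)
  expect_true(all(shr >= raw - 1e-12))
})

test_that("Wald test matches closed forms at zero dispersion", {
  design <- make_design(c("t", "t", "control", "control"))
  sf <- stats::setNames(rep(1, 4), sprintf("s%02d", 1:4))

  # identical groups: log2fc = 0, p = 1
  y <- stats::setNames(c(10, 10, 10, 10), names(sf))
  res <- wald_test_group(y, sf, design, "t", alpha = 0)
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)

  # (40,40) vs (10,10) at alpha = 0: exact fold change 4 => log2fc = 2
  y2 <- stats::setNames(c(40, 40, 10, 10), names(sf))
  res2 <- wald_test_group(y2, sf, design, "t", alpha = 0)
  expect_equal(res2$log2fc, 2, tolerance = 1e-9)
  # closed-form Poisson information: var = 1/80 + 1/20, on log2 scale
  expect_equal(res2$se, sqrt(1 / 80 + 1 / 20) / log(2), tolerance = 1e-6)

  # the normal tail: |wald| = 1.959964 corresponds to p = 0.05
  expect_equal(2 * stats::pnorm(-abs(res2$wald)), res2$p, tolerance = 1e-12)
  expect_equal(2 * stats::pnorm(-1.959964), 0.05, tolerance = 1e-6)

  # all-zero group is flagged rather than fitted
  y3 <- stats::setNames(c(0, 0, 10, 10), names(sf))
  expect_true(is.na(wald_test_group(y3, sf, design, "t", alpha = 0.1)$p))
  expect_error(wald_test_group(y2, sf, design, "control"), "control")
})

test_that("BH adjustment matches the step-up oracle and base examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (i in seq_len(1000)) {
    n <- sample(1:50, 1)
    p <- round(runif(n), sample(1:6, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  # q >= p always
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p - 1e-15))
})

test_that("direction calls respect FDR threshold and fold-change sign", {
  tab <- data.frame(
    gene = c("g1", "g2", "g3", "g4"), group = "t",
    log2fc = c(1.2, 0, -3, 0.5), se = 1, wald = 1,
    p = c(1e-7, 1e-7, 1.5e-5, 0.2),
    q = c(1e-6, 1e-6, 2e-5, 0.4),
    call = "ns", stringsAsFactors = FALSE)
  de <- structure(list(table = tab, fdr = 1e-5, groups = "t",
                       control_group = "control"), class = "de_result")
  d <- call_directions(de)
  expect_identical(unname(d[, "t"]), c(1L, 0L, 0L, 0L))
  d4 <- call_directions(de, fdr = 1e-4)
  expect_identical(unname(d4[, "t"]), c(1L, 0L, -1L, 0L))
})

test_that("fold-change estimates recover planted effects", {
  set.seed(101)
  G <- 600; n1 <- 5; n0 <- 4
  mu <- runif(G, 50, 2000)
  beta <- numeric(G)
  de_idx <- sample(G, 180)
  beta[de_idx] <- sample(c(-1, 1), 180, TRUE) * runif(180, 1, 3)
  mean_mat <- cbind(matrix(mu * 2^beta, G, n1), matrix(mu, G, n0))
  y <- matrix(rnbinom(G * (n1 + n0), mu = mean_mat, size = 10), G)
  cm <- make_cm(y)
  design <- make_design(c(rep("tumor", n1), rep("control", n0)))
  res <- run_de(cm, design, verbose = FALSE)
  pl <- beta[match(res$table$gene, rownames(cm$counts))]
  expect_gt(cor(pl, res$table$log2fc, use = "complete.obs"), 0.9)
  called <- res$table$call != "ns"
  expect_gt(sum(called), 50)
  expect_gte(mean(sign(pl[called]) == sign(res$table$log2fc[called])), 0.98)
  # invariants on the result table
  ok <- !is.na(res$table$p)
  expect_true(all(res$table$q[ok] >= res$table$p[ok] - 1e-15))
  up <- res$table$call == "up"
  expect_true(all(res$table$log2fc[up] > 0 & res$table$q[up] <= res$fdr))
})

test_that("a singleton group is testable via trend dispersion", {
  set.seed(55)
  design <- make_design(c(rep("big", 5), "GL1", rep("control", 4)))
  y <- matrix(rnbinom(300 * 10, mu = 200, size = 8), 300L)
  y[1:30, 6] <- rnbinom(30, mu = 1600, size = 8)  # planted up in GL1
  cm <- make_cm(y)
  res <- run_de(cm, design, verbose = FALSE)
  gl1 <- res$table[res$table$group == "GL1", ]
  expect_true(all(!is.na(gl1$p)))
  expect_gt(mean(gl1$log2fc[1:30]), 2)
})
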