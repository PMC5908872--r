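#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with nonzero counts in every sample) of the ratio between the
#' sample's count and the gene's geometric mean across samples.  Factors are
#' rescaled to have geometric mean 1 so that normalized counts stay on the
#' raw-count scale.
#'
#' @param cm a [count_matrix()].
#' @param rescale rescale to geometric mean 1 (default TRUE).
#' @return named numeric vector of positive per-sample size factors.
#' @export
estimate_size_factors <- function(cm, rescale = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has nonzero counts in all samples; ",
         "use total-count normalization instead")
  }
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- exp(apply(logc - loggeo, 2L, stats::median))
  if (rescale) sf <- sf / exp(mean(log(sf)))
  sf
}

#' Total-count size factors
#'
#' Simpler alternative normalization: column sums rescaled to geometric
#' mean 1.
#'
#' @param cm a [count_matrix()].
#' @return named numeric vector of positive per-sample size factors.
#' @export
total_count_size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  tot <- colSums(cm$counts)
  if (any(tot == 0)) stop("sample with zero total count: ",
                          colnames(cm$counts)[tot == 0][1L])
  tot / exp(mean(log(tot)))
}

#' Moderated log2 expression
#'
#' A pseudocount-stabilized log scale for visualization and PCA:
#' `log2(count / s_j + pseudocount)`.  Monotone in the count; the
#' pseudocount damps differences between samples for genes with small
#' counts.
#'
#' @param cm a [count_matrix()].
#' @param size_factors per-sample positive factors.
#' @param pseudocount positive stabilizer added on the normalized-count
#'   scale (default 1).
#' @return numeric gene x sample matrix.
#' @export
moderated_log <- function(cm, size_factors, pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"), pseudocount > 0)
  if (!is.null(names(size_factors))) {
    size_factors <- size_factors[colnames(cm$counts)]
  }
  log2(sweep(cm$counts, 2L, size_factors, `/`) + pseudocount)
}

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Per gene, the raw estimate is `max(0, (v - m) / m^2)` where `m` is the
#' mean of the size-factor-normalized counts and `v` the within-group
#' pooled variance over all groups with at least two replicates (singleton
#' groups contribute no variance information).  A mean-dispersion trend
#' `a0 + a1 / m` is then fit across genes by least squares and each raw
#' estimate is shrunk toward the trend: `(1 - w) * raw + w * trend`.
#' Shrinkage is one-sided: estimates above the trend are kept as-is, since
#' pulling a high gene-wise dispersion down would understate the test
#' variance and inflate Wald statistics; only estimates below the trend are
#' moved up toward it.
#'
#' @param cm a [count_matrix()].
#' @param size_factors per-sample positive factors.
#' @param design a [group_design()].
#' @param shrink shrinkage weight `w` in `[0, 1]` toward the fitted trend
#'   (default 0.5; 0 returns the raw method-of-moments estimates).
#' @param pooled if no group has two replicates, set TRUE to pool all
#'   samples into one variance group (otherwise an error).
#' @return named numeric vector of per-gene dispersions `alpha >= 0`.
#' @export
estimate_dispersion <- function(cm, size_factors, design, shrink = 0.5,
                                pooled = FALSE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(design, "group_design"),
            shrink >= 0, shrink <= 1)
  if (!is.null(names(size_factors))) {
    size_factors <- size_factors[colnames(cm$counts)]
  }
  k <- sweep(cm$counts, 2L, size_factors, `/`)
  grp <- design$sample_to_group[colnames(cm$counts)]
  if (pooled) grp <- rep("all", length(grp))
  tab <- table(grp)
  rep_groups <- names(tab)[tab >= 2L]
  if (!length(rep_groups)) {
    stop("all groups are singletons; rerun with pooled = TRUE")
  }
  ss <- 0
  n_eff <- 0L
  for (g in rep_groups) {
    cols <- grp == g
    kg <- k[, cols, drop = FALSE]
    ss <- ss + rowSums((kg - rowMeans(kg))^2)
    n_eff <- n_eff + sum(cols)
  }
  v <- ss / (n_eff - length(rep_groups))
  m <- rowMeans(k)
  raw <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  names(raw) <- rownames(cm$counts)
  if (shrink == 0) return(raw)
  use <- m > 0
  trend <- rep(0, length(raw))
  if (sum(use) >= 3L && stats::var(1 / m[use]) > 0) {
    fit <- stats::lm.fit(cbind(1, 1 / m[use]), raw[use])
    trend[use] <- pmax(0, fit$coefficients[1L] +
                         fit$coefficients[2L] / m[use])
  } else {
    trend[use] <- mean(raw[use])
  }
  out <- pmax(0, raw, (1 - shrink) * raw + shrink * trend)
  names(out) <- rownames(cm$counts)
  out
}

# Vectorized Newton solve for per-gene NB log-means with known dispersion.
# For the group-mean parameterization the likelihood separates by group, and
# the score for the log-mean b of one group is
#   sum_j (y_j - mu_j) / (1 + alpha * mu_j),   mu_j = s_j * exp(b).
# Returns b, the observed Fisher information, and a convergence flag.
nb_fit_group <- function(y, sf, alpha, max_iter = 100L, tol = 1e-10) {
  y <- as.matrix(y)
  pos <- rowSums(y) > 0
  b <- rep(NA_real_, nrow(y))
  b[pos] <- log(rowSums(y[pos, , drop = FALSE]) / sum(sf))
  active <- which(pos)
  iter <- 0L
  while (length(active) && iter < max_iter) {
    iter <- iter + 1L
    mu <- exp(b[active]) %o% sf
    denom <- 1 + alpha[active] * mu
    f <- rowSums((y[active, , drop = FALSE] - mu) / denom)
    fp <- -rowSums(mu * (1 + alpha[active] * y[active, , drop = FALSE]) /
                     denom^2)
    step <- f / fp
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 5), -5)  # damp early overshoot
    b[active] <- b[active] - step
    active <- active[abs(step) > tol]
  }
  converged <- pos
  if (length(active)) converged[active] <- FALSE
  mu <- exp(b) %o% sf
  info <- rowSums(mu / (1 + alpha * mu))  # expected information in b
  list(b = b, info = info, converged = converged)
}

#' Per-group NB Wald tests against the control group
#'
#' For every gene and every non-control group, fits a negative-binomial
#' log-link model with group-mean parameterization (group and control means
#' estimated by Newton iteration at the supplied per-gene dispersion) and
#' tests H0: log2 fold change = 0 with a Wald statistic.  The log2 fold
#' change is the difference of the two log-mean coefficients divided by
#' ln 2; its standard error comes from the expected Fisher information; the
#' p-value is the two-sided standard-normal tail.  Genes whose group or
#' control counts are all zero (or that fail to converge) are flagged with
#' `p = NA` and excluded from that contrast's Benjamini-Hochberg vector.
#'
#' @param cm a [count_matrix()] (typically expression-filtered).
#' @param design a [group_design()].
#' @param size_factors optional per-sample factors; estimated by
#'   [estimate_size_factors()] if missing.
#' @param dispersion optional per-gene alpha; estimated by
#'   [estimate_dispersion()] if missing.
#' @param fdr FDR threshold for direction calls (default 1e-5).
#' @param shrink dispersion shrinkage weight passed through.
#' @param max_iter Newton iteration cap per fit.
#' @param verbose log stage summaries.
#' @return object of class `de_result`: a list with `table` (long
#'   data.frame: gene, group, log2fc, se, wald, p, q, call), `fdr`, and the
#'   `size_factors` and `dispersion` used.
#' @export
run_de <- function(cm, design, size_factors = NULL, dispersion = NULL,
                   fdr = 1e-5, shrink = 0.5, max_iter = 100L,
                   verbose = TRUE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(design, "group_design"))
  if (is.null(size_factors)) size_factors <- estimate_size_factors(cm)
  if (!is.null(names(size_factors))) {
    size_factors <- size_factors[colnames(cm$counts)]
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(cm, size_factors, design,
                                      shrink = shrink)
  }
  genes <- rownames(cm$counts)
  ctrl_samples <- group_samples(design, design$control_group)
  fit0 <- nb_fit_group(cm$counts[, ctrl_samples, drop = FALSE],
                       size_factors[ctrl_samples], dispersion,
                       max_iter = max_iter)
  rows <- vector("list", length(design$group_order))
  names(rows) <- design$group_order
  for (g in design$group_order) {
    gs <- group_samples(design, g)
    fit1 <- nb_fit_group(cm$counts[, gs, drop = FALSE],
                         size_factors[gs], dispersion, max_iter = max_iter)
    ok <- fit0$converged & fit1$converged
    log2fc <- (fit1$b - fit0$b) / log(2)
    se <- sqrt(1 / fit1$info + 1 / fit0$info) / log(2)
    wald <- log2fc / se
    p <- 2 * stats::pnorm(-abs(wald))
    # identical mean estimates: Wald exactly 0, p exactly 1
    p[ok & log2fc == 0] <- 1
    log2fc[!ok] <- NA_real_
    se[!ok] <- NA_real_
    wald[!ok] <- NA_real_
    p[!ok] <- NA_real_
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
    call <- ifelse(!is.na(q) & q <= fdr & log2fc > 0, "up",
                   ifelse(!is.na(q) & q <= fdr & log2fc < 0, "down", "ns"))
    n_na <- sum(!ok)
    if (n_na) {
      stage_log("de", sprintf(
        "%s: %d gene(s) flagged non-convergent (all-zero group), p = NA",
        g, n_na), verbose = verbose)
    }
    rows[[g]] <- data.frame(gene = genes, group = g, log2fc = log2fc,
                            se = se, wald = wald, p = p, q = q,
                            call = call, stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  stage_log("de", sprintf(
    "%d genes x %d contrasts, FDR <= %g: %d up, %d down",
    length(genes), length(design$group_order), fdr,
    sum(table$call == "up"), sum(table$call == "down")),
    verbose = verbose)
  structure(list(table = table, fdr = fdr, size_factors = size_factors,
                 dispersion = dispersion, groups = design$group_order,
                 control_group = design$control_group),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d genes x %d contrasts at FDR <= %g\n",
              length(unique(x$table$gene)), length(x$groups), x$fdr))
  invisible(x)
}

#' Wald test for a single gene and group
#'
#' Convenience scalar interface over the vectorized machinery of
#' [run_de()]; mainly useful for spot checks and examples.
#'
#' @param counts_g named per-sample counts for one gene.
#' @param size_factors per-sample positive factors (named).
#' @param design a [group_design()].
#' @param group the non-control group to test.
#' @param alpha NB dispersion for this gene.
#' @param max_iter Newton iteration cap.
#' @return list with `log2fc`, `se`, `wald`, `p` (all `NA` when a side has
#'   all-zero counts).
#' @export
wald_test_group <- function(counts_g, size_factors, design, group,
                            alpha = 0, max_iter = 100L) {
  stopifnot(inherits(design, "group_design"))
  if (identical(group, design$control_group)) {
    stop("group must differ from the control group")
  }
  gs <- group_samples(design, group)
  cs <- group_samples(design, design$control_group)
  f1 <- nb_fit_group(matrix(counts_g[gs], 1L), size_factors[gs],
                     alpha, max_iter = max_iter)
  f0 <- nb_fit_group(matrix(counts_g[cs], 1L), size_factors[cs],
                     alpha, max_iter = max_iter)
  if (!f1$converged || !f0$converged) {
    return(list(log2fc = NA_real_, se = NA_real_, wald = NA_real_,
                p = NA_real_))
  }
  log2fc <- (f1$b - f0$b) / log(2)
  se <- sqrt(1 / f1$info + 1 / f0$info) / log(2)
  wald <- log2fc / se
  p <- if (log2fc == 0) 1 else 2 * stats::pnorm(-abs(wald))
  list(log2fc = log2fc, se = se, wald = wald, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * n / j`, capped at
#' 1 and mapped back to input order.
#'
#' @param p vector of p-values in `[0, 1]` (no NAs).
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NAs")
  }
  stats::p.adjust(p, method = "BH")
}

#' Direction calls from DE results
#'
#' @param de a `de_result` from [run_de()].
#' @param fdr FDR threshold (default: the one stored in `de`).
#' @return integer gene x group matrix with entries +1 (up), -1 (down),
#'   0 (not significant / not testable), class `direction_matrix`.
#' @export
call_directions <- function(de, fdr = de$fdr) {
  stopifnot(inherits(de, "de_result"))
  tab <- de$table
  called <- !is.na(tab$q) & tab$q <= fdr & !is.na(tab$log2fc) &
    tab$log2fc != 0
  d <- ifelse(called, sign(tab$log2fc), 0L)
  genes <- unique(tab$gene)
  m <- matrix(0L, length(genes), length(de$groups),
              dimnames = list(genes, de$groups))
  m[cbind(tab$gene, tab$group)] <- as.integer(d)
  structure(m, class = c("direction_matrix", class(m)))
}
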