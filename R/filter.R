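#' Detection filter
#'
#' Retains genes observed with at least one read in at least one library.
#' This is the first stage of the two-stage expression filter, and its
#' surviving gene set also defines the "detected universe" used as the
#' denominator population for pathway scoring.
#'
#' @param cm a [count_matrix()].
#' @param verbose log a stage summary to stderr.
#' @return list with `counts` (the filtered [count_matrix()]) and `report`
#'   (class `filter_report`: per-biotype data.frame with `n_annotated`,
#'   `n_detected`, `n_retained`).
#' @export
detection_filter <- function(cm, verbose = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  detected <- rowSums(cm$counts) >= 1L
  keep <- rownames(cm$counts)[detected]
  out <- if (length(keep)) subset_genes(cm, keep) else
    count_matrix(cm$counts[detected, , drop = FALSE],
                 gene_ids = character(0),
                 sample_ids = colnames(cm$counts),
                 biotype = character(0))
  report <- filter_report(cm, out, detected_cm = out)
  stage_log("detection_filter",
            sprintf("%d/%d genes with >=1 read in >=1 of %d libraries",
                    sum(detected), nrow(cm$counts), ncol(cm$counts)),
            verbose = verbose)
  list(counts = out, report = report)
}

filter_report <- function(before, after, detected_cm = after,
                          thresholds = NULL) {
  biotypes <- c("protein_coding", "miRNA", "lncRNA")
  tab <- data.frame(
    biotype = biotypes,
    n_annotated = as.integer(table(factor(before$biotype, biotypes))),
    n_detected = as.integer(table(factor(detected_cm$biotype, biotypes))),
    n_retained = as.integer(table(factor(after$biotype, biotypes))),
    stringsAsFactors = FALSE)
  structure(list(per_biotype = tab, thresholds = thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  print(x$per_biotype)
  invisible(x)
}

#' Low-expression percentile filter
#'
#' Second filter stage: within each sample and each biotype, the q-th
#' percentile (linear interpolation between order statistics, the "type 7"
#' convention) of the library-size-normalized counts of that biotype's genes
#' is taken as a threshold; a gene is retained iff its normalized count
#' strictly exceeds the threshold in at least one sample.  The percentile
#' population includes all (detection-filtered) genes of the biotype,
#' zeros included.
#'
#' @param cm a detection-filtered [count_matrix()].
#' @param size_factors positive per-sample normalization factors (named by
#'   sample id, or in column order).
#' @param q percentile as a fraction in (0, 1); default 0.40.
#' @param verbose log a stage summary to stderr.
#' @return list with `counts` (filtered [count_matrix()]) and `report`
#'   (`filter_report` whose `thresholds` element is a biotype x sample
#'   matrix of the percentile values used).
#' @export
percentile_filter <- function(cm, size_factors, q = 0.40, verbose = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must be a fraction strictly between 0 and 1")
  }
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (!is.null(names(size_factors))) {
    size_factors <- size_factors[colnames(cm$counts)]
  }
  stopifnot(length(size_factors) == ncol(cm$counts))
  norm <- sweep(cm$counts, 2L, size_factors, `/`)
  biotypes <- unique(cm$biotype)
  thresholds <- matrix(NA_real_, length(biotypes), ncol(norm),
                       dimnames = list(biotypes, colnames(norm)))
  keep <- logical(nrow(norm))
  for (b in biotypes) {
    rows <- cm$biotype == b
    thr <- apply(norm[rows, , drop = FALSE], 2L, stats::quantile,
                 probs = q, type = 7, names = FALSE)
    thresholds[b, ] <- thr
    exceeds <- sweep(norm[rows, , drop = FALSE], 2L, thr, `>`)
    keep[rows] <- rowSums(exceeds) >= 1L
  }
  out <- subset_genes(cm, rownames(cm$counts)[keep])
  report <- filter_report(cm, out, detected_cm = cm, thresholds = thresholds)
  stage_log("percentile_filter",
            sprintf("%d/%d genes above the %.0fth percentile in >=1 sample",
                    sum(keep), nrow(cm$counts), 100 * q),
            verbose = verbose)
  list(counts = out, report = report)
}
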