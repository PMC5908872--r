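#' Detected gene universe
#'
#' The denominator population for pathway scoring: genes of the *raw*
#' (pre-percentile-filter) matrix with at least one read in at least one
#' library.  Deliberately distinct from the expression-filtered gene set
#' used for testing — a gene that fails the percentile filter but has one
#' read still belongs to the universe.
#'
#' @param cm_raw the raw [count_matrix()] before any filtering.
#' @return character vector of detected gene ids.
#' @export
detected_universe <- function(cm_raw) {
  stopifnot(inherits(cm_raw, "count_matrix"))
  rownames(cm_raw$counts)[rowSums(cm_raw$counts) >= 1L]
}

#' Net expression of a pathway in one group
#'
#' The signed fraction `(n_up - n_down) / n_detected`: the number of
#' significantly up-regulated minus significantly down-regulated member
#' genes, relative to the number of member genes in the detected universe.
#' Always in `[-1, 1]`.
#'
#' @param n_up,n_down counts of up- and down-called member genes.
#' @param n_detected number of pathway members in the detected universe.
#' @return the net-expression value.
#' @export
net_expression <- function(n_up, n_down, n_detected) {
  stopifnot(n_up >= 0, n_down >= 0)
  if (any(n_detected <= 0)) {
    stop("n_detected must be positive (pathway should have been excluded)")
  }
  if (any(n_up + n_down > n_detected)) {
    stop("n_up + n_down exceeds n_detected")
  }
  (n_up - n_down) / n_detected
}

#' Pathway x group net-expression matrix
#'
#' Restricts every gene set to the detected universe, drops (and logs)
#' pathways with fewer than `min_size` detected members, and computes the
#' net expression for every retained pathway in every group of the
#' direction matrix.
#'
#' @param dirs a `direction_matrix` from [call_directions()].
#' @param sets a `gene_set_collection`.
#' @param universe character vector of detected gene ids (from
#'   [detected_universe()]).
#' @param min_size minimum number of detected members (default 20).
#' @param verbose log a stage summary.
#' @return object of class `net_expression_matrix`: a list with `ne`
#'   (pathway x group numeric matrix), `n_up`, `n_down` (same shape),
#'   `n_detected` (per-pathway integer vector), `min_size`.
#' @export
net_expression_matrix <- function(dirs, sets, universe, min_size = 20L,
                                  verbose = TRUE) {
  stopifnot(is.matrix(dirs))
  members <- lapply(sets, intersect, universe)
  n_det <- lengths(members)
  keep <- n_det >= min_size
  if (!any(keep)) {
    stop("no pathway has >= ", min_size, " detected genes")
  }
  stage_log("net_expression", sprintf(
    "%d/%d pathways with >= %d detected genes (universe %d genes)",
    sum(keep), length(sets), min_size, length(universe)),
    verbose = verbose)
  members <- members[keep]
  n_det <- n_det[keep]
  groups <- colnames(dirs)
  n_up <- n_down <- matrix(0L, length(members), length(groups),
                           dimnames = list(names(members), groups))
  in_dirs <- lapply(members, intersect, rownames(dirs))
  for (i in seq_along(members)) {
    d <- dirs[in_dirs[[i]], , drop = FALSE]
    n_up[i, ] <- colSums(d == 1L)
    n_down[i, ] <- colSums(d == -1L)
  }
  ne <- (n_up - n_down) / n_det
  structure(list(ne = ne, n_up = n_up, n_down = n_down,
                 n_detected = stats::setNames(as.integer(n_det),
                                              names(members)),
                 min_size = as.integer(min_size)),
            class = "net_expression_matrix")
}

#' @export
print.net_expression_matrix <- function(x, ...) {
  cat(sprintf(
    "net_expression_matrix: %d pathways x %d groups (min %d detected genes)\n",
    nrow(x$ne), ncol(x$ne), x$min_size))
  invisible(x)
}

#' Classify a net-expression value into a band
#'
#' Bands follow the conventions used to summarize pathway dysregulation:
#' `near_zero` when `|v| <= 0.05`, `negative` when `v < -0.10`, `positive`
#' when `v > 0.10`, and `weak` for the remaining gap
#' (`0.05 < |v| <= 0.10`), which is labelled here so that the
#' classification is total.
#'
#' @param value numeric vector of net-expression values in `[-1, 1]`.
#' @return character vector of band labels.
#' @export
classify_band <- function(value) {
  stopifnot(all(value >= -1 & value <= 1))
  ifelse(abs(value) <= 0.05, "near_zero",
         ifelse(value < -0.10, "negative",
                ifelse(value > 0.10, "positive", "weak")))
}

#' Long-format net-expression table
#'
#' @param nem a `net_expression_matrix`.
#' @return data.frame with columns `pathway`, `group`, `n_up`, `n_down`,
#'   `n_detected`, `NE`, `band`.
#' @export
net_expression_table <- function(nem) {
  stopifnot(inherits(nem, "net_expression_matrix"))
  groups <- colnames(nem$ne)
  pws <- rownames(nem$ne)
  out <- data.frame(
    pathway = rep(pws, times = length(groups)),
    group = rep(groups, each = length(pws)),
    n_up = as.integer(nem$n_up),
    n_down = as.integer(nem$n_down),
    n_detected = rep(unname(nem$n_detected), times = length(groups)),
    NE = as.numeric(nem$ne),
    band = classify_band(as.numeric(nem$ne)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
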