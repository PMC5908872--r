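#' Per-group DEG tallies
#'
#' Counts up-, down- and total called genes per group, the size of the DEG
#' union over any named group subsets, and the fraction of called genes
#' with moderate fold changes (`|log2fc| <= 2`) per group.
#'
#' @param dirs a `direction_matrix`.
#' @param de the matching `de_result` (for fold-change fractions); optional.
#' @param subsets optional named list of group-label vectors over which DEG
#'   unions are counted.
#' @return object of class `deg_summary`: list with `per_group`
#'   (data.frame: group, n_up, n_down, n_total, frac_moderate) and `unions`
#'   (named integer vector).
#' @export
deg_summary <- function(dirs, de = NULL, subsets = NULL) {
  groups <- colnames(dirs)
  n_up <- colSums(dirs == 1L)
  n_down <- colSums(dirs == -1L)
  frac_moderate <- rep(NA_real_, length(groups))
  if (!is.null(de)) {
    stopifnot(inherits(de, "de_result"))
    tab <- de$table[de$table$call != "ns", , drop = FALSE]
    for (i in seq_along(groups)) {
      fc <- tab$log2fc[tab$group == groups[i]]
      if (length(fc)) frac_moderate[i] <- mean(abs(fc) <= 2)
    }
  }
  per_group <- data.frame(group = groups, n_up = as.integer(n_up),
                          n_down = as.integer(n_down),
                          n_total = as.integer(n_up + n_down),
                          frac_moderate = frac_moderate,
                          stringsAsFactors = FALSE)
  unions <- integer(0)
  if (!is.null(subsets)) {
    unions <- vapply(subsets, function(gs) {
      unknown <- setdiff(gs, groups)
      if (length(unknown)) stop("unknown group label: ", unknown[1L])
      sum(rowSums(dirs[, gs, drop = FALSE] != 0L) >= 1L)
    }, integer(1))
  }
  structure(list(per_group = per_group, unions = unions),
            class = "deg_summary")
}

#' @export
print.deg_summary <- function(x, ...) {
  print(x$per_group)
  if (length(x$unions)) {
    cat("unions:", paste(names(x$unions), x$unions, sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' PCA of moderated log expression over differentially expressed genes
#'
#' Centers and scales each gene (rows of `logexpr`) to unit variance,
#' dropping zero-variance genes first, then decomposes the sample-by-gene
#' matrix with `prcomp`.  Each component is sign-oriented so its
#' largest-magnitude loading is positive, making scores deterministic
#' across linear-algebra backends.
#'
#' @param logexpr numeric gene x sample matrix (typically
#'   [moderated_log()] restricted to the DEG union).
#' @param k number of components to return (default 2).
#' @param verbose log dropped zero-variance genes.
#' @return object of class `pca_result`: list with `scores` (sample x k),
#'   `var_frac` (variance fraction of each of the min(n-1, p) components),
#'   `n_genes_used`.
#' @export
pca_degs <- function(logexpr, k = 2L, verbose = TRUE) {
  stopifnot(is.matrix(logexpr), ncol(logexpr) >= 2L)
  v <- apply(logexpr, 1L, stats::var)
  drop <- v == 0 | is.na(v)
  if (any(drop)) {
    stage_log("pca", sprintf("dropping %d zero-variance gene(s)", sum(drop)),
              verbose = verbose)
  }
  x <- logexpr[!drop, , drop = FALSE]
  if (nrow(x) < 2L) stop("need >= 2 non-constant genes for PCA")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  structure(list(scores = scores, var_frac = var_frac,
                 n_genes_used = nrow(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples x %d components; var frac %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$var_frac[seq_len(ncol(x$scores))]),
                    collapse = ", ")))
  invisible(x)
}
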