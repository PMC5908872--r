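#' Venn partition of direction calls
#'
#' Assigns every gene called in at least one of the selected groups to
#' exactly one combination cell (the exact set of selected groups calling
#' it), computed separately for up-calls and down-calls.  Cell labels are
#' the sorted group names joined by `&`.
#'
#' @param dirs a `direction_matrix` from [call_directions()].
#' @param groups subset of groups (>= 2) to partition over.
#' @return list with elements `up` and `down`, each a named list mapping
#'   combination labels to character vectors of gene ids.
#' @export
venn_partition <- function(dirs, groups = colnames(dirs)) {
  unknown <- setdiff(groups, colnames(dirs))
  if (length(unknown)) stop("unknown group label: ", unknown[1L])
  if (length(groups) < 2L) stop("need at least 2 groups")
  d <- dirs[, groups, drop = FALSE]
  one_sign <- function(target) {
    hit <- d == target
    called <- rowSums(hit) >= 1L
    labels <- apply(hit[called, , drop = FALSE], 1L, function(h) {
      paste(sort(groups[h]), collapse = "&")
    })
    split(rownames(d)[called], labels)
  }
  list(up = one_sign(1L), down = one_sign(-1L))
}

#' Consistency classification against a reference group
#'
#' For each gene called in the reference group, classifies its behaviour
#' across comparison groups: `concordant_up` if up in the reference and up
#' or unchanged (no call) in every comparison group; `concordant_down`
#' symmetrically; otherwise `discordant`.  Genes not called in the
#' reference are `not_called`.
#'
#' @param dirs a `direction_matrix`.
#' @param reference_group reference group label.
#' @param comparison_groups labels of the groups compared against.
#' @return named character vector over genes with values in
#'   `c("concordant_up", "concordant_down", "discordant", "not_called")`.
#' @export
consistency_class <- function(dirs, reference_group, comparison_groups) {
  unknown <- setdiff(c(reference_group, comparison_groups), colnames(dirs))
  if (length(unknown)) stop("unknown group label: ", unknown[1L])
  ref <- dirs[, reference_group]
  comp <- dirs[, comparison_groups, drop = FALSE]
  up_ok <- rowSums(comp == -1L) == 0L
  down_ok <- rowSums(comp == 1L) == 0L
  out <- ifelse(ref == 0L, "not_called",
                ifelse(ref == 1L & up_ok, "concordant_up",
                       ifelse(ref == -1L & down_ok, "concordant_down",
                              "discordant")))
  stats::setNames(out, rownames(dirs))
}

#' All-group core of direction calls
#'
#' Restricts to genes called (d != 0) in every group and splits them by
#' sign pattern: uniformly up, uniformly down, or mixed (discordant).  The
#' three sets are disjoint and their union is the core.
#'
#' @param dirs a `direction_matrix` with >= 2 groups.
#' @return list with character-vector elements `concordant_up`,
#'   `concordant_down`, `discordant`.
#' @export
all_group_core <- function(dirs) {
  if (ncol(dirs) < 2L) stop("need at least 2 groups")
  core <- rowSums(dirs != 0L) == ncol(dirs)
  g <- rownames(dirs)
  all_up <- core & rowSums(dirs == 1L) == ncol(dirs)
  all_down <- core & rowSums(dirs == -1L) == ncol(dirs)
  list(concordant_up = g[all_up],
       concordant_down = g[all_down],
       discordant = g[core & !all_up & !all_down])
}

#' Full concordance table
#'
#' Per-gene summary combining the direction vector, the partition label
#' (the combination of groups calling the gene, in any direction), and the
#' consistency class relative to a reference group.  Percentages reported
#' downstream use the reference group's called-gene count as denominator.
#'
#' @param dirs a `direction_matrix`.
#' @param reference_group reference for the consistency classification.
#' @param comparison_groups comparison groups (default: all others).
#' @return data.frame with columns `gene`, one direction column per group,
#'   `partition`, `class`.
#' @export
concordance_table <- function(dirs, reference_group,
                              comparison_groups =
                                setdiff(colnames(dirs), reference_group)) {
  cls <- consistency_class(dirs, reference_group, comparison_groups)
  called <- dirs != 0L
  partition <- apply(called, 1L, function(h) {
    if (!any(h)) "" else paste(sort(colnames(dirs)[h]), collapse = "&")
  })
  out <- data.frame(gene = rownames(dirs), unclass(dirs),
                    partition = partition, class = unname(cls),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
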