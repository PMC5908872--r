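#' Construct a validated count matrix
#'
#' The central data container of the pipeline: a gene-by-sample matrix of
#' non-negative integer read counts with one biotype label per gene
#' (protein-coding, miRNA or lncRNA).  Gene and sample identifiers are opaque
#' strings and must be unique.
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   the matrix rownames).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to the matrix colnames).
#' @param biotype per-gene label in `c("protein_coding", "miRNA", "lncRNA")`;
#'   recycled if length 1.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with dimnames), and `biotype` (named character vector).
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts),
                         biotype = "protein_coding") {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (or set dimnames on counts)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(counts)) {
    stop("length(gene_ids) != nrow(counts)")
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("length(sample_ids) != ncol(counts)")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                 gene_ids[i[1L]], sample_ids[i[2L]], counts[bad[1L]]))
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sample_ids)
  biotype <- rep_len(as.character(biotype), nrow(counts))
  ok <- biotype %in% c("protein_coding", "miRNA", "lncRNA")
  if (!all(ok)) stop("unknown biotype label: ", biotype[!ok][1L])
  names(biotype) <- gene_ids
  structure(list(counts = counts, biotype = biotype), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$biotype)),
                            as.integer(table(x$biotype))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or sample identifiers
#'
#' @param cm a [count_matrix()].
#' @param genes,samples character vectors of identifiers to keep (default all).
#' @return a `count_matrix` restricted to the requested rows/columns, order
#'   as given.
#' @export
subset_genes <- function(cm, genes = rownames(cm$counts),
                         samples = colnames(cm$counts)) {
  stopifnot(inherits(cm, "count_matrix"))
  missing_g <- setdiff(genes, rownames(cm$counts))
  if (length(missing_g)) stop("unknown gene id: ", missing_g[1L])
  missing_s <- setdiff(samples, colnames(cm$counts))
  if (length(missing_s)) stop("unknown sample id: ", missing_s[1L])
  count_matrix(cm$counts[genes, samples, drop = FALSE],
               gene_ids = genes, sample_ids = samples,
               biotype = cm$biotype[genes])
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample identifiers, gene identifiers in the first
#' column, and optionally a `biotype` second column (absent columns default
#' every gene to `protein_coding`).  Cells must be non-negative integers;
#' violations raise an error naming the offending gene and sample.
#'
#' @param path path to a tab-separated file.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("no samples: cannot read '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) stop("no samples: '", path, "' has no count columns")
  gene_ids <- as.character(df[[1L]])
  has_biotype <- ncol(df) >= 2L && identical(names(df)[2L], "biotype")
  biotype <- if (has_biotype) as.character(df[[2L]]) else "protein_coding"
  first_count <- if (has_biotype) 3L else 2L
  if (ncol(df) < first_count) stop("no samples: '", path,
                                   "' has no count columns")
  counts <- as.matrix(df[, first_count:ncol(df), drop = FALSE])
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(counts), nrow = nrow(counts)))) & !is.na(counts))
    i <- if (length(bad)) arrayInd(bad[1L], dim(counts)) else c(1L, 1L)
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 gene_ids[i[1L]], colnames(counts)[i[2L]]))
  }
  count_matrix(counts, gene_ids = gene_ids,
               sample_ids = colnames(counts), biotype = biotype)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]; always writes the `biotype` column.
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts),
                   biotype = unname(cm$biotype),
                   cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' Construct a sample-to-group design
#'
#' Maps every sample to exactly one group and designates one group as the
#' non-neoplastic control.  Variance estimation needs replication in the
#' control group, so fewer than two control samples is an error unless
#' explicitly overridden (degenerate designs are useful in tests).
#'
#' @param sample_to_group named character vector: names are sample ids,
#'   values are group labels.
#' @param control_group label of the control group.
#' @param group_order optional canonical ordering of the non-control groups;
#'   defaults to order of first appearance.
#' @param allow_single_control set `TRUE` to permit a control group with
#'   fewer than 2 samples.
#' @return an object of class `group_design`.
#' @export
group_design <- function(sample_to_group, control_group,
                         group_order = NULL,
                         allow_single_control = FALSE) {
  stopifnot(is.character(sample_to_group) | is.factor(sample_to_group))
  sample_to_group <- stats::setNames(as.character(sample_to_group),
                                     names(sample_to_group))
  if (length(sample_to_group) &&
      (is.null(names(sample_to_group)) ||
       anyDuplicated(names(sample_to_group)))) {
    stop("sample_to_group must have unique sample-id names")
  }
  if (!control_group %in% sample_to_group && length(sample_to_group) > 0L) {
    stop("control group '", control_group, "' has no samples")
  }
  n_ctrl <- sum(sample_to_group == control_group)
  if (n_ctrl < 2L && !allow_single_control && length(sample_to_group) > 0L) {
    stop("control group '", control_group, "' has ", n_ctrl,
         " sample(s); >=2 required for variance estimation ",
         "(set allow_single_control = TRUE to override)")
  }
  seen <- unique(unname(sample_to_group))
  noncontrol <- setdiff(seen, control_group)
  if (is.null(group_order)) {
    group_order <- noncontrol
  } else {
    if (!setequal(group_order, noncontrol)) {
      stop("group_order must be a permutation of the non-control groups")
    }
  }
  structure(list(sample_to_group = sample_to_group,
                 control_group = control_group,
                 group_order = group_order),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  tab <- table(x$sample_to_group)
  cat(sprintf("group_design: %d samples, control = '%s'\n  %s\n",
              length(x$sample_to_group), x$control_group,
              paste(sprintf("%s(%d)", names(tab), as.integer(tab)),
                    collapse = " ")))
  invisible(x)
}

#' Samples belonging to one group
#' @param design a [group_design()].
#' @param group a group label.
#' @return character vector of sample ids.
#' @export
group_samples <- function(design, group) {
  stopifnot(inherits(design, "group_design"))
  if (!group %in% c(design$group_order, design$control_group,
                    design$sample_to_group)) {
    stop("unknown group label: ", group)
  }
  names(design$sample_to_group)[design$sample_to_group == group]
}

#' Total number of libraries in a design
#'
#' Sum of replicate counts over all groups, controls included.  The default
#' study design (12 + 4 + 5 + 5 + 1 + 2 + 4 tumor/cell-line samples plus 4
#' controls) yields 37 libraries.
#'
#' @param design a [group_design()].
#' @return integer sample count.
#' @export
total_library_count <- function(design) {
  stopifnot(inherits(design, "group_design"))
  length(design$sample_to_group)
}

#' Read a sample sheet TSV into a group design
#'
#' @param path TSV with columns `sample` and `group`.
#' @param control_group the group label to treat as control.
#' @param ... passed to [group_design()].
#' @return a [group_design()].
#' @export
read_sample_sheet <- function(path, control_group, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("sample sheet must have columns 'sample' and 'group'")
  }
  group_design(stats::setNames(df$group, df$sample), control_group, ...)
}

#' Write a group design as a sample sheet TSV
#' @param design a [group_design()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sample_sheet <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  write_tsv_table(data.frame(sample = names(design$sample_to_group),
                             group = unname(design$sample_to_group),
                             stringsAsFactors = FALSE), path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, `set_id TAB description TAB
#' member...`.  Duplicate members within a set are dropped on load; lines
#' with fewer than three fields raise an error naming the line number.
#'
#' @param path path to a GMT file.
#' @return an object of class `gene_set_collection`: a named list of unique
#'   member-gene character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT format error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set id: ", ids[duplicated(ids)][1L])
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  structure(sets, description = stats::setNames(desc, ids),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#' @param sets a `gene_set_collection` (or plain named list of character
#'   vectors).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[names(sets)[i]]], sets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, member counts %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}
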