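# Independent brute-force oracles and small fixture builders.  Every oracle
# here is written from the mathematical definition, not by calling the code
# path it checks.

# --- fixtures ---------------------------------------------------------------

make_cm <- function(counts, biotype = "protein_coding",
                    genes = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(counts)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(counts)))
  count_matrix(counts, gene_ids = genes, sample_ids = samples,
               biotype = biotype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_design <- function(groups_per_sample, control = "control", ...) {
  sample_ids <- sprintf("s%02d", seq_along(groups_per_sample))
  group_design(stats::setNames(groups_per_sample, sample_ids), control, ...)
}

# direction matrix from a plain integer matrix
make_dirs <- function(m, genes = NULL, groups = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  rownames(m) <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- groups %||% LETTERS[seq_len(ncol(m))]
  structure(m, class = c("direction_matrix", class(m)))
}

rand_dirs <- function(n_genes, groups, prob = c(0.25, 0.5, 0.25)) {
  make_dirs(matrix(sample(c(-1L, 0L, 1L), n_genes * length(groups),
                          replace = TRUE, prob = prob),
                   n_genes, length(groups)),
            groups = groups)
}

# mock SOM model with a fixed codebook (assign_bmu/quantization_error only
# read the codebook and class)
make_som_model <- function(codebook, grid = hex_grid(4L, 4L)) {
  rownames(codebook) <- paste0("unit", seq_len(nrow(codebook)))
  structure(list(codebook = codebook, grid = grid,
                 qe_trace = NA_real_, epochs = 0L,
                 radius = c(2, 0.3), rate = c(0.05, 0.01), seed = 0L),
            class = "som_model")
}

# --- oracles ----------------------------------------------------------------

# Benjamini-Hochberg step-up from the definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# type-7 percentile by explicit sort + linear interpolation
brute_quantile7 <- function(x, q) {
  xs <- sort(x)
  h <- (length(xs) - 1) * q
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(xs))] - xs[lo + 1])
}

# percentile filter by per-sample, per-biotype scan
brute_percentile_keep <- function(counts, biotype, sf, q) {
  norm <- sweep(counts, 2, sf, `/`)
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      pop <- norm[biotype == biotype[g], j]
      if (norm[g, j] > brute_quantile7(pop, q)) keep[g] <- TRUE
    }
  }
  keep
}

# venn partition by per-gene scan over all non-empty group combinations
brute_venn <- function(dirs, groups, target) {
  cells <- list()
  for (g in rownames(dirs)) {
    hit <- groups[dirs[g, groups] == target]
    if (length(hit)) {
      label <- paste(sort(hit), collapse = "&")
      cells[[label]] <- c(cells[[label]], g)
    }
  }
  cells
}

# BMU by explicit double loop
brute_bmu <- function(codebook, x) {
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    d <- apply(codebook, 1, function(w) sqrt(sum((x[i, ] - w)^2)))
    out[i] <- which.min(d)
  }
  out
}

# canonical form for comparing venn cell lists (sorted names and members;
# empty lists compare equal regardless of name attribute)
norm_cells <- function(l) {
  if (!length(l)) return(list())
  l <- lapply(l, sort)
  l[sort(names(l))]
}

brute_qe <- function(codebook, x) {
  mean(vapply(seq_len(nrow(x)), function(i) {
    min(apply(codebook, 1, function(w) sqrt(sum((x[i, ] - w)^2))))
  }, numeric(1)))
}
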