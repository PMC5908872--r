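#' Hexagonal SOM grid
#'
#' Offset hexagonal layout: the unit in grid row `r` (0-based) and column
#' `c` sits at `x = c + 0.5 * (r %% 2)`, `y = r * sqrt(3) / 2`, so every
#' pair of neighbouring unit centers is at distance exactly 1.  Unit
#' indices are row-major, 1-based, and stable.
#'
#' @param rows,cols grid dimensions (default 4 x 4).
#' @return data.frame with columns `unit`, `row`, `col`, `x`, `y`.
#' @export
hex_grid <- function(rows = 4L, cols = 4L) {
  stopifnot(rows >= 1L, cols >= 1L)
  r <- rep(seq_len(rows) - 1L, each = cols)
  c <- rep(seq_len(cols) - 1L, times = rows)
  data.frame(unit = seq_len(rows * cols), row = r, col = c,
             x = c + 0.5 * (r %% 2), y = r * sqrt(3) / 2)
}

# Pairwise Euclidean distances between unit centers of a hex_grid.
grid_distances <- function(grid) {
  as.matrix(stats::dist(grid[, c("x", "y")]))
}

#' Train a self-organizing map on net-expression profiles
#'
#' Classical online Kohonen algorithm: the codebook is initialized by
#' sampling data rows (seeded); in each epoch every row is presented in a
#' reshuffled order and all codebook vectors move toward it, weighted by a
#' Gaussian neighbourhood kernel `exp(-d^2 / (2 r(t)^2))` over grid
#' distance to the best-matching unit (BMU).  Learning rate and radius
#' decay linearly across epochs.  Identical seeds give identical models.
#' Inputs are not standardized: net expressions already share the
#' `[-1, 1]` scale.
#'
#' @param data a `net_expression_matrix` or plain numeric matrix
#'   (rows = pathways, columns = groups); no missing values.
#' @param grid a [hex_grid()] (default 4 x 4).
#' @param epochs training epochs (default 100).
#' @param radius length-2 initial/final neighbourhood radius; default from
#'   half the grid diagonal down to 0.3, so the last epochs are effectively
#'   winner-take-all and refine the quantization (a final radius at or above
#'   the inter-unit distance of 1 would keep every hex neighbour at Gaussian
#'   weight 0.61 and leave the map permanently smoothed, preventing the
#'   quantization error from improving on its initialization).
#' @param rate length-2 initial/final learning rate (default 0.05 to 0.01).
#' @param seed integer seed for initialization and presentation order.
#' @return object of class `som_model`: list with `codebook` (unit x group
#'   matrix), `grid`, `qe_trace` (quantization error after each epoch,
#'   entry 1 = after initialization), and the hyperparameters.
#' @export
train_som <- function(data, grid = hex_grid(4L, 4L), epochs = 100L,
                      radius = NULL, rate = c(0.05, 0.01), seed = 1L) {
  x <- if (inherits(data, "net_expression_matrix")) data$ne else as.matrix(data)
  if (!nrow(x)) stop("empty training data")
  if (anyNA(x)) stop("training data must not contain missing values")
  n_units <- nrow(grid)
  gd <- grid_distances(grid)
  if (is.null(radius)) {
    diag_len <- sqrt((max(grid$x) - min(grid$x))^2 +
                       (max(grid$y) - min(grid$y))^2)
    radius <- c(diag_len / 2, 0.3)
  }
  stopifnot(length(radius) == 2L, all(radius > 0),
            length(rate) == 2L, all(rate > 0), epochs >= 1L)
  with_seed(seed, {
    init_rows <- sample.int(nrow(x), n_units, replace = nrow(x) < n_units)
    w <- x[init_rows, , drop = FALSE]
    rownames(w) <- paste0("unit", seq_len(n_units))
    qe_trace <- numeric(epochs + 1L)
    qe_trace[1L] <- quantization_error_codebook(w, x)
    frac <- if (epochs > 1L) (seq_len(epochs) - 1L) / (epochs - 1L) else 0
    r_t <- radius[1L] + frac * (radius[2L] - radius[1L])
    eta_t <- rate[1L] + frac * (rate[2L] - rate[1L])
    for (t in seq_len(epochs)) {
      for (i in sample.int(nrow(x))) {
        xi <- x[i, ]
        d2 <- rowSums((w - matrix(xi, n_units, ncol(x), byrow = TRUE))^2)
        bmu <- which.min(d2)  # ties: lowest unit index
        h <- exp(-gd[, bmu]^2 / (2 * r_t[t]^2))
        w <- w + eta_t[t] * h * (matrix(xi, n_units, ncol(x),
                                        byrow = TRUE) - w)
      }
      qe_trace[t + 1L] <- quantization_error_codebook(w, x)
    }
    structure(list(codebook = w, grid = grid, qe_trace = qe_trace,
                   epochs = as.integer(epochs), radius = radius,
                   rate = rate, seed = seed),
              class = "som_model")
  })
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf(
    "som_model: %d units x %d features, %d epochs, final QE %.4g\n",
    nrow(x$codebook), ncol(x$codebook), x$epochs,
    x$qe_trace[length(x$qe_trace)]))
  invisible(x)
}

quantization_error_codebook <- function(w, x) {
  d <- row_unit_distances(w, x)
  mean(apply(d, 1L, min))
}

# rows x units matrix of Euclidean distances
row_unit_distances <- function(w, x) {
  x2 <- rowSums(x^2)
  w2 <- rowSums(w^2)
  d2 <- outer(x2, w2, `+`) - 2 * x %*% t(w)
  sqrt(pmax(d2, 0))
}

#' Assign pathways to their best-matching units
#'
#' BMU = unit with the smallest Euclidean distance to the row; ties go to
#' the lowest unit index.  Also computes per-unit summaries: member count,
#' per-group mean of member net expressions, the median over all member
#' values, and its band via [classify_band()].
#'
#' @param model a `som_model`.
#' @param data a `net_expression_matrix` or numeric matrix with the same
#'   columns the model was trained on.
#' @return object of class `som_assignment`: list with `unit` (named
#'   integer vector pathway -> unit), `units` (data.frame: unit, n,
#'   median_ne, band), `unit_means` (unit x group matrix).
#' @export
assign_bmu <- function(model, data) {
  stopifnot(inherits(model, "som_model"))
  x <- if (inherits(data, "net_expression_matrix")) data$ne else as.matrix(data)
  if (ncol(x) != ncol(model$codebook)) {
    stop("dimension mismatch: data has ", ncol(x),
         " columns, codebook has ", ncol(model$codebook))
  }
  d <- row_unit_distances(model$codebook, x)
  unit <- apply(d, 1L, which.min)  # which.min breaks ties at lowest index
  names(unit) <- rownames(x)
  n_units <- nrow(model$codebook)
  unit_means <- matrix(NA_real_, n_units, ncol(x),
                       dimnames = list(seq_len(n_units), colnames(x)))
  median_ne <- rep(NA_real_, n_units)
  n <- integer(n_units)
  for (u in seq_len(n_units)) {
    rows <- x[unit == u, , drop = FALSE]
    n[u] <- nrow(rows)
    if (n[u]) {
      unit_means[u, ] <- colMeans(rows)
      median_ne[u] <- stats::median(rows)
    }
  }
  units <- data.frame(unit = seq_len(n_units), n = n,
                      median_ne = median_ne,
                      band = ifelse(is.na(median_ne), NA_character_,
                                    classify_band(ifelse(is.na(median_ne),
                                                         0, median_ne))),
                      stringsAsFactors = FALSE)
  structure(list(unit = unit, units = units, unit_means = unit_means),
            class = "som_assignment")
}

#' @export
print.som_assignment <- function(x, ...) {
  cat(sprintf("som_assignment: %d pathways over %d units (%d occupied)\n",
              length(x$unit), nrow(x$units), sum(x$units$n > 0)))
  invisible(x)
}

#' Quantization error
#'
#' Mean Euclidean distance from each data row to the codebook vector of its
#' best-matching unit; the standard SOM fit diagnostic.
#'
#' @param model a `som_model`.
#' @param data a `net_expression_matrix` or numeric matrix.
#' @return non-negative scalar.
#' @export
quantization_error <- function(model, data) {
  stopifnot(inherits(model, "som_model"))
  x <- if (inherits(data, "net_expression_matrix")) data$ne else as.matrix(data)
  if (ncol(x) != ncol(model$codebook)) stop("dimension mismatch")
  quantization_error_codebook(model$codebook, x)
}

#' SOM assignment table
#'
#' @param assignment a `som_assignment`.
#' @return data.frame with columns `pathway`, `unit`, `unit_band`.
#' @export
som_assignment_table <- function(assignment) {
  stopifnot(inherits(assignment, "som_assignment"))
  data.frame(pathway = names(assignment$unit),
             unit = unname(assignment$unit),
             unit_band = assignment$units$band[unname(assignment$unit)],
             stringsAsFactors = FALSE)
}

#' Serialize a SOM model to JSON
#'
#' Dumps codebook, grid and hyperparameters; readable back into an
#' equivalent model with [read_som_model()].
#'
#' @param model a `som_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_som_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  obj <- list(codebook = unclass(model$codebook),
              groups = colnames(model$codebook),
              grid = model$grid, qe_trace = model$qe_trace,
              epochs = model$epochs, radius = model$radius,
              rate = model$rate, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a SOM model from JSON
#' @param path path written by [write_som_model()].
#' @return a `som_model`.
#' @export
read_som_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  codebook <- as.matrix(obj$codebook)
  dimnames(codebook) <- list(paste0("unit", seq_len(nrow(codebook))),
                             obj$groups)
  structure(list(codebook = codebook,
                 grid = as.data.frame(obj$grid),
                 qe_trace = obj$qe_trace,
                 epochs = as.integer(obj$epochs),
                 radius = obj$radius, rate = obj$rate, seed = obj$seed),
            class = "som_model")
}
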