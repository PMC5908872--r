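#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All randomized stages funnel through this, so an explicit integer
# seed fully determines their output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# One line per pipeline stage, to stderr, stating dimensions and the active
# thresholds so the effect of every filter is auditable.
stage_log <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[netexpr:%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tab-separated writer shared by every output table; fixed dialect (UTF-8,
# '.' decimal, no quoting) so write-then-read round-trips are reproducible.
write_tsv_table <- function(df, path, row_names = FALSE) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
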