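# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a taxa x samples count matrix. Returns it invisibly.
check_count_table <- function(table, arg = "table") {
  if (!is.matrix(table) || !is.numeric(table))
    stop(sprintf("`%s` must be a numeric taxa x samples matrix", arg), call. = FALSE)
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop(sprintf("`%s` must have taxon rownames and sample colnames", arg), call. = FALSE)
  if (anyDuplicated(rownames(table)))
    stop("duplicate taxon ids in count table", call. = FALSE)
  if (anyDuplicated(colnames(table)))
    stop("duplicate sample ids in count table", call. = FALSE)
  if (any(table < 0) || any(!is.finite(table)))
    stop("count table must contain non-negative finite values", call. = FALSE)
  invisible(table)
}

# Column-wise relative abundances (samples sum to 1).
relative_abundance <- function(table) {
  tot <- colSums(table)
  if (any(tot == 0)) stop("sample(s) with zero total count: ",
                          paste(colnames(table)[tot == 0], collapse = ", "),
                          call. = FALSE)
  sweep(table, 2, tot, "/")
}

# Structured error with a class so tests can target specific failures.
mn_stop <- function(class, msg, data = NULL) {
  cond <- structure(
    class = c(class, "micronet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}
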