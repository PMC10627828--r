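# Internal helpers shared across modules.

# One root seed fans out to per-stage streams so that stages are
# independently reproducible; kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 7919L + as.integer(stage)
}

softmax_rows <- function(logx) {
  m <- apply(logx, 1L, max)
  e <- exp(logx - m)
  e / rowSums(e)
}

# strict matrix check used by most entry points
check_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop(sprintf("'%s' must be a numeric samples x taxa matrix", what))
  if (any(counts < 0)) stop(sprintf("'%s' contains negative values", what))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(sprintf("'%s' needs sample rownames and taxon colnames", what))
  invisible(counts)
}

upper_tri_vec <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
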