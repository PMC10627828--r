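#' Normalized read concentration
#'
#' Per-sample QC statistic: the library size divided by the volume of
#' the sample pooled into its sequencing run (the read concentration),
#' scaled by the median read concentration of that run. The run median
#' is computed over all samples of the run, negative controls included.
#'
#' @param counts samples x taxa count matrix.
#' @param run_info data frame with one row per sample: \code{sample_id},
#'   \code{run_id}, \code{pooled_volume} (> 0), \code{is_control}.
#' @return named numeric vector of normalized read concentrations, in
#'   the row order of \code{counts}.
#' @examples
#' counts <- matrix(c(8000, 4000, 100), 3, 1,
#'                  dimnames = list(c("a", "b", "c"), "t1"))
#' ri <- data.frame(sample_id = c("a", "b", "c"), run_id = "run1",
#'                  pooled_volume = 2, is_control = FALSE)
#' normalized_read_concentration(counts, ri)  # 2.0 1.0 0.025
#' @export
normalized_read_concentration <- function(counts, run_info) {
  check_count_matrix(counts)
  ri <- run_info[match(rownames(counts), run_info$sample_id), , drop = FALSE]
  if (anyNA(ri$sample_id))
    stop("samples missing from run_info: ",
         paste(setdiff(rownames(counts), run_info$sample_id), collapse = ", "))
  if (any(!is.na(ri$pooled_volume) & ri$pooled_volume <= 0))
    stop("pooled_volume must be > 0 for all samples")
  lib <- rowSums(counts)
  conc <- lib / ri$pooled_volume
  med <- tapply(conc, ri$run_id, median)
  nrc <- conc / as.numeric(med[as.character(ri$run_id)])
  if (any(!is.finite(nrc)))
    warning("run(s) with all-zero library sizes: normalized read concentration is NaN")
  setNames(as.numeric(nrc), rownames(counts))
}

#' Sample quality control
#'
#' Retains samples whose normalized read concentration is strictly
#' greater than \code{nrc_min} and whose library size is strictly
#' greater than \code{depth_min}. Negative controls are always excluded
#' from the returned analysis table but appear in the report.
#'
#' @inheritParams normalized_read_concentration
#' @param nrc_min normalized-read-concentration cut-off (default 0.05).
#' @param depth_min library-size cut-off in reads (default 2000).
#' @return list with \code{counts} (retained samples) and \code{report},
#'   a \code{qc_report} data frame (one row per input sample) with
#'   library size, read concentration, normalized read concentration,
#'   the per-criterion pass flags and the retention decision; the
#'   thresholds used are stored as attributes.
#' @export
filter_samples <- function(counts, run_info, nrc_min = 0.05, depth_min = 2000) {
  nrc <- normalized_read_concentration(counts, run_info)
  ri <- run_info[match(rownames(counts), run_info$sample_id), , drop = FALSE]
  lib <- rowSums(counts)
  is_control <- ri$is_control %||% rep(FALSE, nrow(counts))
  pass_nrc <- !is.na(nrc) & nrc > nrc_min
  pass_depth <- lib > depth_min
  retained <- pass_nrc & pass_depth & !is_control
  report <- data.frame(
    sample_id = rownames(counts), run_id = ri$run_id,
    is_control = is_control, library_size = lib,
    read_concentration = lib / ri$pooled_volume,
    normalized_read_concentration = nrc,
    pass_nrc = pass_nrc, pass_depth = pass_depth, retained = retained,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "nrc_min") <- nrc_min
  attr(report, "depth_min") <- depth_min
  attr(report, "run_median_includes_controls") <- TRUE
  class(report) <- c("qc_report", "data.frame")
  if (!any(retained)) warning("no samples pass quality control")
  list(counts = counts[retained, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d retained (%s%%); nrc > %s, depth > %s\n",
              nrow(x), sum(x$retained),
              count_ratio_pct(sum(x$retained), nrow(x)),
              format(attr(x, "nrc_min")), format(attr(x, "depth_min"))))
  invisible(x)
}

#' Taxon quality control
#'
#' Drops non-bacterial taxa (for example mitochondrial reads) and taxa
#' whose recorded sequence length exceeds \code{max_len} bases (strict
#' "greater than"; taxa without a recorded length are kept). The
#' prevalence filter used before network inference and per-taxon
#' association testing is separate and off by default; enable it with
#' \code{apply_prevalence = TRUE} or call \code{\link{filter_prevalence}}
#' directly.
#'
#' @param counts samples x taxa count matrix.
#' @param taxonomy data frame with at least \code{taxon_id},
#'   \code{is_bacterial}, and optionally \code{sequence_length}; must
#'   cover every taxon in \code{counts}.
#' @param max_len maximum sequence length in bases (default 260).
#' @param apply_prevalence also apply the prevalence filter?
#' @param prevalence_min minimum fraction of samples a taxon must be
#'   present in (abundance > 0), default 0.10.
#' @return filtered count matrix.
#' @export
filter_taxa <- function(counts, taxonomy, max_len = 260,
                        apply_prevalence = FALSE, prevalence_min = 0.10) {
  check_count_matrix(counts)
  miss <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(miss))
    stop("taxa absent from taxonomy: ", paste(miss, collapse = ", "))
  tx <- taxonomy[match(colnames(counts), taxonomy$taxon_id), , drop = FALSE]
  len <- tx$sequence_length %||% rep(NA_real_, nrow(tx))
  keep <- tx$is_bacterial & (is.na(len) | len <= max_len)
  out <- counts[, keep, drop = FALSE]
  if (apply_prevalence) out <- filter_prevalence(out, prevalence_min)
  out
}

#' Prevalence filter
#'
#' Keeps taxa present (abundance greater than zero) in at least
#' \code{prevalence_min} of the samples. Applied, as in the upstream
#' methods, only before network inference and per-taxon association
#' testing, on the post-sample-QC table.
#'
#' @inheritParams filter_taxa
#' @return filtered count matrix.
#' @export
filter_prevalence <- function(counts, prevalence_min = 0.10) {
  check_count_matrix(counts)
  prev <- colMeans(counts > 0)
  counts[, prev >= prevalence_min, drop = FALSE]
}

#' Percentage from a pair of counts
#'
#' Reporting helper for cohort summaries such as retention and
#' prevalence fractions: \code{100 * k / n} rounded to \code{digits}
#' decimals (half away from zero).
#'
#' @param k,n numerator and denominator counts.
#' @param digits decimals to keep (default 1).
#' @examples
#' count_ratio_pct(3196, 3345)  # 95.5
#' @export
count_ratio_pct <- function(k, n, digits = 1) {
  stopifnot(n > 0, k >= 0)
  x <- 100 * k / n
  # round half away from zero (printed-table convention)
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
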