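#' Flag extreme-tail measurements of one phenotype
#'
#' Pools all measurements of a phenotype across past and current photos and
#' flags values strictly below the `lower_pct` percentile or strictly above
#' the `100 - upper_pct` percentile (linear-interpolation percentiles,
#' [stats::quantile()] type 7). Values exactly at a boundary survive, so at
#' least `100 - lower_pct - upper_pct` percent of the data is always kept.
#' Trimming is not idempotent: re-trimming the kept values trims again.
#'
#' An alternative boxplot rule (flag outside the Tukey fences
#' `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`) is available via `method = "iqr"` for
#' comparison; the percentile rule is the default.
#'
#' @param values Numeric vector (one phenotype, pooled over photos).
#' @param lower_pct,upper_pct Percent trimmed from each tail (default 2).
#' @param method `"percentile"` (default) or `"iqr"`.
#' @return Character vector the length of `values` with levels
#'   `"kept"`, `"low_tail"`, `"high_tail"`.
#' @examples
#' table(trim_tails(1:50))
#' @export
trim_tails <- function(values, lower_pct = 2, upper_pct = 2,
                       method = c("percentile", "iqr")) {
  method <- match.arg(method)
  if (length(values) < 1L) stop_eafg("trim_tails: empty input")
  if (anyNA(values)) stop_eafg("trim_tails: NA values not allowed")
  if (lower_pct < 0 || upper_pct < 0 || lower_pct + upper_pct >= 100) {
    stop_eafg("trim_tails: need 0 <= lower_pct + upper_pct < 100")
  }
  if (method == "percentile") {
    lo <- quantile(values, lower_pct / 100, names = FALSE, type = 7)
    hi <- quantile(values, 1 - upper_pct / 100, names = FALSE, type = 7)
  } else {
    qs <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- qs[2] - qs[1]
    lo <- qs[1] - 1.5 * iqr
    hi <- qs[2] + 1.5 * iqr
  }
  out <- rep("kept", length(values))
  out[values < lo] <- "low_tail"
  out[values > hi] <- "high_tail"
  out
}

#' Apply tail trimming to a long-format phenotype table
#'
#' Runs [trim_tails()] independently for every phenotype, pooling all photos
#' (past and current) of all persons, and returns the QC mask. Each record is
#' flagged exactly once. Single (person, photo, phenotype) records are
#' dropped, not whole photos.
#'
#' @param phenotypes Long-format phenotype data frame.
#' @inheritParams trim_tails
#' @return `phenotypes` with added columns `qc_flag` and `qc_pass`.
#' @export
apply_measurement_qc <- function(phenotypes, lower_pct = 2, upper_pct = 2,
                                 method = c("percentile", "iqr")) {
  method <- match.arg(method)
  flag <- rep(NA_character_, nrow(phenotypes))
  for (ph in unique(phenotypes$phenotype)) {
    idx <- which(phenotypes$phenotype == ph)
    flag[idx] <- trim_tails(phenotypes$value[idx], lower_pct, upper_pct,
                            method = method)
  }
  phenotypes$qc_flag <- flag
  phenotypes$qc_pass <- flag == "kept"
  phenotypes
}
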