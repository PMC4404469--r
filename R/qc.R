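#' Filter samples on RNA quality metrics
#'
#' Keeps a sample only if its RNA Quality Indicator exceeds `rqi_min` (strict
#' inequality: "above 7") and its A260/A280 absorbance ratio lies within
#' `[ratio_low, ratio_high]`. The partition is exhaustive and disjoint, and
#' every rejected sample carries a machine-readable reason code: `"rqi"`,
#' `"ratio"`, `"rqi,ratio"` or `"missing_qc"`.
#'
#' @param meta data frame with columns `sample_id`, `rqi`, `a260_280`.
#' @param rqi_min minimum RQI, exclusive (default 7).
#' @param ratio_low,ratio_high inclusive A260/280 bounds (defaults 1.9, 2.1).
#' @param missing_qc policy for samples with missing QC fields: `"reject"`
#'   (default, reason `"missing_qc"`) or `"keep"`.
#' @return A list with `kept` (character vector of sample ids) and `rejected`
#'   (data frame with columns `sample_id`, `reason`).
#' @examples
#' meta <- data.frame(sample_id = c("a", "b", "c"),
#'                    rqi = c(7.5, 6.9, 9.0),
#'                    a260_280 = c(2.0, 2.0, 1.85))
#' qc_filter_samples(meta)
#' @export
qc_filter_samples <- function(meta, rqi_min = 7, ratio_low = 1.9,
                              ratio_high = 2.1,
                              missing_qc = c("reject", "keep")) {
  missing_qc <- match.arg(missing_qc)
  if (!all(c("sample_id", "rqi", "a260_280") %in% names(meta)))
    stop("`meta` needs columns sample_id, rqi, a260_280")
  n <- nrow(meta)
  reason <- character(n)
  incomplete <- is.na(meta$rqi) | is.na(meta$a260_280)
  fail_rqi <- !is.na(meta$rqi) & meta$rqi <= rqi_min
  fail_ratio <- !is.na(meta$a260_280) &
    (meta$a260_280 < ratio_low | meta$a260_280 > ratio_high)
  for (i in seq_len(n)) {
    codes <- c(if (fail_rqi[i]) "rqi", if (fail_ratio[i]) "ratio")
    if (incomplete[i] && missing_qc == "reject")
      codes <- c(codes, "missing_qc")
    reason[i] <- paste(codes, collapse = ",")
  }
  rejected <- reason != ""
  list(kept = meta$sample_id[!rejected],
       rejected = data.frame(sample_id = meta$sample_id[rejected],
                             reason = reason[rejected],
                             stringsAsFactors = FALSE))
}
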