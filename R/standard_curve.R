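# Standard-curve fitting and amplification-efficiency estimation.

#' PCR amplification efficiency from a standard-curve slope
#'
#' Converts the slope of a Cq-versus-log10(dilution) regression into the
#' percent amplification efficiency, `E(%) = (10^(-1/slope) - 1) * 100`.
#' A slope of `-1/log10(2) = -3.321928...` corresponds to perfect doubling
#' (100%).
#'
#' @param slope regression slope in cycles per log10 dilution unit; must be
#'   negative for an amplifying assay.
#' @return Efficiency in percent.
#' @examples
#' compute_efficiency(-1 / log10(2))   # 100
#' compute_efficiency(-3)              # 115.443...
#' @export
compute_efficiency <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope))
    stop("`slope` must be a single finite number")
  if (slope >= 0)
    stop("`slope` must be negative for an amplifying standard curve")
  (10^(-1 / slope) - 1) * 100
}

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares regression of mean Cq on log10 relative template
#' amount over a serial-dilution series. The slope yields the amplification
#' efficiency via [compute_efficiency()].
#'
#' @param log10_dilution log10 relative template amounts (at least 3 distinct
#'   levels).
#' @param mean_cq mean Cq observed at each dilution.
#' @param gene_id optional assay identifier carried in the result.
#' @return An object of class `standard_curve` with fields `gene_id`,
#'   `log10_dilutions`, `mean_cq_per_dilution`, `slope`, `intercept`,
#'   `r_squared` and `efficiency_percent`.
#' @export
fit_standard_curve <- function(log10_dilution, mean_cq,
                               gene_id = NA_character_) {
  stopifnot(length(log10_dilution) == length(mean_cq))
  ok <- is.finite(log10_dilution) & is.finite(mean_cq)
  x <- log10_dilution[ok]; y <- mean_cq[ok]
  if (length(unique(x)) < 3L)
    stop("a standard curve needs at least 3 distinct dilution levels")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("non-amplifying curve: slope must be negative")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(gene_id = gene_id,
                 log10_dilutions = x,
                 mean_cq_per_dilution = y,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 efficiency_percent = compute_efficiency(slope)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve%s: slope %.4f, intercept %.3f, r2 %.4f, E = %.1f%%\n",
    if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
    x$slope, x$intercept, x$r_squared, x$efficiency_percent))
  invisible(x)
}
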