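# Cq -> relative-quantity transformation and Cq summaries.

#' Transform Cq values to relative quantities
#'
#' For each gene g with amplification factor A_g, the relative quantity in
#' sample s is `q = A_g^(min_Cq - Cq)`, so the sample with the lowest Cq
#' (highest expression) is the calibrator with q = 1 and every quantity lies
#' in (0, 1]. This is the standard delta-Cq transform applied before
#' stability analysis; with the default A = 2 it equals `2^(-dCq)`.
#'
#' Missing entries are handled first, per `missing`: `"drop"` removes every
#' sample with any missing gene (both downstream stability algorithms need a
#' complete matrix), `"impute"` replaces missing Cq with `max_cycles`
#' (treating "no amplification" as censored at the final cycle).
#'
#' @param table a [cq_table()] with technical replicates already aggregated.
#' @param efficiencies per-gene amplification factor (unitless, `1 + E/100`),
#'   a scalar or a vector named by gene; values must lie in (1, 3].
#'   Default 2 (100% efficiency).
#' @param missing missing-Cq policy, `"drop"` (default) or `"impute"`.
#' @param calibrator optional sample id to use as the calibrator for every
#'   gene instead of the per-gene minimum-Cq sample.
#' @return An object of class `quantity_matrix` with fields `genes`,
#'   `samples`, `q` (matrix, all > 0, per-gene max 1 under the default
#'   calibrator) and `efficiencies`.
#' @export
cq_to_quantities <- function(table, efficiencies = 2,
                             missing = c("drop", "impute"),
                             calibrator = NULL) {
  stopifnot(inherits(table, "cq_table"))
  missing <- match.arg(missing)
  G <- length(table$genes)
  A <- .expand_efficiencies(efficiencies, table$genes)
  cq <- table$cq
  all_missing <- rowSums(!is.na(cq)) == 0L
  if (any(all_missing))
    stop("gene(s) missing in every sample: ",
         paste(table$genes[all_missing], collapse = ", "))
  if (anyNA(cq)) {
    if (missing == "impute") {
      cq[is.na(cq)] <- table$max_cycles
    } else {
      keep <- colSums(is.na(cq)) == 0L
      if (!any(keep))
        stop("no complete samples remain under the 'drop' missing policy")
      cq <- cq[, keep, drop = FALSE]
    }
  }
  if (is.null(calibrator)) {
    ref <- apply(cq, 1L, min)
  } else {
    if (!calibrator %in% colnames(cq))
      stop("calibrator sample not found: ", calibrator)
    ref <- cq[, calibrator]
  }
  q <- A^(ref - cq)   # A and ref recycle down columns (genes in rows)
  structure(list(genes = table$genes, samples = colnames(cq), q = q,
                 efficiencies = A),
            class = "quantity_matrix")
}

.expand_efficiencies <- function(efficiencies, genes) {
  if (length(efficiencies) == 1L && is.null(names(efficiencies)))
    efficiencies <- stats::setNames(rep(efficiencies, length(genes)), genes)
  if (is.null(names(efficiencies)) && length(efficiencies) == length(genes))
    names(efficiencies) <- genes
  if (!all(genes %in% names(efficiencies)))
    stop("efficiencies missing for gene(s): ",
         paste(setdiff(genes, names(efficiencies)), collapse = ", "))
  A <- efficiencies[genes]
  if (any(A <= 1 | A > 3))
    stop("amplification factors must lie in (1, 3]")
  A
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("quantity_matrix: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  invisible(x)
}

#' Log2-transform a quantity matrix
#'
#' @param q a `quantity_matrix` (or a positive numeric matrix).
#' @return A numeric matrix `log2(q)`, same shape and dimnames.
#' @export
log_transform <- function(q) {
  m <- if (inherits(q, "quantity_matrix")) q$q else as.matrix(q)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all quantities must be finite and positive")
  log2(m)
}

#' Fold difference in template abundance between two Cq values
#'
#' Each amplification cycle multiplies template by the amplification factor,
#' so a transcript detected `cq_high - cq_low` cycles earlier is
#' `A^(cq_high - cq_low)`-fold more abundant.
#'
#' @param cq_low Cq of the more abundant transcript (cycles).
#' @param cq_high Cq of the less abundant transcript (cycles).
#' @param amplification_factor per-cycle yield, > 1 (default 2, i.e. perfect
#'   doubling).
#' @return The fold abundance (may be < 1 if `cq_high < cq_low`).
#' @examples
#' fold_abundance(9.42, 27.31)   # ~2.4e5-fold
#' @export
fold_abundance <- function(cq_low, cq_high, amplification_factor = 2) {
  if (amplification_factor <= 1)
    stop("`amplification_factor` must exceed 1")
  amplification_factor^(cq_high - cq_low)
}

#' Per-gene summary of the Cq distribution
#'
#' Summarizes present Cq values gene by gene: median, quartiles, 5th/95th
#' percentiles (whisker/outlier bounds in the usual expression-range plot),
#' minimum and maximum. Percentiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param table a [cq_table()].
#' @return Data frame with one row per gene and columns `gene`, `n`, `min`,
#'   `p5`, `q1`, `median`, `q3`, `p95`, `max`. Genes with no present values
#'   are omitted with a warning.
#' @export
summarize_cq_distribution <- function(table) {
  stopifnot(inherits(table, "cq_table"))
  counts <- rowSums(!is.na(table$cq))
  if (any(counts == 0L))
    warning("omitting gene(s) with no present Cq values: ",
            paste(table$genes[counts == 0L], collapse = ", "))
  keep <- which(counts > 0L)
  rows <- lapply(keep, function(i) {
    v <- table$cq[i, ]
    v <- v[!is.na(v)]
    qs <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95),
                          names = FALSE, type = 7)
    data.frame(gene = table$genes[i], n = length(v), min = min(v),
               p5 = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4],
               p95 = qs[5], max = max(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
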