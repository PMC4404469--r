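# Consensus ranking across stability algorithms: integer rank weights per
# method, combined by geometric mean, lowest GM = most stable.

#' Assign rank weights from per-method gene orderings
#'
#' Each method contributes a weight per gene: continuous integers 1..G from
#' its most to least stable gene. A method may be given either as a
#' character vector (genes best to worst, no ties) or as a named numeric
#' vector of scores/ranks where lower means more stable; tied scores share
#' the mean of the integers they span (e.g. a tied best pair gets 1.5 each).
#'
#' @param rankings named list of methods, each a character ordering or a
#'   named numeric score vector over the same gene set.
#' @return Numeric matrix of weights, genes in rows, methods in columns.
#' @export
assign_weights <- function(rankings) {
  stopifnot(is.list(rankings), length(rankings) >= 1L)
  to_weights <- function(r) {
    if (is.character(r)) {
      if (anyDuplicated(r)) stop("duplicated gene in an ordering")
      stats::setNames(rank(seq_along(r)), r)
    } else if (is.numeric(r) && !is.null(names(r))) {
      rank(r, ties.method = "average")
    } else {
      stop("each method must be a character ordering or named numeric scores")
    }
  }
  ws <- lapply(rankings, to_weights)
  genes <- names(ws[[1L]])
  for (w in ws[-1L])
    if (!setequal(names(w), genes))
      stop("methods disagree on the gene set")
  out <- vapply(ws, function(w) w[genes], numeric(length(genes)))
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, names(rankings)))
  out
}

#' Consensus ranking by geometric mean of rank weights
#'
#' The comprehensive ranking: each gene's weights across methods are combined
#' by their geometric mean, and genes are re-ranked ascending — the gene with
#' the lowest GM is viewed as the most stable. GM ties are broken by the mean
#' per-method weight, then by input order.
#'
#' @param per_method_ranks weight matrix from [assign_weights()] (genes in
#'   rows, >= 2 method columns), or a named list accepted by it.
#' @return An object of class `consensus_ranking` with `per_method_ranks`,
#'   `gm` (named, input gene order) and `final_order` (genes, most stable
#'   first).
#' @export
geometric_mean_rank <- function(per_method_ranks) {
  if (is.list(per_method_ranks) && !is.matrix(per_method_ranks))
    per_method_ranks <- assign_weights(per_method_ranks)
  w <- as.matrix(per_method_ranks)
  if (ncol(w) < 2L) stop("consensus needs at least 2 methods")
  if (any(w <= 0)) stop("rank weights must be positive")
  gm <- stats::setNames(exp(rowMeans(log(w))), rownames(w))
  ord <- order(gm, rowMeans(w), seq_along(gm))
  structure(list(per_method_ranks = w, gm = gm,
                 final_order = rownames(w)[ord]),
            class = "consensus_ranking")
}

#' Consensus of a geNorm and a NormFinder analysis
#'
#' Convenience wrapper: takes the two algorithm results on the same gene
#' panel, converts each to rank weights (the geNorm final pair tied at 1.5;
#' NormFinder ranks with mean-rank ties) and combines them with
#' [geometric_mean_rank()].
#'
#' @param genorm_result a `genorm_result`.
#' @param normfinder_result a `normfinder_result`.
#' @return A `consensus_ranking`.
#' @export
consensus_rank <- function(genorm_result, normfinder_result) {
  stopifnot(inherits(genorm_result, "genorm_result"),
            inherits(normfinder_result, "normfinder_result"))
  geometric_mean_rank(list(geNorm = genorm_weights(genorm_result),
                           NormFinder = normfinder_result$rank))
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("Consensus ranking (geometric mean of rank weights)\n")
  for (g in x$final_order)
    cat(sprintf("  %-12s GM = %.3f\n", g, x$gm[g]))
  invisible(x)
}
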