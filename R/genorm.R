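# geNorm: pairwise expression stability (M), stepwise exclusion,
# normalization factors and the V(n/n+1) criterion.
#
# All log-ratios are base 2 and all standard deviations use the n-1
# denominator, the conventions of the original geNorm implementation.

.as_q_matrix <- function(q) {
  m <- if (inherits(q, "quantity_matrix")) q$q else as.matrix(q)
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  if (any(!is.finite(m)) || any(m <= 0))
    stop("relative quantities must be finite and positive")
  m
}

#' Pairwise variation between two genes
#'
#' The geNorm pairwise variation V_jk is the sample standard deviation
#' (denominator n - 1) across samples of the log2 ratio of the two genes'
#' relative quantities. Two genes whose ratio is constant across samples
#' have V = 0; V is symmetric in its arguments.
#'
#' @param q a `quantity_matrix` or positive numeric matrix (genes in rows).
#' @param gene_j,gene_k gene names or row indices; must share at least two
#'   samples.
#' @return The pairwise variation (unitless SD of log2 ratios).
#' @export
pairwise_variation <- function(q, gene_j, gene_k) {
  m <- .as_q_matrix(q)
  if (ncol(m) < 2L) stop("pairwise variation needs at least 2 common samples")
  stats::sd(log2(m[gene_j, ] / m[gene_k, ]))
}

#' geNorm expression stability values (M)
#'
#' M_j is the average of the pairwise variations V_jk of gene j against all
#' other genes in the panel; lower M means more stable expression.
#'
#' @param q a `quantity_matrix` or positive numeric matrix with at least 3
#'   genes and 2 samples (complete: apply a missing policy first).
#' @return Named numeric vector of M values (one per gene, all >= 0).
#' @export
m_values <- function(q) {
  m <- .as_q_matrix(q)
  G <- nrow(m)
  if (G < 3L) stop("M values need at least 3 genes in the panel")
  if (ncol(m) < 2L) stop("M values need at least 2 samples")
  y <- log2(m)
  V <- matrix(0, G, G)
  for (j in seq_len(G - 1L))
    for (k in (j + 1L):G)
      V[j, k] <- V[k, j] <- stats::sd(y[j, ] - y[k, ])
  stats::setNames(rowSums(V) / (G - 1L), rownames(m))
}

#' Rank genes by stepwise exclusion of the least stable
#'
#' The geNorm ranking procedure: compute M on the current panel, remove the
#' gene with the highest M, and repeat until two genes remain. The final two
#' cannot be ranked against each other and are reported as a tied pair with
#' their shared M (the SD of their mutual log2 ratio). Exact ties in the
#' maximal M (within 1e-12) are broken by excluding the gene that appears
#' latest in the input order, making the trace deterministic.
#'
#' @param q a `quantity_matrix` or positive numeric matrix, >= 3 genes.
#' @return A list of class `genorm_ranking` with `exclusion_order` (least to
#'   most stable), `final_pair`, `final_pair_m`, `per_step_m` (M values at
#'   every step, full panel first) and `stability_order` (all genes, best
#'   first; the final pair leads, in input order).
#' @export
rank_by_stepwise_exclusion <- function(q) {
  m <- .as_q_matrix(q)
  if (nrow(m) < 3L) stop("stepwise exclusion needs at least 3 genes")
  remaining <- rownames(m)
  exclusion_order <- character(0)
  per_step_m <- list()
  while (length(remaining) > 2L) {
    M <- m_values(m[remaining, , drop = FALSE])
    per_step_m[[length(per_step_m) + 1L]] <- M
    cand <- which(M >= max(M) - 1e-12)
    worst <- names(M)[cand[length(cand)]]   # latest in input order
    exclusion_order <- c(exclusion_order, worst)
    remaining <- setdiff(remaining, worst)
  }
  final_pair_m <- stats::sd(log2(m[remaining[1L], ] / m[remaining[2L], ]))
  structure(list(exclusion_order = exclusion_order,
                 final_pair = remaining,
                 final_pair_m = final_pair_m,
                 per_step_m = per_step_m,
                 stability_order = c(remaining, rev(exclusion_order))),
            class = "genorm_ranking")
}

#' Per-sample normalization factor for a reference-gene set
#'
#' NF_s is the geometric mean of the chosen genes' relative quantities in
#' sample s.
#'
#' @param q a `quantity_matrix` or positive numeric matrix.
#' @param genes_subset non-empty vector of gene names (or row indices).
#' @return Named numeric vector of normalization factors, one per sample.
#' @export
normalization_factor <- function(q, genes_subset) {
  m <- .as_q_matrix(q)
  if (!length(genes_subset)) stop("`genes_subset` must be non-empty")
  sub <- m[genes_subset, , drop = FALSE]
  2^colMeans(log2(sub))
}

#' Pairwise variation of successive normalization factors, V(n/n+1)
#'
#' For n = 2 .. G-1, V_n/n+1 is the sample SD across samples of
#' `log2(NF_n / NF_{n+1})`, where NF_n is built from the n most stable genes.
#' A small V means the (n+1)-th gene adds little to the normalization.
#'
#' @param q a `quantity_matrix` or positive numeric matrix.
#' @param stability_order all genes ordered best to worst (e.g. from
#'   [rank_by_stepwise_exclusion()]).
#' @return Data frame with columns `n` and `v`.
#' @export
v_n_series <- function(q, stability_order) {
  m <- .as_q_matrix(q)
  G <- nrow(m)
  if (G < 3L) stop("V(n/n+1) needs at least 3 genes")
  if (!setequal(stability_order, rownames(m)))
    stop("`stability_order` must contain exactly the genes of `q`")
  v <- vapply(2:(G - 1L), function(n) {
    nf_n <- normalization_factor(m, stability_order[seq_len(n)])
    nf_n1 <- normalization_factor(m, stability_order[seq_len(n + 1L)])
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1))
  data.frame(n = 2:(G - 1L), v = v)
}

#' Recommend how many reference genes to use
#'
#' Applies the conventional 0.15 cutoff to a V(n/n+1) series:
#' `recommended_n` is the smallest n whose V_n/n+1 falls at or below the
#' cutoff (n genes suffice). `optional_extra_n` is the largest m such that
#' every V_k/k+1 with k < m is also at or below the cutoff — genes up to that
#' count could also be used without degrading the normalization. If no V
#' meets the cutoff, `recommended_n` is the full panel size with
#' `all_above_cutoff = TRUE`.
#'
#' @param v_series data frame with columns `n`, `v` (as from [v_n_series()]).
#' @param cutoff pairwise-variation threshold (default 0.15).
#' @return A list with `recommended_n`, `optional_extra_n`, `cutoff` and
#'   `all_above_cutoff`.
#' @examples
#' recommend_gene_count(data.frame(n = c(2, 3), v = c(0.13, 0.177)))
#' @export
recommend_gene_count <- function(v_series, cutoff = 0.15) {
  stopifnot(is.data.frame(v_series), all(c("n", "v") %in% names(v_series)),
            nrow(v_series) >= 1L)
  v_series <- v_series[order(v_series$n), , drop = FALSE]
  G <- max(v_series$n) + 1L
  under <- v_series$v <= cutoff
  if (!any(under))
    return(list(recommended_n = G, optional_extra_n = G, cutoff = cutoff,
                all_above_cutoff = TRUE))
  recommended_n <- min(v_series$n[under])
  extra <- 2L
  for (m in 2:G) {
    prior <- v_series$n < m
    if (all(under[prior])) extra <- m else break
  }
  list(recommended_n = recommended_n, optional_extra_n = extra,
       cutoff = cutoff, all_above_cutoff = FALSE)
}

#' Classify a geNorm M value
#'
#' By convention, M values at or below 0.5 indicate stable expression in
#' homogeneous sample panels; in heterogeneous panels values up to 1 are
#' still acceptable.
#'
#' @param m M value (>= 0).
#' @param panel `"homogeneous"` or `"heterogeneous"`.
#' @return `"stable"`, `"acceptable"` or `"unstable"`.
#' @export
classify_m <- function(m, panel = c("homogeneous", "heterogeneous")) {
  panel <- match.arg(panel)
  if (!is.numeric(m) || any(m < 0)) stop("`m` must be non-negative")
  out <- ifelse(m <= 0.5, "stable",
                ifelse(panel == "heterogeneous" & m <= 1, "acceptable",
                       "unstable"))
  unname(out)
}

#' Full geNorm analysis
#'
#' Runs the complete geNorm procedure on a relative-quantity matrix:
#' full-panel M values, stepwise exclusion ranking, the V(n/n+1) series along
#' the resulting stability order, and the reference-gene-count
#' recommendation.
#'
#' @param q a `quantity_matrix` or positive numeric matrix, >= 3 genes.
#' @param cutoff V(n/n+1) cutoff passed to [recommend_gene_count()].
#' @return An object of class `genorm_result` with fields `m_values`
#'   (full panel), `exclusion_order`, `final_pair`, `final_pair_m`,
#'   `per_step_m`, `stability_order`, `v_series`, `recommended_n`,
#'   `optional_extra_n` and `all_above_cutoff`.
#' @export
genorm <- function(q, cutoff = 0.15) {
  m <- .as_q_matrix(q)
  ranking <- rank_by_stepwise_exclusion(m)
  v <- v_n_series(m, ranking$stability_order)
  rec <- recommend_gene_count(v, cutoff = cutoff)
  structure(c(list(m_values = ranking$per_step_m[[1L]]),
              unclass(ranking),
              list(v_series = v,
                   recommended_n = rec$recommended_n,
                   optional_extra_n = rec$optional_extra_n,
                   all_above_cutoff = rec$all_above_cutoff,
                   cutoff = cutoff)),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm analysis\n")
  cat("  most stable pair:", paste(x$final_pair, collapse = " / "),
      sprintf("(M = %.3f)\n", x$final_pair_m))
  cat("  stability order (best first):",
      paste(x$stability_order, collapse = ", "), "\n")
  cat(sprintf("  recommended genes: %d (up to %d usable at V <= %g)\n",
              x$recommended_n, x$optional_extra_n, x$cutoff))
  invisible(x)
}

#' Rank weights from a geNorm result
#'
#' Integer-style weights for consensus ranking: the tied final pair shares
#' weight 1.5, then 3, 4, ... along the exclusion trace (most stable first).
#'
#' @param x a `genorm_result`.
#' @return Named numeric vector of weights, one per gene.
#' @export
genorm_weights <- function(x) {
  stopifnot(inherits(x, "genorm_result"))
  w <- c(1.5, 1.5, seq(3, length.out = length(x$exclusion_order)))
  stats::setNames(w, x$stability_order)
}
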