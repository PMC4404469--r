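# NormFinder: model-based stability estimation on log2 expression.
#
# The model treats each group of samples as a two-way (gene x sample) layout:
#   y_igj = alpha_i + b_gj + d_ig + eps_igj
# where d_ig is gene i's differential expression in group g (zero-sum over
# genes within a group) and eps has gene-specific variance sigma2_ig. The
# estimator corrects the naive residual variance for contamination by the
# other genes' variances (factor G/(G-2)) and shrinks the estimated group
# effects toward zero by tau2 / (tau2 + sigma2/n).

.two_way_residuals <- function(y) {
  sweep(sweep(y, 1L, rowMeans(y)), 2L, colMeans(y)) + mean(y)
}

# Unbiased per-gene intra-group variance from a two-way layout.
# z_i = sum_j R_ij^2 / (n-1); sigma2_i = (z_i - sum(z)/(G(G-1))) * G/(G-2).
.intra_group_variance <- function(y, floor_variance = TRUE) {
  G <- nrow(y); n <- ncol(y)
  R <- .two_way_residuals(y)
  z <- rowSums(R^2) / (n - 1L)
  sigma2 <- (z - sum(z) / (G * (G - 1L))) * G / (G - 2L)
  if (floor_variance) sigma2 <- pmax(sigma2, 0)
  sigma2
}

#' NormFinder stability analysis
#'
#' Estimates per-gene expression stability from log2 relative quantities,
#' optionally accounting for sample subgroups (tissues, treatments, ...).
#' Lower stability values indicate more stably expressed genes; genes are
#' ranked ascending.
#'
#' Ungrouped mode treats all samples as one group and reports
#' `sqrt(max(0, sigma2_i))`, the estimated gene-specific SD after removing
#' the overall gene and sample effects and correcting for contamination by
#' the other genes. Grouped mode additionally estimates each gene's
#' differential expression `d_ig` between groups, shrinks it by
#' `tau2 / (tau2 + sigma2_ig/n_g)` where `tau2` is the variance of the group
#' effects across genes, and combines both sources:
#' `rho_ig = |d_shrunk| + sqrt((sigma2_ig/n_g) * tau2 / (tau2 + sigma2_ig/n_g))`,
#' averaged over groups.
#'
#' When the estimated `tau2` is exactly 0 the grouped stability degenerates
#' to 0 for every gene; the function then falls back to the ungrouped
#' estimator and flags the result (`tau2_zero_fallback = TRUE`) so a usable
#' ranking is always returned.
#'
#' @param y a `quantity_matrix`, a positive quantity matrix, or (with
#'   `log_input = TRUE`) a log2-expression matrix; genes in rows. At least 3
#'   genes (the correction divides by G - 2).
#' @param groups optional factor/character of group labels, one per sample;
#'   every group needs at least 2 samples. `NULL` or a single level gives the
#'   ungrouped estimator.
#' @param log_input set `TRUE` if `y` is already log2-transformed.
#' @param floor_variance floor negative intra-group variance estimates at 0
#'   (default). `FALSE` keeps the raw unbiased estimates in `intra_var`
#'   (stability still uses the floored value).
#' @return An object of class `normfinder_result` with fields `stability`,
#'   `rank` (ties share the mean rank), `grouped`, `intra_var` (genes x
#'   groups), `inter_effect` (d_ig, grouped only), `tau2` and
#'   `tau2_zero_fallback`.
#' @export
normfinder <- function(y, groups = NULL, log_input = FALSE,
                       floor_variance = TRUE) {
  m <- if (log_input) as.matrix(y) else log_transform(y)
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  if (nrow(m) < 3L)
    stop("NormFinder needs at least 3 candidate genes")
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (length(groups) != ncol(m))
      stop("`groups` must have one label per sample")
  }
  if (is.null(groups) || nlevels(groups) == 1L)
    return(.normfinder_ungrouped(m, floor_variance))
  .normfinder_grouped(m, groups, floor_variance)
}

.normfinder_ungrouped <- function(m, floor_variance = TRUE) {
  if (ncol(m) < 3L) stop("ungrouped NormFinder needs at least 3 samples")
  sigma2_raw <- .intra_group_variance(m, floor_variance = FALSE)
  stability <- sqrt(pmax(sigma2_raw, 0))
  intra <- matrix(if (floor_variance) pmax(sigma2_raw, 0) else sigma2_raw,
                  ncol = 1L, dimnames = list(rownames(m), "all"))
  .new_normfinder_result(stability, rownames(m), grouped = FALSE,
                         intra_var = intra, inter_effect = NULL,
                         tau2 = NA_real_, fallback = FALSE)
}

.normfinder_grouped <- function(m, groups, floor_variance = TRUE) {
  G <- nrow(m)
  lev <- levels(groups)
  n_g <- table(groups)
  if (any(n_g < 2L))
    stop("every group needs at least 2 samples; too small: ",
         paste(lev[n_g < 2L], collapse = ", "))
  Gam <- length(lev)
  sigma2_raw <- sapply(lev, function(g)
    .intra_group_variance(m[, groups == g, drop = FALSE],
                          floor_variance = FALSE))
  sigma2 <- if (floor_variance) pmax(sigma2_raw, 0) else sigma2_raw
  group_means <- sapply(lev, function(g)
    rowMeans(m[, groups == g, drop = FALSE]))
  d <- .two_way_residuals(group_means)   # d_ig, zero-sum over genes per group
  nvec <- as.numeric(n_g[lev])
  # stability always uses the floored variances; the flag only controls what
  # is stored in intra_var
  samp_var <- sweep(pmax(sigma2_raw, 0), 2L, nvec, "/")   # sigma2_ig / n_g
  tau2 <- max(0, sum(d^2) / ((G - 1L) * (Gam - 1L)) - mean(samp_var))
  if (tau2 == 0) {
    res <- .normfinder_ungrouped(m, floor_variance)
    res$grouped <- TRUE
    res$intra_var <- sigma2
    res$inter_effect <- d
    res$tau2 <- 0
    res$tau2_zero_fallback <- TRUE
    return(res)
  }
  shrink <- tau2 / (tau2 + samp_var)
  rho <- abs(d * shrink) + sqrt(samp_var * shrink)
  stability <- rowMeans(rho)
  .new_normfinder_result(stability, rownames(m), grouped = TRUE,
                         intra_var = sigma2, inter_effect = d,
                         tau2 = tau2, fallback = FALSE)
}

.new_normfinder_result <- function(stability, genes, grouped, intra_var,
                                   inter_effect, tau2, fallback) {
  stability <- stats::setNames(as.numeric(stability), genes)
  structure(list(stability = stability,
                 rank = rank(stability, ties.method = "average"),
                 grouped = grouped,
                 intra_var = intra_var,
                 inter_effect = inter_effect,
                 tau2 = tau2,
                 tau2_zero_fallback = fallback),
            class = "normfinder_result")
}

#' Genes ordered by NormFinder stability
#'
#' @param result a `normfinder_result`.
#' @return Character vector of gene names, most stable first (ties kept in
#'   input order).
#' @export
rank_genes <- function(result) {
  stopifnot(inherits(result, "normfinder_result"))
  names(sort(result$stability))
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("NormFinder analysis (%s%s)\n",
              if (x$grouped) "grouped" else "ungrouped",
              if (isTRUE(x$tau2_zero_fallback))
                ", tau2 = 0: ungrouped fallback" else ""))
  ord <- order(x$stability)
  cat("  stability (best first):\n")
  for (i in ord)
    cat(sprintf("    %-12s %.4f\n", names(x$stability)[i], x$stability[i]))
  invisible(x)
}
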