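# Synthetic Cq data with known ground truth, emulating a factorial plant
# growth study: tissues x inoculation treatment x temperature x sampling
# week, three biological replicates per condition cell (destructive
# sampling), two qPCR technical replicates per RNA sample.

#' The study's factorial design
#'
#' The 24 condition cells of the growth experiment: leaves and stems, with
#' and without PGPR inoculation, sampled at weeks 4/6/8 at 20 degrees C;
#' flowers and seeds (appearing later) at weeks 6/8; and uninoculated leaves
#' grown at 15 and 25 degrees C sampled at weeks 4/6.
#'
#' @return Data frame with columns `tissue`, `treatment`, `temperature`,
#'   `week`, one row per condition cell.
#' @export
paper_design <- function() {
  cell <- function(tissue, treatment, temperature, weeks)
    data.frame(tissue = tissue, treatment = treatment,
               temperature = temperature, week = weeks,
               stringsAsFactors = FALSE)
  rbind(
    cell("leaves", "uninoculated", 20, c(4, 6, 8)),
    cell("leaves", "PGPR", 20, c(4, 6, 8)),
    cell("stems", "PGPR", 20, c(4, 6, 8)),
    cell("stems", "uninoculated", 20, c(4, 6, 8)),
    cell("flowers", "uninoculated", 20, c(6, 8)),
    cell("seeds", "uninoculated", 20, c(6, 8)),
    cell("flowers", "PGPR", 20, c(6, 8)),
    cell("seeds", "PGPR", 20, c(6, 8)),
    cell("leaves", "uninoculated", 15, c(4, 6)),
    cell("leaves", "uninoculated", 25, c(4, 6))
  )
}

# Default panel ordered from most to least stable (the default noise SDs
# increase along it, echoing the study system: tubulin/clathrin-adaptor
# genes stable, ribosomal 18S and alpha-actin unstable).
.default_genes <- c("a-tub", "CAC", "UBQ", "PP2a", "GAPDH", "b-act",
                    "RUBISCO", "EF-1a", "a-act", "18S")

# Baseline mean Cq per gene: the 18S ribosomal RNA far more abundant than
# the protein-coding genes (Cq ~ 11.6), most genes in the twenties, the
# least abundant transcript near cycle 35.
.default_baseline <- c(25, 24, 26, 27, 27.5, 28, 30.7, 35.4, 29, 11.6)

#' Simulation configuration
#'
#' Defines the generative model for synthetic Cq data:
#' `y = b_sample + d_gene,group + eps`, with per-sample log2 effects
#' `b ~ N(0, sample_effect_sd^2)` shared by all genes (overall template
#' amount), per-gene group shifts `d` (zero-sum over genes within each
#' group), and gene-specific noise `eps ~ N(0, gene_noise_sd^2)`. Cq values
#' follow as `baseline - y / log2(efficiency)`; technical replicates add
#' independent N(0, 0.1) cycles of instrument noise; any Cq beyond
#' `max_cycles` is censored to missing.
#'
#' @param n_genes number of candidate reference genes (default 10).
#' @param design data frame of condition cells (`tissue`, `treatment`,
#'   `temperature`, `week`); default [paper_design()].
#' @param bio_reps biological replicates per cell (default 3).
#' @param tech_reps qPCR technical replicates per biological sample
#'   (default 2).
#' @param baseline_cq per-gene mean Cq (cycles).
#' @param sample_effect_sd SD of the shared per-sample effect, log2 units
#'   (default 1).
#' @param gene_noise_sd per-gene noise SD, log2 units; default
#'   `c(0.05, 0.1, 0.3, 0.5, ...)` increasing by 0.2.
#' @param group_effects optional genes x groups matrix of log2 shifts,
#'   zero-sum over genes within each group; groups are the levels of
#'   `group_var` in the design.
#' @param group_var design column defining the groups for `group_effects`
#'   (default `"tissue"`).
#' @param efficiency per-gene amplification factor (default 2).
#' @param missing_rate extra probability that a measurement is censored to
#'   missing (default 0).
#' @param tech_rep_sd instrument noise SD between technical replicates,
#'   cycles (default 0.1, typical plate repeatability).
#' @param max_cycles thermal cycles run (default 40).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10,
                       design = paper_design(),
                       bio_reps = 3,
                       tech_reps = 2,
                       baseline_cq = NULL,
                       sample_effect_sd = 1,
                       gene_noise_sd = NULL,
                       group_effects = NULL,
                       group_var = "tissue",
                       efficiency = 2,
                       missing_rate = 0,
                       tech_rep_sd = 0.1,
                       max_cycles = 40) {
  stopifnot(n_genes >= 1, bio_reps >= 1, tech_reps >= 1,
            sample_effect_sd >= 0, missing_rate >= 0, missing_rate <= 1,
            tech_rep_sd >= 0,
            is.data.frame(design), nrow(design) >= 1)
  genes <- if (n_genes == 10) .default_genes else
    paste0("gene", seq_len(n_genes))
  if (is.null(baseline_cq))
    baseline_cq <- if (n_genes == 10) .default_baseline else
      rep(27, n_genes)
  if (is.null(gene_noise_sd))
    gene_noise_sd <- c(0.05, 0.1, seq(0.3, by = 0.2,
                                      length.out = max(0, n_genes - 2)))[
                                        seq_len(n_genes)]
  baseline_cq <- rep_len(baseline_cq, n_genes)
  gene_noise_sd <- rep_len(gene_noise_sd, n_genes)
  efficiency <- rep_len(efficiency, n_genes)
  stopifnot(all(gene_noise_sd >= 0), all(efficiency > 1), all(efficiency <= 3))
  if (!is.null(group_effects)) {
    group_effects <- as.matrix(group_effects)
    if (nrow(group_effects) != n_genes)
      stop("`group_effects` must have one row per gene")
    if (!group_var %in% names(design))
      stop("`group_var` not found in the design: ", group_var)
    lev <- unique(design[[group_var]])
    if (ncol(group_effects) != length(lev))
      stop("`group_effects` must have one column per level of ", group_var)
    colnames(group_effects) <- lev
    if (any(abs(colSums(group_effects)) > 1e-8))
      stop("`group_effects` must sum to zero over genes within each group")
  }
  structure(list(n_genes = n_genes, genes = genes, design = design,
                 bio_reps = bio_reps, tech_reps = tech_reps,
                 baseline_cq = stats::setNames(baseline_cq, genes),
                 sample_effect_sd = sample_effect_sd,
                 gene_noise_sd = stats::setNames(gene_noise_sd, genes),
                 group_effects = group_effects, group_var = group_var,
                 efficiency = stats::setNames(efficiency, genes),
                 missing_rate = missing_rate, tech_rep_sd = tech_rep_sd,
                 max_cycles = max_cycles),
            class = "sim_config")
}

#' Simulate a Cq dataset with known ground truth
#'
#' Draws a dataset from the generative model described in [sim_config()] and
#' attaches per-sample metadata (tissue, treatment, temperature, week,
#' replicate ids, and QC fields: RQI uniform on 7-10 and A260/280 uniform on
#' 1.9-2.1, so that default datasets pass QC; corrupt them explicitly to
#' exercise the QC filter).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same (config, seed) pair reproduces the
#'   dataset bit-exactly.
#' @return A list with `cq` (a [cq_table()] with one column per technical
#'   replicate), `meta` (data frame, one row per technical replicate) and
#'   `truth` (class `synthetic_truth`: the config, the true log2 expression
#'   matrix `y` of biological samples, and `true_order`, genes ascending by
#'   total variation `mean(|d|) + noise SD`).
#' @export
simulate_cq <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  des <- config$design
  cells <- des[rep(seq_len(nrow(des)), each = config$bio_reps), ,
               drop = FALSE]
  cells$bio_rep <- rep(seq_len(config$bio_reps), nrow(des))
  S <- nrow(cells)
  G <- config$n_genes
  bio_id <- sprintf("%s_%s_%sC_w%s_r%d", cells$tissue,
                    cells$treatment, cells$temperature, cells$week,
                    cells$bio_rep)
  b <- stats::rnorm(S, 0, config$sample_effect_sd)
  eps <- matrix(stats::rnorm(G * S), G, S) * config$gene_noise_sd
  d_term <- matrix(0, G, S)
  if (!is.null(config$group_effects)) {
    grp <- as.character(cells[[config$group_var]])
    d_term <- config$group_effects[, grp, drop = FALSE]
  }
  y <- sweep(eps + d_term, 2L, b, "+")
  dimnames(y) <- list(config$genes, bio_id)
  cq_bio <- config$baseline_cq - y / log2(config$efficiency)
  tech <- do.call(cbind, lapply(seq_len(config$tech_reps), function(t)
    cq_bio + matrix(stats::rnorm(G * S, 0, config$tech_rep_sd), G, S)))
  tech_id <- as.vector(vapply(seq_len(config$tech_reps), function(t)
    paste0(bio_id, ".t", t), character(S)))
  colnames(tech) <- tech_id
  tech[tech > config$max_cycles] <- NA_real_
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(tech)) < config$missing_rate,
                   nrow(tech))
    tech[drop] <- NA_real_
  }
  meta <- data.frame(
    sample_id = tech_id,
    tissue = rep(cells$tissue, config$tech_reps),
    treatment = rep(cells$treatment, config$tech_reps),
    temperature = rep(cells$temperature, config$tech_reps),
    week = rep(cells$week, config$tech_reps),
    bio_rep = rep(cells$bio_rep, config$tech_reps),
    tech_rep = rep(seq_len(config$tech_reps), each = S),
    rqi = rep(stats::runif(S, 7, 10), config$tech_reps),
    a260_280 = rep(stats::runif(S, 1.9, 2.1), config$tech_reps),
    stringsAsFactors = FALSE)
  total_var <- config$gene_noise_sd +
    if (is.null(config$group_effects)) 0 else rowMeans(abs(config$group_effects))
  truth <- structure(list(config = config, y = y,
                          true_order = config$genes[order(total_var)]),
                     class = "synthetic_truth")
  list(cq = cq_table(tech, max_cycles = config$max_cycles),
       meta = meta, truth = truth)
}

#' Canned synthetic datasets
#'
#' Deterministic datasets used in tests and documentation:
#' \describe{
#'   \item{tiny}{3 genes x 4 biological samples, complete, no technical
#'     replicates.}
#'   \item{paper_design}{the full factorial design: 10 genes, 24 condition
#'     cells x 3 biological replicates x 2 technical replicates.}
#'   \item{null_model}{as paper_design but every gene has the same noise SD
#'     (0.2) and there are no group effects.}
#'   \item{one_bad_gene}{as null_model (SD 0.1) except the last gene has a
#'     10x noise SD (1.0).}
#' }
#'
#' @param name one of `"tiny"`, `"paper_design"`, `"null_model"`,
#'   `"one_bad_gene"`.
#' @param seed seed forwarded to [simulate_cq()] (default 101).
#' @return As [simulate_cq()].
#' @export
make_fixture <- function(name, seed = 101L) {
  known <- c("tiny", "paper_design", "null_model", "one_bad_gene")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    stop("unknown fixture '", name, "'; options: ",
         paste(known, collapse = ", "))
  cfg <- switch(name,
    tiny = sim_config(n_genes = 3,
                      design = data.frame(tissue = "leaves",
                                          treatment = "uninoculated",
                                          temperature = 20, week = c(4, 6),
                                          stringsAsFactors = FALSE),
                      bio_reps = 2, tech_reps = 1,
                      gene_noise_sd = c(0.1, 0.2, 0.3)),
    paper_design = sim_config(),
    null_model = sim_config(gene_noise_sd = rep(0.2, 10)),
    one_bad_gene = sim_config(gene_noise_sd = c(rep(0.1, 9), 1.0)))
  simulate_cq(cfg, seed = seed)
}
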