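# Full analysis pipeline: QC -> replicate aggregation -> quantities ->
# geNorm + NormFinder -> consensus, over configurable sample panels.

#' Pipeline configuration
#'
#' Validates and bundles everything [run_pipeline()] needs. Panels
#' (`subsets`) are metadata filters, not hard-coded tissue names: each is a
#' named list of allowed values per metadata column, e.g.
#' `list(leaves = list(tissue = "leaves"))`; the panel `all` (no filter) is
#' always added if absent. Unknown arguments are rejected before any
#' computation.
#'
#' @param cq a [cq_table()] or path to a long-layout CSV.
#' @param meta per-sample metadata data frame (ignored if `cq` is a path to
#'   a long file carrying metadata columns).
#' @param subsets named list of panel filters (see above).
#' @param qc list with `rqi_min`, `ratio_low`, `ratio_high` (see
#'   [qc_filter_samples()]).
#' @param missing_policy `"drop"` or `"impute"` (see [cq_to_quantities()]).
#' @param efficiencies per-gene amplification factors, scalar or named
#'   (default 2).
#' @param group_var metadata column used as the NormFinder grouping within
#'   each panel (default `"tissue"`; panels where it has a single level are
#'   analyzed ungrouped).
#' @param rep_tol technical-replicate discordance warning threshold, cycles.
#' @param v_cutoff V(n/n+1) cutoff (default 0.15).
#' @param seed integer recorded in the config (the pipeline itself is
#'   deterministic; the seed is echoed into outputs for provenance).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cq, meta = NULL,
                            subsets = list(),
                            qc = list(rqi_min = 7, ratio_low = 1.9,
                                      ratio_high = 2.1),
                            missing_policy = c("drop", "impute"),
                            efficiencies = 2,
                            group_var = "tissue",
                            rep_tol = 1.0,
                            v_cutoff = 0.15,
                            seed = 1L,
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  missing_policy <- match.arg(missing_policy)
  if (is.character(cq)) {
    loaded <- read_cq_table(cq, layout = "long")
    cq <- loaded$cq
    if (is.null(meta)) meta <- loaded$meta
  }
  stopifnot(inherits(cq, "cq_table"), is.data.frame(meta))
  bad_qc <- setdiff(names(qc), c("rqi_min", "ratio_low", "ratio_high"))
  if (length(bad_qc))
    stop("unknown qc key(s): ", paste(bad_qc, collapse = ", "))
  qc <- utils::modifyList(list(rqi_min = 7, ratio_low = 1.9,
                               ratio_high = 2.1), qc)
  if (!"all" %in% names(subsets)) subsets <- c(subsets, list(all = list()))
  for (nm in names(subsets)) {
    unknown <- setdiff(names(subsets[[nm]]), names(meta))
    if (length(unknown))
      stop("panel '", nm, "' filters on unknown metadata column(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(cq = cq, meta = meta, subsets = subsets, qc = qc,
                 missing_policy = missing_policy,
                 efficiencies = efficiencies, group_var = group_var,
                 rep_tol = rep_tol, v_cutoff = v_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.filter_panel <- function(meta, filter) {
  keep <- rep(TRUE, nrow(meta))
  for (col in names(filter))
    keep <- keep & meta[[col]] %in% filter[[col]]
  meta$sample_id[keep]
}

#' Run the full stability-analysis pipeline
#'
#' For every configured panel: QC-filter the samples, aggregate technical
#' replicates, summarize the Cq distributions, transform to relative
#' quantities, run geNorm and NormFinder, and build the consensus ranking.
#' Deterministic given identical inputs and configuration.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `refstab_report`: a list with `qc` (global QC
#'   partition), `panels` (per-panel list of `cq_summary`, `genorm`,
#'   `normfinder`, `consensus`, `n_samples`), `top2` (data frame comparing
#'   each panel's two best genes per method) and the echoed `config` scalars.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  qc <- qc_filter_samples(config$meta, rqi_min = config$qc$rqi_min,
                          ratio_low = config$qc$ratio_low,
                          ratio_high = config$qc$ratio_high)
  meta_ok <- config$meta[config$meta$sample_id %in% qc$kept, , drop = FALSE]
  if (!nrow(meta_ok)) stop("no samples pass QC")
  cq_ok <- with(config$cq,
                cq_table(cq[, samples %in% qc$kept, drop = FALSE],
                         max_cycles = config$cq$max_cycles))
  agg <- aggregate_technical_replicates(cq_ok, meta_ok, tol = config$rep_tol)
  panels <- list()
  for (nm in names(config$subsets)) {
    ids <- .filter_panel(agg$meta, config$subsets[[nm]])
    if (!length(ids)) stop("panel '", nm, "' is empty after QC")
    sub_cq <- cq_table(agg$cq$cq[, ids, drop = FALSE],
                       max_cycles = agg$cq$max_cycles)
    sub_meta <- agg$meta[match(ids, agg$meta$sample_id), , drop = FALSE]
    q <- cq_to_quantities(sub_cq, efficiencies = config$efficiencies,
                          missing = config$missing_policy)
    groups <- NULL
    if (config$group_var %in% names(sub_meta)) {
      g <- sub_meta[[config$group_var]][match(q$samples, sub_meta$sample_id)]
      if (length(unique(g)) > 1L && min(table(g)) >= 2L) groups <- g
    }
    gn <- genorm(q, cutoff = config$v_cutoff)
    nf <- normfinder(q, groups = groups)
    panels[[nm]] <- list(n_samples = length(ids),
                         cq_summary = summarize_cq_distribution(sub_cq),
                         genorm = gn, normfinder = nf,
                         consensus = consensus_rank(gn, nf))
  }
  top2 <- do.call(rbind, lapply(names(panels), function(nm) {
    p <- panels[[nm]]
    data.frame(panel = nm,
               genorm_pair = paste(sort(p$genorm$final_pair),
                                   collapse = "/"),
               genorm_m = p$genorm$final_pair_m,
               normfinder_top2 = paste(rank_genes(p$normfinder)[1:2],
                                       collapse = "/"),
               consensus_top2 = paste(p$consensus$final_order[1:2],
                                      collapse = "/"),
               stringsAsFactors = FALSE)
  }))
  structure(list(qc = qc, panels = panels, top2 = top2,
                 missing_policy = config$missing_policy,
                 group_var = config$group_var, seed = config$seed),
            class = "refstab_report")
}

#' @export
print.refstab_report <- function(x, ...) {
  cat(sprintf("refstab report: %d panel(s), %d sample(s) kept, %d rejected\n",
              length(x$panels), length(x$qc$kept), nrow(x$qc$rejected)))
  print(x$top2)
  invisible(x)
}

#' Export pipeline results to CSV and JSON
#'
#' Writes a stable set of files into `dir`: `qc.json` (kept/rejected with
#' reasons), `cq_summary.csv`, `genorm_m.csv` (columns panel, step, gene, M),
#' `genorm_v.csv`, `normfinder.csv`, `consensus.csv` (ordered most to least
#' stable) and `report.json` (the full numeric results; floats at full
#' precision so re-reading reproduces the values exactly).
#'
#' @param report a `refstab_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
export_tables <- function(report, dir) {
  stopifnot(inherits(report, "refstab_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  jsonlite::write_json(report$qc, file.path(dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths <- c(paths, file.path(dir, "qc.json"))
  collect <- function(f) do.call(rbind, lapply(names(report$panels), f))
  wr(collect(function(nm)
    cbind(panel = nm, report$panels[[nm]]$cq_summary)), "cq_summary.csv")
  wr(collect(function(nm) {
    gn <- report$panels[[nm]]$genorm
    do.call(rbind, lapply(seq_along(gn$per_step_m), function(s)
      data.frame(panel = nm, step = s, gene = names(gn$per_step_m[[s]]),
                 M = unname(gn$per_step_m[[s]]))))
  }), "genorm_m.csv")
  wr(collect(function(nm)
    cbind(panel = nm, report$panels[[nm]]$genorm$v_series,
          recommended_n = report$panels[[nm]]$genorm$recommended_n)),
    "genorm_v.csv")
  wr(collect(function(nm) {
    nf <- report$panels[[nm]]$normfinder
    data.frame(panel = nm, gene = names(nf$stability),
               stability = unname(nf$stability), rank = unname(nf$rank),
               grouped = nf$grouped)
  }), "normfinder.csv")
  wr(collect(function(nm) {
    cns <- report$panels[[nm]]$consensus
    data.frame(panel = nm, gene = cns$final_order,
               gm = unname(cns$gm[cns$final_order]),
               position = seq_along(cns$final_order))
  }), "consensus.csv")
  wr(report$top2, "top2.csv")
  json <- lapply(report$panels, function(p) list(
    n_samples = p$n_samples,
    genorm = list(m_values = as.list(p$genorm$m_values),
                  stability_order = p$genorm$stability_order,
                  final_pair = p$genorm$final_pair,
                  final_pair_m = p$genorm$final_pair_m,
                  v_series = p$genorm$v_series,
                  recommended_n = p$genorm$recommended_n,
                  optional_extra_n = p$genorm$optional_extra_n),
    normfinder = list(stability = as.list(p$normfinder$stability),
                      rank = as.list(p$normfinder$rank),
                      grouped = p$normfinder$grouped,
                      tau2 = p$normfinder$tau2),
    consensus = list(gm = as.list(p$consensus$gm),
                     final_order = p$consensus$final_order)))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths <- c(paths, file.path(dir, "report.json"))
  invisible(paths)
}
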