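# Cq tables: gene x sample matrices of quantification-cycle values.
# Missing entries (no amplification by the final cycle) are NA.

#' Construct a Cq table
#'
#' A `cq_table` holds quantification-cycle (Cq) values as a genes-by-samples
#' numeric matrix. `NA` marks a reaction that never crossed the detection
#' threshold. All present values must lie in `(0, max_cycles]`.
#'
#' @param cq numeric matrix of Cq values (genes in rows, samples in columns).
#' @param genes,samples character identifiers; default to the dimnames of `cq`.
#' @param max_cycles number of thermal cycles run (default 40); present Cq
#'   values cannot exceed it.
#' @return An object of class `cq_table` with fields `genes`, `samples`,
#'   `cq` and `max_cycles`.
#' @examples
#' m <- matrix(c(20, 21, 22, 25, 26, 27), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("ACT", "GAPDH"), c("s1", "s2", "s3")))
#' cq_table(m)
#' @export
cq_table <- function(cq, genes = rownames(cq), samples = colnames(cq),
                     max_cycles = 40) {
  cq <- as.matrix(cq)
  storage.mode(cq) <- "double"
  if (is.null(genes) || is.null(samples))
    stop("gene and sample identifiers are required (set dimnames or pass them)")
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (nrow(cq) != length(genes) || ncol(cq) != length(samples))
    stop("dimensions of `cq` must equal |genes| x |samples|")
  if (anyDuplicated(genes))
    stop("duplicated gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicated sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (!is.numeric(max_cycles) || length(max_cycles) != 1L || max_cycles <= 0)
    stop("`max_cycles` must be a single positive number")
  present <- cq[!is.na(cq)]
  if (any(!is.finite(present)))
    stop("present Cq values must be finite")
  if (any(present <= 0) || any(present > max_cycles))
    stop("present Cq values must lie in (0, max_cycles]")
  dimnames(cq) <- list(genes, samples)
  structure(list(genes = genes, samples = samples, cq = cq,
                 max_cycles = max_cycles),
            class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("cq_table: %d genes x %d samples, %d missing (max %g cycles)\n",
              length(x$genes), length(x$samples), sum(is.na(x$cq)),
              x$max_cycles))
  invisible(x)
}

#' @export
dim.cq_table <- function(x) dim(x$cq)

# sentinel strings that mean "no amplification"
.cq_sentinels <- c("", "NA", "N/A", "Undetermined", "undetermined", "Undet")

.parse_cq_column <- function(x, rows = seq_along(x)) {
  x <- trimws(as.character(x))
  miss <- x %in% .cq_sentinels | is.na(x)
  val <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(val)
  if (any(bad))
    stop(sprintf("non-numeric Cq value '%s' at row %d", x[which(bad)[1]],
                 rows[which(bad)[1]]))
  val[miss] <- NA_real_
  val
}

.meta_columns <- c("tissue", "treatment", "temperature", "week",
                   "bio_rep", "tech_rep", "rqi", "a260_280")

#' Read a Cq table from delimited text
#'
#' Two layouts are supported. `"long"` expects one row per measurement with
#' columns `gene`, `sample`, `cq` and optional metadata columns (`tissue`,
#' `treatment`, `temperature`, `week`, `bio_rep`, `tech_rep`, `rqi`,
#' `a260_280`). `"wide"` expects genes in rows (first column `gene`) and
#' samples in columns, with metadata supplied in a sidecar file via
#' `meta_path` (one row per sample, first column `sample_id`).
#'
#' Empty cells and the sentinels `"NA"`/`"Undetermined"` become missing
#' entries; any other non-numeric Cq raises a parse error naming the row.
#'
#' @param path file to read (CSV by default; `sep` is passed through).
#' @param layout `"long"` or `"wide"`.
#' @param meta_path sidecar metadata CSV for the wide layout.
#' @param max_cycles see [cq_table()].
#' @param sep field separator.
#' @return A list with components `cq` (a [cq_table()]) and `meta`
#'   (a data frame of per-sample metadata, possibly with zero columns beyond
#'   `sample_id`).
#' @export
read_cq_table <- function(path, layout = c("long", "wide"), meta_path = NULL,
                          max_cycles = 40, sep = ",") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (layout == "long") {
    need <- c("gene", "sample", "cq")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols))
      stop("malformed header: missing column(s) ",
           paste(sQuote(missing_cols), collapse = ", "))
    raw$cq <- .parse_cq_column(raw$cq, rows = seq_len(nrow(raw)) + 1L)
    key <- paste(raw$gene, raw$sample, sep = "\r")
    col_id <- raw$sample
    if (anyDuplicated(key)) {
      if (!"tech_rep" %in% names(raw))
        stop("duplicated (gene, sample) rows without a tech_rep column")
      key2 <- paste(key, raw$tech_rep, sep = "\r")
      if (anyDuplicated(key2))
        stop("duplicated (gene, sample, tech_rep) rows")
      col_id <- paste(raw$sample, raw$tech_rep, sep = ".")
    }
    genes <- unique(raw$gene)
    samples <- unique(col_id)
    cq <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
    cq[cbind(match(raw$gene, genes), match(col_id, samples))] <- raw$cq
    meta_cols <- intersect(.meta_columns, names(raw))
    meta <- raw[!duplicated(col_id), meta_cols, drop = FALSE]
    meta <- data.frame(sample_id = samples[match(unique(col_id), samples)],
                       meta, stringsAsFactors = FALSE, check.names = FALSE)
    for (nm in intersect(c("temperature", "week", "bio_rep", "tech_rep",
                           "rqi", "a260_280"), names(meta)))
      meta[[nm]] <- suppressWarnings(as.numeric(meta[[nm]]))
    rownames(meta) <- NULL
  } else {
    if (!"gene" %in% names(raw))
      stop("malformed header: missing column 'gene' in wide layout")
    genes <- raw$gene
    samples <- setdiff(names(raw), "gene")
    cq <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
    for (j in seq_along(samples))
      cq[, j] <- .parse_cq_column(raw[[samples[j]]],
                                  rows = seq_len(nrow(raw)) + 1L)
    if (!is.null(meta_path)) {
      meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
      if (!"sample_id" %in% names(meta))
        stop("malformed header: metadata sidecar needs a 'sample_id' column")
    } else {
      meta <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
    }
  }
  list(cq = cq_table(cq, max_cycles = max_cycles), meta = meta)
}

#' Write a Cq table (and optional metadata) to CSV
#'
#' Writes the wide layout read back by [read_cq_table()]. Values are written
#' with 17 significant digits so a write/read round trip reproduces the
#' matrix bit-exactly, including the missing mask.
#'
#' @param table a [cq_table()].
#' @param path output CSV path.
#' @param meta optional per-sample metadata data frame (`sample_id` first).
#' @param meta_path where to write `meta` (required if `meta` given).
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(table, path, meta = NULL, meta_path = NULL) {
  stopifnot(inherits(table, "cq_table"))
  chr <- formatC(table$cq, digits = 17, format = "g")
  chr[is.na(table$cq)] <- "NA"
  out <- data.frame(gene = table$genes, chr, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c("gene", table$samples)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(meta)) {
    if (is.null(meta_path)) stop("`meta_path` required when writing metadata")
    utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Average technical replicates into biological samples
#'
#' Collapses columns of a Cq table that are technical replicates of the same
#' biological sample, taking the arithmetic mean of the present Cq values in
#' each group (the conventional treatment of qPCR technical replicates).
#' Groups whose values are all missing stay missing. Replicates of one
#' biological sample that disagree by more than `tol` cycles trigger a
#' warning, not an error.
#'
#' @param table a [cq_table()].
#' @param meta per-sample metadata containing `sample_id` and the columns in
#'   `group_cols`.
#' @param group_cols metadata columns that jointly identify a biological
#'   sample; defaults to the intersection of
#'   `c("tissue","treatment","temperature","week","bio_rep")` with `meta`.
#' @param tol discordance warning threshold in cycles (default 1.0).
#' @return A list with `cq` (one column per biological sample) and `meta`
#'   (one row per biological sample; `tech_rep` dropped, QC fields taken from
#'   the first replicate).
#' @export
aggregate_technical_replicates <- function(table, meta, group_cols = NULL,
                                           tol = 1.0) {
  stopifnot(inherits(table, "cq_table"))
  if (is.null(group_cols))
    group_cols <- intersect(c("tissue", "treatment", "temperature", "week",
                              "bio_rep"), names(meta))
  if (!length(group_cols))
    stop("no grouping columns available to identify biological samples")
  meta <- meta[match(table$samples, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata is missing rows for some samples in the table")
  key <- do.call(paste, c(meta[group_cols], sep = "_"))
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  agg <- vapply(groups, function(idx) {
    rowMeans(table$cq[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(length(table$genes)))
  agg[is.nan(agg)] <- NA_real_     # all-missing groups stay missing
  if (length(table$genes) == 1L) agg <- matrix(agg, nrow = 1L,
                                               dimnames = list(table$genes,
                                                               names(groups)))
  # discordance check per (gene, biological sample)
  for (g in names(groups)) {
    sub <- table$cq[, groups[[g]], drop = FALSE]
    rng <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) 0 else diff(range(v))
    })
    if (any(rng > tol))
      warning(sprintf(
        "technical replicates of sample '%s' differ by more than %g cycles for gene(s): %s",
        g, tol, paste(table$genes[rng > tol], collapse = ", ")))
  }
  first <- vapply(groups, `[`, integer(1), 1L)
  keep <- setdiff(names(meta), "tech_rep")
  new_meta <- meta[first, keep, drop = FALSE]
  new_meta$sample_id <- names(groups)
  rownames(new_meta) <- NULL
  list(cq = cq_table(agg, genes = table$genes, samples = names(groups),
                     max_cycles = table$max_cycles),
       meta = new_meta[, c("sample_id", setdiff(names(new_meta), "sample_id")),
                       drop = FALSE])
}
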