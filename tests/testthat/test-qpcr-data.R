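# Cq input handling, QC filtering, replicate aggregation, standard curves
# and the Cq -> quantity transform.

make_wide_file <- function(df) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}

test_that("wide files round-trip through write/read bit-exactly", {
  set.seed(11)
  m <- matrix(runif(6, 15, 35), 2, 3,
              dimnames = list(c("ACT", "GAPDH"), c("s1", "s2", "s3")))
  m[2, 3] <- NA
  tab <- cq_table(m)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(tab, p)
  back <- read_cq_table(p, layout = "wide")
  expect_identical(back$cq$cq, tab$cq)
  expect_identical(is.na(back$cq$cq), is.na(tab$cq))
  expect_equal(back$cq$genes, tab$genes)
})

test_that("long layout maps sentinels to missing and flags bad values", {
  df <- data.frame(gene = rep(c("A", "B"), each = 2),
                   sample = rep(c("s1", "s2"), 2),
                   cq = c("20.1", "Undetermined", "22.0", "23.5"))
  p <- make_wide_file(df)
  got <- read_cq_table(p, layout = "long")
  expect_equal(sum(is.na(got$cq$cq)), 1L)
  expect_true(is.na(got$cq$cq["A", "s2"]))

  df$cq[3] <- "abc"
  p2 <- make_wide_file(df)
  expect_error(read_cq_table(p2, layout = "long"), "row 4")

  names(df)[3] <- "value"
  p3 <- make_wide_file(df)
  expect_error(read_cq_table(p3, layout = "long"), "'cq'")
})

test_that("duplicated (gene, sample, tech_rep) measurements are rejected", {
  df <- data.frame(gene = "A", sample = "s1", cq = c("20", "21"),
                   tech_rep = c(1, 1))
  expect_error(read_cq_table(make_wide_file(df), layout = "long"),
               "duplicated")
  df$tech_rep <- c(1, 2)
  got <- read_cq_table(make_wide_file(df), layout = "long")
  expect_equal(ncol(got$cq$cq), 2L)
})

test_that("cq_table enforces its invariants", {
  m <- matrix(c(20, 45), 1, 2, dimnames = list("A", c("s1", "s2")))
  expect_error(cq_table(m), "max_cycles")
  m2 <- matrix(20, 2, 1, dimnames = list(c("A", "A"), "s1"))
  expect_error(cq_table(m2), "duplicated gene")
})

test_that("QC filter applies the RQI and absorbance-ratio rules", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                     rqi = c(7.5, 6.9, 9.0, 7.0, NA),
                     a260_280 = c(2.0, 2.0, 1.85, 1.7, 2.0))
  got <- qc_filter_samples(meta)
  expect_equal(got$kept, "a")
  expect_equal(got$rejected$reason[got$rejected$sample_id == "b"], "rqi")
  expect_equal(got$rejected$reason[got$rejected$sample_id == "c"], "ratio")
  expect_equal(got$rejected$reason[got$rejected$sample_id == "d"],
               "rqi,ratio")   # rqi = 7 fails the strict "above 7" rule
  expect_equal(got$rejected$reason[got$rejected$sample_id == "e"],
               "missing_qc")
  kept_relaxed <- qc_filter_samples(meta, missing_qc = "keep")
  expect_true("e" %in% kept_relaxed$kept)
})

test_that("QC partition is exhaustive and disjoint on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    meta <- data.frame(sample_id = paste0("s", 1:n),
                       rqi = runif(n, 5, 10),
                       a260_280 = runif(n, 1.5, 2.5))
    got <- qc_filter_samples(meta)
    expect_equal(length(got$kept) + nrow(got$rejected), n)
    expect_length(intersect(got$kept, got$rejected$sample_id), 0)
  }
})

test_that("technical replicates average present values and keep gaps", {
  m <- matrix(c(20.0, 20.4,
                21.0, NA,
                NA, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("x.t1", "x.t2")))
  meta <- data.frame(sample_id = c("x.t1", "x.t2"), tissue = "leaves",
                     bio_rep = 1, tech_rep = 1:2)
  got <- aggregate_technical_replicates(cq_table(m), meta)
  expect_equal(ncol(got$cq$cq), 1L)
  expect_equal(unname(got$cq$cq[, 1]), c(20.2, 21.0, NA))
  expect_equal(nrow(got$meta), 1L)
})

test_that("discordant technical replicates warn but still aggregate", {
  m <- matrix(c(20, 21.5), 1, 2,
              dimnames = list("A", c("x.t1", "x.t2")))
  meta <- data.frame(sample_id = c("x.t1", "x.t2"), tissue = "leaves",
                     bio_rep = 1, tech_rep = 1:2)
  expect_warning(got <- aggregate_technical_replicates(cq_table(m), meta),
                 "differ by more than")
  expect_equal(unname(got$cq$cq[1, 1]), 20.75)
})

test_that("standard curves recover slope, r2 and efficiency", {
  d <- -(0:4)   # five orders of magnitude
  perfect <- fit_standard_curve(d, 30 - 3.321928 * d)
  expect_equal(perfect$slope, -3.321928, tolerance = 1e-9)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)
  expect_equal(perfect$efficiency_percent, 100, tolerance = 1e-4)

  set.seed(3)
  noisy <- fit_standard_curve(d, 30 - 3.321928 * d + rnorm(5, 0, 0.01))
  expect_lt(abs(noisy$slope - (-3.321928)), 0.02)

  expect_error(fit_standard_curve(c(0, -1), c(30, 33)), "3 distinct")
  expect_error(fit_standard_curve(0:3, 20 + 3 * (0:3)), "non-amplifying")
})

test_that("efficiency follows the closed form", {
  expect_equal(compute_efficiency(-1 / log10(2)), 100, tolerance = 1e-12)
  expect_equal(compute_efficiency(-1), 900)
  expect_equal(compute_efficiency(-3), (10^(1 / 3) - 1) * 100)
  expect_equal(round(compute_efficiency(-3), 3), 115.443)
  expect_error(compute_efficiency(2), "negative")
})

test_that("cq_to_quantities follows the calibrator convention", {
  tab <- cq_table(matrix(c(20, 21, 20, 20, 15, 18), nrow = 3, byrow = TRUE,
                         dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  q <- cq_to_quantities(tab, efficiencies = c(A = 2, B = 2, C = 1.9))
  expect_equal(unname(q$q["A", ]), c(1, 0.5))
  expect_equal(unname(q$q["B", ]), c(1, 1))
  expect_equal(unname(q$q["C", ]), c(1, 1.9^(-3)))
  expect_equal(unname(apply(q$q, 1, max)), rep(1, 3))
})

test_that("missing policies drop or impute before the transform", {
  m <- matrix(c(20, 21, NA, 25, 26, 27), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  tab <- cq_table(m, max_cycles = 40)
  dropped <- cq_to_quantities(tab, missing = "drop")
  expect_equal(dropped$samples, c("s1", "s2"))
  imputed <- cq_to_quantities(tab, missing = "impute")
  expect_equal(unname(imputed$q["A", "s3"]), 2^(20 - 40))
  tab2 <- cq_table(matrix(c(NA, NA, 25, 26), 2, 2, byrow = TRUE,
                          dimnames = list(c("A", "B"), c("s1", "s2"))))
  expect_error(cq_to_quantities(tab2), "missing in every sample")
})

test_that("lower Cq always means strictly higher relative quantity", {
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(runif(24, 15, 35), 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    q <- cq_to_quantities(cq_table(m), efficiencies = runif(1, 1.8, 2.1))
    for (g in 1:4) {
      ord <- order(m[g, ])
      expect_true(all(diff(q$q[g, ord]) <= 0))
      expect_true(all(diff(rank(m[g, ])) == diff(rank(-q$q[g, ]))))
    }
  }
})

test_that("fold abundance reproduces doublings and is reciprocal", {
  expect_equal(fold_abundance(9, 10), 2)
  expect_equal(fold_abundance(20, 20), 1)
  expect_equal(fold_abundance(10, 9) * fold_abundance(9, 10), 1)
  expect_equal(fold_abundance(9.42, 27.31) * fold_abundance(27.31, 9.42), 1)
})

test_that("Cq distribution summaries use interpolated percentiles", {
  tab <- cq_table(matrix(1:100, nrow = 1,
                         dimnames = list("A", paste0("s", 1:100))),
                  max_cycles = 100)
  s <- summarize_cq_distribution(tab)
  expect_equal(s$median, 50.5)
  expect_equal(s$p5, 5.95)    # 1 + 0.05 * 99 under linear interpolation
  expect_equal(s$p95, 95.05)

  const <- summarize_cq_distribution(
    cq_table(matrix(25, 1, 3, dimnames = list("A", paste0("s", 1:3)))))
  expect_equal(unlist(const[c("min", "p5", "median", "p95", "max")]),
               c(min = 25, p5 = 25, median = 25, p95 = 25, max = 25))

  two <- summarize_cq_distribution(
    cq_table(matrix(c(9.42, 35.48), 1, 2,
                    dimnames = list("A", c("s1", "s2")))))
  expect_equal(two$min, 9.42)
  expect_equal(two$max, 35.48)
})

test_that("genes with no present values are omitted with a warning", {
  m <- matrix(c(20, 21, NA, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_warning(s <- summarize_cq_distribution(cq_table(m)), "B")
  expect_equal(s$gene, "A")
})
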