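# NormFinder variance decomposition, grouped and ungrouped.

sim_two_way <- function(G, S, sds, seed, group_shift = NULL, groups = NULL) {
  set.seed(seed)
  y <- outer(rnorm(G, 25, 2), rep(1, S)) +          # gene levels
    outer(rep(1, G), rnorm(S, 0, 1)) +              # sample effects
    matrix(rnorm(G * S), G, S) * sds
  if (!is.null(group_shift)) y <- y + group_shift[, groups, drop = FALSE]
  rownames(y) <- paste0("g", seq_len(G))
  colnames(y) <- paste0("s", seq_len(S))
  y
}

test_that("log transform is the exact base-2 inverse of 2^y", {
  q <- random_q(3, 5, seed = 4)
  y <- log_transform(q)
  expect_equal(2^y, q, tolerance = 1e-12)
  expect_equal(log_transform(matrix(c(1, 0.5), 1, 2))[1, ], c(0, -1))
  expect_error(log_transform(matrix(c(1, -1), 1, 2)), "positive")
})

test_that("two-way residuals match the four-loop oracle", {
  for (i in 1:10) {
    G <- sample(3:6, 1); S <- sample(3:12, 1)
    y <- matrix(rnorm(G * S), G, S)
    expect_equal(refstab:::.two_way_residuals(y), oracle_residuals(y),
                 tolerance = 1e-12)
  }
})

test_that("a gene tracking the per-sample column means has zero stability", {
  y <- sim_two_way(4, 10, sds = c(0.2, 0.3, 0.3, 0.3), seed = 2)
  y[1, ] <- colMeans(y)   # zero residual after two-way centering
  nf <- normfinder(y, log_input = TRUE)
  expect_equal(unname(nf$stability["g1"]), 0, tolerance = 1e-9)
  expect_equal(unname(nf$rank["g1"]), 1)
  expect_error(normfinder(y[1:2, ], log_input = TRUE), "3 candidate")
})

test_that("ungrouped stability recovers the noisiest and quietest genes", {
  wins <- 0
  for (s in 1:60) {
    y <- sim_two_way(5, 50, sds = c(0.05, 0.1, 0.4, 0.4, 0.4), seed = 400 + s)
    nf <- normfinder(y, log_input = TRUE)
    if (names(which.min(nf$stability)) == "g1") wins <- wins + 1
  }
  expect_gte(wins / 60, 0.9)
})

test_that("stabilities are non-negative and ranks tie by mean", {
  y <- sim_two_way(5, 12, sds = rep(0.3, 5), seed = 10)
  nf <- normfinder(y, log_input = TRUE)
  expect_true(all(nf$stability >= 0))
  expect_equal(sort(unname(nf$rank)), 1:5)
  fake <- refstab:::.new_normfinder_result(
    c(a = 0.2, b = 0.2, c = 0.5), c("a", "b", "c"), FALSE,
    NULL, NULL, NA_real_, FALSE)
  expect_equal(unname(fake$rank), c(1.5, 1.5, 3))
  expect_equal(rank_genes(fake), c("a", "b", "c"))
})

test_that("grouped effects are zero-sum over genes within each group", {
  groups <- rep(c("leaf", "stem", "seed"), each = 6)
  shift <- matrix(c(1, -0.5, -0.5, 0, 0,
                    0, 0.5, -0.5, 0, 0,
                    -1, 0, 1, 0, 0), 5, 3)
  y <- sim_two_way(5, 18, sds = rep(0.2, 5), seed = 6,
                   group_shift = shift,
                   groups = as.integer(factor(groups,
                                              c("leaf", "stem", "seed"))))
  nf <- normfinder(y, groups = groups, log_input = TRUE)
  expect_true(nf$grouped)
  expect_equal(unname(colSums(nf$inter_effect)), rep(0, 3),
               tolerance = 1e-10)
  expect_gte(nf$tau2, 0)
  expect_true(all(nf$stability >= 0))
})

test_that("a gene with a strong group effect ranks last", {
  shift <- matrix(0, 5, 2)
  shift[1, ] <- c(1, -1)              # d = +-1 split across two groups
  shift <- sweep(shift, 2, colMeans(shift))   # keep zero-sum over genes
  groups <- rep(c("a", "b"), each = 20)
  last <- 0
  for (s in 1:60) {
    y <- sim_two_way(5, 40, sds = rep(0.2, 5), seed = 700 + s,
                     group_shift = shift,
                     groups = as.integer(factor(groups)))
    nf <- normfinder(y, groups = groups, log_input = TRUE)
    if (names(which.max(nf$stability)) == "g1") last <- last + 1
  }
  expect_gte(last / 60, 0.95)
})

test_that("under the null tau2 shrinks toward zero with group size", {
  tau_small <- tau_big <- numeric(20)
  for (s in 1:20) {
    y1 <- sim_two_way(6, 8, sds = rep(0.3, 6), seed = 900 + s)
    y2 <- sim_two_way(6, 80, sds = rep(0.3, 6), seed = 900 + s)
    nf1 <- normfinder(y1, groups = rep(c("a", "b"), each = 4),
                      log_input = TRUE)
    nf2 <- normfinder(y2, groups = rep(c("a", "b"), each = 40),
                      log_input = TRUE)
    tau_small[s] <- nf1$tau2
    tau_big[s] <- nf2$tau2
  }
  expect_lte(mean(tau_big), mean(tau_small) + 1e-6)
})

test_that("stability is invariant to gene and sample location shifts", {
  y <- sim_two_way(5, 12, sds = c(0.1, 0.2, 0.3, 0.4, 0.5), seed = 13)
  nf <- normfinder(y, log_input = TRUE)
  y2 <- y; y2[3, ] <- y2[3, ] + 7        # gene row shift
  y3 <- y; y3[, 5] <- y3[, 5] - 4.2      # sample column shift
  expect_equal(normfinder(y2, log_input = TRUE)$stability, nf$stability,
               tolerance = 1e-10)
  expect_equal(normfinder(y3, log_input = TRUE)$stability, nf$stability,
               tolerance = 1e-10)
  groups <- rep(c("a", "b"), each = 6)
  nfg <- normfinder(y, groups = groups, log_input = TRUE)
  expect_equal(normfinder(y2, groups = groups,
                          log_input = TRUE)$stability, nfg$stability,
               tolerance = 1e-10)
})

test_that("a single group dispatches to the ungrouped estimator", {
  y <- sim_two_way(4, 10, sds = c(0.1, 0.2, 0.3, 0.4), seed = 17)
  a <- normfinder(y, log_input = TRUE)
  b <- normfinder(y, groups = rep("only", 10), log_input = TRUE)
  expect_equal(a$stability, b$stability)
  expect_equal(a$rank, b$rank)
})

test_that("tau2 = 0 falls back to a usable ungrouped ranking", {
  # identical group structure, no group effects, tiny noise: tau2 hits its
  # floor at 0 on many draws; the result must still rank genes
  found <- FALSE
  for (s in 1:40) {
    y <- sim_two_way(4, 12, sds = c(0.05, 0.1, 0.2, 0.4), seed = 1200 + s)
    nf <- normfinder(y, groups = rep(c("a", "b"), each = 6),
                     log_input = TRUE)
    if (isTRUE(nf$tau2_zero_fallback)) {
      found <- TRUE
      expect_equal(nf$tau2, 0)
      expect_true(all(nf$stability >= 0))
      expect_gt(max(nf$stability), 0)
      expect_equal(sum(nf$rank), sum(1:4))   # a valid mean-tie ranking
      expect_equal(unname(nf$rank), unname(rank(nf$stability)))
    }
  }
  expect_true(found)
})

test_that("negative variance floors apply unless disabled", {
  y <- sim_two_way(4, 6, sds = c(0.01, 0.5, 0.5, 0.5), seed = 29)
  floored <- normfinder(y, log_input = TRUE)
  raw <- normfinder(y, log_input = TRUE, floor_variance = FALSE)
  expect_true(all(floored$intra_var >= 0))
  expect_equal(floored$stability, raw$stability)  # stability always floored
})
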