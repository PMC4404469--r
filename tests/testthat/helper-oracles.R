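# Independent brute-force reference implementations used to cross-check the
# package's vectorized code. Deliberately naive: explicit loops, no shared
# code with R/.

# geNorm M by the defining double loop over the pairwise log2-ratio SDs.
oracle_m_values <- function(q) {
  G <- nrow(q)
  M <- numeric(G)
  for (j in seq_len(G)) {
    vs <- c()
    for (k in seq_len(G)) {
      if (k == j) next
      ratios <- log2(q[j, ] / q[k, ])
      vs <- c(vs, sd(ratios))
    }
    M[j] <- mean(vs)
  }
  names(M) <- rownames(q)
  M
}

# V(n/n+1) via explicitly constructed normalization-factor vectors.
oracle_v_series <- function(q, order_best_first) {
  G <- nrow(q)
  nf <- function(genes) {
    apply(q[genes, , drop = FALSE], 2, function(col) prod(col)^(1 / length(genes)))
  }
  sapply(2:(G - 1), function(n) {
    a <- nf(order_best_first[1:n])
    b <- nf(order_best_first[1:(n + 1)])
    sd(log2(a / b))
  })
}

# Two-way centered residuals by four explicit loops.
oracle_residuals <- function(y) {
  G <- nrow(y); S <- ncol(y)
  gm <- mean(y)
  R <- matrix(0, G, S)
  for (i in 1:G) {
    for (j in 1:S) {
      ri <- mean(y[i, ])
      cj <- mean(y[, j])
      R[i, j] <- y[i, j] - ri - cj + gm
    }
  }
  R
}

# Random positive quantity matrix with a calibrator max of 1 per gene.
random_q <- function(G, S, seed) {
  set.seed(seed)
  m <- matrix(2^rnorm(G * S, 0, 1), G, S,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(S))))
  sweep(m, 1, apply(m, 1, max), "/")
}
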