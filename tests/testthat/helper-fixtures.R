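# Shared in-code fixtures for the suite.

# Tiny gene-effect matrix with explicit values.
tiny_gem <- function() {
  m <- matrix(c(-1.0, 0.0, 0.5, NA, 0.2, -0.3), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA (1)", "GB (2)", "GC (3)"),
                              c("L1", "L2")))
  m
}

# Hand-made correlation_matrix from a full symmetric r matrix.
corr_from_matrix <- function(r, n = 200L) {
  diag(r) <- 1
  structure(list(r = r, n_obs = matrix(as.integer(n), nrow(r), nrow(r),
                                       dimnames = dimnames(r)),
                 min_overlap = 1L),
            class = "correlation_matrix")
}

# Small simulation: k modules over a handful of genes, quick to run.
small_params <- function(seed = 1L, ...) {
  sim_params(n_genes = 60L, n_lines = 300L, n_modules = 5L,
             module_size_range = c(4L, 6L), n_common_essential = 5L,
             seed = seed, ...)
}

# Independent brute-force Pearson over pairwise-complete observations.
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive concordant-pair AUC oracle (ties half weight).
auc_oracle <- function(observed, simulated) {
  total <- 0
  for (o in observed) for (s in simulated) {
    total <- total + (o > s) + 0.5 * (o == s)
  }
  total / (length(observed) * length(simulated))
}

# Hand step-up BH oracle.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in rev(seq_len(n))) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  pmin(q, 1)
}

# Pooled two-sample t oracle.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
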