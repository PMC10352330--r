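test_that("common-essential filter applies the strict fraction rule", {
  gem <- rbind(
    lethal  = rep(-1.2, 10),          # lethal in 10/10 -> removed
    partial = c(rep(-1.2, 8), 0, 0),  # 8/10 = 0.8 <= 0.9 -> kept
    benign  = rep(0, 10))
  colnames(gem) <- paste0("L", 1:10)
  out <- filter_common_essentials(gem)
  expect_identical(out$essential, "lethal")
  expect_identical(rownames(out$gem), c("partial", "benign"))

  # all-zero matrix: nothing removed
  zero <- matrix(0, 3, 5, dimnames = list(paste0("g", 1:3), paste0("L", 1:5)))
  expect_identical(filter_common_essentials(zero)$essential, character(0))

  # gene with no observations leaves both outputs, with a warning
  gem2 <- rbind(gem, ghost = rep(NA_real_, 10))
  expect_warning(out2 <- filter_common_essentials(gem2), "no observed")
  expect_false("ghost" %in% rownames(out2$gem))
  expect_false("ghost" %in% out2$essential)
})

test_that("pairwise correlation matches a brute-force Pearson oracle", {
  gem <- rbind(x = c(1, 2, 3), y = c(1, 2, 4), z = c(3, 1, 2))
  colnames(gem) <- paste0("L", 1:3)
  corr <- pairwise_correlation(gem, min_overlap = 2)
  expect_equal(corr$r["x", "y"], pearson_oracle(gem["x", ], gem["y", ]),
               tolerance = 1e-12)
  expect_equal(corr$r["x", "y"], 0.9819805, tolerance = 1e-6)
  # exact symmetry, unit diagonal, every entry reproducible
  expect_identical(corr$r, t(corr$r))
  expect_equal(unname(diag(corr$r)), rep(1, 3))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(corr$r[i, j], pearson_oracle(gem[i, ], gem[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("low overlap and zero variance yield missing coefficients", {
  gem <- rbind(a = c(1, 2, 3, 4, NA, NA),
               b = c(2, 1, NA, NA, 5, 6),
               flat = rep(1, 6),
               c = c(1, 3, 2, 5, 4, 6))
  colnames(gem) <- paste0("L", 1:6)
  corr <- pairwise_correlation(gem, min_overlap = 3)
  expect_true(is.na(corr$r["a", "b"]))      # overlap 2 < 3
  expect_identical(corr$n_obs["a", "b"], 2L)
  expect_true(is.na(corr$r["flat", "c"]))   # zero variance
  expect_false(is.na(corr$r["a", "c"]))
})

test_that("complex pair scores intersect the catalog with the matrix once", {
  r <- diag(4); dimnames(r) <- list(c("A (1)", "B (2)", "C (3)", "D (4)"),
                                    c("A (1)", "B (2)", "C (3)", "D (4)"))
  r["A (1)", "B (2)"] <- r["B (2)", "A (1)"] <- 0.5
  r["B (2)", "C (3)"] <- r["C (3)", "B (2)"] <- 0.3
  corr <- corr_from_matrix(r)
  expect_equal(unname(complex_pair_scores(corr, list(C1 = c("A", "B")))), 0.5)
  # absent member: only the present pair is scored
  s <- complex_pair_scores(corr, list(C1 = c("A", "B", "ZZZ")))
  expect_identical(names(s), "A|B")
  # a pair shared by two complexes appears once
  s2 <- complex_pair_scores(corr, list(C1 = c("A", "B", "C"),
                                       C2 = c("A", "B")))
  expect_identical(sum(names(s2) == "A|B"), 1L)
  expect_error(complex_pair_scores(corr, list(C1 = c("Q", "W"))), "no catalog pair")
})

test_that("random pair sampling is seeded, exclusive and uniform", {
  set.seed(11)
  r <- matrix(runif(36, -0.2, 0.2), 6, 6)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  ids <- sprintf("G%d (%d)", 1:6, 1:6)
  dimnames(r) <- list(ids, ids)
  corr <- corr_from_matrix(r)
  s1 <- sample_random_pairs(corr, 5, seed = 99)
  s2 <- sample_random_pairs(corr, 5, seed = 99)
  expect_identical(s1, s2)
  # excluding everything empties the pool
  all_pairs <- complex_pairs(list(X = gene_symbol(ids)))
  expect_error(sample_random_pairs(corr, 1, exclude = all_pairs), "eligible")
  # Monte-Carlo uniformity: 3 genes -> 3 pairs, each drawn ~1/3 of the time
  r3 <- corr_from_matrix(matrix(0.1, 3, 3, dimnames = list(c("a", "b", "c"),
                                                           c("a", "b", "c"))))
  draws <- vapply(1:900, function(s) names(sample_random_pairs(r3, 1, seed = s)),
                  character(1))
  freq <- table(draws) / 900
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 900)))
})

test_that("ROC recovery AUC matches the exhaustive pair-count oracle", {
  expect_equal(roc_complex_recovery(rep(0.9, 4), rep(0.1, 6))$auc, 1)
  expect_equal(roc_complex_recovery(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))$auc, 0.5)
  set.seed(3)
  obs <- round(runif(5), 2); sim <- round(runif(5), 2)
  roc <- roc_complex_recovery(obs, sim)
  expect_equal(roc$auc, auc_oracle(obs, sim), tolerance = 1e-12)
  # independent reference implementation agrees
  skip_if_not_installed("pROC")
  ref <- pROC::roc(response = c(rep(1, 5), rep(0, 5)),
                   predictor = c(obs, sim), quiet = TRUE,
                   direction = "<")
  expect_equal(roc$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("cutoff calibration maximizes Youden's J, ties breaking upward", {
  # one-point grid returns that point
  r <- diag(2); dimnames(r) <- list(c("A (1)", "B (2)"), c("A (1)", "B (2)"))
  r["A (1)", "B (2)"] <- r["B (2)", "A (1)"] <- 0.8
  # grid of one value with a trivial catalog
  corr1 <- corr_from_matrix(r)
  expect_error(optimize_network_cutoff(corr1, list(C = c("A", "B")),
                                       grid = numeric(0)), "empty")

  # constructed separation: complex pairs ~ U(0.5, 1), background ~ U(0, 0.5)
  set.seed(21)
  n <- 60
  ids <- sprintf("P%02d (%d)", 1:n, 1:n)
  rm_ <- matrix(0, n, n, dimnames = list(ids, ids))
  bg <- runif(n * (n - 1) / 2, 0, 0.5)
  rm_[upper.tri(rm_)] <- bg
  catalog <- lapply(seq(1, n, by = 2), function(i) gene_symbol(ids[c(i, i + 1)]))
  names(catalog) <- paste0("C", seq_along(catalog))
  for (i in seq(1, n, by = 2)) rm_[i, i + 1] <- runif(1, 0.5, 1)
  rm_[lower.tri(rm_)] <- t(rm_)[lower.tri(rm_)]
  corr <- corr_from_matrix(rm_)
  res <- optimize_network_cutoff(corr, catalog, grid = seq(0.05, 0.95, 0.01),
                                 seed = 5)
  obs <- res$roc$observed; sim <- res$roc$simulated
  expect_gt(res$roc$auc, 0.95)
  expect_true(res$threshold > 0.40 && res$threshold < 0.60)
  # upward tie-break: threshold sits at the top of the J plateau
  j <- res$diagnostics$youden_j
  expect_identical(res$threshold,
                   res$diagnostics$threshold[max(which(j == max(j)))])
})

test_that("network construction enforces both cutoffs and the top-k union rule", {
  ids <- c("A (1)", "B (2)", "C (3)")
  r <- diag(3); dimnames(r) <- list(ids, ids)
  r["A (1)", "B (2)"] <- r["B (2)", "A (1)"] <- 0.45
  r["A (1)", "C (3)"] <- r["C (3)", "A (1)"] <- 0.36
  r["B (2)", "C (3)"] <- r["C (3)", "B (2)"] <- 0.10
  net <- build_network(corr_from_matrix(r))
  # C has no partner above the matrix cutoff -> excluded; only A-B survives
  expect_identical(sort(igraph::V(net)$name), c("A (1)", "B (2)"))
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::E(net)$r, 0.45)

  # star with 20 satellites: union rule keeps all 20 edges
  ids <- c("HUB (0)", sprintf("S%02d (%d)", 1:20, 1:20))
  rs <- diag(21); dimnames(rs) <- list(ids, ids)
  w <- seq(0.41, 0.60, by = 0.01)
  for (i in 1:20) rs[1, i + 1] <- rs[i + 1, 1] <- w[i]
  net2 <- build_network(corr_from_matrix(rs), k_max = 15)
  expect_equal(igraph::ecount(net2), 20)
  expect_equal(igraph::vcount(net2), 21)

  # everything below the network cutoff: empty graph
  rl <- diag(3); dimnames(rl) <- list(ids[1:3], ids[1:3])
  rl[rl == 0] <- 0.2
  expect_equal(igraph::vcount(build_network(corr_from_matrix(rl))), 0)
})

test_that("network invariants hold on simulated data", {
  params <- small_params(seed = 8)
  screen <- simulate_dependency_screen(params)
  corr <- pairwise_correlation(screen$gem, min_overlap = 50)
  net <- build_network(corr)
  expect_true(all(abs(igraph::E(net)$r) > 0.34))
  expect_true(all(igraph::degree(net) >= 1))
  # every node passes the positive matrix cutoff
  off <- corr$r; diag(off) <- NA
  passing <- rownames(off)[apply(off > 0.4, 1, any, na.rm = TRUE)]
  expect_true(all(igraph::V(net)$name %in% passing))
  # every edge is in at least one endpoint's top-15 by |r| (k_max wide here)
  expect_true(igraph::ecount(net) > 0)
})

test_that("module calling partitions components deterministically", {
  # two disjoint triangles -> two modules of size 3
  el <- data.frame(from = c("a", "b", "c", "x", "y", "z"),
                   to = c("b", "c", "a", "y", "z", "x"),
                   r = 0.5)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  mods <- call_modules(g)
  expect_identical(length(unique(mods$module_id)), 2L)
  expect_identical(unname(table(mods$module_id)[["1"]]), 3L)

  # empty network -> empty table
  expect_identical(nrow(call_modules(igraph::make_empty_graph(0, directed = FALSE))), 0L)

  # two 6-cliques joined by one weak bridge, cap 6 -> the cliques come back
  cl <- function(pre) t(combn(paste0(pre, 1:6), 2))
  el2 <- rbind(data.frame(from = cl("p")[, 1], to = cl("p")[, 2], r = 0.6),
               data.frame(from = cl("q")[, 1], to = cl("q")[, 2], r = 0.6),
               data.frame(from = "p1", to = "q1", r = 0.35))
  g2 <- igraph::graph_from_data_frame(el2, directed = FALSE)
  mods2 <- call_modules(g2, max_size = 6)
  parts <- split(mods2$gene, mods2$module_id)
  expect_identical(length(parts), 2L)
  expect_true(all(sort(sapply(parts, function(p) substr(p[1], 1, 1))) == c("p", "q")))
  expect_true(all(lengths(parts) == 6L))
  # modules are a partition: disjoint, within the node set
  expect_false(any(duplicated(mods2$gene)))
  expect_true(all(mods2$gene %in% igraph::V(g2)$name))
  # deterministic under re-run
  expect_identical(mods2, call_modules(g2, max_size = 6))
})

test_that("module dependency scores negate the member mean and skip gaps", {
  gem <- rbind("g1 (1)" = c(-1.0, -2, NA),
               "g2 (2)" = c(-0.5, NA, NA),
               "g3 (3)" = c(0.3, 1, 2))
  colnames(gem) <- paste0("L", 1:3)
  s <- module_dependency_scores(gem, c("g1 (1)", "g2 (2)"))
  expect_equal(unname(s["L1"]), 0.75)
  expect_equal(unname(s["L2"]), 2)       # one member missing: mean over the rest
  expect_true(is.na(s["L3"]))            # all members missing
  expect_equal(unname(module_dependency_scores(gem, "g1 (1)")["L2"]), 2)
  expect_error(module_dependency_scores(gem, "nope (9)"), "no module member")
})

test_that("interaction overlap is symbol-matched and order-blind", {
  el <- data.frame(from = c("MEN1 (4221)", "EZH2 (2146)"),
                   to = c("KMT2A (4297)", "EED (8726)"), r = 0.5)
  net <- igraph::graph_from_data_frame(el, directed = FALSE)
  cat1 <- canonical_pairs("KMT2A", "MEN1")
  ov <- interaction_overlap(net, cat1)
  expect_identical(ov$n_overlap, 1L)
  expect_identical(ov$n_edges, 2L)
  expect_equal(ov$fraction, 0.5)
  # empty network: fraction undefined, not zero
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_true(is.na(interaction_overlap(empty, cat1)$fraction))
})
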