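#' Remove common-essential genes
#'
#' Genes whose knockout is lethal in nearly every line carry no context
#' signal for co-dependency mapping and are removed before correlation.
#' A gene is dropped when the fraction of its non-missing gene effects
#' strictly below `effect_cutoff` exceeds `line_fraction` (defaults: effect
#' score < -1 in more than 90% of lines). Genes with zero non-missing
#' entries are excluded from both outputs with a warning.
#'
#' @param gem Genes x lines numeric matrix.
#' @param effect_cutoff Gene-effect threshold below which a knockout counts
#'   as lethal in a line. Default `-1`.
#' @param line_fraction Fraction of lines above which a gene is called
#'   common-essential. Default `0.9`.
#' @return List with `gem` (retained genes) and `essential` (removed gene ids).
#' @export
filter_common_essentials <- function(gem, effect_cutoff = -1, line_fraction = 0.9) {
  stopifnot(is.matrix(gem), nrow(gem) > 0L, line_fraction > 0, line_fraction <= 1)
  n_obs <- rowSums(!is.na(gem))
  empty <- n_obs == 0L
  if (any(empty)) {
    warning(sum(empty), " gene(s) with no observed effects excluded: ",
            paste(utils::head(rownames(gem)[empty], 5L), collapse = ", "))
  }
  frac_lethal <- rowSums(gem < effect_cutoff, na.rm = TRUE) / pmax(n_obs, 1L)
  essential <- !empty & frac_lethal > line_fraction
  list(gem = gem[!essential & !empty, , drop = FALSE],
       essential = rownames(gem)[essential])
}

#' Pairwise-complete Pearson correlation of dependency profiles
#'
#' Correlates every gene pair's effect profiles over the cell lines where
#' both are observed. Pairs with fewer than `min_overlap` shared lines, or
#' with zero variance on the overlap, are marked missing rather than
#' estimated. The diagonal is 1.
#'
#' @param gem Genes x lines numeric matrix.
#' @param min_overlap Minimum number of shared non-missing lines for a pair
#'   to receive a coefficient. Default 100, sized for pan-cancer panels of
#'   ~1000 lines.
#' @return A `correlation_matrix`: list with symmetric `r` and integer
#'   `n_obs` matrices (gene ids on both dimnames).
#' @export
pairwise_correlation <- function(gem, min_overlap = 100L) {
  stopifnot(is.matrix(gem), ncol(gem) >= 2L)
  complete <- !anyNA(gem)
  r <- suppressWarnings(
    if (complete) stats::cor(t(gem))
    else stats::cor(t(gem), use = "pairwise.complete.obs"))
  if (complete) {
    n_obs <- matrix(ncol(gem), nrow(gem), nrow(gem),
                    dimnames = dimnames(r))
  } else {
    obs <- !is.na(gem)
    n_obs <- tcrossprod(obs * 1L)
  }
  storage.mode(n_obs) <- "integer"
  r[n_obs < min_overlap] <- NA_real_
  r[is.nan(r)] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, n_obs = n_obs, min_overlap = as.integer(min_overlap)),
            class = "correlation_matrix")
}

#' Correlation scores of within-complex gene pairs
#'
#' For every unordered pair of genes co-annotated to a complex, returns the
#' pair's correlation coefficient when both genes are present in the matrix
#' (symbol-matched) and the coefficient is non-missing. Pairs shared by
#' several complexes are counted once.
#'
#' @param corr A `correlation_matrix`.
#' @param catalog Complex catalog (named list of member symbol vectors).
#' @return Named numeric vector of pair scores (`"A|B"` names).
#' @export
complex_pair_scores <- function(corr, catalog) {
  pairs <- complex_pairs(catalog)
  pair_scores(corr, pairs)
}

#' Look up correlation scores for a canonical pair set
#'
#' @param corr A `correlation_matrix`.
#' @param pairs Canonical pair matrix (symbols).
#' @return Named numeric vector of the non-missing scores.
#' @export
pair_scores <- function(corr, pairs) {
  sym <- gene_symbol(rownames(corr$r))
  ia <- match(pairs[, 1L], sym)
  ib <- match(pairs[, 2L], sym)
  ok <- !is.na(ia) & !is.na(ib)
  scores <- rep(NA_real_, nrow(pairs))
  scores[ok] <- corr$r[cbind(ia[ok], ib[ok])]
  keep <- !is.na(scores)
  if (!any(keep)) stop("no catalog pair is scored in the correlation matrix")
  stats::setNames(scores[keep], paste(pairs[keep, 1L], pairs[keep, 2L], sep = "|"))
}

#' Sample random gene pairs as a null score set
#'
#' Draws `n` unordered gene pairs uniformly without replacement from all
#' pairs with a non-missing coefficient, excluding a given pair set
#' (typically the observed complex pairs). Reproducible given `seed`.
#'
#' @param corr A `correlation_matrix`.
#' @param n Number of pairs to draw.
#' @param exclude Canonical pair matrix (symbols) to exclude, or `NULL`.
#' @param seed Integer seed.
#' @return Named numeric vector of `n` pair scores.
#' @export
sample_random_pairs <- function(corr, n, exclude = NULL, seed = 1L) {
  r <- corr$r
  sym <- gene_symbol(rownames(r))
  elig <- upper.tri(r) & !is.na(r)
  if (!is.null(exclude) && nrow(exclude)) {
    ia <- match(exclude[, 1L], sym)
    ib <- match(exclude[, 2L], sym)
    ok <- !is.na(ia) & !is.na(ib)
    if (any(ok)) {
      elig[cbind(pmin(ia[ok], ib[ok]), pmax(ia[ok], ib[ok]))] <- FALSE
    }
  }
  idx <- which(elig)
  if (n > length(idx)) {
    stop("requested ", n, " random pairs but only ", length(idx), " are eligible")
  }
  take <- withr::with_seed(seed, sample(idx, n))
  ij <- arrayInd(take, dim(r))
  stats::setNames(r[take], paste(sym[ij[, 1L]], sym[ij[, 2L]], sep = "|"))
}

#' ROC for recovering complex-level pairs from correlation scores
#'
#' Observed (within-complex) pair scores are labelled 1 and random pair
#' scores 0. For each threshold t, sensitivity is the fraction of observed
#' scores >= t and specificity the fraction of random scores < t. The AUC
#' is the rank (Mann-Whitney) statistic — the probability that a random
#' observed score exceeds a random simulated one, ties counted half — which
#' makes it exactly checkable against exhaustive pair enumeration. A pooled
#' two-sample t-test between the two score sets is reported alongside.
#'
#' @param observed Numeric vector of within-complex pair scores.
#' @param simulated Numeric vector of random pair scores.
#' @param grid Ascending threshold grid. Default `seq(0.05, 0.95, by = 0.01)`.
#' @return A `roc_result`: list with `diagnostics` (threshold, sensitivity,
#'   specificity, youden_j), `auc`, `t_test` (t, p), and the score vectors.
#' @export
roc_complex_recovery <- function(observed, simulated,
                                 grid = seq(0.05, 0.95, by = 0.01)) {
  stopifnot(length(observed) > 0L, length(simulated) > 0L)
  observed <- observed[!is.na(observed)]
  simulated <- simulated[!is.na(simulated)]
  sens <- vapply(grid, function(t) mean(observed >= t), numeric(1L))
  spec <- vapply(grid, function(t) mean(simulated < t), numeric(1L))
  n1 <- length(observed); n2 <- length(simulated)
  rk <- rank(c(observed, simulated))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  tt <- students_t_two_sample(observed, simulated)
  structure(list(diagnostics = data.frame(threshold = grid, sensitivity = sens,
                                          specificity = spec,
                                          youden_j = sens + spec - 1),
                 auc = auc, t_test = tt,
                 observed = observed, simulated = simulated),
            class = "roc_result")
}

#' Calibrate the network cutoff against a complex catalog
#'
#' Scores all within-complex pairs (observed) and an equal-ratio random
#' pair sample (simulated), then picks the grid threshold maximizing
#' Youden's J = sensitivity + specificity - 1; ties break toward the larger
#' (stricter) threshold. The full per-threshold diagnostics table is
#' returned for audit.
#'
#' @param corr A `correlation_matrix`.
#' @param catalog Complex catalog.
#' @param grid Ascending threshold grid in (0, 1).
#' @param n_random_per_obs Random pairs drawn per observed pair. Default 1.
#' @param seed Integer seed for the random-pair draw.
#' @return List with `threshold`, `roc` (a `roc_result`), and `diagnostics`.
#' @export
optimize_network_cutoff <- function(corr, catalog,
                                    grid = seq(0.05, 0.95, by = 0.01),
                                    n_random_per_obs = 1, seed = 1L) {
  if (!length(grid)) stop("threshold grid is empty")
  stopifnot(!is.unsorted(grid), all(grid > 0), all(grid < 1))
  pairs <- complex_pairs(catalog)
  observed <- pair_scores(corr, pairs)
  simulated <- sample_random_pairs(corr, n = round(n_random_per_obs * length(observed)),
                                   exclude = pairs, seed = seed)
  roc <- roc_complex_recovery(observed, simulated, grid)
  j <- roc$diagnostics$youden_j
  best <- max(which(j == max(j)))   # ties break upward
  list(threshold = grid[best], roc = roc, diagnostics = roc$diagnostics)
}

#' Build the dependency correlation network
#'
#' Two-step cutoff: node candidates are genes with at least one partner at
#' r > `matrix_cutoff` (positive sign — the complex-level step); among
#' candidates, edges are pairs with |r| > `network_cutoff`. Each gene then
#' retains only its `k_max` strongest candidate edges by |r|; an edge
#' survives if retained by at least one endpoint (union rule), and nodes
#' left without edges are removed.
#'
#' @param corr A `correlation_matrix`.
#' @param matrix_cutoff Positive-r node cutoff. Default 0.4.
#' @param network_cutoff Absolute-r edge cutoff. Default 0.34.
#' @param k_max Per-gene edge cap. Default 15.
#' @return An `igraph` with edge attribute `r` (signed weight) and graph
#'   attributes recording the parameters.
#' @export
build_network <- function(corr, matrix_cutoff = 0.4, network_cutoff = 0.34,
                          k_max = 15L) {
  stopifnot(network_cutoff > 0, network_cutoff <= matrix_cutoff,
            matrix_cutoff < 1, k_max >= 1L)
  r <- corr$r
  off <- r; diag(off) <- NA_real_
  cand <- rownames(r)[apply(off > matrix_cutoff, 1L, any, na.rm = TRUE)]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (length(cand) >= 2L) {
    sub <- r[cand, cand, drop = FALSE]
    diag(sub) <- NA_real_
    ut <- which(upper.tri(sub) & !is.na(sub) & abs(sub) > network_cutoff,
                arr.ind = TRUE)
    if (nrow(ut)) {
      w <- sub[ut]
      # per-endpoint top-k by |r|; ties by partner id for determinism
      keep <- rep(FALSE, nrow(ut))
      ends <- rbind(cbind(ut[, 1L], seq_len(nrow(ut))),
                    cbind(ut[, 2L], seq_len(nrow(ut))))
      for (node in unique(ends[, 1L])) {
        eids <- ends[ends[, 1L] == node, 2L]
        partner <- ifelse(ut[eids, 1L] == node, ut[eids, 2L], ut[eids, 1L])
        ord <- order(-abs(w[eids]), cand[partner])
        keep[eids[utils::head(ord, k_max)]] <- TRUE
      }
      ut <- ut[keep, , drop = FALSE]
      w <- w[keep]
      g <- igraph::graph_from_data_frame(
        data.frame(from = cand[ut[, 1L]], to = cand[ut[, 2L]], r = w,
                   stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = sort(unique(c(cand[ut[, 1L]], cand[ut[, 2L]]))))
    }
  }
  g <- igraph::set_graph_attr(g, "matrix_cutoff", matrix_cutoff)
  g <- igraph::set_graph_attr(g, "network_cutoff", network_cutoff)
  g <- igraph::set_graph_attr(g, "k_max", as.integer(k_max))
  g
}

#' Call co-dependency modules from the network
#'
#' Connected components of size <= `max_size` become modules directly;
#' larger components are split by greedy modularity community detection
#' (edge weights |r|) applied recursively until every part fits. When the
#' modularity optimum refuses to split an oversized component, the
#' community dendrogram is cut at k = 2 to force progress. Vertices are
#' processed in lexicographic order so the result is deterministic;
#' singleton parts are discarded. Modules are numbered in order of
#' descending mean internal |r|.
#'
#' @param net Network from [build_network()].
#' @param max_size Maximum module size. Default 15.
#' @return A module table: `data.frame(module_id, gene, module_size,
#'   mean_abs_r)`, one row per member gene.
#' @export
call_modules <- function(net, max_size = 15L) {
  if (igraph::vcount(net) == 0L) {
    return(data.frame(module_id = integer(), gene = character(),
                      module_size = integer(), mean_abs_r = numeric(),
                      stringsAsFactors = FALSE))
  }
  net <- igraph::permute(net, match(igraph::V(net)$name,
                                    sort(igraph::V(net)$name)))
  comp <- igraph::components(net)
  groups <- split(igraph::V(net)$name, comp$membership)
  final <- list()
  while (length(groups)) {
    grp <- groups[[1L]]
    groups <- groups[-1L]
    sub <- igraph::induced_subgraph(net, grp)
    cc <- igraph::components(sub)
    if (cc$no > 1L) {   # community splits can disconnect a part
      groups <- c(split(igraph::V(sub)$name, cc$membership), groups)
      next
    }
    if (length(grp) <= max_size) {
      if (length(grp) >= 2L) final[[length(final) + 1L]] <- grp
      next
    }
    fg <- igraph::cluster_fast_greedy(sub, weights = abs(igraph::E(sub)$r))
    memb <- igraph::membership(fg)
    if (length(unique(memb)) < 2L) memb <- igraph::cut_at(fg, no = 2L)
    groups <- c(split(igraph::V(sub)$name, memb), groups)
  }
  if (!length(final)) {
    return(data.frame(module_id = integer(), gene = character(),
                      module_size = integer(), mean_abs_r = numeric(),
                      stringsAsFactors = FALSE))
  }
  mean_r <- vapply(final, function(grp) {
    sub <- igraph::induced_subgraph(net, grp)
    mean(abs(igraph::E(sub)$r))
  }, numeric(1L))
  ord <- order(-mean_r, vapply(final, function(g) sort(g)[1L], character(1L)))
  final <- final[ord]; mean_r <- mean_r[ord]
  do.call(rbind, lapply(seq_along(final), function(k) {
    data.frame(module_id = k, gene = sort(final[[k]]),
               module_size = length(final[[k]]), mean_abs_r = mean_r[k],
               stringsAsFactors = FALSE)
  }))
}

#' Per-line module dependency scores
#'
#' The dependency score of a module in a cell line is the opposite number
#' (negation) of the mean gene-effect value of its members in that line —
#' higher score = the line depends more on the module. Missing member
#' effects are skipped; a line is scored missing only when every member is
#' missing.
#'
#' @param gem Genes x lines matrix.
#' @param members Character vector of member gene ids.
#' @return Named numeric vector over the matrix's cell lines.
#' @export
module_dependency_scores <- function(gem, members) {
  present <- intersect(members, rownames(gem))
  if (!length(present)) stop("no module member present in the gene-effect matrix")
  sub <- gem[present, , drop = FALSE]
  s <- -colMeans(sub, na.rm = TRUE)
  s[colSums(!is.na(sub)) == 0L] <- NA_real_
  s
}

#' Score every module against a gene-effect matrix
#'
#' @param gem Genes x lines matrix.
#' @param modules Module table from [call_modules()].
#' @return Lines x modules numeric matrix (columns named by module_id).
#' @export
score_modules <- function(gem, modules) {
  ids <- unique(modules$module_id)
  out <- vapply(ids, function(k) {
    module_dependency_scores(gem, modules$gene[modules$module_id == k])
  }, numeric(ncol(gem)))
  dimnames(out) <- list(colnames(gem), as.character(ids))
  out
}

#' Overlap of network edges with an interaction catalog
#'
#' Symbol-matches each network edge against a canonical pair catalog
#' (e.g. curated physical/genetic interactions) and reports the overlap.
#'
#' @param net Network from [build_network()].
#' @param catalog Canonical pair matrix from [read_interaction_catalog()].
#' @return List with `n_overlap`, `n_edges`, `fraction` (`NA` when the
#'   network has no edges).
#' @export
interaction_overlap <- function(net, catalog) {
  el <- igraph::as_edgelist(net)
  n_edges <- nrow(el)
  if (n_edges == 0L) return(list(n_overlap = 0L, n_edges = 0L, fraction = NA_real_))
  a <- gene_symbol(el[, 1L]); b <- gene_symbol(el[, 2L])
  edge_key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  cat_key <- paste(catalog[, 1L], catalog[, 2L], sep = "\r")
  n_overlap <- sum(edge_key %in% cat_key)
  list(n_overlap = n_overlap, n_edges = n_edges,
       fraction = n_overlap / n_edges)
}
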