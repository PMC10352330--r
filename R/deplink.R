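#' Association-engine configuration
#'
#' Bundles the gates used by the context-association analyses: minimum
#' carrier count for binary features (`freq_min`), the top/bottom ranking
#' fraction (`percentile`), raw-p and FDR significance gates, the minimum
#' mean-difference gate for continuous-feature hits (`diff_cutoff`), the
#' fold-change gate for expression-level comparisons (`fc_cutoff`), and the
#' minimum cancer-type size (`min_lines_per_type`).
#'
#' @param freq_min Minimum carriers for a binary feature. Default 10.
#' @param percentile Ranking fraction in (0, 0.5). Default 0.18.
#' @param p_cutoff Raw-p gate. Default 0.05.
#' @param q_cutoff BH-FDR gate. Default 0.1.
#' @param diff_cutoff Minimum |mean difference| for continuous hits. Default 0.1.
#' @param fc_cutoff Fold-change gate for expression splits. Default 2.
#' @param min_lines_per_type Minimum lines per cancer type. Default 10.
#' @return List of class `deplink_config`.
#' @export
deplink_config <- function(freq_min = 10L, percentile = 0.18, p_cutoff = 0.05,
                           q_cutoff = 0.1, diff_cutoff = 0.1, fc_cutoff = 2,
                           min_lines_per_type = 10L) {
  stopifnot(percentile > 0, percentile < 0.5, freq_min > 0, p_cutoff > 0,
            q_cutoff > 0, diff_cutoff > 0, fc_cutoff > 0, min_lines_per_type > 0)
  structure(list(freq_min = as.integer(freq_min), percentile = percentile,
                 p_cutoff = p_cutoff, q_cutoff = q_cutoff,
                 diff_cutoff = diff_cutoff, fc_cutoff = fc_cutoff,
                 min_lines_per_type = as.integer(min_lines_per_type)),
            class = "deplink_config")
}

#' Pooled-variance two-sample t-test
#'
#' Unpaired, two-tailed Student's t with equal-variance pooling and
#' df = n1 + n2 - 2, the test used throughout the association analyses.
#' When the pooled variance is (essentially) zero the test is undefined;
#' a non-significant sentinel (t = 0, p = 1) is returned with a flag
#' instead of an error so family-level scans can proceed.
#'
#' @param x,y Numeric vectors, each of length >= 2 after NA removal.
#' @return List with `t`, `p`, `df`, and logical `degenerate`.
#' @export
students_t_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least 2 non-missing values (got ",
         length(x), " and ", length(y), ")")
  }
  res <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {   # essentially constant data
    return(list(t = 0, p = 1, df = length(x) + length(y) - 2L,
                degenerate = TRUE))
  }
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), degenerate = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input. NAs propagate.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Split cell lines by ranked value
#'
#' Ranks the non-missing values and takes the top `floor(percentile * n)`
#' lines as the high group; the other group is the bottom
#' `floor(percentile * n)` (`top_vs_bottom`) or all remaining lines
#' (`top_vs_rest`). Ties break by line id so re-runs are deterministic.
#'
#' @param values Named numeric vector (names = line ids).
#' @param percentile Ranking fraction.
#' @param mode `"top_vs_bottom"` or `"top_vs_rest"`.
#' @return List with character vectors `high` and `other`.
#' @export
rank_and_split <- function(values, percentile,
                           mode = c("top_vs_bottom", "top_vs_rest")) {
  mode <- match.arg(mode)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n && max(values) == min(values)) {
    stop("values are constant; ranking split is undefined")
  }
  g <- floor(percentile * n)
  if (g < 2L) {
    stop("ranking group size floor(", percentile, " * ", n, ") = ", g,
         " is below 2")
  }
  ord <- order(-values, names(values))
  ids <- names(values)[ord]
  high <- ids[seq_len(g)]
  other <- if (mode == "top_vs_bottom") rev(ids)[seq_len(g)] else ids[-seq_len(g)]
  list(high = high, other = other)
}

.assoc_record <- function(module_id, feature_id, high, other, tt) {
  data.frame(module_id = module_id, feature_id = feature_id,
             n_high = length(high), n_other = length(other),
             effect = mean(high) - mean(other),
             t = tt$t, p = tt$p, q = NA_real_, passes = NA,
             stringsAsFactors = FALSE)
}

#' Cancer-type-specific module dependencies
#'
#' For every module x cancer type (types with at least
#' `min_lines_per_type` annotated, scored lines), tests the module's
#' dependency scores in that type against all other retained lines with a
#' pooled t-test. Effect = mean(type) - mean(others). BH correction is
#' applied jointly over all module x type tests; a record passes when
#' q < `q_cutoff`.
#'
#' @param score_mat Lines x modules matrix from [score_modules()].
#' @param annotations Data frame with columns `line_id`, `cancer_type`
#'   (and optionally `lineage_class`).
#' @param cfg A [deplink_config()].
#' @return Association table: one row per module x type with columns
#'   module_id, feature_id, n_high, n_other, effect, t, p, q, passes.
#' @export
cancer_type_specificity <- function(score_mat, annotations, cfg = deplink_config()) {
  ann <- annotations[match(rownames(score_mat), annotations$line_id), ]
  type <- as.character(ann$cancer_type)
  keep_types <- names(which(table(type[!is.na(type)]) >= cfg$min_lines_per_type))
  if (length(keep_types) < 2L) {
    stop("need at least 2 cancer types with >= ", cfg$min_lines_per_type, " lines")
  }
  in_panel <- !is.na(type) & type %in% keep_types
  recs <- list()
  for (m in colnames(score_mat)) {
    s <- score_mat[, m]
    for (ty in keep_types) {
      hi <- s[in_panel & type == ty]
      ot <- s[in_panel & type != ty]
      hi <- hi[!is.na(hi)]; ot <- ot[!is.na(ot)]
      if (length(hi) < 2L || length(ot) < 2L) next
      recs[[length(recs) + 1L]] <- .assoc_record(m, ty, hi, ot,
                                                 students_t_two_sample(hi, ot))
    }
  }
  .finalize_family(recs, gate = "q", cfg)
}

#' Binary-feature module associations
#'
#' Tests each module's dependency scores in feature carriers against
#' non-carriers within a line subset. Features with fewer than `freq_min`
#' carriers, or fewer than 2 non-carriers, are dropped with a warning.
#' The significance gate is raw p < `p_cutoff` (`significance = "p"`, the
#' mutational-signature convention) or BH q < `q_cutoff`
#' (`significance = "q"`).
#'
#' @param score_mat Lines x modules matrix.
#' @param features Binary `feature_table`.
#' @param line_subset Line ids to analyse; default all scored lines.
#' @param cfg A [deplink_config()].
#' @param significance `"p"` or `"q"`.
#' @return Association table as in [cancer_type_specificity()].
#' @export
binary_feature_dependency <- function(score_mat, features, line_subset = NULL,
                                      cfg = deplink_config(),
                                      significance = c("p", "q")) {
  significance <- match.arg(significance)
  stopifnot(identical(attr(features, "kind"), "binary"))
  lines <- intersect(rownames(score_mat),
                     if (is.null(line_subset)) rownames(features) else line_subset)
  lines <- intersect(lines, rownames(features))
  if (!length(lines)) stop("line subset does not overlap scored, profiled lines")
  fm <- unclass(features)[lines, , drop = FALSE]
  recs <- list()
  dropped <- character()
  for (f in colnames(fm)) {
    v <- fm[, f]
    carriers <- lines[!is.na(v) & v == 1]
    noncar <- lines[!is.na(v) & v == 0]
    if (length(carriers) < cfg$freq_min || length(noncar) < 2L) {
      dropped <- c(dropped, f)
      next
    }
    for (m in colnames(score_mat)) {
      hi <- score_mat[carriers, m]; ot <- score_mat[noncar, m]
      hi <- hi[!is.na(hi)]; ot <- ot[!is.na(ot)]
      if (length(hi) < 2L || length(ot) < 2L) next
      recs[[length(recs) + 1L]] <- .assoc_record(m, f, hi, ot,
                                                 students_t_two_sample(hi, ot))
    }
  }
  if (length(dropped)) {
    warning(length(dropped), " binary feature(s) dropped (carriers < ",
            cfg$freq_min, " or no contrast group): ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  .finalize_family(recs, gate = significance, cfg)
}

#' Continuous-feature module associations
#'
#' For each feature, the high group is the top `percentile` of lines by
#' feature value (top-vs-rest split); each module's dependency scores in
#' the high group are tested against the rest. BH correction is applied
#' over all module x feature tests; a record passes when q < `q_cutoff`
#' and |effect| > `diff_cutoff`.
#'
#' @inheritParams binary_feature_dependency
#' @param features Continuous `feature_table`.
#' @return Association table.
#' @export
continuous_feature_dependency <- function(score_mat, features, line_subset = NULL,
                                          cfg = deplink_config()) {
  stopifnot(identical(attr(features, "kind"), "continuous"))
  lines <- intersect(rownames(score_mat),
                     if (is.null(line_subset)) rownames(features) else line_subset)
  lines <- intersect(lines, rownames(features))
  if (!length(lines)) stop("line subset does not overlap scored, profiled lines")
  fm <- unclass(features)[lines, , drop = FALSE]
  recs <- list()
  for (f in colnames(fm)) {
    v <- fm[, f]
    v <- v[!is.na(v)]
    if (length(v) < cfg$freq_min) {
      warning("feature '", f, "' observed in fewer than ", cfg$freq_min,
              " lines; dropped")
      next
    }
    split <- rank_and_split(v, cfg$percentile, mode = "top_vs_rest")
    for (m in colnames(score_mat)) {
      hi <- score_mat[split$high, m]; ot <- score_mat[split$other, m]
      hi <- hi[!is.na(hi)]; ot <- ot[!is.na(ot)]
      if (length(hi) < 2L || length(ot) < 2L) next
      recs[[length(recs) + 1L]] <- .assoc_record(m, f, hi, ot,
                                                 students_t_two_sample(hi, ot))
    }
  }
  .finalize_family(recs, gate = "q", cfg, diff_gate = TRUE)
}

#' Gene-set signature scores from expression
#'
#' Per line, the mean over set genes of across-line z-scored expression.
#' Genes absent from the matrix or with zero expression variance are
#' skipped (with a warning for the latter); a line scores missing only
#' when every set gene is missing.
#'
#' @param expr Genes x lines expression matrix.
#' @param gene_set Character vector of gene ids (symbol-matched against
#'   the matrix rownames).
#' @return Named numeric vector over cell lines.
#' @export
signature_score <- function(expr, gene_set) {
  sym <- gene_symbol(rownames(expr))
  rows <- which(sym %in% gene_symbol(gene_set) | rownames(expr) %in% gene_set)
  if (!length(rows)) stop("no signature gene present in the expression matrix")
  sub <- expr[rows, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd, na.rm = TRUE)
  flat <- is.na(sds) | sds == 0
  if (any(flat)) {
    warning(sum(flat), " signature gene(s) with zero expression variance skipped")
    sub <- sub[!flat, , drop = FALSE]
  }
  if (!nrow(sub)) stop("all signature genes have zero expression variance")
  mu <- rowMeans(sub, na.rm = TRUE)
  sd_ <- apply(sub, 1L, stats::sd, na.rm = TRUE)
  z <- (sub - mu) / sd_
  s <- colMeans(z, na.rm = TRUE)
  s[colSums(!is.na(z)) == 0L] <- NA_real_
  stats::setNames(s, colnames(expr))
}

#' Readout contrast between dependent and non-dependent lines
#'
#' Splits the lines into top and bottom `percentile` groups by one
#' module's dependency score and t-tests a per-line readout (hallmark
#' signature score, z-scored drug ln-IC50, ...) between them. Effect =
#' mean(high-dependency) - mean(low-dependency). Gating is left to the
#' family wrappers.
#'
#' @param scores Named numeric vector: one module's per-line dependency.
#' @param readout Named numeric vector over (a superset of) the same lines.
#' @param cfg A [deplink_config()].
#' @return One-row association data frame (q, passes unset).
#' @export
dependency_group_readout <- function(scores, readout, cfg = deplink_config()) {
  common <- intersect(names(scores)[!is.na(scores)],
                      names(readout)[!is.na(readout)])
  split <- rank_and_split(scores[common], cfg$percentile, mode = "top_vs_bottom")
  hi <- readout[split$high]; ot <- readout[split$other]
  .assoc_record(NA_character_, NA_character_, hi, ot,
                students_t_two_sample(hi, ot))
}

#' Hallmark-signature contrasts for all modules
#'
#' For every module x gene-set pair, computes the signature score
#' ([signature_score()]) and contrasts it between high- and low-dependency
#' lines ([dependency_group_readout()]). Passes at raw p < 0.01.
#'
#' @param score_mat Lines x modules matrix.
#' @param expr Genes x lines expression matrix.
#' @param gene_sets Named list of gene-id vectors.
#' @param cfg A [deplink_config()].
#' @param p_gate Raw-p gate for this family. Default 0.01.
#' @return Association table.
#' @export
hallmark_signature_dependency <- function(score_mat, expr, gene_sets,
                                          cfg = deplink_config(), p_gate = 0.01) {
  recs <- list()
  for (gs in names(gene_sets)) {
    sig <- signature_score(expr, gene_sets[[gs]])
    for (m in colnames(score_mat)) {
      rec <- dependency_group_readout(score_mat[, m], sig, cfg)
      rec$module_id <- m; rec$feature_id <- gs
      recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, recs)
  out$q <- bh_fdr(out$p)
  out$passes <- !is.na(out$p) & out$p < p_gate
  out
}

#' Drug-sensitivity contrasts for all modules
#'
#' ln-IC50 values are z-scored across cell lines per drug, then contrasted
#' between high- and low-dependency lines for every module. BH correction
#' runs over all drug x module tests; a pair passes when q < `q_cutoff`
#' and the |mean z difference| exceeds `z_gate`. Note the sign: lower
#' IC50 = more sensitive, so increased sensitivity in dependent lines
#' shows as a negative effect.
#'
#' @param score_mat Lines x modules matrix.
#' @param drugs Continuous `feature_table` of ln-IC50 (lines x drugs).
#' @param cfg A [deplink_config()].
#' @param z_gate Minimum |mean z-score difference|. Default 0.2.
#' @return Association table.
#' @export
drug_sensitivity_dependency <- function(score_mat, drugs,
                                        cfg = deplink_config(), z_gate = 0.2) {
  stopifnot(identical(attr(drugs, "kind"), "continuous"))
  zmat <- apply(unclass(drugs), 2L, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(v * 0)  # constant drug: degenerate, sentinel downstream
    (v - mean(v, na.rm = TRUE)) / s
  })
  rownames(zmat) <- rownames(drugs)
  recs <- list()
  for (d in colnames(zmat)) {
    z <- stats::setNames(zmat[, d], rownames(zmat))
    if (all(is.na(z))) next
    for (m in colnames(score_mat)) {
      rec <- dependency_group_readout(score_mat[, m], z, cfg)
      rec$module_id <- m; rec$feature_id <- d
      recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, recs)
  out$q <- bh_fdr(out$p)
  out$passes <- !is.na(out$q) & out$q < cfg$q_cutoff & abs(out$effect) > z_gate
  out
}

#' Expression--dependency correlation for one gene
#'
#' Pearson correlation between a gene's expression and its (or its
#' module's) dependency over the overlapping lines, with the
#' single-predictor regression F-test p-value (identical to the
#' correlation t-test).
#'
#' @param expr_gene Named numeric vector: per-line expression.
#' @param dep_gene Named numeric vector: per-line dependency.
#' @param min_overlap Minimum overlapping lines. Default 10.
#' @return List with `r`, `p`, `n`.
#' @export
expression_dependency_correlation <- function(expr_gene, dep_gene,
                                              min_overlap = 10L) {
  common <- intersect(names(expr_gene)[!is.na(expr_gene)],
                      names(dep_gene)[!is.na(dep_gene)])
  if (length(common) < min_overlap) {
    stop("only ", length(common), " overlapping lines (need ", min_overlap, ")")
  }
  x <- expr_gene[common]; y <- dep_gene[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance on one side of the correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

# Joint BH + gating for one association family. gate: "p" or "q";
# diff_gate additionally requires |effect| > diff_cutoff.
.finalize_family <- function(recs, gate, cfg, diff_gate = FALSE) {
  if (!length(recs)) {
    return(data.frame(module_id = character(), feature_id = character(),
                      n_high = integer(), n_other = integer(),
                      effect = numeric(), t = numeric(), p = numeric(),
                      q = numeric(), passes = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out$q <- bh_fdr(out$p)
  out$passes <- if (gate == "p") {
    !is.na(out$p) & out$p < cfg$p_cutoff
  } else {
    !is.na(out$q) & out$q < cfg$q_cutoff
  }
  if (diff_gate) out$passes <- out$passes & abs(out$effect) > cfg$diff_cutoff
  rownames(out) <- NULL
  out
}
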