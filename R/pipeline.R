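#' Default run configuration
#'
#' Assembles every parameter of the two end-to-end runs with the standard
#' defaults: common-essential filter (effect < -1 in > 90% of lines),
#' pairwise correlation (min overlap 100), matrix cutoff 0.4, network
#' cutoff 0.34, per-gene edge cap 15, module-size cap 15, and the
#' association gates of [deplink_config()].
#'
#' @param ... Overrides for any field.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    matrix_path = NULL, annotations_path = NULL,
    binary_features_path = NULL, continuous_features_path = NULL,
    drug_path = NULL, expression_path = NULL,
    complex_catalog_path = NULL, interaction_catalog_path = NULL,
    out_dir = ".",
    effect_cutoff = -1, line_fraction = 0.9, min_overlap = 100L,
    matrix_cutoff = 0.4, network_cutoff = 0.34, k_max = 15L,
    max_module_size = 15L, calibrate = FALSE,
    roc_grid = seq(0.05, 0.95, by = 0.01),
    deplink = deplink_config(), seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror [run_config()] field names; `deplink:` may be a nested map
#' of [deplink_config()] fields.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$deplink)) y$deplink <- do.call(deplink_config, y$deplink)
  do.call(run_config, y)
}

#' Run the network-construction pipeline
#'
#' Filter common essentials -> pairwise correlation -> (optional)
#' complex-catalog calibration -> build network -> call modules ->
#' export. Artifacts written under `cfg$out_dir`: `modules.tsv`,
#' `edges.tsv`, `removed_essentials.txt`, and when a complex catalog is
#' supplied `roc_diagnostics.tsv`; a `manifest.tsv` with md5 checksums
#' closes the run. Idempotent given the seed.
#'
#' @param cfg A [run_config()]; `matrix_path` is required (or pass `gem`).
#' @param gem Optional in-memory genes x lines matrix overriding
#'   `matrix_path`.
#' @return List with `network`, `modules`, `correlation`, `filtered`,
#'   `calibration` (or NULL), `manifest`.
#' @export
run_build_dcn <- function(cfg = run_config(), gem = NULL) {
  if (is.null(gem)) {
    if (is.null(cfg$matrix_path)) stop("stage input: no matrix supplied")
    gem <- read_gene_effect_csv(cfg$matrix_path, orientation = "lines_as_rows",
                                header_dialect = "depmap")
  }
  filt <- .stage("filter_common_essentials",
                 filter_common_essentials(gem, cfg$effect_cutoff, cfg$line_fraction))
  corr <- .stage("pairwise_correlation",
                 pairwise_correlation(filt$gem, cfg$min_overlap))
  calib <- NULL
  network_cutoff <- cfg$network_cutoff
  if (!is.null(cfg$complex_catalog_path)) {
    catalog <- read_complex_catalog(cfg$complex_catalog_path)
    calib <- .stage("optimize_network_cutoff",
                    optimize_network_cutoff(corr, catalog, cfg$roc_grid,
                                            seed = cfg$seed))
    if (isTRUE(cfg$calibrate)) network_cutoff <- calib$threshold
  } else {
    message("no complex catalog supplied; calibration stage skipped")
  }
  net <- .stage("build_network",
                build_network(corr, cfg$matrix_cutoff, network_cutoff, cfg$k_max))
  modules <- .stage("call_modules", call_modules(net, cfg$max_module_size))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("modules.tsv", "edges.tsv", "removed_essentials.txt")
  utils::write.table(modules, file.path(cfg$out_dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  el <- igraph::as_data_frame(net, what = "edges")
  colnames(el) <- c("gene_a", "gene_b", "r")
  utils::write.table(el, file.path(cfg$out_dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(filt$essential, file.path(cfg$out_dir, "removed_essentials.txt"))
  if (!is.null(calib)) {
    utils::write.table(calib$diagnostics,
                       file.path(cfg$out_dir, "roc_diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "roc_diagnostics.tsv")
  }
  manifest <- data.frame(
    file = files, md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(network = net, modules = modules, correlation = corr, filtered = filt,
       calibration = calib, manifest = manifest)
}

#' Run the context-association pipeline
#'
#' Scores every module, then runs each association family whose inputs
#' are available: cancer-type specificity (annotations), binary features,
#' continuous features, and drug sensitivity. One TSV per family is
#' written under `cfg$out_dir`; a family whose inputs are missing or
#' unusable is skipped with a message and the run continues.
#'
#' @param cfg A [run_config()].
#' @param gem Genes x lines matrix (post- or pre-filter; scoring uses it
#'   as given).
#' @param modules Module table from [call_modules()]; must be non-empty.
#' @param annotations Optional annotations data frame (else read from
#'   `cfg$annotations_path`).
#' @param binary,continuous,drugs Optional feature tables (else read from
#'   the corresponding paths).
#' @return List with `scores` and one association table per executed
#'   family, plus `summary` (family, n_tests, n_pass).
#' @export
run_deplink <- function(cfg = run_config(), gem, modules,
                        annotations = NULL, binary = NULL,
                        continuous = NULL, drugs = NULL) {
  if (is.null(modules) || nrow(modules) == 0L) stop("empty module list")
  scores <- score_modules(gem, modules)
  if (is.null(annotations) && !is.null(cfg$annotations_path)) {
    annotations <- utils::read.table(cfg$annotations_path, header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
  }
  if (is.null(binary) && !is.null(cfg$binary_features_path)) {
    binary <- read_feature_table(cfg$binary_features_path, kind = "binary")
  }
  if (is.null(continuous) && !is.null(cfg$continuous_features_path)) {
    continuous <- read_feature_table(cfg$continuous_features_path,
                                     kind = "continuous")
  }
  if (is.null(drugs) && !is.null(cfg$drug_path)) {
    drugs <- read_feature_table(cfg$drug_path, kind = "continuous")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(scores = scores)
  fam <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      message("family '", name, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      utils::write.table(res, file.path(cfg$out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
  }
  if (!is.null(annotations)) {
    out$cancer_type <- fam("cancer_type",
                           cancer_type_specificity(scores, annotations, cfg$deplink))
  }
  if (!is.null(binary)) {
    out$binary <- fam("binary_features",
                      binary_feature_dependency(scores, binary, cfg = cfg$deplink,
                                                significance = "p"))
  }
  if (!is.null(continuous)) {
    out$continuous <- fam("continuous_features",
                          continuous_feature_dependency(scores, continuous,
                                                        cfg = cfg$deplink))
  }
  if (!is.null(drugs)) {
    out$drugs <- fam("drug_sensitivity",
                     drug_sensitivity_dependency(scores, drugs, cfg = cfg$deplink))
  }
  done <- setdiff(names(out), "scores")
  out$summary <- data.frame(
    family = done,
    n_tests = vapply(out[done], function(x) if (is.null(x)) 0L else nrow(x), integer(1L)),
    n_pass = vapply(out[done], function(x) if (is.null(x)) 0L else sum(x$passes), integer(1L)),
    stringsAsFactors = FALSE)
  out
}

#' End-to-end synthetic validation
#'
#' Generates the reference synthetic condition, runs network construction
#' and module calling, and compares called to planted modules with the
#' adjusted Rand index; then runs the association engine over the planted
#' couplings and reports detection power. Used by the `validate` CLI
#' subcommand and the acceptance checks.
#'
#' @param seed Integer seed.
#' @param params Optional [sim_params()] override.
#' @return List with `ari`, `n_modules_called`, `binary_power`,
#'   `drug_power`, and the underlying objects.
#' @export
validate_synthetic <- function(seed = 1L, params = NULL) {
  if (is.null(params)) {
    params <- sim_params(
      seed = seed,
      binary_couplings = data.frame(module = sprintf("M%02d", 1:5),
                                    feature = sprintf("mutsig_%02d", 1:5),
                                    carrier_fraction = 0.1, shift = 1),
      drug_couplings = data.frame(module = sprintf("M%02d", 6:10),
                                  drug = sprintf("drug_%02d", 1:5),
                                  slope = -0.8, noise_sd = 0.5))
  }
  screen <- simulate_dependency_screen(params)
  profiles <- simulate_profiles(screen, params)
  filt <- filter_common_essentials(screen$gem)
  corr <- pairwise_correlation(filt$gem)
  net <- build_network(corr)
  modules <- call_modules(net)
  ari <- module_recovery_ari(modules, screen$truth$members)
  scores <- score_modules(filt$gem, modules)
  map <- match_modules_to_truth(modules, screen$truth$members)

  binary_power <- NA_real_
  if (!is.null(params$binary_couplings) && !is.null(profiles$binary)) {
    res <- binary_feature_dependency(scores, profiles$binary,
                                     significance = "p")
    binary_power <- .coupling_power(res, params$binary_couplings, "feature", map)
  }
  drug_power <- NA_real_
  if (!is.null(params$drug_couplings) && !is.null(profiles$drugs)) {
    res <- drug_sensitivity_dependency(scores, profiles$drugs)
    drug_power <- .coupling_power(res, params$drug_couplings, "drug", map)
  }
  list(ari = ari, n_modules_called = length(unique(modules$module_id)),
       binary_power = binary_power, drug_power = drug_power,
       modules = modules, truth = screen$truth, scores = scores,
       profiles = profiles, network = net, gem = filt$gem)
}

#' Adjusted Rand index between called and planted modules
#'
#' Computed over the union of genes in called modules and planted
#' modules; genes outside either partition get a shared background label.
#'
#' @param modules Module table.
#' @param planted Named list: module id -> member gene ids.
#' @return ARI in \[-1, 1\].
#' @export
module_recovery_ari <- function(modules, planted) {
  genes <- union(modules$gene, unlist(planted, use.names = FALSE))
  called <- stats::setNames(rep("bg", length(genes)), genes)
  called[modules$gene] <- as.character(modules$module_id)
  truth <- stats::setNames(rep("bg", length(genes)), genes)
  for (k in names(planted)) truth[planted[[k]]] <- k
  .adjusted_rand(called, truth)
}

#' Match called modules to planted modules by maximal overlap
#'
#' @param modules Module table.
#' @param planted Named list of planted member vectors.
#' @return Named character vector: planted id -> called module_id (NA if
#'   no called module overlaps).
#' @export
match_modules_to_truth <- function(modules, planted) {
  called <- split(modules$gene, modules$module_id)
  vapply(planted, function(mem) {
    ov <- vapply(called, function(g) length(intersect(g, mem)), integer(1L))
    if (!length(ov) || max(ov) == 0L) NA_character_ else names(called)[which.max(ov)]
  }, character(1L))
}

# Hubert-Arabie adjusted Rand from the pair-count contingency table.
# (Kept internal; mclust::adjustedRandIndex is the independent oracle in
# the test suite.)
.adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

.coupling_power <- function(res, couplings, feature_col, map) {
  hit <- logical(nrow(couplings))
  for (i in seq_len(nrow(couplings))) {
    called_id <- map[[as.character(couplings$module[i])]]
    f <- as.character(couplings[[feature_col]][i])
    if (is.na(called_id)) next
    row <- res$module_id == called_id & res$feature_id == f
    hit[i] <- any(res$passes[row])
  }
  mean(hit)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}
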