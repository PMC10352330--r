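#' Simulation parameters for a planted-module dependency screen
#'
#' The generator emulates the statistical structure the network and
#' association analyses assume: a genes x lines gene-effect matrix with
#' disjoint planted co-dependent modules (a one-factor model per module),
#' a common-essential subset, and context couplings that shift module
#' dependency for carriers of a binary feature, tie continuous features
#' linearly to a module's latent factor, and tie drug ln-IC50 linearly to
#' a module's dependency score.
#'
#' Defaults describe the reference study condition used throughout the
#' test suite: 20 modules of size 4--8 among 3000 genes over 1000 lines,
#' with within-module correlation targeting
#' `lambda^2 sigma_m^2 / (lambda^2 sigma_m^2 + sigma_e^2) = 0.6`
#' (`lambda = 1`, `sigma_m = 1`, `sigma_e = sqrt(2/3)`), plus 50 common
#' essentials at mean effect -1.5.
#'
#' @param n_genes Total genes (modules + essentials + background). Default 3000.
#' @param n_lines Cell lines. Default 1000.
#' @param n_modules Planted modules. Default 20.
#' @param module_size_range Inclusive size range, within 2..15. Default c(4, 8).
#' @param loading Factor loading lambda per module gene. Default 1.
#' @param latent_sd Latent factor SD sigma_m. Default 1.
#' @param noise_sd Per-gene residual SD sigma_e. Default `sqrt(2/3)`.
#' @param baseline_mean Mean effect of non-essential genes. Default 0.
#' @param n_common_essential Common-essential genes. Default 50.
#' @param essential_mean Mean effect of essentials (< -1). Default -1.5.
#' @param binary_couplings Data frame (module, feature, carrier_fraction,
#'   shift) — carriers' module dependency is shifted by `shift` latent-sd
#'   units (positive shift = carriers more dependent).
#' @param continuous_couplings Data frame (module, feature, slope, noise_sd):
#'   feature = slope * latent + noise.
#' @param drug_couplings Data frame (module, drug, slope, noise_sd):
#'   ln-IC50 = slope * module dependency score + noise.
#' @param n_null_binary,n_null_continuous,n_null_drugs Uncoupled noise
#'   features emitted alongside. Defaults 5 each.
#' @param null_carrier_fraction Carrier fraction of null binary features.
#'   Default 0.15.
#' @param cancer_type_fractions Named numeric, line fractions per type
#'   (must sum to 1). Default 6 types.
#' @param blood_types Types labelled `blood`; the rest are `solid`.
#' @param expression_addiction_r Correlation between a module gene's
#'   expression and its dependency score (oncogene-addiction pattern);
#'   0 disables. Default 0.
#' @param seed Integer seed; all randomness flows from it. Default 1.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_genes = 3000L, n_lines = 1000L, n_modules = 20L,
                       module_size_range = c(4L, 8L), loading = 1,
                       latent_sd = 1, noise_sd = sqrt(2 / 3),
                       baseline_mean = 0, n_common_essential = 50L,
                       essential_mean = -1.5,
                       binary_couplings = NULL, continuous_couplings = NULL,
                       drug_couplings = NULL,
                       n_null_binary = 5L, n_null_continuous = 5L,
                       n_null_drugs = 5L, null_carrier_fraction = 0.15,
                       cancer_type_fractions = c(LUAD = 0.2, BRCA = 0.2,
                                                 COAD = 0.15, SKCM = 0.15,
                                                 LAML = 0.15, DLBC = 0.15),
                       blood_types = c("LAML", "DLBC"),
                       expression_addiction_r = 0,
                       seed = 1L) {
  stopifnot(module_size_range[1L] >= 2L, module_size_range[2L] <= 15L,
            module_size_range[1L] <= module_size_range[2L],
            latent_sd >= 0, noise_sd >= 0, essential_mean < -1,
            abs(sum(cancer_type_fractions) - 1) < 1e-8)
  p <- list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
            n_modules = as.integer(n_modules),
            module_size_range = as.integer(module_size_range),
            loading = loading, latent_sd = latent_sd, noise_sd = noise_sd,
            baseline_mean = baseline_mean,
            n_common_essential = as.integer(n_common_essential),
            essential_mean = essential_mean,
            binary_couplings = binary_couplings,
            continuous_couplings = continuous_couplings,
            drug_couplings = drug_couplings,
            n_null_binary = as.integer(n_null_binary),
            n_null_continuous = as.integer(n_null_continuous),
            n_null_drugs = as.integer(n_null_drugs),
            null_carrier_fraction = null_carrier_fraction,
            cancer_type_fractions = cancer_type_fractions,
            blood_types = blood_types,
            expression_addiction_r = expression_addiction_r,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' Simulate a gene-effect matrix with planted modules
#'
#' Generative model, drawn in a fixed order from a single seeded stream
#' (module sizes; latent factors; binary carrier sets; module-gene noise;
#' essential noise; background noise): for module k, latent
#' `m_k(line) ~ N(0, sigma_m^2)`, minus `shift * sigma_m` for carriers of
#' any coupled binary feature; member gene effect =
#' `baseline + loading * m_k + N(0, sigma_e^2)`; background genes =
#' `baseline + N(0, sigma_e^2)`; common essentials =
#' `essential_mean + N(0, 0.1^2)`.
#'
#' Gene ids carry synthetic symbols with pseudo-entrez suffixes
#' (`"SYNM001A (900101)"`) so the DepMap-dialect round trip and
#' symbol-level catalog matching are exercised end to end.
#'
#' @param params A [sim_params()].
#' @return List with `gem` (genes x lines matrix) and `truth` (module
#'   memberships, essential list, latent factors, carrier sets, coupling
#'   specs, seed).
#' @export
simulate_dependency_screen <- function(params = sim_params()) {
  p <- params
  withr::with_seed(p$seed, {
    size_pool <- seq(p$module_size_range[1L], p$module_size_range[2L])
    sizes <- if (length(size_pool) == 1L) rep(size_pool, p$n_modules)
             else sample(size_pool, p$n_modules, replace = TRUE)
    if (sum(sizes) + p$n_common_essential > p$n_genes) {
      stop("module + essential genes exceed n_genes")
    }
    line_ids <- sprintf("ACH-%06d", seq_len(p$n_lines))
    module_ids <- sprintf("M%02d", seq_len(p$n_modules))
    gene_ids <- .synth_gene_ids(p$n_genes)
    cursor <- 0L
    members <- stats::setNames(vector("list", p$n_modules), module_ids)
    for (k in seq_len(p$n_modules)) {
      members[[k]] <- gene_ids[cursor + seq_len(sizes[k])]
      cursor <- cursor + sizes[k]
    }
    essential <- if (p$n_common_essential > 0L)
      gene_ids[cursor + seq_len(p$n_common_essential)] else character()
    background <- gene_ids[-seq_len(cursor + p$n_common_essential)]

    latent <- matrix(stats::rnorm(p$n_modules * p$n_lines, 0, p$latent_sd),
                     nrow = p$n_modules,
                     dimnames = list(module_ids, line_ids))
    # binary-coupling carriers shift the coupled module's latent factor;
    # negative latent shift -> more negative member effects -> carriers
    # more dependent, so a positive `shift` reads as increased dependency
    carriers <- list()
    bc <- p$binary_couplings
    if (!is.null(bc) && nrow(bc)) {
      for (i in seq_len(nrow(bc))) {
        mod <- as.character(bc$module[i])
        if (!mod %in% module_ids) stop("binary coupling references unknown module ", mod)
        n_car <- round(bc$carrier_fraction[i] * p$n_lines)
        car <- sample(line_ids, n_car)
        carriers[[as.character(bc$feature[i])]] <- car
        latent[mod, car] <- latent[mod, car] - bc$shift[i] * p$latent_sd
      }
    }

    gem <- matrix(NA_real_, p$n_genes, p$n_lines,
                  dimnames = list(gene_ids, line_ids))
    for (k in seq_len(p$n_modules)) {
      for (g in members[[k]]) {
        gem[g, ] <- p$baseline_mean + p$loading * latent[k, ] +
          stats::rnorm(p$n_lines, 0, p$noise_sd)
      }
    }
    for (g in essential) {
      gem[g, ] <- p$essential_mean + stats::rnorm(p$n_lines, 0, 0.1)
    }
    if (length(background)) {
      gem[background, ] <- p$baseline_mean +
        stats::rnorm(length(background) * p$n_lines, 0, p$noise_sd)
    }
    truth <- list(members = members, essential = essential,
                  latent = latent, carriers = carriers,
                  binary_couplings = bc,
                  continuous_couplings = p$continuous_couplings,
                  drug_couplings = p$drug_couplings,
                  seed = p$seed)
    list(gem = gem, truth = truth)
  })
}

#' Simulate molecular profiles and annotations coupled to the screen
#'
#' Emits, in depmap_io-writable form: binary carrier features (coupled
#' carriers realized in [simulate_dependency_screen()], plus uncoupled
#' null features), continuous features (`slope * latent + noise` for
#' coupled pairs, pure noise otherwise), drug ln-IC50 tables
#' (`slope * module dependency score + noise`, plus null drugs),
#' per-module-gene expression optionally correlated with dependency
#' (oncogene-addiction pattern), and cancer-type annotations with a
#' blood/solid class.
#'
#' Uses its own seed stream (`seed + 1`) so profiles are reproducible
#' given the same truth.
#'
#' @param screen Output of [simulate_dependency_screen()].
#' @param params The same [sim_params()].
#' @return List with `binary`, `continuous`, `drugs` (feature tables),
#'   `expression` (genes x lines matrix), `annotations` (data frame).
#' @export
simulate_profiles <- function(screen, params) {
  p <- params
  gem <- screen$gem
  truth <- screen$truth
  line_ids <- colnames(gem)
  module_ids <- rownames(truth$latent)
  mod_scores <- vapply(module_ids, function(k)
    module_dependency_scores(gem, truth$members[[k]]), numeric(length(line_ids)))
  withr::with_seed(p$seed + 1L, {
    # binary features: coupled carrier sets from truth, then null carriers
    bnames <- character(); bcols <- list()
    for (f in names(truth$carriers)) {
      bnames <- c(bnames, f)
      bcols[[f]] <- as.numeric(line_ids %in% truth$carriers[[f]])
    }
    if (p$n_null_binary > 0L) {
      for (i in seq_len(p$n_null_binary)) {
        f <- sprintf("null_mut_%02d", i)
        car <- sample(line_ids, round(p$null_carrier_fraction * p$n_lines))
        bnames <- c(bnames, f)
        bcols[[f]] <- as.numeric(line_ids %in% car)
      }
    }
    binary <- if (length(bcols)) {
      feature_table(matrix(unlist(bcols), ncol = length(bcols),
                           dimnames = list(line_ids, bnames)), kind = "binary")
    } else NULL

    # continuous features
    cnames <- character(); ccols <- list()
    cc <- truth$continuous_couplings
    if (!is.null(cc) && nrow(cc)) {
      for (i in seq_len(nrow(cc))) {
        mod <- as.character(cc$module[i])
        if (!mod %in% module_ids) stop("continuous coupling references unknown module ", mod)
        f <- as.character(cc$feature[i])
        cnames <- c(cnames, f)
        ccols[[f]] <- cc$slope[i] * truth$latent[mod, ] +
          stats::rnorm(p$n_lines, 0, cc$noise_sd[i])
      }
    }
    if (p$n_null_continuous > 0L) {
      for (i in seq_len(p$n_null_continuous)) {
        f <- sprintf("null_mark_%02d", i)
        cnames <- c(cnames, f)
        ccols[[f]] <- stats::rnorm(p$n_lines)
      }
    }
    continuous <- if (length(ccols)) {
      feature_table(matrix(unlist(ccols), ncol = length(ccols),
                           dimnames = list(line_ids, cnames)),
                    kind = "continuous")
    } else NULL

    # drug ln-IC50
    dnames <- character(); dcols <- list()
    dc <- truth$drug_couplings
    if (!is.null(dc) && nrow(dc)) {
      for (i in seq_len(nrow(dc))) {
        mod <- as.character(dc$module[i])
        if (!mod %in% module_ids) stop("drug coupling references unknown module ", mod)
        d <- as.character(dc$drug[i])
        dnames <- c(dnames, d)
        dcols[[d]] <- dc$slope[i] * mod_scores[, mod] +
          stats::rnorm(p$n_lines, 0, dc$noise_sd[i])
      }
    }
    if (p$n_null_drugs > 0L) {
      for (i in seq_len(p$n_null_drugs)) {
        d <- sprintf("null_drug_%02d", i)
        dnames <- c(dnames, d)
        dcols[[d]] <- stats::rnorm(p$n_lines)
      }
    }
    drugs <- if (length(dcols)) {
      feature_table(matrix(unlist(dcols), ncol = length(dcols),
                           dimnames = list(line_ids, dnames)),
                    kind = "continuous")
    } else NULL

    # expression for module genes; optional addiction coupling to dependency
    mod_genes <- unlist(truth$members, use.names = FALSE)
    expr <- matrix(stats::rnorm(length(mod_genes) * p$n_lines, 5, 1),
                   length(mod_genes), p$n_lines,
                   dimnames = list(mod_genes, line_ids))
    rho <- p$expression_addiction_r
    if (rho != 0) {
      for (k in module_ids) {
        dep <- mod_scores[, k]
        depz <- (dep - mean(dep)) / stats::sd(dep)
        for (g in truth$members[[k]]) {
          expr[g, ] <- 5 + rho * depz + sqrt(1 - rho^2) * stats::rnorm(p$n_lines)
        }
      }
    }

    # cancer types: deterministic block assignment of shuffled lines
    shuffled <- sample(line_ids)
    n_per <- floor(p$cancer_type_fractions * p$n_lines)
    n_per[1L] <- p$n_lines - sum(n_per[-1L])
    type <- rep(names(n_per), n_per)
    annotations <- data.frame(
      line_id = shuffled, cancer_type = type,
      lineage_class = ifelse(type %in% p$blood_types, "blood", "solid"),
      stringsAsFactors = FALSE)
    annotations <- annotations[match(line_ids, annotations$line_id), ]
    rownames(annotations) <- NULL

    list(binary = binary, continuous = continuous, drugs = drugs,
         expression = expr, annotations = annotations)
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Serializes the screen and profiles in the exact dialects the IO module
#' reads (DepMap-dialect gene-effect CSV, tab-delimited feature tables and
#' annotations, complex catalog built from the planted modules, truth
#' sidecar as JSON) and returns a manifest with md5 checksums.
#'
#' @param dir Output directory (created if needed).
#' @param screen Output of [simulate_dependency_screen()].
#' @param profiles Output of [simulate_profiles()].
#' @return Data frame manifest (file, md5), invisibly the paths exist.
#' @export
write_fixture_bundle <- function(dir, screen, profiles) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  w <- function(name) { files <<- c(files, name); file.path(dir, name) }
  write_gene_effect_csv(screen$gem, w("gene_effect.csv"),
                        orientation = "lines_as_rows")
  if (!is.null(profiles$binary))
    write_feature_table(profiles$binary, w("binary_features.tsv"))
  if (!is.null(profiles$continuous))
    write_feature_table(profiles$continuous, w("continuous_features.tsv"))
  if (!is.null(profiles$drugs))
    write_feature_table(profiles$drugs, w("drug_lnic50.tsv"))
  utils::write.table(
    data.frame(gene = rownames(profiles$expression),
               format(profiles$expression, digits = 17, trim = TRUE,
                      scientific = FALSE), check.names = FALSE),
    w("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(profiles$annotations, w("annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # planted modules double as a complex catalog for calibration tests
  utils::write.table(
    data.frame(complex_id = names(screen$truth$members),
               members = vapply(screen$truth$members, function(m)
                 paste(gene_symbol(m), collapse = ";"), character(1L))),
    w("complex_catalog.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- screen$truth
  truth_json$latent <- NULL   # bulky; reproducible from the seed
  jsonlite::write_json(truth_json, w("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

.synth_gene_ids <- function(n) {
  # synthetic symbols SYNM001A..; pseudo-entrez ids keep the depmap dialect
  syms <- sprintf("SYN%04X", seq_len(n))
  sprintf("%s (%d)", syms, 900000L + seq_len(n))
}
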