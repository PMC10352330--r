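#' Read a gene-effect matrix from delimited text
#'
#' Parses a genes x cell-lines fitness matrix into the canonical orientation
#' (genes as rows, cell lines as columns) regardless of how the file is laid
#' out on disk. The DepMap dialect stores cell lines as rows and gene columns
#' headed `"SYMBOL (ENTREZID)"`; the plain dialect uses arbitrary unique ids.
#' Empty cells become `NA` and are preserved as missing throughout the
#' package (never imputed).
#'
#' @param path Path to a CSV/TSV file with one header row and one id column
#'   (the first column).
#' @param orientation `"genes_as_rows"` or `"lines_as_rows"`: which entity
#'   the file's rows represent.
#' @param header_dialect `"depmap"` (gene ids of the form `"SYMBOL (ENTREZID)"`)
#'   or `"plain"`. With `"depmap"`, gene ids are validated against that form.
#' @param sep Field separator, default `","`.
#' @return A numeric matrix, genes as rows (rownames = gene ids), cell lines
#'   as columns (colnames = line ids).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("gene,L1,L2", "g1,-1.0,0.0", "g2,0.5,"), tf)
#' gem <- read_gene_effect_csv(tf, orientation = "genes_as_rows",
#'                             header_dialect = "plain")
#' is.na(gem["g2", "L2"])
#' @export
read_gene_effect_csv <- function(path,
                                 orientation = c("lines_as_rows", "genes_as_rows"),
                                 header_dialect = c("depmap", "plain"),
                                 sep = ",") {
  orientation <- match.arg(orientation)
  header_dialect <- match.arg(header_dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), comment.char = "")
  if (ncol(df) < 2L) stop("matrix file must have an id column and at least one value column")
  row_ids <- as.character(df[[1L]])
  col_ids <- colnames(df)[-1L]
  .check_unique_ids(row_ids, "row id")
  .check_unique_ids(col_ids, "column id")
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     v[bad[1L]], row_ids[bad[1L]], col_ids[j]))
      }
      vals[[j]] <- as.numeric(v)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- row_ids
  if (orientation == "lines_as_rows") m <- t(m)
  if (header_dialect == "depmap") {
    bad <- rownames(m)[!grepl("^\\S+ \\(\\d+\\)$", rownames(m))]
    if (length(bad)) {
      stop("depmap dialect requires gene ids of the form 'SYMBOL (ENTREZID)'; offenders: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  m
}

#' Write a gene-effect matrix
#'
#' Inverse of [read_gene_effect_csv()]: writes the canonical genes x lines
#' matrix in the requested on-disk orientation. Missing entries are written
#' as empty cells. Full `.17g`-style precision is used so write-then-read is
#' value-identical.
#'
#' @param gem Numeric matrix, genes as rows.
#' @param path Output path.
#' @inheritParams read_gene_effect_csv
#' @return `path`, invisibly.
#' @export
write_gene_effect_csv <- function(gem, path,
                                  orientation = c("lines_as_rows", "genes_as_rows"),
                                  sep = ",") {
  orientation <- match.arg(orientation)
  m <- if (orientation == "lines_as_rows") t(gem) else gem
  id_name <- if (orientation == "lines_as_rows") "line" else "gene"
  df <- data.frame(id = rownames(m), format(m, digits = 17, trim = TRUE,
                                            scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[df == "NA"] <- ""
  colnames(df)[1L] <- id_name
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a collection of cell-line features
#'
#' Reads molecular features (expression, chromatin-mark abundance, signature
#' exposures, mutation status, drug ln-IC50, ...) into a `feature_table`:
#' a lines x features numeric matrix tagged with a declared kind. Binary
#' features are validated to contain only 0/1 (or NA); the kind is never
#' inferred from the data.
#'
#' @param path Delimited text file. `layout = "long"` expects three columns
#'   (line_id, feature_id, value); the wide layouts expect an id column plus
#'   one column per feature (or per line).
#' @param kind `"continuous"` or `"binary"` — applies to every feature in the
#'   file.
#' @param layout `"long"`, `"lines_as_rows"` or `"features_as_rows"`.
#' @param sep Field separator, default tab.
#' @return A `feature_table`: numeric matrix (rows = line ids, columns =
#'   feature ids) with attribute `kind`.
#' @export
read_feature_table <- function(path, kind = c("continuous", "binary"),
                               layout = c("lines_as_rows", "features_as_rows", "long"),
                               sep = "\t") {
  kind <- match.arg(kind)
  layout <- match.arg(layout)
  if (layout == "long") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, na.strings = c("", "NA"))
    if (ncol(df) != 3L) stop("long layout requires exactly 3 columns (line, feature, value)")
    lines <- unique(as.character(df[[1L]]))
    feats <- unique(as.character(df[[2L]]))
    m <- matrix(NA_real_, length(lines), length(feats),
                dimnames = list(lines, feats))
    m[cbind(match(df[[1L]], lines), match(df[[2L]], feats))] <- as.numeric(df[[3L]])
  } else {
    m <- read_gene_effect_csv(path, orientation = "genes_as_rows",
                              header_dialect = "plain", sep = sep)
    if (layout == "features_as_rows") m <- t(m)   # canonical: lines as rows
  }
  feature_table(m, kind = kind)
}

#' Construct a feature table
#'
#' @param values Numeric matrix, rows = cell lines, columns = features.
#' @param kind `"continuous"` or `"binary"`.
#' @return The matrix with class `feature_table` and attribute `kind`.
#' @export
feature_table <- function(values, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature table needs line rownames and feature colnames")
  .check_unique_ids(rownames(values), "line id")
  .check_unique_ids(colnames(values), "feature id")
  if (kind == "binary") {
    bad <- which(!is.na(values) & !(values %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("binary feature table contains non-{0,1} value %s at line '%s', feature '%s'",
                   values[bad[1L, , drop = FALSE]],
                   rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
    }
  }
  structure(values, kind = kind, class = c("feature_table", "matrix", "array"))
}

#' Write a feature table
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @param sep Field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, sep = "\t") {
  df <- data.frame(line = rownames(ft),
                   format(unclass(ft), digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[df == "NA"] <- ""
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-complex catalog
#'
#' Two-column table: `complex_id` and a semicolon-joined member list (the
#' CORUM-core style consumed here). Complexes with fewer than two resolvable
#' members are dropped with a warning.
#'
#' @param path Tab-delimited file with a header row.
#' @param sep Field separator, default tab.
#' @return Named list: complex id -> character vector of member gene symbols.
#' @export
read_complex_catalog <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("complex catalog needs (complex_id, members) columns")
  members <- lapply(strsplit(as.character(df[[2L]]), ";", fixed = TRUE),
                    function(x) unique(trimws(x[nzchar(trimws(x))])))
  names(members) <- as.character(df[[1L]])
  small <- lengths(members) < 2L
  if (any(small)) {
    warning(sum(small), " complex(es) with fewer than 2 members dropped: ",
            paste(utils::head(names(members)[small], 5L), collapse = ", "))
    members <- members[!small]
  }
  if (!length(members)) stop("no usable complexes in catalog")
  members
}

#' Read a pairwise-interaction catalog
#'
#' Consumes a BioGRID-style tab-delimited file via two official-symbol
#' columns. Pairs are canonicalized (sorted endpoints) and de-duplicated;
#' self-pairs are dropped with a warning.
#'
#' @param path Tab-delimited file with a header row.
#' @param symbol_cols Names (or indices) of the two gene-symbol columns;
#'   the BioGRID tab3 defaults are used when present, else columns 1:2.
#' @param sep Field separator, default tab.
#' @return Character matrix with columns `gene_a`, `gene_b`, one canonical
#'   pair per row.
#' @export
read_interaction_catalog <- function(path, symbol_cols = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (is.null(symbol_cols)) {
    tab3 <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
    symbol_cols <- if (all(tab3 %in% colnames(df))) tab3 else 1:2
  }
  a <- as.character(df[[symbol_cols[[1L]]]])
  b <- as.character(df[[symbol_cols[[2L]]]])
  canonical_pairs(a, b)
}

#' Canonicalize unordered gene pairs
#'
#' Sorts each pair's endpoints, drops self-pairs (with a warning) and
#' collapses duplicates.
#'
#' @param a,b Character vectors of equal length; `a[i]`--`b[i]` is one pair.
#' @return Character matrix with columns `gene_a`, `gene_b`.
#' @export
canonical_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  cbind(gene_a = lo[keep], gene_b = hi[keep])
}

#' Expand complexes to within-complex pairs
#'
#' A complex of n members yields all n(n-1)/2 unordered member pairs; the
#' union over complexes is de-duplicated.
#'
#' @param catalog Named list of member vectors (see [read_complex_catalog()]).
#' @return Canonical pair matrix as in [canonical_pairs()].
#' @export
complex_pairs <- function(catalog) {
  pieces <- lapply(catalog, function(m) {
    m <- unique(m)
    if (length(m) < 2L) return(NULL)
    cmb <- utils::combn(sort(m), 2L)
    cbind(cmb[1L, ], cmb[2L, ])
  })
  all <- do.call(rbind, pieces)
  if (is.null(all)) stop("catalog expands to zero pairs")
  canonical_pairs(all[, 1L], all[, 2L])
}

# Gene identity: full "SYMBOL (ENTREZID)" where available; catalogs carry
# bare symbols, so matching against them goes through the symbol component.
#' Extract the symbol component of a gene id
#'
#' `"MEN1 (4221)"` -> `"MEN1"`; ids without an entrez suffix pass through.
#'
#' @param gene_ids Character vector.
#' @return Character vector of symbols.
#' @export
gene_symbol <- function(gene_ids) {
  sub(" \\(\\d+\\)$", "", gene_ids)
}

.check_unique_ids <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d)) {
    stop("duplicate ", what, "(s): ", paste(utils::head(d, 5L), collapse = ", "))
  }
  invisible(TRUE)
}
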