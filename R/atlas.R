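#' Normalize gene symbols
#'
#' Trims whitespace, uppercases, and optionally resolves aliases through a
#' user-supplied table. No live database queries are performed: alias
#' resolution is fully reproducible from the supplied table. Symbols absent
#' from the alias table are returned in their normalized form and flagged.
#'
#' @param raw Character vector of raw gene identifiers.
#' @param alias_table Optional alias mapping: either a named character vector
#'   (names are aliases, values are approved symbols) or a two-column
#'   data.frame (alias, symbol). Aliases are matched after normalization.
#' @return Character vector of normalized symbols. When `alias_table` is
#'   given, the attribute `"unresolved"` is a logical vector marking inputs
#'   that were not found in the table (returned as-normalized).
#' @examples
#' normalize_symbol(" csf1r ")
#' normalize_symbol("CD115", alias_table = c(CD115 = "CSF1R"))
#' @export
normalize_symbol <- function(raw, alias_table = NULL) {
  if (!is.character(raw)) raw <- as.character(raw)
  norm <- toupper(trimws(raw))
  if (any(is.na(norm) | !nzchar(norm))) {
    bad <- which(is.na(norm) | !nzchar(norm))
    stop_ligrec("empty gene symbol at position(s): ",
                paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (is.null(alias_table)) return(norm)
  if (is.data.frame(alias_table)) {
    map <- stats::setNames(as.character(alias_table[[2L]]),
                           toupper(trimws(as.character(alias_table[[1L]]))))
  } else {
    map <- stats::setNames(as.character(alias_table),
                           toupper(trimws(names(alias_table))))
  }
  hit <- norm %in% names(map)
  out <- norm
  out[hit] <- toupper(trimws(unname(map[norm[hit]])))
  attr(out, "unresolved") <- !hit
  out
}

#' Construct an expression atlas
#'
#' An expression atlas is a genes x cell-types matrix of non-negative TPM
#' values with unique, normalized gene symbols and unique cell-type names.
#' When a replicate map is supplied, per-sample columns are collapsed to the
#' arithmetic mean of each cell type's replicate libraries (a cell type with
#' a single library is its own mean); no re-normalization is applied after
#' averaging.
#'
#' @param tpm Numeric matrix, rows named by gene symbol, columns by
#'   sample or cell-type name.
#' @param replicate_map Optional data.frame with columns `sample` and
#'   `cell_type` mapping every column of `tpm` to a cell type.
#' @param alias_table Optional alias table passed to [normalize_symbol()].
#' @return An object of class `expression_atlas`: the TPM matrix plus the
#'   replicate map used (if any) stored as attribute `"replicate_map"`.
#' @export
expression_atlas <- function(tpm, replicate_map = NULL, alias_table = NULL) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    stop_ligrec("`tpm` must be a numeric matrix")
  }
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop_ligrec("`tpm` must have gene rownames and sample/cell colnames")
  }
  bad <- which(!is.finite(tpm) | tpm < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_ligrec("negative or non-finite TPM at row '", rownames(tpm)[bad[1, 1]],
                "', column '", colnames(tpm)[bad[1, 2]], "'",
                if (nrow(bad) > 1L) paste0(" (and ", nrow(bad) - 1L, " more)"))
  }
  genes <- normalize_symbol(rownames(tpm), alias_table)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop_ligrec("duplicate gene symbols after normalization: ",
                paste(utils::head(dup, 10L), collapse = ", "))
  }
  rownames(tpm) <- as.character(genes)
  if (!is.null(replicate_map)) {
    tpm <- collapse_replicates(tpm, replicate_map)
  }
  if (anyDuplicated(colnames(tpm))) {
    stop_ligrec("duplicate cell-type names: ",
                paste(unique(colnames(tpm)[duplicated(colnames(tpm))]), collapse = ", "))
  }
  structure(tpm, class = c("expression_atlas", "matrix", "array"),
            replicate_map = replicate_map)
}

# mean of replicate columns per cell type; sample order is irrelevant
collapse_replicates <- function(tpm, replicate_map) {
  rm_df <- as.data.frame(replicate_map)
  if (!all(c("sample", "cell_type") %in% names(rm_df))) {
    stop_ligrec("replicate_map needs columns `sample` and `cell_type`")
  }
  missing <- setdiff(colnames(tpm), rm_df$sample)
  if (length(missing) > 0L) {
    stop_ligrec("samples absent from replicate_map: ",
                paste(utils::head(missing, 10L), collapse = ", "))
  }
  rm_df <- rm_df[match(colnames(tpm), rm_df$sample), ]
  cts <- unique(rm_df$cell_type)
  out <- vapply(cts, function(ct) {
    cols <- which(rm_df$cell_type == ct)
    rowMeans(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(tpm),
                                     dimnames = list(rownames(tpm), cts))
  colnames(out) <- cts
  out
}

#' Read an expression atlas from TSV
#'
#' Reads a tab-separated table whose first column holds gene identifiers and
#' whose remaining columns hold per-sample (or per-cell-type) TPM values,
#' in the layout of FANTOM5-style per-gene expression tables. Gene symbols
#' are normalized (trimmed, uppercased, optionally alias-resolved); duplicate
#' symbols after normalization and negative or non-numeric values are errors.
#'
#' @param path Path to the TSV file.
#' @param replicate_map Optional data.frame (`sample`, `cell_type`); when
#'   given, sample columns are collapsed to per-cell-type means.
#' @param alias_table Optional alias table for [normalize_symbol()].
#' @return An [expression_atlas()] object.
#' @export
read_expression_atlas <- function(path, replicate_map = NULL, alias_table = NULL) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop_ligrec("atlas TSV needs a gene column plus >=1 sample column")
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))),
                 arr.ind = TRUE)
    stop_ligrec("non-numeric TPM value at row ", bad[1, 1], ", column '",
                colnames(df)[-1L][bad[1, 2]], "'")
  }
  rownames(mat) <- genes
  expression_atlas(mat, replicate_map = replicate_map, alias_table = alias_table)
}

#' Write an expression atlas to TSV
#'
#' Values are written at 6 significant digits; round-tripping through
#' [read_expression_atlas()] preserves names exactly and values to that
#' precision.
#'
#' @param atlas An `expression_atlas`.
#' @param path Output file path.
#' @param digits Significant digits for TPM values (default 6).
#' @return The path, invisibly.
#' @export
write_expression_atlas <- function(atlas, path, digits = 6L) {
  df <- data.frame(gene = rownames(atlas),
                   signif(unclass(atlas), digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("Expression atlas: ", nrow(x), " genes x ", ncol(x), " cell types\n", sep = "")
  cat("TPM range: [", format(min(x)), ", ", format(max(x)), "]\n", sep = "")
  if (!is.null(attr(x, "replicate_map"))) {
    cat("Collapsed from", nrow(attr(x, "replicate_map")), "replicate libraries\n")
  }
  invisible(x)
}
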