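# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical lineage labels
#'
#' The six broad cell-type lineage classes used throughout the lineage
#' analyses: endothelial, epithelial, haematopoietic, mesenchymal, nervous
#' (system) and other.
#'
#' @return Character vector of the six lineage labels.
#' @export
lineage_levels <- function() {
  c("endothelial", "epithelial", "haematopoietic", "mesenchymal",
    "nervous", "other")
}

#' Canonical subcellular localization classes
#'
#' The seven consensus localization labels: cytoplasm, multiple, nucleus,
#' other, plasma_membrane, secreted and n/a (unclassifiable).
#'
#' @return Character vector of the seven class labels.
#' @export
localization_classes <- function() {
  c("cytoplasm", "multiple", "nucleus", "other", "plasma_membrane",
    "secreted", "n/a")
}

stop_ligrec <- function(...) stop(..., call. = FALSE)

# collapse a character vector into a single ';'-joined field (TSV-safe)
collapse_field <- function(x) {
  x <- unique(x[!is.na(x) & nzchar(x)])
  if (length(x) == 0L) "" else paste(sort(x), collapse = ";")
}

split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
}

# write a data.frame as UTF-8 TSV with header, numerics at 6 significant digits
write_tsv <- function(df, path, digits = 6L) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8", ...)
}
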