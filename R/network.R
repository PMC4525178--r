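#' Threshold an atlas into a detection matrix
#'
#' A gene is called detected in a cell type when its TPM is at or above the
#' threshold. 10 TPM is the conservative default used throughout the
#' downstream analyses (roughly 3 transcript copies per cell in CAGE data);
#' 50 and 100 TPM are the other standard presets. The comparison operator
#' defaults to `>=` and is exposed as configuration.
#'
#' @param atlas An [expression_atlas()].
#' @param threshold Positive TPM threshold.
#' @param op Comparison operator, `">="` (default) or `">"`.
#' @return Logical genes x cell-types matrix with attribute
#'   `"threshold_tpm"`.
#' @export
detect <- function(atlas, threshold = 10, op = c(">=", ">")) {
  op <- match.arg(op)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_ligrec("threshold must be a single positive number")
  }
  m <- if (op == ">=") unclass(atlas) >= threshold else unclass(atlas) > threshold
  structure(m, threshold_tpm = threshold, replicate_map = NULL)
}

# detection row for a gene; genes absent from the matrix are never detected
det_row <- function(det, gene) {
  if (gene %in% rownames(det)) det[gene, ] else
    stats::setNames(rep(FALSE, ncol(det)), colnames(det))
}

warn_missing_genes <- function(det, pairs) {
  genes <- unique(c(pairs$ligand, pairs$receptor))
  missing <- setdiff(genes, rownames(det))
  if (length(missing) > 0L) {
    warning(length(missing), " pair gene(s) absent from the atlas, ",
            "treated as never detected: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ...", call. = FALSE)
  }
  invisible(missing)
}

#' Pairs expressed anywhere in the atlas
#'
#' Keeps the pairs whose ligand is detected in at least one cell type and
#' whose receptor is detected in at least one cell type (not necessarily the
#' same one). Excluded pairs are dropped first; pair genes absent from the
#' atlas are treated as never detected, with a warning.
#'
#' @param pairs A `pair_set`.
#' @param det Detection matrix from [detect()].
#' @return The expressed subset, a `pair_set`.
#' @export
expressed_pairs <- function(pairs, det) {
  act <- active_pairs(pairs)
  warn_missing_genes(det, act)
  any_det <- rowSums(det) > 0L
  gene_ok <- function(g) g %in% rownames(det) && any_det[g]
  keep <- vapply(seq_len(nrow(act)),
                 function(i) gene_ok(act$ligand[i]) && gene_ok(act$receptor[i]),
                 logical(1L))
  out <- act[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pair_set", "data.frame"))
}

#' Per-cell ligand and receptor repertoires
#'
#' Counts, for every cell type, the distinct ligand genes and distinct
#' receptor genes (drawn from the non-excluded pairs) detected in that cell.
#'
#' @inheritParams expressed_pairs
#' @return Data.frame (cell_type, n_ligands, n_receptors).
#' @export
repertoire_counts <- function(det, pairs) {
  act <- active_pairs(pairs)
  ligs <- intersect(unique(act$ligand), rownames(det))
  recs <- intersect(unique(act$receptor), rownames(det))
  data.frame(
    cell_type = colnames(det),
    n_ligands = as.integer(colSums(det[ligs, , drop = FALSE])),
    n_receptors = as.integer(colSums(det[recs, , drop = FALSE])),
    stringsAsFactors = FALSE)
}

#' Autocrine signalling fractions
#'
#' For each cell type: the fraction of its expressed ligands whose cognate
#' receptor (for at least one pair) is also detected on the same cell, and
#' the reciprocal fraction for receptors. Fractions are NA when the cell
#' expresses no ligand (receptor) at all.
#'
#' @inheritParams expressed_pairs
#' @return Data.frame (cell_type, ligand_fraction, receptor_fraction,
#'   n_autocrine_ligands, n_autocrine_receptors).
#' @export
autocrine_fractions <- function(det, pairs) {
  act <- active_pairs(pairs)
  cells <- colnames(det)
  res <- lapply(cells, function(cc) {
    dcol <- det[, cc]
    is_det <- function(g) g %in% rownames(det) && dcol[g]
    el <- unique(act$ligand[vapply(act$ligand, is_det, logical(1L))])
    er <- unique(act$receptor[vapply(act$receptor, is_det, logical(1L))])
    n_al <- sum(vapply(el, function(l) {
      any(vapply(act$receptor[act$ligand == l], is_det, logical(1L)))
    }, logical(1L)))
    n_ar <- sum(vapply(er, function(r) {
      any(vapply(act$ligand[act$receptor == r], is_det, logical(1L)))
    }, logical(1L)))
    data.frame(cell_type = cc,
               ligand_fraction = if (length(el) == 0L) NA_real_ else n_al / length(el),
               receptor_fraction = if (length(er) == 0L) NA_real_ else n_ar / length(er),
               n_autocrine_ligands = n_al, n_autocrine_receptors = n_ar,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Expression breadth and specific/broad quadrants
#'
#' Breadth is the number of cell types in which a gene is detected. Ligand
#' and receptor medians are computed over the genes participating in the
#' supplied (expressed) pairs; a gene is "specific" in its role when its
#' breadth is at or below that role's median (the `<=` tie rule keeps the
#' median gene specific), otherwise "broad". Each pair falls in one of four
#' quadrants (ligand class / receptor class); the returned fractions sum
#' to 1.
#'
#' @param det Detection matrix from [detect()].
#' @param pairs Pairs from [expressed_pairs()].
#' @return List: `breadth` (named integer per gene), `ligand_median`,
#'   `receptor_median`, `pairs` (per-pair quadrant data.frame) and
#'   `quadrant_fractions` (named numeric over the four quadrants).
#' @export
breadth_and_quadrants <- function(det, pairs) {
  act <- active_pairs(pairs)
  if (nrow(act) == 0L) stop_ligrec("no pairs supplied")
  genes <- unique(c(act$ligand, act$receptor))
  breadth <- vapply(genes, function(g) sum(det_row(det, g)), integer(1L))
  lig_med <- stats::median(breadth[unique(act$ligand)])
  rec_med <- stats::median(breadth[unique(act$receptor)])
  lig_specific <- breadth[act$ligand] <= lig_med
  rec_specific <- breadth[act$receptor] <= rec_med
  quadrant <- paste(ifelse(lig_specific, "specific", "broad"),
                    ifelse(rec_specific, "specific", "broad"), sep = "/")
  levels4 <- c("specific/specific", "specific/broad",
               "broad/specific", "broad/broad")
  fr <- as.numeric(table(factor(quadrant, levels = levels4))) / nrow(act)
  list(breadth = breadth,
       ligand_median = lig_med, receptor_median = rec_med,
       pairs = data.frame(ligand = act$ligand, receptor = act$receptor,
                          ligand_breadth = as.integer(breadth[act$ligand]),
                          receptor_breadth = as.integer(breadth[act$receptor]),
                          quadrant = quadrant, stringsAsFactors = FALSE),
       quadrant_fractions = stats::setNames(fr, levels4))
}

#' Cell-by-cell signalling path counts
#'
#' Entry (A, B) counts the pairs whose ligand is detected in cell A and
#' whose receptor is detected in cell B, over all ordered cell-type pairs
#' including A = B (autocrine paths on the diagonal).
#'
#' @inheritParams expressed_pairs
#' @return Integer cells x cells matrix.
#' @export
path_count_matrix <- function(det, pairs) {
  act <- active_pairs(pairs)
  cells <- colnames(det)
  if (nrow(act) == 0L) {
    return(matrix(0L, length(cells), length(cells), dimnames = list(cells, cells)))
  }
  Lp <- matrix(FALSE, nrow(act), length(cells))
  Rp <- matrix(FALSE, nrow(act), length(cells))
  for (i in seq_len(nrow(act))) {
    Lp[i, ] <- det_row(det, act$ligand[i])
    Rp[i, ] <- det_row(det, act$receptor[i])
  }
  m <- crossprod(Lp * 1L, Rp * 1L)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(cells, cells)
  m
}

#' Build weighted cell-to-cell edges
#'
#' For every pair and every ordered (source, target) cell-type combination
#' where the ligand is at or above the threshold in the source cell and the
#' receptor at or above it in the target cell, emits an edge weighted by
#' ligand TPM x receptor TPM. Self-edges (source = target) are genuine
#' autocrine edges and included by default. With `top_n`, edges are ranked
#' by weight (ties broken by ligand, receptor, source cell, target cell,
#' lexicographically) and truncated.
#'
#' @param atlas An [expression_atlas()].
#' @param pairs A `pair_set` (excluded pairs are dropped).
#' @param threshold Positive TPM threshold (default 10).
#' @param top_n Optional number of top-weight edges to keep.
#' @param include_self Keep autocrine self-edges (default TRUE).
#' @return Data.frame of edges (source_cell, target_cell, ligand, receptor,
#'   ligand_tpm, receptor_tpm, weight).
#' @export
build_edges <- function(atlas, pairs, threshold = 10, top_n = NULL,
                        include_self = TRUE) {
  act <- active_pairs(pairs)
  tpm <- unclass(atlas)
  rows <- vector("list", nrow(act))
  for (i in seq_len(nrow(act))) {
    l <- act$ligand[i]; r <- act$receptor[i]
    if (!(l %in% rownames(tpm)) || !(r %in% rownames(tpm))) next
    src <- which(tpm[l, ] >= threshold)
    tgt <- which(tpm[r, ] >= threshold)
    if (length(src) == 0L || length(tgt) == 0L) next
    grid <- expand.grid(s = src, t = tgt, KEEP.OUT.ATTRS = FALSE)
    rows[[i]] <- data.frame(
      source_cell = colnames(tpm)[grid$s], target_cell = colnames(tpm)[grid$t],
      ligand = l, receptor = r,
      ligand_tpm = unname(tpm[l, grid$s]), receptor_tpm = unname(tpm[r, grid$t]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(df)) return(as_edge_df(NULL))
  if (!include_self) df <- df[df$source_cell != df$target_cell, , drop = FALSE]
  df$weight <- df$ligand_tpm * df$receptor_tpm
  ord <- order(-df$weight, df$ligand, df$receptor, df$source_cell, df$target_cell)
  df <- df[ord, , drop = FALSE]
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  rownames(df) <- NULL
  as_edge_df(df)
}

#' Detection-versus-proteome concordance arithmetic
#'
#' Given the genes detected by the transcriptome assay in one cell type and
#' independent support sets (whole-cell proteome, literature reports), the
#' supported fraction is `|detected n (proteome u literature)| / |detected|`.
#' For the false-negative check against a microarray compendium: among
#' proteome-only genes (in the proteome but not detected) that carry a
#' unique array probe, the fraction with detectable array signal; and the
#' same fraction among the detected genes with probes.
#'
#' @param detected Character vector of detected gene symbols (non-empty).
#' @param proteome Character vector of proteome-supported symbols.
#' @param literature Optional character vector of literature-supported
#'   symbols.
#' @param array_probed Optional symbols with unique array probes.
#' @param array_detected Optional symbols detected on the array.
#' @return List with `supported_fraction` (plus numerator/denominator) and,
#'   when array sets are given, `proteome_only_array_fraction` and
#'   `detected_array_fraction` with their counts.
#' @export
detection_concordance <- function(detected, proteome, literature = character(0),
                                  array_probed = NULL, array_detected = NULL) {
  if (length(detected) == 0L) stop_ligrec("empty detected set")
  detected <- unique(detected)
  support <- union(proteome, literature)
  n_sup <- length(intersect(detected, support))
  out <- list(supported_fraction = n_sup / length(detected),
              n_supported = n_sup, n_detected = length(detected))
  if (!is.null(array_probed) && !is.null(array_detected)) {
    proteome_only <- setdiff(proteome, detected)
    po <- intersect(proteome_only, array_probed)
    dd <- intersect(detected, array_probed)
    out$proteome_only_array_fraction <-
      if (length(po) == 0L) NA_real_ else length(intersect(po, array_detected)) / length(po)
    out$n_proteome_only_probed <- length(po)
    out$detected_array_fraction <-
      if (length(dd) == 0L) NA_real_ else length(intersect(dd, array_detected)) / length(dd)
    out$n_detected_probed <- length(dd)
  }
  out
}
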