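#' Read / validate a cell-type to lineage map
#'
#' Every cell type of the atlas must map to exactly one of the six lineage
#' labels (see [lineage_levels()]); unmapped cell types are a hard error.
#'
#' @param x Data.frame with columns `cell_type` and `lineage`, or a named
#'   character vector (names = cell types).
#' @param cell_types Optional character vector of atlas cell types to
#'   validate coverage against.
#' @return Named character vector cell_type -> lineage.
#' @export
lineage_map <- function(x, cell_types = NULL) {
  if (is.data.frame(x)) {
    lm <- stats::setNames(as.character(x$lineage), as.character(x$cell_type))
  } else {
    lm <- x
  }
  bad <- setdiff(unique(lm), lineage_levels())
  if (length(bad) > 0L) {
    stop_ligrec("unknown lineage label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(lm))) {
    stop_ligrec("cell type mapped to more than one lineage: ",
                paste(unique(names(lm)[duplicated(names(lm))]), collapse = ", "))
  }
  if (!is.null(cell_types)) {
    missing <- setdiff(cell_types, names(lm))
    if (length(missing) > 0L) {
      stop_ligrec("cell type(s) missing from lineage map: ",
                  paste(utils::head(missing, 10L), collapse = ", "))
    }
  }
  lm
}

#' Extract major-signalling pairs
#'
#' For each ligand-receptor pair, finds the major transmitter (the cell type
#' with the highest ligand TPM) and the major receiver (the cell type with
#' the highest receptor TPM). Argmax ties are broken by the
#' lexicographically smallest cell-type name, deterministically. Pairs whose
#' ligand or receptor has all-zero expression (or is absent from the atlas)
#' are dropped with a warning.
#'
#' @param atlas An [expression_atlas()].
#' @param pairs A `pair_set`, normally restricted to [expressed_pairs()] at
#'   the working threshold.
#' @return Data.frame (ligand, receptor, max_transmitter, max_receiver,
#'   ligand_tpm, receptor_tpm).
#' @export
major_pairs <- function(atlas, pairs) {
  act <- active_pairs(pairs)
  tpm <- unclass(atlas)
  cells <- colnames(tpm)
  ord <- order(cells)  # ties -> lexicographically smallest name
  argmax_cell <- function(g) {
    if (!(g %in% rownames(tpm))) return(NULL)
    v <- tpm[g, ord]
    if (max(v) <= 0) return(NULL)
    i <- which.max(v)
    list(cell = cells[ord][i], tpm = unname(v[i]))
  }
  rows <- vector("list", nrow(act))
  dropped <- 0L
  for (i in seq_len(nrow(act))) {
    ml <- argmax_cell(act$ligand[i])
    mr <- argmax_cell(act$receptor[i])
    if (is.null(ml) || is.null(mr)) { dropped <- dropped + 1L; next }
    rows[[i]] <- data.frame(ligand = act$ligand[i], receptor = act$receptor[i],
                            max_transmitter = ml$cell, max_receiver = mr$cell,
                            ligand_tpm = ml$tpm, receptor_tpm = mr$tpm,
                            stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    warning(dropped, " pair(s) dropped: ligand or receptor undetectable ",
            "(all-zero or absent from atlas)", call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(ligand = character(0), receptor = character(0),
                      max_transmitter = character(0), max_receiver = character(0),
                      ligand_tpm = numeric(0), receptor_tpm = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Lineage-by-lineage tally of major-signalling pairs
#'
#' Cross-tabulates major-signalling pairs by the lineage of their major
#' transmitter (rows) and major receiver (columns). The total over all 36
#' cells equals the number of pairs.
#'
#' @param mp Data.frame from [major_pairs()].
#' @param lm Lineage map from [lineage_map()].
#' @return 6x6 integer matrix over the lineage labels.
#' @export
lineage_matrix <- function(mp, lm) {
  cells_used <- unique(c(mp$max_transmitter, mp$max_receiver))
  lm <- lineage_map(lm, cell_types = cells_used)
  levs <- lineage_levels()
  tl <- factor(unname(lm[mp$max_transmitter]), levels = levs)
  rl <- factor(unname(lm[mp$max_receiver]), levels = levs)
  m <- table(transmitter = tl, receiver = rl)
  m <- matrix(as.integer(m), 6L, 6L, dimnames = list(levs, levs))
  m
}

bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# two-sided exact binomial p with safe handling of degenerate nulls
binom_p2 <- function(x, n, p0) {
  if (p0 <= 0) {
    if (x > 0) stop_ligrec("degenerate null: p0 = 0 with observed count > 0")
    return(1)
  }
  if (p0 >= 1) return(if (x == n) 1 else 0)
  stats::binom.test(x, n, p = p0, alternative = "two.sided")$p.value
}

#' Lineage over/under-representation of max-expression
#'
#' Tests, per lineage and per role (ligand / receptor), whether pairs reach
#' their maximum ligand (receptor) expression in that lineage more or less
#' often than expected from the lineage's share of cell types. For lineage
#' l and role ligand: x = number of pairs whose major transmitter lies in l,
#' n = number of pairs, null probability p0 = (number of cell types in l) /
#' (total cell types). Two-sided exact binomial test;
#' Benjamini-Hochberg adjustment across the 12 lineage x role tests
#' (one family); direction over/under reported separately.
#'
#' @param mp Data.frame from [major_pairs()].
#' @param lm Lineage map.
#' @param n_cells_per_lineage Named integer vector of cell-type counts per
#'   lineage; derived from `lm` when NULL.
#' @return Data.frame (lineage, role, x, n, p0, p, q, direction).
#' @export
lineage_representation_test <- function(mp, lm, n_cells_per_lineage = NULL) {
  lm <- lineage_map(lm)
  if (is.null(n_cells_per_lineage)) {
    tb <- table(factor(unname(lm), levels = lineage_levels()))
    n_cells_per_lineage <- stats::setNames(as.integer(tb), names(tb))
  }
  total_cells <- sum(n_cells_per_lineage)
  if (total_cells <= 0L) stop_ligrec("total cell count must be > 0")
  n <- nrow(mp)
  rows <- list()
  for (role in c("ligand", "receptor")) {
    max_cell <- if (role == "ligand") mp$max_transmitter else mp$max_receiver
    lin <- unname(lm[max_cell])
    for (l in lineage_levels()) {
      x <- sum(lin == l)
      p0 <- unname(n_cells_per_lineage[l]) / total_cells
      p0 <- if (is.na(p0)) 0 else p0
      p <- if (n == 0L) 1 else binom_p2(x, n, p0)
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = l, role = role, x = x, n = n, p0 = p0, p = p,
        direction = if (n > 0L && x / n > p0) "over" else if (n > 0L && x / n < p0) "under" else "none",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[c("lineage", "role", "x", "n", "p0", "p", "q", "direction")]
  rownames(out) <- NULL
  out
}

#' Intra/inter-lineage path bias
#'
#' Tests, for each ordered lineage pair (A, B), whether major-signalling
#' pairs flow from A to B more or less often than expected given the
#' marginal distributions of max-transmitters and max-receivers (ignoring
#' how many cell types each lineage contains): x = count(A, B), n = total
#' pairs, p0 = rowsum(A)/n x colsum(B)/n. Two-sided exact binomial tests
#' with Benjamini-Hochberg adjustment across the 36 cells (one family).
#'
#' The default plug-in p0 (marginals estimated from the same matrix) makes
#' the exact binomial somewhat conservative, as with standardized residuals
#' in contingency tables; supplying a fixed `null_p0` matrix tests against
#' known null probabilities instead, and `n_perm` switches to a
#' marginal-preserving permutation test (receiver labels permuted against
#' transmitter labels) whose p-values are calibrated by construction.
#'
#' @param lmtx 6x6 lineage matrix from [lineage_matrix()].
#' @param null_p0 Optional fixed matrix of null probabilities (same
#'   dimnames as `lmtx`); defaults to the product of the observed
#'   marginals.
#' @param n_perm When non-NULL, number of permutations for the permutation
#'   variant.
#' @return Data.frame (from, to, x, n, p0, p, q, direction).
#' @export
path_bias_test <- function(lmtx, null_p0 = NULL, n_perm = NULL) {
  n <- sum(lmtx)
  if (n < 1L) stop_ligrec("empty lineage matrix")
  rowm <- rowSums(lmtx) / n
  colm <- colSums(lmtx) / n
  perm_exceed <- NULL
  if (!is.null(n_perm)) {
    tx <- rep(rownames(lmtx), rowSums(lmtx))
    rx <- rep(colnames(lmtx), colSums(lmtx))
    e_mat <- outer(rowm, colm) * n
    obs_dev <- abs(lmtx - e_mat)
    perm_exceed <- matrix(0L, nrow(lmtx), ncol(lmtx), dimnames = dimnames(lmtx))
    for (b in seq_len(n_perm)) {
      pm <- table(factor(tx, levels = rownames(lmtx)),
                  factor(sample(rx), levels = colnames(lmtx)))
      perm_exceed <- perm_exceed + (abs(pm - e_mat) >= obs_dev - 1e-9)
    }
  }
  rows <- list()
  for (a in rownames(lmtx)) for (b in colnames(lmtx)) {
    x <- lmtx[a, b]
    p0 <- if (is.null(null_p0)) rowm[a] * colm[b] else null_p0[a, b]
    p <- if (is.null(n_perm)) binom_p2(x, n, p0) else
      (1 + perm_exceed[a, b]) / (1 + n_perm)
    rows[[length(rows) + 1L]] <- data.frame(
      from = a, to = b, x = as.integer(x), n = n, p0 = unname(p0), p = p,
      direction = if (x / n > p0) "over" else if (x / n < p0) "under" else "none",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[c("from", "to", "x", "n", "p0", "p", "q", "direction")]
  rownames(out) <- NULL
  out
}

#' Export gene lists for external enrichment analysis
#'
#' Foreground: the ligands and receptors of major-signalling pairs on the
#' lineage edge A -> B. Background: all ligands and receptors in the
#' expressed pair set. Intended for GO/domain enrichment in external tools.
#'
#' @param mp Data.frame from [major_pairs()].
#' @param lm Lineage map.
#' @param from_lineage,to_lineage Lineage labels for the edge of interest.
#' @param out_dir Optional directory; when given, writes
#'   `foreground_<A>_to_<B>.txt` and `background.txt` (one symbol per line).
#' @return List with character vectors `foreground` and `background`.
#' @export
export_lineage_gene_lists <- function(mp, lm, from_lineage, to_lineage,
                                      out_dir = NULL) {
  lm <- lineage_map(lm)
  tl <- unname(lm[mp$max_transmitter])
  rl <- unname(lm[mp$max_receiver])
  on_edge <- !is.na(tl) & !is.na(rl) & tl == from_lineage & rl == to_lineage
  fg <- sort(unique(c(mp$ligand[on_edge], mp$receptor[on_edge])))
  bg <- sort(unique(c(mp$ligand, mp$receptor)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(fg, file.path(out_dir, paste0("foreground_", from_lineage,
                                             "_to_", to_lineage, ".txt")))
    writeLines(bg, file.path(out_dir, "background.txt"))
  }
  list(foreground = fg, background = bg)
}
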