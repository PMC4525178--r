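# Brute-force oracles and tiny fixture builders, independent of the
# implementation paths they check.

rand_atlas <- function(n_genes, n_cells, seed, max_tpm = 200) {
  set.seed(seed)
  m <- matrix(round(runif(n_genes * n_cells, 0, max_tpm), 2),
              n_genes, n_cells,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("cell_%02d", seq_len(n_cells))))
  # sprinkle zeros so detection is non-trivial
  m[runif(length(m)) < 0.3] <- 0
  expression_atlas(m)
}

rand_pairs <- function(n_pairs, genes, seed) {
  set.seed(seed)
  half <- length(genes) %/% 2L
  ligs <- genes[seq_len(half)]
  recs <- genes[-seq_len(half)]
  df <- unique(data.frame(ligand = sample(ligs, n_pairs, replace = TRUE),
                          receptor = sample(recs, n_pairs, replace = TRUE),
                          stringsAsFactors = FALSE))
  df$status <- "putative"; df$sources <- "sim"; df$pmids <- ""; df$inferred <- FALSE
  structure(df, class = c("pair_set", "data.frame"))
}

# triple-loop path counts: (A, B) -> number of pairs with ligand in A, receptor in B
oracle_path_counts <- function(det, pairs) {
  cells <- colnames(det)
  has <- function(g, cc) g %in% rownames(det) && det[g, cc]
  m <- matrix(0L, length(cells), length(cells), dimnames = list(cells, cells))
  for (a in cells) for (b in cells) {
    cnt <- 0L
    for (i in seq_len(nrow(pairs))) {
      if (has(pairs$ligand[i], a) && has(pairs$receptor[i], b)) cnt <- cnt + 1L
    }
    m[a, b] <- cnt
  }
  m
}

oracle_expressed <- function(det, pairs) {
  keep <- logical(nrow(pairs))
  anywhere <- function(g) g %in% rownames(det) && any(det[g, ])
  for (i in seq_len(nrow(pairs))) {
    keep[i] <- anywhere(pairs$ligand[i]) && anywhere(pairs$receptor[i])
  }
  keep
}

oracle_repertoire <- function(det, pairs, cell) {
  has <- function(g) g %in% rownames(det) && det[g, cell]
  c(n_ligands = length(unique(pairs$ligand[vapply(pairs$ligand, has, TRUE)])),
    n_receptors = length(unique(pairs$receptor[vapply(pairs$receptor, has, TRUE)])))
}

oracle_autocrine <- function(det, pairs, cell) {
  has <- function(g) g %in% rownames(det) && det[g, cell]
  el <- unique(pairs$ligand[vapply(pairs$ligand, has, TRUE)])
  er <- unique(pairs$receptor[vapply(pairs$receptor, has, TRUE)])
  nl <- sum(vapply(el, function(l)
    any(vapply(pairs$receptor[pairs$ligand == l], has, TRUE)), TRUE))
  nr <- sum(vapply(er, function(r)
    any(vapply(pairs$ligand[pairs$receptor == r], has, TRUE)), TRUE))
  c(lig = if (length(el)) nl / length(el) else NA_real_,
    rec = if (length(er)) nr / length(er) else NA_real_)
}

# one-sided binomial tail by direct summation
oracle_binom_tail_ge <- function(x, n, p0) {
  sum(vapply(x:n, function(k)
    choose(n, k) * p0^k * (1 - p0)^(n - k), numeric(1)))
}

# Mann-Whitney U by pairwise comparison count
oracle_u_stat <- function(a, b) {
  u <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    u <- u + (a[i] > b[j]) + 0.5 * (a[i] == b[j])
  }
  u
}

rand_edges <- function(n, seed) {
  set.seed(seed)
  lt <- round(runif(n, 10, 500), 2)
  rt <- round(runif(n, 10, 500), 2)
  data.frame(
    source_cell = sample(paste0("cell", 1:6), n, replace = TRUE),
    target_cell = sample(paste0("cell", 1:6), n, replace = TRUE),
    ligand = sample(paste0("L", 1:8), n, replace = TRUE),
    receptor = sample(paste0("R", 1:8), n, replace = TRUE),
    ligand_tpm = lt, receptor_tpm = rt, weight = lt * rt,
    stringsAsFactors = FALSE)
}

edge_multiset <- function(df) {
  key <- do.call(paste, c(df[c("source_cell", "target_cell", "ligand", "receptor")],
                          lapply(df[c("ligand_tpm", "receptor_tpm", "weight")],
                                 function(v) format(v, digits = 10)),
                          sep = "|"))
  sort(key)
}

toy_lineage_map <- function(n_per = 2L) {
  cells <- unlist(lapply(lineage_levels(), function(l) paste0(l, "_", seq_len(n_per))))
  setNames(rep(lineage_levels(), each = n_per), cells)
}
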