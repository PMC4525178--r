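# Synthetic input generators. Every generator is a pure function of the
# configuration: the RNG state is seeded from cfg$seed (plus a fixed
# per-generator offset) and restored afterwards, so identical configs give
# bit-identical outputs regardless of call order.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic pipeline inputs: a
#' scaled-down atlas of 24 cell types (4 per lineage) x 300 genes with
#' heavy-tailed (log-normal) TPM values, 120 planted ligand-receptor pairs,
#' lineage-restricted expression blocks, and tunable evolutionary-age
#' parameters.
#'
#' @param seed Integer RNG seed.
#' @param cells_per_lineage Named integer vector of cell types per lineage.
#' @param n_housekeeping,n_restricted Gene counts for broadly expressed and
#'   lineage-restricted genes.
#' @param n_pairs Number of planted ligand-receptor pairs.
#' @param frac_reference Fraction of known pairs given a PMID (reference
#'   status).
#' @param frac_novel Fraction of planted pairs withheld from the known-pair
#'   sources (recoverable only through PPI evidence).
#' @param lineage_bias_frac Fraction of pairs whose ligand and receptor are
#'   restricted to `biased_lineage` (the planted lineage bias).
#' @param biased_lineage Home lineage of the biased pairs.
#' @param tpm_meanlog,tpm_sdlog Log-scale location/scale of baseline TPM.
#' @param tpm_noise_sdlog Log-scale multiplicative measurement noise.
#' @param dropout_rate Probability that a restricted gene is exactly zero
#'   outside its home lineage.
#' @param lineage_block_effect Fold-change of restricted genes in their home
#'   lineage.
#' @param receptor_older_excess Excess probability epsilon in \[0, 0.5\] that
#'   the ligand is younger than its receptor given untied ages
#'   (P = 0.5 + epsilon).
#' @param younger_shorter_prob Planted probability that, in a
#'   length-discordant PPI pair, the younger protein is the shorter one.
#' @param tie_prob Probability that a pair's partners share a phylostratum.
#' @param n_decoy_ppi Decoy PPI rows among non-candidate proteins.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       cells_per_lineage = c(endothelial = 4L, epithelial = 4L,
                                             haematopoietic = 4L, mesenchymal = 4L,
                                             nervous = 4L, other = 4L),
                       n_housekeeping = 180L, n_restricted = 120L,
                       n_pairs = 120L, frac_reference = 0.7, frac_novel = 0.25,
                       lineage_bias_frac = 0.5, biased_lineage = "haematopoietic",
                       tpm_meanlog = log(30), tpm_sdlog = 1.2,
                       tpm_noise_sdlog = 0.5, dropout_rate = 0.9,
                       lineage_block_effect = 10,
                       receptor_older_excess = 0.25,
                       younger_shorter_prob = 0.591, tie_prob = 0.15,
                       n_decoy_ppi = 60L) {
  probs <- c(frac_reference = frac_reference, frac_novel = frac_novel,
             lineage_bias_frac = lineage_bias_frac, dropout_rate = dropout_rate,
             younger_shorter_prob = younger_shorter_prob, tie_prob = tie_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_ligrec("probabilities must lie in [0, 1]: ",
                paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (receptor_older_excess < 0 || receptor_older_excess > 0.5) {
    stop_ligrec("receptor_older_excess must lie in [0, 0.5]")
  }
  counts <- c(n_housekeeping, n_restricted, n_pairs, n_decoy_ppi,
              cells_per_lineage)
  if (any(counts < 0)) stop_ligrec("counts must be >= 0")
  if (!all(names(cells_per_lineage) %in% lineage_levels())) {
    stop_ligrec("cells_per_lineage names must be lineage labels")
  }
  structure(as.list(environment())[c(
    "seed", "cells_per_lineage", "n_housekeeping", "n_restricted", "n_pairs",
    "frac_reference", "frac_novel", "lineage_bias_frac", "biased_lineage",
    "tpm_meanlog", "tpm_sdlog", "tpm_noise_sdlog", "dropout_rate",
    "lineage_block_effect", "receptor_older_excess", "younger_shorter_prob",
    "tie_prob", "n_decoy_ppi")], class = "sim_config")
}

#' Simulate a lineage-blocked expression atlas
#'
#' Housekeeping genes draw from one log-normal across all cell types (with
#' multiplicative log-normal noise). Lineage-restricted genes are elevated
#' by `lineage_block_effect` in their home lineage and, outside it, are
#' zero with probability `dropout_rate` (otherwise at baseline).
#'
#' @param cfg A [sim_config()].
#' @return List: `atlas` (an [expression_atlas()]), `lineage_map` (named
#'   vector), `truth` (data.frame gene, type, home_lineage).
#' @export
simulate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cpl <- cfg$cells_per_lineage[cfg$cells_per_lineage > 0L]
  if (sum(cpl) == 0L) stop_ligrec("configuration has zero cells")
  with_seed(cfg$seed + 11L, {
    cells <- unlist(lapply(names(cpl), function(l) {
      paste0(l, "_", seq_len(cpl[[l]]))
    }))
    lmap <- stats::setNames(rep(names(cpl), unname(cpl)), cells)
    hk <- sprintf("HK%04d", seq_len(cfg$n_housekeeping))
    rg <- sprintf("RG%04d", seq_len(cfg$n_restricted))
    home <- rep(names(cpl), length.out = cfg$n_restricted)
    noise <- function(n) exp(stats::rnorm(n, 0, cfg$tpm_noise_sdlog))
    tpm <- matrix(0, cfg$n_housekeeping + cfg$n_restricted, length(cells),
                  dimnames = list(c(hk, rg), cells))
    base_hk <- stats::rlnorm(cfg$n_housekeeping, cfg$tpm_meanlog, cfg$tpm_sdlog)
    for (j in seq_along(cells)) {
      tpm[hk, j] <- base_hk * noise(cfg$n_housekeeping)
    }
    base_rg <- stats::rlnorm(cfg$n_restricted, cfg$tpm_meanlog, cfg$tpm_sdlog)
    for (i in seq_along(rg)) {
      at_home <- lmap[cells] == home[i]
      v <- numeric(length(cells))
      v[at_home] <- base_rg[i] * cfg$lineage_block_effect * noise(sum(at_home))
      n_away <- sum(!at_home)
      keep <- stats::runif(n_away) >= cfg$dropout_rate
      v[!at_home] <- ifelse(keep, base_rg[i] * noise(n_away), 0)
      tpm[rg[i], ] <- v
    }
    list(atlas = expression_atlas(tpm),
         lineage_map = lmap,
         truth = data.frame(gene = c(hk, rg),
                            type = rep(c("housekeeping", "restricted"),
                                       c(cfg$n_housekeeping, cfg$n_restricted)),
                            home_lineage = c(rep(NA_character_, cfg$n_housekeeping),
                                             home),
                            stringsAsFactors = FALSE))
  })
}

# split a gene vector into ligand-pool / receptor-pool halves
split_pool <- function(genes) {
  h <- ceiling(length(genes) / 2L)
  list(lig = genes[seq_len(h)], rec = genes[-seq_len(h)])
}

#' Simulate known-pair sources and PPI evidence
#'
#' Plants `n_pairs` true ligand-receptor pairs over the atlas genes. A
#' fraction `lineage_bias_frac` draws both partners from genes restricted
#' to `biased_lineage` (the planted lineage bias); the rest draw from the
#' remaining genes. Ligand and receptor pools are disjoint, so no self
#' pairs or swapped-role conflicts arise. Known pairs are spread over three
#' overlapping mock sources; a fraction `frac_novel` is withheld from all
#' sources and instead given qualifying PPI support (HPRD-style evidence
#' types or STRING-style channels with confidence >= 700), so that PPI
#' inference recovers exactly the withheld pairs. Decoy PPI rows connect
#' dedicated non-candidate proteins, with STRING-style scores drawn
#' uniformly around the 700 boundary.
#'
#' @param cfg A [sim_config()].
#' @param atlas_truth The `truth` data.frame from [simulate_atlas()].
#' @return List: `sources` (list of known-pair sources for [merge_known()]),
#'   `ppi` (data.frame), `truth_pairs` (ligand, receptor, novel, biased),
#'   `gene_roles` (gene, role in ligand_pool/receptor_pool/none).
#' @export
simulate_pairs_and_ppi <- function(cfg, atlas_truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(atlas_truth) < 2L) stop_ligrec("need at least 2 genes")
  with_seed(cfg$seed + 22L, {
    biased_genes <- atlas_truth$gene[atlas_truth$type == "restricted" &
                                       atlas_truth$home_lineage == cfg$biased_lineage]
    other_genes <- setdiff(atlas_truth$gene, biased_genes)
    bp <- split_pool(biased_genes)
    op <- split_pool(other_genes)

    n_biased <- round(cfg$n_pairs * cfg$lineage_bias_frac)
    if (length(biased_genes) < 2L) n_biased <- 0L
    sample_pairs <- function(ligs, recs, k) {
      if (k == 0L) return(NULL)
      seen <- character(0)
      out <- list()
      guard <- 0L
      while (length(out) < k && guard < 50L * k) {
        guard <- guard + 1L
        l <- sample(ligs, 1L); r <- sample(recs, 1L)
        key <- pair_key(l, r)
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- data.frame(ligand = l, receptor = r,
                                              stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    truth <- rbind(
      if (n_biased > 0L) cbind(sample_pairs(bp$lig, bp$rec, n_biased), biased = TRUE),
      cbind(sample_pairs(op$lig, op$rec, cfg$n_pairs - n_biased), biased = FALSE))
    truth$novel <- stats::runif(nrow(truth)) < cfg$frac_novel

    known <- truth[!truth$novel, , drop = FALSE]
    src_names <- c("mockDLRP", "mockIUPHAR", "mockHPMR")
    membership <- matrix(stats::runif(nrow(known) * 3L) < 0.6, ncol = 3L)
    none <- rowSums(membership) == 0L
    membership[cbind(which(none), sample.int(3L, sum(none), replace = TRUE))] <- TRUE
    has_pmid <- stats::runif(nrow(known)) < cfg$frac_reference
    pmids <- ifelse(has_pmid, sprintf("PMID%06d", seq_len(nrow(known))), NA_character_)
    sources <- lapply(seq_along(src_names), function(s) {
      idx <- which(membership[, s])
      list(source_name = src_names[s],
           pairs = data.frame(ligand = known$ligand[idx],
                              receptor = known$receptor[idx],
                              pmid = ifelse(s == 1L, pmids[idx], NA_character_),
                              stringsAsFactors = FALSE))
    })

    novel <- truth[truth$novel, , drop = FALSE]
    ppi_rows <- list()
    if (nrow(novel) > 0L) {
      for (i in seq_len(nrow(novel))) {
        if (i %% 2L == 1L) {
          ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
            protein_a = novel$ligand[i], protein_b = novel$receptor[i],
            source = "hprd_like",
            evidence_type = sample(c("in_vitro", "in_vivo", "yeast2hybrid"), 1L),
            confidence = NA_real_, stringsAsFactors = FALSE)
        } else {
          ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
            protein_a = novel$receptor[i], protein_b = novel$ligand[i],
            source = "string_like",
            evidence_type = sample(c("physical_binding", "experimental"), 1L),
            confidence = round(stats::runif(1L, 700, 950)),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (cfg$n_decoy_ppi > 0L) {
      decoys <- sprintf("DECOY%03d", seq_len(max(10L, cfg$n_decoy_ppi %/% 3L)))
      for (i in seq_len(cfg$n_decoy_ppi)) {
        ab <- sample(decoys, 2L)
        ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
          protein_a = ab[1L], protein_b = ab[2L],
          source = "string_like",
          evidence_type = sample(c("physical_binding", "experimental"), 1L),
          confidence = round(stats::runif(1L, 650, 750)),
          stringsAsFactors = FALSE)
      }
    }
    ppi <- if (length(ppi_rows) > 0L) do.call(rbind, ppi_rows) else
      data.frame(protein_a = character(0), protein_b = character(0),
                 source = character(0), evidence_type = character(0),
                 confidence = numeric(0), stringsAsFactors = FALSE)

    roles <- data.frame(gene = atlas_truth$gene,
                        role = "none", stringsAsFactors = FALSE)
    roles$role[roles$gene %in% c(bp$lig, op$lig)] <- "ligand_pool"
    roles$role[roles$gene %in% c(bp$rec, op$rec)] <- "receptor_pool"
    rownames(truth) <- NULL
    list(sources = sources, ppi = ppi,
         truth_pairs = truth[c("ligand", "receptor", "novel", "biased")],
         gene_roles = roles)
  })
}

#' Simulate localization evidence consistent with planted roles
#'
#' Ligand-pool genes are given secreted evidence and receptor-pool genes
#' plasma-membrane evidence (with plausible TMH counts), spread over
#' annotation tiers; remaining genes receive nucleus or cytoplasm
#' annotations. This makes [build_candidates()] place the planted pools in
#' the candidate ligand/receptor sets.
#'
#' @param cfg A [sim_config()].
#' @param gene_roles `gene_roles` data.frame from [simulate_pairs_and_ppi()].
#' @return Localization evidence data.frame for [classify_localization()].
#' @export
simulate_localization_evidence <- function(cfg, gene_roles) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 33L, {
    n <- nrow(gene_roles)
    ev <- data.frame(symbol = gene_roles$gene,
                     uniprot_class = NA_character_, hprd_class = NA_character_,
                     hprd_pmid = NA_character_, predicted_class = NA_character_,
                     tmh_count = 0L, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      role <- gene_roles$role[i]
      u <- stats::runif(1L)
      if (role == "ligand_pool") {
        if (u < 0.5) ev$uniprot_class[i] <- "secreted"
        else { ev$predicted_class[i] <- "secreted"; ev$tmh_count[i] <- sample(0:1, 1L) }
      } else if (role == "receptor_pool") {
        ev$tmh_count[i] <- sample(1:7, 1L)
        if (u < 0.4) ev$uniprot_class[i] <- "plasma_membrane"
        else if (u < 0.7) { ev$hprd_class[i] <- "plasma_membrane"
                            ev$hprd_pmid[i] <- sprintf("PMID%06d", 900000L + i) }
        else ev$predicted_class[i] <- "plasma_membrane"
      } else {
        cls <- sample(c("nucleus", "cytoplasm"), 1L)
        if (u < 0.6) ev$uniprot_class[i] <- cls else ev$predicted_class[i] <- cls
      }
    }
    ev
  })
}

#' Simulate phylostratum ages and protein lengths for pairs
#'
#' Receptor strata are drawn first (ranks 5-15 on a 1-20 scale, larger =
#' younger); ligand strata tie with probability `tie_prob` and otherwise
#' are younger with probability `0.5 + receptor_older_excess`. Each gene
#' receives a single age: for ligands appearing in several pairs the first
#' pair drives the draw, so the planted probability is exact only when
#' genes are not reused across pairs. Ligand lengths are drawn around a
#' median of 267 aa and receptor lengths around 515 aa (log-normal),
#' mirroring the shorter-ligand/longer-receptor asymmetry of curated pairs.
#'
#' @param cfg A [sim_config()].
#' @param pairs Data.frame with `ligand`, `receptor` columns (the planted
#'   truth pairs, or any pair table).
#' @param extra_genes Optional additional symbols to age (background genes).
#' @return List: `ages` (named rank vector), `lengths` (named aa vector),
#'   `age_table` (symbol, phylostratum, mya), `length_table` (symbol,
#'   length_aa).
#' @export
simulate_ages_lengths <- function(cfg, pairs, extra_genes = character(0)) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 44L, {
    p_younger <- 0.5 + cfg$receptor_older_excess
    recs <- unique(pairs$receptor)
    ages <- stats::setNames(sample(5:15, length(recs), replace = TRUE), recs)
    ligs <- unique(pairs$ligand)
    for (g in ligs) {
      first <- which(pairs$ligand == g)[1L]
      r_age <- ages[[pairs$receptor[first]]]
      u <- stats::runif(1L)
      ages[[g]] <- if (u < cfg$tie_prob) r_age
      else if (u < cfg$tie_prob + (1 - cfg$tie_prob) * p_younger) {
        r_age + sample(1:4, 1L)
      } else r_age - sample(1:4, 1L)
    }
    bg <- setdiff(extra_genes, names(ages))
    if (length(bg) > 0L) {
      ages <- c(ages, stats::setNames(sample(1:20, length(bg), replace = TRUE), bg))
    }
    lengths <- c(
      stats::setNames(round(stats::rlnorm(length(ligs), log(267), 0.5)), ligs),
      stats::setNames(round(stats::rlnorm(length(setdiff(recs, ligs)), log(515), 0.5)),
                      setdiff(recs, ligs)))
    if (length(bg) > 0L) {
      lengths <- c(lengths,
                   stats::setNames(round(stats::rlnorm(length(bg), log(400), 0.6)), bg))
    }
    lengths[lengths < 1] <- 1
    list(ages = ages, lengths = lengths,
         age_table = data.frame(symbol = names(ages),
                                phylostratum = as.integer(unname(ages)),
                                mya = (21L - as.integer(unname(ages))) * 50,
                                stringsAsFactors = FALSE),
         length_table = data.frame(symbol = names(lengths),
                                   length_aa = as.integer(unname(lengths)),
                                   stringsAsFactors = FALSE))
  })
}

#' Simulate a length-discordant PPI set with planted younger-shorter bias
#'
#' Generates a protein universe with log-normal lengths, then samples PPI
#' pairs joining one lower-quartile protein to one upper-quartile protein
#' (without reusing proteins), and assigns phylostratum ranks so that the
#' younger partner is the shorter one with probability
#' `cfg$younger_shorter_prob`. Supports parameter-recovery checks of
#' [length_bias_null()].
#'
#' @param cfg A [sim_config()].
#' @param n_ppi Number of PPI pairs (default 2000).
#' @return List: `ppi` (protein_a, protein_b, source, evidence_type,
#'   confidence), `lengths`, `ages` (named vectors over the universe),
#'   `q_planted`.
#' @export
simulate_length_bias_ppi <- function(cfg, n_ppi = 2000L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 55L, {
    n_univ <- 8L * n_ppi
    univ <- sprintf("PR%06d", seq_len(n_univ))
    lens <- stats::setNames(round(stats::rlnorm(n_univ, log(400), 0.6)), univ)
    lens[lens < 1] <- 1
    q <- stats::quantile(lens, c(0.25, 0.75), names = FALSE)
    shorts <- sample(univ[lens <= q[1]], n_ppi)
    longs <- sample(univ[lens >= q[2]], n_ppi)
    base <- sample(5:15, n_ppi, replace = TRUE)
    d <- sample(1:4, n_ppi, replace = TRUE)
    shorter_younger <- stats::runif(n_ppi) < cfg$younger_shorter_prob
    ages <- stats::setNames(rep(NA_real_, n_univ), univ)
    ages[shorts] <- ifelse(shorter_younger, base + d, base - d)
    ages[longs] <- base
    rest <- is.na(ages)
    ages[rest] <- sample(1:20, sum(rest), replace = TRUE)
    ppi <- data.frame(protein_a = shorts, protein_b = longs,
                      source = "hprd_like", evidence_type = "in_vitro",
                      confidence = NA_real_, stringsAsFactors = FALSE)
    list(ppi = ppi, lengths = lens, ages = ages,
         q_planted = cfg$younger_shorter_prob)
  })
}

#' Write a full synthetic input bundle to disk
#'
#' Runs every generator and writes the TSV tables the pipeline consumes
#' (atlas, lineage map, per-source known pairs, PPI table, localization
#' evidence, age and length tables) plus a `truth.json` with the planted
#' structure.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
simulate_inputs <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atl <- simulate_atlas(cfg)
  pp <- simulate_pairs_and_ppi(cfg, atl$truth)
  loc_ev <- simulate_localization_evidence(cfg, pp$gene_roles)
  al <- simulate_ages_lengths(cfg, pp$truth_pairs,
                              extra_genes = atl$truth$gene)
  paths <- list()
  paths$atlas <- file.path(out_dir, "atlas.tsv")
  write_expression_atlas(atl$atlas, paths$atlas)
  paths$lineage_map <- file.path(out_dir, "lineage_map.tsv")
  write_tsv(data.frame(cell_type = names(atl$lineage_map),
                       lineage = unname(atl$lineage_map)), paths$lineage_map)
  for (src in pp$sources) {
    p <- file.path(out_dir, paste0("pairs_", src$source_name, ".tsv"))
    write_tsv(src$pairs, p)
    paths[[paste0("pairs_", src$source_name)]] <- p
  }
  paths$ppi <- file.path(out_dir, "ppi.tsv")
  write_tsv(pp$ppi, paths$ppi)
  paths$localization <- file.path(out_dir, "localization_evidence.tsv")
  write_tsv(loc_ev, paths$localization)
  paths$ages <- file.path(out_dir, "ages.tsv")
  write_tsv(al$age_table, paths$ages)
  paths$lengths <- file.path(out_dir, "lengths.tsv")
  write_tsv(al$length_table, paths$lengths)
  paths$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(config = unclass(cfg),
                            truth_pairs = pp$truth_pairs,
                            gene_truth = atl$truth),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
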