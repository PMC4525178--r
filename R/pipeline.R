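read_input_bundle <- function(dir) {
  path <- function(f) file.path(dir, f)
  need <- c("atlas.tsv", "lineage_map.tsv", "ppi.tsv",
            "localization_evidence.tsv", "ages.tsv", "lengths.tsv")
  missing <- need[!file.exists(path(need))]
  if (length(missing) > 0L) {
    stop_ligrec("input stage failed: missing file(s) in ", dir, ": ",
                paste(missing, collapse = ", "))
  }
  src_files <- list.files(dir, pattern = "^pairs_.*\\.tsv$", full.names = TRUE)
  if (length(src_files) == 0L) {
    stop_ligrec("input stage failed: no pairs_<source>.tsv files in ", dir)
  }
  lmap_df <- read_tsv(path("lineage_map.tsv"))
  list(
    atlas = read_expression_atlas(path("atlas.tsv")),
    lineage_map = lineage_map(lmap_df),
    sources = lapply(src_files, function(f) {
      list(source_name = sub("^pairs_(.*)\\.tsv$", "\\1", basename(f)),
           pairs = read_tsv(f))
    }),
    ppi = read_tsv(path("ppi.tsv")),
    localization = read_tsv(path("localization_evidence.tsv")),
    ages = local({
      at <- read_tsv(path("ages.tsv"))
      stats::setNames(as.numeric(at$phylostratum), at$symbol)
    }),
    lengths = local({
      lt <- read_tsv(path("lengths.tsv"))
      stats::setNames(as.numeric(lt$length_aa), lt$symbol)
    }),
    curation = if (file.exists(path("curation.tsv"))) read_tsv(path("curation.tsv")) else NULL,
    orphan_ligands = if (file.exists(path("orphan_ligands.txt")))
      readLines(path("orphan_ligands.txt")) else character(0),
    orphan_receptors = if (file.exists(path("orphan_receptors.txt")))
      readLines(path("orphan_receptors.txt")) else character(0)
  )
}

#' Run the full cell-to-cell signalling pipeline
#'
#' Executes the five analysis stages in order — localization consensus,
#' pair assembly, expression network, lineage analysis, evolutionary
#' statistics — on either a synthetic-input configuration (a
#' [sim_config()]; inputs are generated in memory) or a directory of input
#' tables in the layout written by [simulate_inputs()]. Re-running with
#' identical inputs and configuration reproduces every output bit for bit.
#'
#' @param inputs A [sim_config()] or a directory path.
#' @param out_dir Optional output directory; when given, stage outputs
#'   (pair set, edges, repertoires, path-count matrix, lineage matrix, test
#'   tables) and a config/version snapshot are written as TSV/JSON.
#' @param threshold_tpm Detection threshold in TPM (default 10).
#' @param top_n Optional cap on exported edges (ranked by weight).
#' @param fdr_alpha FDR level recorded in the report (default 0.05).
#' @return A run report: per-stage record counts plus the main result
#'   objects, invisibly classed as `ligrec_report`.
#' @export
run_all <- function(inputs, out_dir = NULL, threshold_tpm = 10,
                    top_n = NULL, fdr_alpha = 0.05) {
  if (inherits(inputs, "sim_config")) {
    atl <- simulate_atlas(inputs)
    pp <- simulate_pairs_and_ppi(inputs, atl$truth)
    al <- simulate_ages_lengths(inputs, pp$truth_pairs,
                                extra_genes = atl$truth$gene)
    bundle <- list(atlas = atl$atlas, lineage_map = atl$lineage_map,
                   sources = pp$sources, ppi = pp$ppi,
                   localization = simulate_localization_evidence(inputs, pp$gene_roles),
                   ages = al$ages, lengths = al$lengths,
                   curation = NULL,
                   orphan_ligands = character(0),
                   orphan_receptors = character(0))
  } else if (is.character(inputs) && length(inputs) == 1L && dir.exists(inputs)) {
    bundle <- read_input_bundle(inputs)
  } else {
    stop_ligrec("`inputs` must be a sim_config or an input directory")
  }

  # stage 1: localization
  loc <- classify_localization(bundle$localization)
  # stage 2: pair assembly
  known <- merge_known(bundle$sources)
  cand <- build_candidates(known, bundle$orphan_ligands,
                           bundle$orphan_receptors, loc)
  inferred <- infer_from_ppi(cand, bundle$ppi)
  pairs <- apply_curation(known, inferred, bundle$curation)
  # stage 3: expression network
  det <- detect(bundle$atlas, threshold_tpm)
  ep <- suppressWarnings(expressed_pairs(pairs, det))
  if (nrow(ep) == 0L) stop_ligrec("network stage failed: no expressed pairs")
  rep_counts <- repertoire_counts(det, ep)
  auto <- autocrine_fractions(det, ep)
  quads <- breadth_and_quadrants(det, ep)
  paths_m <- path_count_matrix(det, ep)
  edges <- build_edges(bundle$atlas, ep, threshold = threshold_tpm, top_n = top_n)
  # stage 4: lineage analysis
  mp <- suppressWarnings(major_pairs(bundle$atlas, ep))
  lmtx <- lineage_matrix(mp, bundle$lineage_map)
  rep_test <- lineage_representation_test(mp, bundle$lineage_map)
  bias_test <- path_bias_test(lmtx)
  # stage 5: evolutionary statistics
  tally <- age_pair_tally(ep, bundle$ages)
  lbn <- tryCatch(length_bias_null(bundle$ppi, bundle$lengths, bundle$ages),
                  error = function(e) NULL)
  rft <- if (!is.null(lbn) &&
             tally$n_ligand_younger + tally$n_ligand_older > 0L) {
    receptor_first_test(tally, p0 = lbn$p0)
  } else NULL

  report <- structure(list(
    counts = c(localized = nrow(loc), known_pairs = nrow(known),
               inferred_pairs = nrow(inferred), final_pairs = nrow(pairs),
               excluded_pairs = sum(pairs$status == "excluded"),
               expressed_pairs = nrow(ep), edges = nrow(edges),
               major_pairs = nrow(mp)),
    threshold_tpm = threshold_tpm, fdr_alpha = fdr_alpha,
    localization = loc, pairs = pairs, expressed_pairs = ep,
    repertoires = rep_counts, autocrine = auto, quadrants = quads,
    path_counts = paths_m, edges = edges, major_pairs = mp,
    lineage_matrix = lmtx, representation_test = rep_test,
    path_bias_test = bias_test, age_tally = tally,
    length_bias_null = lbn, receptor_first = rft), class = "ligrec_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(loc, file.path(out_dir, "localization.tsv"))
    write_pair_set(pairs, file.path(out_dir, "pairs.tsv"))
    write_tsv(rep_counts, file.path(out_dir, "repertoires.tsv"))
    write_tsv(auto, file.path(out_dir, "autocrine.tsv"))
    write_tsv(quads$pairs, file.path(out_dir, "quadrants.tsv"))
    utils::write.table(paths_m, file.path(out_dir, "path_counts.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    write_edge_list(edges, file.path(out_dir, "edges.tsv"), "tsv")
    write_tsv(mp, file.path(out_dir, "major_pairs.tsv"))
    utils::write.table(lmtx, file.path(out_dir, "lineage_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    write_tsv(rep_test, file.path(out_dir, "lineage_representation_test.tsv"))
    write_tsv(bias_test, file.path(out_dir, "lineage_path_bias_test.tsv"))
    snapshot <- list(threshold_tpm = threshold_tpm, top_n = top_n,
                     fdr_alpha = fdr_alpha,
                     package_version = as.character(utils::packageVersion("ligrecnet")),
                     inputs = if (inherits(inputs, "sim_config")) unclass(inputs) else inputs)
    jsonlite::write_json(snapshot, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' @export
print.ligrec_report <- function(x, ...) {
  cat("Cell-to-cell signalling pipeline report (threshold ",
      x$threshold_tpm, " TPM)\n", sep = "")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %d\n", nm, x$counts[[nm]]))
  }
  if (!is.null(x$receptor_first)) {
    cat("  receptor-before-ligand: estimate ",
        format(x$receptor_first$estimate, digits = 3), " vs p0 ",
        format(x$receptor_first$p0, digits = 3), " (p = ",
        format(x$receptor_first$p_value, digits = 3), ")\n", sep = "")
  }
  invisible(x)
}
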