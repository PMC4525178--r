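pair_key <- function(l, r) paste(l, r, sep = "\x1f")

new_pair_set <- function(df) {
  need <- c("ligand", "receptor", "status", "sources", "pmids", "inferred")
  for (col in setdiff(need, names(df))) {
    df[[col]] <- if (col == "inferred") logical(nrow(df)) else character(nrow(df))
  }
  df <- df[need]
  if (anyDuplicated(pair_key(df$ligand, df$receptor))) {
    stop_ligrec("duplicate (ligand, receptor) pairs in pair set")
  }
  structure(df, class = c("pair_set", "data.frame"))
}

#' @export
print.pair_set <- function(x, ...) {
  cat("Ligand-receptor pair set: ", nrow(x), " pairs (",
      sum(x$status == "reference"), " reference, ",
      sum(x$status == "putative"), " putative, ",
      sum(x$status == "excluded"), " excluded)\n", sep = "")
  invisible(x)
}

#' Pairs usable by downstream network modules
#'
#' Drops pairs with status "excluded"; excluded pairs are retained in the
#' pair set for provenance but must never reach the expression-network or
#' lineage modules.
#'
#' @param pairs A `pair_set`.
#' @return The non-excluded subset, still a `pair_set`.
#' @export
active_pairs <- function(pairs) {
  out <- pairs[pairs$status != "excluded", , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pair_set", "data.frame"))
}

#' Merge known ligand-receptor pair sources
#'
#' Unions directed (ligand, receptor) pairs from several curated databases
#' into one non-redundant set with per-pair provenance (contributing source
#' names, PubMed IDs). Roles are directional: the same unordered gene pair
#' appearing with swapped ligand/receptor roles across sources is a
#' conflict and raises an error listing the offenders.
#'
#' @param sources List of sources; each source is a list with elements
#'   `source_name` (string) and `pairs` (data.frame with columns `ligand`,
#'   `receptor` and optionally `pmid`).
#' @param alias_table Optional alias table for [normalize_symbol()].
#' @return A `pair_set` data.frame (ligand, receptor, status, sources,
#'   pmids, inferred); status is "reference" when a PMID is attached,
#'   otherwise "putative".
#' @export
merge_known <- function(sources, alias_table = NULL) {
  if (length(sources) < 1L) stop_ligrec("need at least one pair source")
  rows <- lapply(sources, function(src) {
    p <- as.data.frame(src$pairs, stringsAsFactors = FALSE)
    data.frame(ligand = normalize_symbol(p$ligand, alias_table),
               receptor = normalize_symbol(p$receptor, alias_table),
               source = src$source_name,
               pmid = if ("pmid" %in% names(p)) as.character(p$pmid) else NA_character_,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  keys <- unique(pair_key(all$ligand, all$receptor))
  kl <- sub("\x1f.*$", "", keys)
  kr <- sub("^.*\x1f", "", keys)
  swapped <- keys[pair_key(kr, kl) %in% keys & kl != kr]
  if (length(swapped) > 0L) {
    labs <- unique(gsub("\x1f", " <-> ", swapped))
    stop_ligrec("ligand/receptor roles conflict across sources for: ",
                paste(utils::head(labs, 10L), collapse = ", "))
  }
  key <- pair_key(all$ligand, all$receptor)
  agg <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    data.frame(ligand = all$ligand[idx[1L]], receptor = all$receptor[idx[1L]],
               sources = collapse_field(all$source[idx]),
               pmids = collapse_field(all$pmid[idx]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, agg)
  df <- df[order(df$ligand, df$receptor), ]
  rownames(df) <- NULL
  df$status <- ifelse(nzchar(df$pmids), "reference", "putative")
  df$inferred <- FALSE
  new_pair_set(df)
}

#' Build candidate ligand and receptor sets
#'
#' Expands the known interacting ligands/receptors with orphan lists and
#' with localization-based candidates: secreted proteins not found among the
#' known receptors become putative ligands, and plasma-membrane proteins not
#' found among the known ligands become putative receptors.
#'
#' @param known A `pair_set` of known pairs.
#' @param orphan_ligands,orphan_receptors Character vectors of orphan
#'   symbols (may be empty).
#' @param loc Localization records from [classify_localization()].
#' @return List with character vectors `putative_ligands` and
#'   `putative_receptors`.
#' @export
build_candidates <- function(known, orphan_ligands = character(0),
                             orphan_receptors = character(0), loc) {
  act <- active_pairs(known)
  known_l <- unique(act$ligand)
  known_r <- unique(act$receptor)
  secreted <- unique(loc$symbol[loc$class == "secreted"])
  pm <- unique(loc$symbol[loc$class == "plasma_membrane"])
  list(
    putative_ligands = sort(unique(c(known_l, normalize_symbol_safe(orphan_ligands),
                                     setdiff(secreted, known_r)))),
    putative_receptors = sort(unique(c(known_r, normalize_symbol_safe(orphan_receptors),
                                       setdiff(pm, known_l))))
  )
}

normalize_symbol_safe <- function(x) {
  if (length(x) == 0L) character(0) else normalize_symbol(x)
}

#' Infer novel ligand-receptor pairs from PPI evidence
#'
#' A protein-protein interaction supports the directed pair (L, R) when its
#' endpoints are {L, R}, L is a candidate ligand, R is a candidate receptor,
#' and the evidence qualifies: HPRD-style sources need evidence type
#' in vitro, in vivo or yeast 2-hybrid; STRING-style sources need a
#' physical-binding or experimental channel with confidence score at or
#' above `min_string_score` (the two channels are evaluated independently).
#' Endpoint order in the PPI table is ignored (undirected evidence for a
#' directed pair). Self-pairs (L equal to R) are dropped unless
#' `allow_self = TRUE`.
#'
#' @param candidates List with `putative_ligands` and `putative_receptors`
#'   (see [build_candidates()]).
#' @param ppi Data.frame with columns `protein_a`, `protein_b`, `source`
#'   ("hprd_like" or "string_like"), `evidence_type`, `confidence` (integer,
#'   required for string_like rows).
#' @param min_string_score Minimum STRING-style confidence, inclusive
#'   (default 700).
#' @param allow_self Keep pairs with identical ligand and receptor symbol?
#' @return Data.frame (ligand, receptor, evidence) with one row per
#'   deduplicated inferred pair; `evidence` collapses the supporting
#'   source:evidence_type records.
#' @export
infer_from_ppi <- function(candidates, ppi, min_string_score = 700L,
                           allow_self = FALSE) {
  if (min_string_score < 0L) stop_ligrec("min_string_score must be >= 0")
  ppi <- as.data.frame(ppi, stringsAsFactors = FALSE)
  if (nrow(ppi) == 0L) {
    return(data.frame(ligand = character(0), receptor = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  a <- normalize_symbol(ppi$protein_a)
  b <- normalize_symbol(ppi$protein_b)
  conf <- if ("confidence" %in% names(ppi)) suppressWarnings(as.numeric(ppi$confidence)) else rep(NA_real_, nrow(ppi))
  ok <- (ppi$source == "hprd_like" &
           ppi$evidence_type %in% c("in_vitro", "in_vivo", "yeast2hybrid")) |
        (ppi$source == "string_like" &
           ppi$evidence_type %in% c("physical_binding", "experimental") &
           !is.na(conf) & conf >= min_string_score)
  idx <- which(ok)
  lig <- candidates$putative_ligands
  rec <- candidates$putative_receptors
  hits <- list()
  for (i in idx) {
    ev <- paste0(ppi$source[i], ":", ppi$evidence_type[i])
    for (orient in list(c(a[i], b[i]), c(b[i], a[i]))) {
      L <- orient[1L]; R <- orient[2L]
      if (!allow_self && L == R) next
      if (L %in% lig && R %in% rec) {
        hits[[length(hits) + 1L]] <- data.frame(ligand = L, receptor = R,
                                                evidence = ev,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(ligand = character(0), receptor = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, hits)
  key <- pair_key(all$ligand, all$receptor)
  agg <- lapply(split(seq_len(nrow(all)), key), function(ii) {
    data.frame(ligand = all$ligand[ii[1L]], receptor = all$receptor[ii[1L]],
               evidence = collapse_field(all$evidence[ii]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$ligand, out$receptor), ]
  rownames(out) <- NULL
  out
}

#' Apply the manual curation table
#'
#' Combines known pairs, PPI-inferred pairs and curation decisions into the
#' final pair set: `(known U inferred U curation-adds) - curation-excludes`.
#' Excluded pairs are retained with status "excluded" (and the curation
#' verdict recorded in `sources`) but are dropped by [active_pairs()] before
#' any network computation. A non-excluded pair is "reference" when at least
#' one PMID is attached, otherwise "putative".
#'
#' @param merged A `pair_set` of known pairs (see [merge_known()]).
#' @param inferred Data.frame from [infer_from_ppi()] (or NULL).
#' @param curation Data.frame with columns `ligand`, `receptor`, `verdict`
#'   ("keep", "exclude" or "add") and `pmid` (optional; NA when none).
#' @return The final `pair_set`.
#' @export
apply_curation <- function(merged, inferred = NULL, curation = NULL) {
  df <- as.data.frame(merged, stringsAsFactors = FALSE)
  if (!is.null(inferred) && nrow(inferred) > 0L) {
    key_known <- pair_key(df$ligand, df$receptor)
    key_inf <- pair_key(inferred$ligand, inferred$receptor)
    new <- !(key_inf %in% key_known)
    if (any(new)) {
      add <- data.frame(ligand = inferred$ligand[new],
                        receptor = inferred$receptor[new],
                        status = "putative",
                        sources = paste0("ppi(", inferred$evidence[new], ")"),
                        pmids = "", inferred = TRUE, stringsAsFactors = FALSE)
      df <- rbind(df, add)
    }
    hit <- match(key_known, key_inf)
    for (j in which(!is.na(hit))) {
      df$sources[j] <- collapse_field(c(split_field(df$sources[j]),
                                        paste0("ppi(", inferred$evidence[hit[j]], ")")))
    }
  }
  if (!is.null(curation) && nrow(curation) > 0L) {
    cur <- as.data.frame(curation, stringsAsFactors = FALSE)
    bad <- setdiff(unique(cur$verdict), c("keep", "exclude", "add"))
    if (length(bad) > 0L) {
      stop_ligrec("unknown curation verdict(s): ", paste(bad, collapse = ", "))
    }
    cur$ligand <- normalize_symbol(cur$ligand)
    cur$receptor <- normalize_symbol(cur$receptor)
    if (!"pmid" %in% names(cur)) cur$pmid <- NA_character_
    for (i in seq_len(nrow(cur))) {
      k <- pair_key(cur$ligand[i], cur$receptor[i])
      j <- match(k, pair_key(df$ligand, df$receptor))
      v <- cur$verdict[i]
      if (v == "add") {
        if (is.na(j)) {
          df <- rbind(df, data.frame(ligand = cur$ligand[i], receptor = cur$receptor[i],
                                     status = "putative", sources = "curation",
                                     pmids = collapse_field(cur$pmid[i]),
                                     inferred = FALSE, stringsAsFactors = FALSE))
        } else {
          df$pmids[j] <- collapse_field(c(split_field(df$pmids[j]), cur$pmid[i]))
          df$sources[j] <- collapse_field(c(split_field(df$sources[j]), "curation"))
        }
      } else if (v == "keep") {
        if (!is.na(j)) {
          df$pmids[j] <- collapse_field(c(split_field(df$pmids[j]), cur$pmid[i]))
        }
      } else { # exclude
        if (!is.na(j)) {
          df$status[j] <- "excluded"
          df$sources[j] <- collapse_field(c(split_field(df$sources[j]), "curation_excluded"))
        } else {
          df <- rbind(df, data.frame(ligand = cur$ligand[i], receptor = cur$receptor[i],
                                     status = "excluded", sources = "curation_excluded",
                                     pmids = collapse_field(cur$pmid[i]),
                                     inferred = FALSE, stringsAsFactors = FALSE))
        }
      }
    }
  }
  keep <- df$status != "excluded"
  df$status[keep] <- ifelse(nzchar(df$pmids[keep]), "reference", "putative")
  df <- df[order(df$ligand, df$receptor), ]
  rownames(df) <- NULL
  new_pair_set(df)
}

#' Write / read a pair set as TSV
#'
#' Columns: ligand, receptor, status, sources, pmids, inferred — the shape
#' of a curated pair supplementary table.
#'
#' @param pairs A `pair_set`.
#' @param path File path.
#' @return `write_pair_set` returns the path invisibly; `read_pair_set`
#'   returns a `pair_set`.
#' @export
write_pair_set <- function(pairs, path) {
  write_tsv(as.data.frame(pairs), path)
}

#' @rdname write_pair_set
#' @export
read_pair_set <- function(path) {
  df <- read_tsv(path, colClasses = c(rep("character", 5), "logical"))
  new_pair_set(df)
}
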