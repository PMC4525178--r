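#' Default compartment synonym map
#'
#' Maps raw annotation/prediction compartment strings (lowercased) onto the
#' four core compartments used by the consensus rules. Any compartment that
#' maps outside {cytoplasm, nucleus, plasma_membrane, secreted} is classed
#' as "other". Users can extend or replace this table.
#'
#' @return Named character vector: names are raw (lowercase) compartment
#'   strings, values are canonical class labels.
#' @export
default_compartment_map <- function() {
  c(
    "cytoplasm" = "cytoplasm", "cytosol" = "cytoplasm", "cytoplasmic" = "cytoplasm",
    "nucleus" = "nucleus", "nuclear" = "nucleus", "nucleolus" = "nucleus",
    "plasma_membrane" = "plasma_membrane", "plasma membrane" = "plasma_membrane",
    "cell membrane" = "plasma_membrane", "pm" = "plasma_membrane",
    "secreted" = "secreted", "extracellular" = "secreted",
    "extracellular space" = "secreted", "extracellular region" = "secreted"
  )
}

CORE_COMPARTMENTS <- c("cytoplasm", "nucleus", "plasma_membrane", "secreted")

canon_tokens <- function(x, compartment_map) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  toks <- tolower(trimws(strsplit(x, ";", fixed = TRUE)[[1L]]))
  toks <- toks[nzchar(toks)]
  mapped <- ifelse(toks %in% names(compartment_map),
                   unname(compartment_map[toks]),
                   ifelse(toks %in% CORE_COMPARTMENTS, toks, "other"))
  unique(mapped)
}

has_pmid <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  !is.na(x) & nzchar(trimws(as.character(x)))
}

#' Tiered consensus subcellular localization
#'
#' Assigns each protein one of seven localization classes (cytoplasm,
#' multiple, nucleus, other, plasma_membrane, secreted, n/a) from annotation
#' and prediction evidence, by precedence:
#'
#' * **Tier 1, UniProt-style annotation**: experimentally verified or
#'   probable compartments are accepted directly, with no transmembrane-helix
#'   (TMH) constraint. Two or more distinct compartments give class
#'   "multiple".
#' * **Tier 1, HPRD-style annotation** (used only when no UniProt-style class
#'   exists): accepted when backed by a PubMed ID. A plasma-membrane
#'   annotation from this source additionally requires at least one
#'   predicted TMH; without it the record falls through to Tier 2.
#' * **Tier 2, computational prediction**: the predicted class is accepted,
#'   except plasma_membrane requires `tmh_count >= 1` and secreted requires
#'   `tmh_count <= 1`; records failing these checks are unclassifiable
#'   ("n/a", no tier).
#'
#' @param evidence Data.frame with columns `symbol`, `uniprot_class`,
#'   `hprd_class`, `hprd_pmid`, `predicted_class`, `tmh_count`. Class fields
#'   may hold several compartments separated by ";"; absent evidence is NA
#'   or "".
#' @param compartment_map Synonym table, see [default_compartment_map()].
#' @return Data.frame with columns `symbol`, `class`, `tier` (1, 2 or NA)
#'   and `rationale` (machine-readable rule id).
#' @examples
#' ev <- data.frame(symbol = "X", uniprot_class = "nucleus", hprd_class = NA,
#'                  hprd_pmid = NA, predicted_class = NA, tmh_count = 3)
#' classify_localization(ev)
#' @export
classify_localization <- function(evidence, compartment_map = default_compartment_map()) {
  ev <- as.data.frame(evidence, stringsAsFactors = FALSE)
  need <- c("symbol", "uniprot_class", "hprd_class", "hprd_pmid",
            "predicted_class", "tmh_count")
  for (col in setdiff(need, names(ev))) ev[[col]] <- NA
  tmh <- ifelse(is.na(ev$tmh_count), 0L, as.integer(ev$tmh_count))
  if (any(tmh < 0L)) stop_ligrec("tmh_count must be >= 0")

  n <- nrow(ev)
  cls <- character(n); tier <- rep(NA_integer_, n); why <- character(n)
  for (i in seq_len(n)) {
    up <- canon_tokens(as.character(ev$uniprot_class[i]), compartment_map)
    if (length(up) > 0L) {
      cls[i] <- if (length(up) >= 2L) "multiple" else up
      tier[i] <- 1L; why[i] <- "uniprot_tier1"
      next
    }
    hp <- character(0)
    if (has_pmid(ev$hprd_pmid[i])) {
      hp <- canon_tokens(as.character(ev$hprd_class[i]), compartment_map)
      pm_dropped <- "plasma_membrane" %in% hp && tmh[i] < 1L
      if (pm_dropped) hp <- setdiff(hp, "plasma_membrane")
      if (length(hp) > 0L) {
        cls[i] <- if (length(hp) >= 2L) "multiple" else hp
        tier[i] <- 1L
        why[i] <- if (pm_dropped) "hprd_tier1_pm_dropped" else "hprd_tier1"
        next
      }
    }
    pr <- canon_tokens(as.character(ev$predicted_class[i]), compartment_map)
    if (length(pr) == 0L) {
      cls[i] <- "n/a"; why[i] <- "no_evidence"
      next
    }
    if (length(pr) >= 2L) {
      cls[i] <- "multiple"; tier[i] <- 2L; why[i] <- "predicted_tier2"
    } else if (pr == "plasma_membrane" && tmh[i] < 1L) {
      cls[i] <- "n/a"; why[i] <- "predicted_pm_no_tmh"
    } else if (pr == "secreted" && tmh[i] > 1L) {
      cls[i] <- "n/a"; why[i] <- "predicted_secreted_tmh_gt1"
    } else {
      cls[i] <- pr; tier[i] <- 2L; why[i] <- "predicted_tier2"
    }
  }
  data.frame(symbol = normalize_symbol(as.character(ev$symbol)),
             class = cls, tier = tier, rationale = why,
             stringsAsFactors = FALSE)
}

#' Tally localization classes
#'
#' @param records Data.frame as returned by [classify_localization()].
#' @return Named integer vector over the seven class labels; sums to
#'   `nrow(records)`.
#' @export
class_counts <- function(records) {
  labs <- localization_classes()
  out <- stats::setNames(integer(length(labs)), labs)
  if (nrow(records) > 0L) {
    tb <- table(factor(records$class, levels = labs))
    out[] <- as.integer(tb)
  }
  out
}
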