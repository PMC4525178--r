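#' Tally ligand vs receptor phylostratigraphic ages
#'
#' Cross-tabulates pairs by the phylostratum rank of the ligand and of the
#' receptor. The rank convention is larger = more recent origin (younger);
#' "ligand younger" means the ligand's rank exceeds the receptor's. Pairs
#' with either age missing are dropped and counted.
#'
#' @param pairs A `pair_set` or data.frame with `ligand`, `receptor`
#'   columns (excluded pairs are dropped when present).
#' @param ages Named numeric vector: gene symbol -> phylostratum rank.
#' @return Object of class `age_pair_tally`: list with the count `matrix`
#'   (ligand stratum x receptor stratum), `n_same`, `n_ligand_younger`,
#'   `n_ligand_older` and `n_dropped`.
#' @export
age_pair_tally <- function(pairs, ages) {
  df <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if ("status" %in% names(df)) df <- df[df$status != "excluded", , drop = FALSE]
  al <- unname(ages[df$ligand])
  ar <- unname(ages[df$receptor])
  keep <- !is.na(al) & !is.na(ar)
  n_dropped <- sum(!keep)
  al <- al[keep]; ar <- ar[keep]
  strata <- if (length(al) > 0L) seq(min(c(al, ar)), max(c(al, ar))) else integer(0)
  m <- table(factor(al, levels = strata), factor(ar, levels = strata))
  m <- matrix(as.integer(m), length(strata), length(strata),
              dimnames = list(ligand = strata, receptor = strata))
  structure(list(matrix = m,
                 n_same = sum(al == ar),
                 n_ligand_younger = sum(al > ar),
                 n_ligand_older = sum(al < ar),
                 n_dropped = n_dropped),
            class = "age_pair_tally")
}

#' @export
print.age_pair_tally <- function(x, ...) {
  cat("Age pair tally: ", x$n_same, " same stratum, ",
      x$n_ligand_younger, " ligand younger, ",
      x$n_ligand_older, " ligand older",
      if (x$n_dropped > 0L) paste0(" (", x$n_dropped, " dropped, missing age)"),
      "\n", sep = "")
  invisible(x)
}

#' Length-bias null probability from PPI data
#'
#' Gene-age estimates are biased by protein length, so the null for the
#' receptor-before-ligand test is calibrated on generic interacting protein
#' pairs of discordant length: restrict the PPI set to pairs where one
#' endpoint lies in the lower quartile of all protein lengths and the other
#' in the upper quartile (boundary values belong to the quartile), exclude
#' age ties, and estimate p0 as the fraction of such pairs in which the
#' younger protein is the shorter one.
#'
#' @param ppi Data.frame with `protein_a`, `protein_b` columns.
#' @param lengths Named numeric vector: symbol -> length in amino acids,
#'   over all proteins in the length table (quartiles are taken over this
#'   whole vector).
#' @param ages Named numeric vector: symbol -> phylostratum rank (larger =
#'   younger).
#' @return List (class `length_bias_null`): `p0`, `x` (younger-is-shorter
#'   count), `n` (qualifying pairs), `q_lower`, `q_upper` (the length cuts).
#' @export
length_bias_null <- function(ppi, lengths, ages) {
  q <- stats::quantile(lengths, probs = c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  a <- as.character(ppi$protein_a); b <- as.character(ppi$protein_b)
  la <- unname(lengths[a]); lb <- unname(lengths[b])
  ga <- unname(ages[a]); gb <- unname(ages[b])
  ok <- !is.na(la) & !is.na(lb) & !is.na(ga) & !is.na(gb)
  discordant <- ok & ((la <= q[1] & lb >= q[2]) | (lb <= q[1] & la >= q[2])) & la != lb
  use <- discordant & ga != gb
  n <- sum(use)
  if (n == 0L) stop_ligrec("no qualifying length-discordant, age-untied PPI pairs")
  shorter_is_a <- la[use] < lb[use]
  younger_is_a <- ga[use] > gb[use]
  x <- sum(shorter_is_a == younger_is_a)
  structure(list(p0 = x / n, x = x, n = n, q_lower = q[1], q_upper = q[2]),
            class = "length_bias_null")
}

#' @export
print.length_bias_null <- function(x, ...) {
  cat("Length-bias null: p0 = ", format(x$p0, digits = 4), " (", x$x, "/", x$n,
      " younger-is-shorter)\n", sep = "")
  invisible(x)
}

#' Receptor-before-ligand binomial test
#'
#' Tests whether ligands are younger than their cognate receptors more
#' often than the length-bias null predicts. Successes x are the pairs with
#' a younger ligand, trials n the pairs with strictly different ages
#' (same-stratum pairs excluded). One-sided exact binomial test of
#' proportion > p0, with the one-sided 95% exact (Clopper-Pearson) lower
#' confidence bound of x/n.
#'
#' @param tally An [age_pair_tally()] result, or NULL when `x`/`n` are
#'   given directly.
#' @param p0 Null success probability in (0, 1), typically from
#'   [length_bias_null()].
#' @param x,n Optional explicit success/trial counts (override `tally`).
#' @param conf_level One-sided confidence level (default 0.95).
#' @return Object of class `bias_test`: list with `x`, `n`, `p0`,
#'   `estimate` (x/n), `p_value` and `ci_lower`.
#' @examples
#' receptor_first_test(p0 = 0.591, x = 1082, n = 1513)
#' @export
receptor_first_test <- function(tally = NULL, p0, x = NULL, n = NULL,
                                conf_level = 0.95) {
  if (is.null(x) || is.null(n)) {
    if (is.null(tally)) stop_ligrec("supply either `tally` or `x` and `n`")
    x <- tally$n_ligand_younger
    n <- tally$n_ligand_younger + tally$n_ligand_older
  }
  if (n == 0L) stop_ligrec("no pairs with strictly different ages (n = 0)")
  if (!(p0 > 0 && p0 < 1)) stop_ligrec("p0 must lie strictly in (0, 1)")
  bt <- stats::binom.test(x, n, p = p0, alternative = "greater",
                          conf.level = conf_level)
  structure(list(x = x, n = n, p0 = p0, estimate = x / n,
                 p_value = bt$p.value, ci_lower = bt$conf.int[1L],
                 conf_level = conf_level),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat("Receptor-before-ligand binomial test\n")
  cat("  ligand-younger pairs: ", x$x, " of ", x$n,
      " (estimate ", format(x$estimate, digits = 4), ")\n", sep = "")
  cat("  null p0 = ", format(x$p0, digits = 4),
      ", one-sided p = ", format(x$p_value, digits = 3), "\n", sep = "")
  cat("  one-sided ", format(100 * x$conf_level), "% CI: [",
      format(round(x$ci_lower, 3), nsmall = 3), ", 1]\n", sep = "")
  invisible(x)
}

#' Compare a metric across localization classes
#'
#' Pairwise two-sided Mann-Whitney U tests of a per-gene metric (cell-type
#' specificity, age in mya, ...) between subcellular localization classes,
#' with Benjamini-Hochberg adjustment over all class pairs and per-class
#' summaries. By default the five classes cytoplasm, nucleus, other,
#' plasma_membrane and secreted are compared; "multiple" and "n/a" only on
#' request. Classes with fewer than 2 members are skipped with a warning.
#'
#' @param values Named numeric vector: gene symbol -> metric value.
#' @param classes Named character vector: gene symbol -> localization class.
#' @param metric_name Label for the metric (cosmetic).
#' @param include Classes to compare.
#' @return List: `tests` (class_a, class_b, U, p, q), `summary` (class, n,
#'   mean, median), `metric`.
#' @export
class_comparison <- function(values, classes, metric_name = "metric",
                             include = c("cytoplasm", "nucleus", "other",
                                         "plasma_membrane", "secreted")) {
  genes <- intersect(names(values), names(classes))
  cl <- classes[genes]; v <- values[genes]
  keep_cl <- character(0)
  for (k in include) {
    if (sum(cl == k & !is.na(v)) >= 2L) keep_cl <- c(keep_cl, k)
    else warning("class '", k, "' has fewer than 2 members; skipped", call. = FALSE)
  }
  if (length(keep_cl) < 2L) stop_ligrec("need at least 2 classes with >= 2 members")
  combs <- utils::combn(keep_cl, 2L)
  tests <- lapply(seq_len(ncol(combs)), function(j) {
    a <- combs[1L, j]; b <- combs[2L, j]
    va <- v[cl == a & !is.na(v)]; vb <- v[cl == b & !is.na(v)]
    wt <- suppressWarnings(stats::wilcox.test(va, vb, alternative = "two.sided"))
    data.frame(class_a = a, class_b = b, U = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  tests$q <- bh_adjust(tests$p)
  summ <- do.call(rbind, lapply(keep_cl, function(k) {
    vk <- v[cl == k & !is.na(v)]
    data.frame(class = k, n = length(vk), mean = mean(vk),
               median = stats::median(vk), stringsAsFactors = FALSE)
  }))
  list(tests = tests, summary = summ, metric = metric_name)
}

#' Cell-type specificity score
#'
#' The default linear score is `1 - breadth / n_cells` on a detection row:
#' 1 means detected in exactly one cell type, 0 in all. The entropy option
#' scores a nonnegative expression vector as `1 - H(p)/log(n)` where p are
#' the expression shares; both scores are monotone decreasing in how evenly
#' or broadly a gene is expressed.
#'
#' @param x Logical detection vector (method "linear") or nonnegative
#'   numeric expression vector (method "entropy"); or a matrix of such rows.
#' @param method "linear" (default) or "entropy".
#' @return Score(s) in \[0, 1\] (NA for an all-zero row).
#' @export
specificity_score <- function(x, method = c("linear", "entropy")) {
  method <- match.arg(method)
  if (is.matrix(x)) {
    return(apply(x, 1L, specificity_score, method = method))
  }
  n <- length(x)
  if (n < 1L) stop_ligrec("need at least one cell")
  if (method == "linear") {
    return(1 - sum(as.logical(x)) / n)
  }
  s <- sum(x)
  if (s <= 0) return(NA_real_)
  p <- x[x > 0] / s
  h <- -sum(p * log(p))
  if (n == 1L) return(1)
  1 - h / log(n)
}
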