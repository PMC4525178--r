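src <- function(name, l, r, pmid = NULL) {
  p <- data.frame(ligand = l, receptor = r, stringsAsFactors = FALSE)
  if (!is.null(pmid)) p$pmid <- pmid
  list(source_name = name, pairs = p)
}

test_that("merging known sources unions pairs with provenance", {
  ps <- merge_known(list(src("dlrp", "L1", "R1"), src("hpmr", "L1", "R1")))
  expect_equal(nrow(ps), 1L)
  expect_setequal(strsplit(ps$sources, ";")[[1]], c("dlrp", "hpmr"))

  a <- src("a", paste0("L", 1:3), paste0("R", 1:3))
  b <- src("b", paste0("L", 4:7), paste0("R", 4:7))
  expect_equal(nrow(merge_known(list(a, b))), 7L)

  # swapped ligand/receptor roles across sources are a conflict
  expect_error(merge_known(list(src("a", "X", "Y"), src("b", "Y", "X"))),
               "conflict")
})

test_that("merged set equals brute-force union with provenance on random sources", {
  set.seed(31)
  for (iter in 1:5) {
    univ_l <- paste0("L", 1:10); univ_r <- paste0("R", 1:10)
    mk <- function(nm) {
      n <- sample(3:12, 1)
      src(nm, sample(univ_l, n, replace = TRUE), sample(univ_r, n, replace = TRUE))
    }
    sources <- list(mk("s1"), mk("s2"), mk("s3"))
    ps <- merge_known(sources)
    manual <- unique(do.call(rbind, lapply(sources, function(s)
      unique(s$pairs[c("ligand", "receptor")]))))
    expect_equal(nrow(ps), nrow(manual))
    for (i in seq_len(nrow(ps))) {
      expected_src <- vapply(sources, function(s)
        any(s$pairs$ligand == ps$ligand[i] & s$pairs$receptor == ps$receptor[i]),
        logical(1))
      expect_setequal(strsplit(ps$sources[i], ";")[[1]],
                      c("s1", "s2", "s3")[expected_src])
    }
  }
})

test_that("candidate sets follow the secreted/PM set algebra", {
  known <- merge_known(list(src("k", c("L1", "L2"), c("R1", "R2"))))
  loc <- data.frame(symbol = c("S1", "S2", "R1", "P1", "L1"),
                    class = c("secreted", "secreted", "secreted",
                              "plasma_membrane", "plasma_membrane"),
                    stringsAsFactors = FALSE)
  cand <- build_candidates(known, loc = loc)
  # secreted genes not in known receptors enter the ligand candidates
  expect_true(all(c("S1", "S2") %in% cand$putative_ligands))
  # a secreted gene that IS a known receptor is excluded
  expect_false("R1" %in% setdiff(cand$putative_ligands, known$receptor))
  expect_true("R1" %in% cand$putative_receptors)  # still a known receptor
  # PM gene that is a known ligand is excluded from receptor candidates
  expect_true("P1" %in% cand$putative_receptors)
  expect_setequal(cand$putative_ligands, c("L1", "L2", "S1", "S2"))
  expect_setequal(cand$putative_receptors, c("R1", "R2", "P1"))

  # orphans join their respective sets
  cand2 <- build_candidates(known, orphan_ligands = "OL",
                            orphan_receptors = "OR", loc = loc)
  expect_true("OL" %in% cand2$putative_ligands)
  expect_true("OR" %in% cand2$putative_receptors)
})

test_that("PPI inference applies evidence rules and the score boundary", {
  cand <- list(putative_ligands = c("L1", "L2", "B"),
               putative_receptors = c("R1", "R2", "B"))
  ppi <- data.frame(
    protein_a = c("L1", "L1", "R2", "L2", "B", "Z1"),
    protein_b = c("R1", "R2", "L2", "R1", "B", "Z2"),
    source = c("string_like", "string_like", "hprd_like", "string_like",
               "hprd_like", "hprd_like"),
    evidence_type = c("physical_binding", "physical_binding", "yeast2hybrid",
                      "coexpression", "in_vivo", "in_vitro"),
    confidence = c(700, 699, NA, 950, NA, NA), stringsAsFactors = FALSE)
  inf <- infer_from_ppi(cand, ppi)
  key <- paste(inf$ligand, inf$receptor)
  expect_true("L1 R1" %in% key)      # score 700 inclusive
  expect_false("L1 R2" %in% key)     # score 699 below threshold
  expect_true("L2 R2" %in% key)      # hprd yeast2hybrid, order ignored
  expect_false("L2 R1" %in% key)     # string evidence type not accepted
  expect_false("B B" %in% key)       # self-pair excluded by default
  expect_false(any(grepl("Z", key))) # endpoints outside candidate sets

  inf_self <- infer_from_ppi(cand, ppi, allow_self = TRUE)
  expect_true("B B" %in% paste(inf_self$ligand, inf_self$receptor))
})

test_that("PPI inference is monotone decreasing in the score threshold", {
  set.seed(17)
  cand <- list(putative_ligands = paste0("L", 1:8),
               putative_receptors = paste0("R", 1:8))
  ppi <- data.frame(protein_a = sample(paste0("L", 1:8), 60, replace = TRUE),
                    protein_b = sample(paste0("R", 1:8), 60, replace = TRUE),
                    source = "string_like",
                    evidence_type = sample(c("physical_binding", "experimental"),
                                           60, replace = TRUE),
                    confidence = sample(400:999, 60), stringsAsFactors = FALSE)
  sizes <- vapply(c(0, 400, 700, 900, 1000),
                  function(s) nrow(infer_from_ppi(cand, ppi, min_string_score = s)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("curation set arithmetic and status rules hold", {
  known <- merge_known(list(src("k", c("L1", "L2"), c("R1", "R2"),
                                pmid = c("11", NA))))
  inferred <- data.frame(ligand = c("L3", "L2"), receptor = c("R3", "R2"),
                         evidence = "hprd_like:in_vivo", stringsAsFactors = FALSE)
  curation <- data.frame(ligand = c("L3", "L9", "L1"),
                         receptor = c("R3", "R9", "R1"),
                         verdict = c("exclude", "add", "keep"),
                         pmid = c(NA, "999", "22"), stringsAsFactors = FALSE)
  ps <- apply_curation(known, inferred, curation)

  l3 <- ps[ps$ligand == "L3", ]
  expect_equal(l3$status, "excluded")
  expect_false("L3" %in% active_pairs(ps)$ligand)   # never reaches networks

  l9 <- ps[ps$ligand == "L9", ]
  expect_equal(l9$status, "reference")              # curation add with PMID

  l1 <- ps[ps$ligand == "L1", ]
  expect_setequal(strsplit(l1$pmids, ";")[[1]], c("11", "22"))
  expect_equal(l1$status, "reference")

  expect_equal(ps[ps$ligand == "L2" & ps$receptor == "R2", ]$status, "putative")

  expect_error(apply_curation(known, NULL,
                              data.frame(ligand = "A", receptor = "B",
                                         verdict = "maybe", pmid = NA)),
               "verdict")
})

test_that("final pair count equals the set arithmetic on random instances", {
  set.seed(23)
  for (iter in 1:5) {
    ligs <- paste0("L", 1:8); recs <- paste0("R", 1:8)
    known_df <- unique(data.frame(
      ligand = sample(ligs, 10, replace = TRUE),
      receptor = sample(recs, 10, replace = TRUE), stringsAsFactors = FALSE))
    known <- merge_known(list(src("k", known_df$ligand, known_df$receptor)))
    inf <- unique(data.frame(ligand = sample(ligs, 6, replace = TRUE),
                             receptor = sample(recs, 6, replace = TRUE),
                             stringsAsFactors = FALSE))
    inf$evidence <- "hprd_like:in_vitro"
    adds <- data.frame(ligand = "LX", receptor = "RX", verdict = "add",
                       pmid = "1", stringsAsFactors = FALSE)
    universe <- unique(rbind(known_df, inf[1:2]))
    excl_idx <- sample(nrow(universe), 3)
    excl <- data.frame(ligand = universe$ligand[excl_idx],
                       receptor = universe$receptor[excl_idx],
                       verdict = "exclude", pmid = NA, stringsAsFactors = FALSE)
    ps <- apply_curation(known, inf, rbind(adds, excl))
    n_union <- nrow(universe) + 1L  # plus the added pair
    expect_equal(nrow(active_pairs(ps)), n_union - 3L)
    expect_equal(sum(ps$status == "excluded"), 3L)
  }
})
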