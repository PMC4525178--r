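mk_pairs <- function(l, r) {
  structure(data.frame(ligand = l, receptor = r, status = "putative",
                       sources = "", pmids = "", inferred = FALSE,
                       stringsAsFactors = FALSE),
            class = c("pair_set", "data.frame"))
}

test_that("major pairs take argmax cells with deterministic ties", {
  m <- matrix(c(1109, 5, 2, 699), 2, 2,
              dimnames = list(c("CSF1", "CSF1R"),
                              c("mast cell stimulated", "endothelial progenitor")))
  mp <- major_pairs(expression_atlas(m), mk_pairs("CSF1", "CSF1R"))
  expect_equal(mp$max_transmitter, "mast cell stimulated")
  expect_equal(mp$max_receiver, "endothelial progenitor")
  expect_equal(mp$ligand_tpm, 1109)
  expect_equal(mp$receptor_tpm, 699)

  # single-cell atlas: that cell plays both roles
  m1 <- matrix(c(10, 20), 2, 1, dimnames = list(c("L", "R"), "only_cell"))
  mp1 <- major_pairs(expression_atlas(m1), mk_pairs("L", "R"))
  expect_equal(mp1$max_transmitter, "only_cell")
  expect_equal(mp1$max_receiver, "only_cell")

  # exact tie -> lexicographically smallest cell name
  mt <- matrix(c(7, 7, 5, 5), 2, 2, byrow = TRUE,
               dimnames = list(c("L", "R"), c("zeta", "alpha")))
  mpt <- major_pairs(expression_atlas(mt), mk_pairs("L", "R"))
  expect_equal(mpt$max_transmitter, "alpha")

  # all-zero ligand -> dropped with a warning
  mz <- matrix(c(0, 0, 5, 6), 2, 2, byrow = TRUE,
               dimnames = list(c("L", "R"), c("a", "b")))
  expect_warning(mpz <- major_pairs(expression_atlas(mz), mk_pairs("L", "R")),
                 "dropped")
  expect_equal(nrow(mpz), 0L)
})

test_that("major pairs equal the argmax enumeration oracle", {
  for (seed in c(2, 22)) {
    atl <- rand_atlas(14, 6, seed = seed)
    pairs <- rand_pairs(10, rownames(atl), seed = seed + 1)
    mp <- suppressWarnings(major_pairs(atl, pairs))
    for (i in seq_len(nrow(mp))) {
      lrow <- unclass(atl)[mp$ligand[i], ]
      cand <- names(lrow)[lrow == max(lrow)]
      expect_equal(mp$max_transmitter[i], sort(cand)[1])
      expect_equal(mp$ligand_tpm[i], max(lrow))
    }
  }
})

test_that("lineage matrix tallies pairs and conserves the total", {
  lm <- toy_lineage_map()
  mp <- data.frame(ligand = "L1", receptor = "R1",
                   max_transmitter = "haematopoietic_1",
                   max_receiver = "haematopoietic_2",
                   ligand_tpm = 50, receptor_tpm = 60, stringsAsFactors = FALSE)
  lmtx <- lineage_matrix(mp, lm)
  expect_equal(lmtx["haematopoietic", "haematopoietic"], 1L)
  expect_equal(sum(lmtx), 1L)

  mp2 <- rbind(mp, transform(mp, max_transmitter = "mesenchymal_1"),
               transform(mp, max_transmitter = "mesenchymal_2"))
  lmtx2 <- lineage_matrix(mp2, lm)
  expect_equal(lmtx2["mesenchymal", "haematopoietic"], 2L)
  expect_equal(sum(lmtx2), nrow(mp2))

  expect_error(lineage_matrix(transform(mp, max_receiver = "unknown_cell"), lm),
               "missing from lineage map")

  # random instances: totals conserved, cells equal brute-force tallies
  set.seed(9)
  cells <- names(lm)
  mp3 <- data.frame(ligand = paste0("L", 1:40), receptor = paste0("R", 1:40),
                    max_transmitter = sample(cells, 40, replace = TRUE),
                    max_receiver = sample(cells, 40, replace = TRUE),
                    ligand_tpm = 1, receptor_tpm = 1, stringsAsFactors = FALSE)
  lmtx3 <- lineage_matrix(mp3, lm)
  expect_equal(sum(lmtx3), 40L)
  for (a in rownames(lmtx3)) for (b in colnames(lmtx3)) {
    expect_equal(unname(lmtx3[a, b]),
                 sum(lm[mp3$max_transmitter] == a & lm[mp3$max_receiver] == b))
  }
})

test_that("representation test handles degenerate and closed-form cases", {
  # all cells in one lineage: p0 = 1, observed = n -> p-value 1
  cells <- paste0("c", 1:4)
  lm1 <- setNames(rep("other", 4), cells)
  mp <- data.frame(ligand = paste0("L", 1:10), receptor = paste0("R", 1:10),
                   max_transmitter = sample(cells, 10, replace = TRUE),
                   max_receiver = sample(cells, 10, replace = TRUE),
                   ligand_tpm = 1, receptor_tpm = 1, stringsAsFactors = FALSE)
  tt <- lineage_representation_test(mp, lm1)
  other <- tt[tt$lineage == "other", ]
  expect_true(all(other$p == 1))
  expect_true(all(other$x == 10))

  # x = 0, n = 100, p0 = 0.5 -> two-sided p = 2 * 2^-100
  lm2 <- setNames(rep(c("epithelial", "nervous"), each = 2), cells)
  mp2 <- data.frame(ligand = paste0("L", 1:100), receptor = paste0("R", 1:100),
                    max_transmitter = sample(cells[1:2], 100, replace = TRUE),
                    max_receiver = sample(cells[1:2], 100, replace = TRUE),
                    ligand_tpm = 1, receptor_tpm = 1, stringsAsFactors = FALSE)
  tt2 <- lineage_representation_test(mp2, lm2)
  nerv <- tt2[tt2$lineage == "nervous" & tt2$role == "ligand", ]
  expect_equal(nerv$x, 0)
  expect_equal(nerv$p0, 0.5)
  expect_equal(nerv$p, 2 * 2^-100, tolerance = 1e-12)
  expect_equal(nerv$direction, "under")

  # BH adjustment spans the 12 tests as one family
  expect_equal(nrow(tt2), 12L)
  expect_equal(tt2$q, p.adjust(tt2$p, "BH"))
})

test_that("path bias test is null-conforming on marginal-product matrices", {
  # fully concentrated matrix: p0 = 1 for the occupied cell -> p = 1
  lmtx <- matrix(0L, 6, 6, dimnames = list(lineage_levels(), lineage_levels()))
  lmtx["nervous", "nervous"] <- 25L
  bt <- path_bias_test(lmtx)
  expect_equal(bt$p[bt$from == "nervous" & bt$to == "nervous"], 1)

  # a matrix exactly equal to the outer product of its marginals
  u <- matrix(10L, 6, 6, dimnames = list(lineage_levels(), lineage_levels()))
  btu <- path_bias_test(u)
  expect_true(all(btu$p >= 0.99))
  expect_equal(nrow(btu), 36L)
  expect_equal(btu$q, p.adjust(btu$p, "BH"))

  expect_error(path_bias_test(u * 0L), "empty")
})

test_that("permutation variant of the path bias test flags planted excess", {
  set.seed(4)
  lmtx <- matrix(5L, 6, 6, dimnames = list(lineage_levels(), lineage_levels()))
  lmtx["haematopoietic", "haematopoietic"] <- 60L
  bt <- path_bias_test(lmtx, n_perm = 499)
  expect_lt(bt$p[bt$from == "haematopoietic" & bt$to == "haematopoietic"], 0.01)
})

test_that("lineage gene lists separate foreground edge from full background", {
  lm <- toy_lineage_map()
  mp <- data.frame(
    ligand = c("L1", "L2", "L3"), receptor = c("R1", "R2", "R3"),
    max_transmitter = c("mesenchymal_1", "mesenchymal_2", "nervous_1"),
    max_receiver = c("haematopoietic_1", "haematopoietic_1", "nervous_2"),
    ligand_tpm = 1, receptor_tpm = 1, stringsAsFactors = FALSE)
  gl <- export_lineage_gene_lists(mp, lm, "mesenchymal", "haematopoietic")
  expect_setequal(gl$foreground, c("L1", "L2", "R1", "R2"))
  expect_setequal(gl$background, c("L1", "L2", "L3", "R1", "R2", "R3"))

  # an empty edge gives an empty foreground but the full background
  gl2 <- export_lineage_gene_lists(mp, lm, "endothelial", "epithelial")
  expect_equal(length(gl2$foreground), 0L)
  expect_equal(length(gl2$background), 6L)
})
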