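test_that("detection thresholding is >= and validates the threshold", {
  m <- matrix(c(0, 10, 9.99, 50), 2, 2,
              dimnames = list(c("A", "B"), c("c1", "c2")))
  atl <- expression_atlas(m)
  d <- detect(atl, 10)
  expect_true(d["B", "c1"])          # exactly 10 is detected
  expect_false(d["A", "c2"])         # 9.99 is not
  expect_error(detect(atl, 0), "positive")
  expect_error(detect(atl, -5), "positive")

  zero <- expression_atlas(matrix(0, 2, 2, dimnames = dimnames(m)))
  expect_false(any(detect(zero, 10)))

  # the operator is configurable; > excludes the boundary
  expect_false(detect(atl, 10, op = ">")["B", "c1"])
})

test_that("expressed pairs require both partners detected somewhere", {
  m <- matrix(c(20, 0, 0, 15, 0, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("L1", "R1", "L2"), c("cellA", "cellB")))
  atl <- expression_atlas(m)
  d <- detect(atl, 10)
  pairs <- structure(
    data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R1"),
               status = "putative", sources = "", pmids = "", inferred = FALSE,
               stringsAsFactors = FALSE),
    class = c("pair_set", "data.frame"))
  ep <- expressed_pairs(pairs, d)
  # L1 in cellA only, R1 in cellB only -> still an expressed pair
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$ligand, "L1")     # L2 detected nowhere -> excluded

  # a pair gene absent from the atlas is treated as never detected, warned
  pairs2 <- structure(
    data.frame(ligand = "MISSING", receptor = "R1", status = "putative",
               sources = "", pmids = "", inferred = FALSE, stringsAsFactors = FALSE),
    class = c("pair_set", "data.frame"))
  expect_warning(ep2 <- expressed_pairs(pairs2, d), "absent")
  expect_equal(nrow(ep2), 0L)
})

test_that("set/count operations equal enumeration oracles on random instances", {
  for (seed in c(3, 14, 159)) {
    atl <- rand_atlas(18, 6, seed = seed)
    pairs <- rand_pairs(15, rownames(atl), seed = seed + 1)
    d <- detect(atl, 10)

    ep <- expressed_pairs(pairs, d)
    expect_equal(nrow(ep), sum(oracle_expressed(d, pairs)))

    rc <- repertoire_counts(d, pairs)
    af <- autocrine_fractions(d, pairs)
    for (cc in colnames(d)) {
      oc <- oracle_repertoire(d, pairs, cc)
      expect_equal(rc$n_ligands[rc$cell_type == cc], unname(oc["n_ligands"]))
      expect_equal(rc$n_receptors[rc$cell_type == cc], unname(oc["n_receptors"]))
      oa <- oracle_autocrine(d, pairs, cc)
      expect_equal(af$ligand_fraction[af$cell_type == cc], unname(oa["lig"]))
      expect_equal(af$receptor_fraction[af$cell_type == cc], unname(oa["rec"]))
    }

    pm <- path_count_matrix(d, pairs)
    expect_equal(pm, oracle_path_counts(d, pairs))
  }
})

test_that("autocrine fractions handle the degenerate single-cell cases", {
  m <- matrix(c(20, 30), 2, 1, dimnames = list(c("L", "R"), "cellA"))
  pairs <- structure(
    data.frame(ligand = "L", receptor = "R", status = "putative",
               sources = "", pmids = "", inferred = FALSE, stringsAsFactors = FALSE),
    class = c("pair_set", "data.frame"))
  af <- autocrine_fractions(detect(expression_atlas(m), 10), pairs)
  expect_equal(af$ligand_fraction, 1.0)
  expect_equal(af$receptor_fraction, 1.0)

  m2 <- matrix(c(20, 0), 2, 1, dimnames = list(c("L", "R"), "cellA"))
  af2 <- autocrine_fractions(detect(expression_atlas(m2), 10), pairs)
  expect_equal(af2$ligand_fraction, 0.0)
  expect_true(is.na(af2$receptor_fraction))  # no expressed receptor
})

test_that("diagonal path counts match the autocrine numerators definitionally", {
  for (seed in c(8, 80)) {
    atl <- rand_atlas(16, 5, seed = seed)
    pairs <- rand_pairs(12, rownames(atl), seed = seed + 2)
    d <- detect(atl, 10)
    pm <- path_count_matrix(d, pairs)
    for (cc in colnames(d)) {
      n_auto <- sum(vapply(seq_len(nrow(pairs)), function(i) {
        has <- function(g) g %in% rownames(d) && d[g, cc]
        has(pairs$ligand[i]) && has(pairs$receptor[i])
      }, logical(1)))
      expect_equal(unname(pm[cc, cc]), n_auto)
    }
  }
})

test_that("breadth medians and quadrant classification follow the <= tie rule", {
  # two ligands with breadths 1 and 5: median 3 -> specific / broad
  m <- matrix(0, 4, 5, dimnames = list(c("L1", "L2", "R1", "R2"),
                                       paste0("c", 1:5)))
  m["L1", 1] <- 20
  m["L2", ] <- 20
  m["R1", 1:2] <- 20
  m["R2", 1:4] <- 20
  pairs <- structure(
    data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
               status = "putative", sources = "", pmids = "", inferred = FALSE,
               stringsAsFactors = FALSE),
    class = c("pair_set", "data.frame"))
  d <- detect(expression_atlas(m), 10)
  bq <- breadth_and_quadrants(d, pairs)
  expect_equal(bq$ligand_median, 3)
  expect_equal(bq$pairs$quadrant, c("specific/specific", "broad/broad"))
  expect_equal(sum(bq$quadrant_fractions), 1)

  # identical breadths: everyone sits at the median -> all specific
  m2 <- m; m2[] <- 20
  bq2 <- breadth_and_quadrants(detect(expression_atlas(m2), 10), pairs)
  expect_true(all(bq2$pairs$quadrant == "specific/specific"))
})

test_that("edge building reproduces the CSF1-CSF1R worked example", {
  m <- matrix(c(1109, 3, 40, 12, 2, 699, 50, 80), nrow = 2, byrow = TRUE,
              dimnames = list(c("CSF1", "CSF1R"),
                              c("mast cell stimulated", "endothelial progenitor",
                                "macrophage", "basophil")))
  atl <- expression_atlas(m)
  pairs <- structure(
    data.frame(ligand = "CSF1", receptor = "CSF1R", status = "reference",
               sources = "k", pmids = "1", inferred = FALSE, stringsAsFactors = FALSE),
    class = c("pair_set", "data.frame"))
  edges <- build_edges(atl, pairs, threshold = 10)
  expect_equal(edges$source_cell[1], "mast cell stimulated")
  expect_equal(edges$target_cell[1], "endothelial progenitor")
  expect_equal(edges$weight[1], 1109 * 699)  # 775191, exact product
  expect_identical(edges$weight, edges$ligand_tpm * edges$receptor_tpm)

  # top_n truncation keeps the heaviest edges deterministically
  top2 <- build_edges(atl, pairs, threshold = 10, top_n = 2)
  expect_equal(nrow(top2), 2L)
  expect_equal(top2$weight, sort(edges$weight, decreasing = TRUE)[1:2])

  # threshold above the maximum TPM yields no edges
  expect_equal(nrow(build_edges(atl, pairs, threshold = 2000)), 0L)
})

test_that("detection counts are non-increasing as the threshold rises", {
  for (seed in c(6, 66)) {
    atl <- rand_atlas(20, 6, seed = seed, max_tpm = 300)
    pairs <- rand_pairs(14, rownames(atl), seed = seed + 4)
    stats <- lapply(c(10, 50, 100), function(thr) {
      d <- detect(atl, thr)
      list(det = sum(d), ep = nrow(expressed_pairs(pairs, d)),
           rep = sum(repertoire_counts(d, pairs)[, -1]),
           paths = sum(path_count_matrix(d, pairs)),
           edges = nrow(build_edges(atl, pairs, threshold = thr)))
    })
    for (f in c("det", "ep", "rep", "paths", "edges")) {
      v <- vapply(stats, `[[`, numeric(1), f)
      expect_true(all(diff(v) <= 0), info = f)
    }
  }
})

test_that("concordance arithmetic matches simple set identities", {
  # detected entirely inside the proteome -> fully supported
  out <- detection_concordance(detected = paste0("G", 1:10),
                               proteome = paste0("G", 1:20))
  expect_equal(out$supported_fraction, 1)
  expect_error(detection_concordance(character(0), "A"), "empty")

  # literature support counts toward the numerator
  out2 <- detection_concordance(detected = c("A", "B", "C", "D"),
                                proteome = "A", literature = "B")
  expect_equal(out2$supported_fraction, 0.5)

  # array check fractions: proteome-only vs detected genes with probes
  out3 <- detection_concordance(
    detected = c("A", "B"), proteome = c("B", "C", "D"),
    array_probed = c("A", "B", "C", "D"), array_detected = c("A", "B", "C"))
  expect_equal(out3$proteome_only_array_fraction, 0.5)  # C of {C, D}
  expect_equal(out3$detected_array_fraction, 1)         # A, B both detected
})
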