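test_that("simulation specs validate their parameters", {
  expect_error(simSpec(nPos = 0, nNeg = 5, nNullFamilies = 1), ">= 1")
  expect_error(simSpec(nPos = 2, nNeg = 2, planted = data.frame(
    family_id = "F", p_pos = 1.2, p_neg = 0, paralog_mean = 0)), "\\[0, 1\\]")
  expect_error(simSpec(nPos = 2, nNeg = 2, planted = data.frame(
    family_id = c("F", "F"), p_pos = 0.5, p_neg = 0.5, paralog_mean = 0)),
    "duplicate")
})

test_that("the simulator is fully reproducible from its seed", {
  sp <- demo_spec(7)
  a <- simulateCohort(sp)
  b <- simulateCohort(sp)
  expect_identical(a$statuses, b$statuses)
  expect_identical(a$taxonomy, b$taxonomy)
  expect_true(ape::all.equal.phylo(a$tree, b$tree))
  expect_identical(plantFamilies(sp, a), plantFamilies(sp, b))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- emitFixtures(a, plantFamilies(sp, a), d1)
  p2 <- emitFixtures(b, plantFamilies(sp, b), d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
})

test_that("decoy carriers exercise both exclusion paths", {
  co <- simulateCohort(demo_spec(19))
  mc <- makeCohorts(co$statuses, co$taxonomy, co$tree)
  exc <- excludedAssemblies(mc$partition)
  expect_equal(sum(exc == "variant_carrier"), 2L)
  expect_equal(sum(exc == "outside_taxon"), 2L)
})

test_that("with clade structure the positives form at most the requested number of clades", {
  sp <- simSpec(nPos = 12, nNeg = 20, nNullFamilies = 1, nPosClades = 3,
                seed = 5)
  co <- simulateCohort(sp)
  tr <- co$tree
  pos <- co$truth$positive
  # count maximal positive-only clades covering the positive tips
  is_pos_tip <- tr$tip.label %in% pos
  n_tip <- ape::Ntip(tr)
  clade_tips <- function(nd) ape::extract.clade(tr, nd)$tip.label
  pure <- vapply((n_tip + 1L):(n_tip + tr$Nnode),
                 function(nd) all(clade_tips(nd) %in% pos), TRUE)
  pure_nodes <- ((n_tip + 1L):(n_tip + tr$Nnode))[pure]
  # maximal pure clades: not contained in another pure clade
  covered <- unique(unlist(lapply(pure_nodes, clade_tips)))
  singletons <- setdiff(pos, covered)
  maximal <- Filter(function(nd) {
    anc <- tr$edge[, 1][tr$edge[, 2] == nd]
    !(length(anc) && anc %in% pure_nodes)
  }, pure_nodes)
  expect_lte(length(maximal) + length(singletons), 3L)
  expect_setequal(pos, c(covered, singletons))
})

test_that("planted families realize their presence probabilities and paralog law", {
  # universal family
  sp1 <- simSpec(nPos = 8, nNeg = 8, planted = data.frame(
    family_id = "U", p_pos = 1, p_neg = 1, paralog_mean = 0), seed = 4)
  co1 <- simulateCohort(sp1)
  pl1 <- plantFamilies(sp1, co1)
  expect_true(all(pl1$matrix[, "U"] == 1L))
  part <- CohortPartition(positive = co1$truth$positive,
                          negative = co1$truth$negative)
  prof <- profilePresenceMatrix(pl1$matrix, part, "limit")
  expect_equal(prof$f_pos, 1)
  expect_equal(prof$f_neg, 1)
  # perfectly split family approaches MI = H(marker) = 1 bit at n_pos = n_neg
  sp2 <- simSpec(nPos = 150, nNeg = 150, planted = data.frame(
    family_id = "S", p_pos = 1, p_neg = 0, paralog_mean = 0), seed = 4)
  co2 <- simulateCohort(sp2)
  pl2 <- plantFamilies(sp2, co2)
  part2 <- CohortPartition(positive = co2$truth$positive,
                           negative = co2$truth$negative)
  expect_equal(profilePresenceMatrix(pl2$matrix, part2, "limit")$mi_bits, 1)
  # paralog_mean = 0 means exactly one copy when present
  expect_true(all(pl2$matrix %in% 0:1))
  # positive paralog mean yields counts >= 1 when present
  sp3 <- simSpec(nPos = 50, nNeg = 50, planted = data.frame(
    family_id = "P", p_pos = 1, p_neg = 1, paralog_mean = 3), seed = 4)
  pl3 <- plantFamilies(sp3, simulateCohort(sp3))
  expect_true(all(pl3$matrix[, "P"] >= 1L))
  expect_gt(mean(pl3$matrix[, "P"]), 2.5)
})

test_that("empirical cohort fractions recover the planted probabilities", {
  planted <- data.frame(family_id = c("C1", "C2", "A1"),
                        p_pos = c(0.9, 0.7, 0.1),
                        p_neg = c(0.1, 0.3, 0.9),
                        paralog_mean = 0)
  sp <- simSpec(nPos = 300, nNeg = 300, nNullFamilies = 0, planted = planted,
                seed = 23)
  co <- simulateCohort(sp)
  pl <- plantFamilies(sp, co)
  part <- CohortPartition(positive = co$truth$positive,
                          negative = co$truth$negative)
  prof <- profilePresenceMatrix(pl$matrix, part, "limit")
  for (i in seq_len(nrow(planted))) {
    row <- prof[prof$family_id == planted$family_id[i], ]
    se_pos <- sqrt(planted$p_pos[i] * (1 - planted$p_pos[i]) / 300)
    se_neg <- sqrt(planted$p_neg[i] * (1 - planted$p_neg[i]) / 300)
    expect_lt(abs(row$f_pos - planted$p_pos[i]), 3 * se_pos + 1e-9)
    expect_lt(abs(row$f_neg - planted$p_neg[i]), 3 * se_neg + 1e-9)
  }
})

test_that("emitted fixtures are format-faithful and classify back to their categories", {
  sp <- demo_spec(31)
  co <- simulateCohort(sp)
  pl <- plantFamilies(sp, co)
  d <- tempfile()
  paths <- emitFixtures(co, pl, d)
  # parser totality: every emitted file parses
  seq2asm <- readIdMap(paths[["seq2asm"]])
  rna <- readRnaHits(paths[["rna_hits"]], seqToAssembly = seq2asm)
  prot2asm <- readIdMap(paths[["prot2asm"]])
  prot <- readProteinHits(paths[["protein_hits"]], proteinToAssembly = prot2asm)
  hmm <- readHmmHits(paths[["hmm_hits"]], proteinToAssembly = prot2asm)
  cmap <- readClusterMap(paths[["clusters"]])
  tree <- readSpeciesTree(paths[["tree"]])
  tax <- readTaxonomy(paths[["taxonomy"]])
  expect_gt(nrow(rna), 0)
  expect_gt(nrow(prot), 0)
  expect_gt(nrow(hmm), 0)
  expect_setequal(tree$tip.label, tax$assembly_id)
  # full-length carriers: best nontruncated hit >= 390
  st <- assemblyStatuses(rna)
  stmap <- structure(st$status, names = st$assembly_id)
  expect_true(all(stmap[co$truth$positive] == "full_length"))
  expect_true(all(st$best_bit_score[st$status == "full_length"] >= 390))
  # variant2 carriers: truncated, or nontruncated scoring in [235, 310)
  v2 <- names(co$truth$excluded)[co$truth$excluded == "variant_carrier"]
  v2 <- v2[stmap[v2] == "variant2"]
  for (a in v2) {
    h <- rna[rna$assembly_id == a, ]
    expect_true(all(h$truncation != "none" |
                      (h$bit_score >= 235 & h$bit_score < 310)))
  }
  # cluster families reproduce the planted presence pattern
  fams_clu <- familiesFromClusters(cmap, prot2asm, minClusterSize = 1)
  expect_true("SMALLCLU" %in% sub(".*\\|(.*)\\|.*", "\\1",
                                  attr(familiesFromClusters(cmap, prot2asm,
                                                            minClusterSize = 5),
                                       "discarded")))
  # HMM families at the recorded cutoff contain exactly the planted members
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  for (f in truth$families$family_id[truth$families$planted]) {
    fh <- hmm[hmm$query_id == f, ]
    fam <- familyFromHmmHits(fh, f, bitMin = truth$hmm_bit_min)
    expect_setequal(familyAssemblies(fam),
                    rownames(pl$matrix)[pl$matrix[, f] > 0])
  }
})
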