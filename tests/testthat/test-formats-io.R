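test_that("covariance-model tblout parsing handles empty and comment-only streams", {
  expect_equal(nrow(readRnaHits(write_tmp(character()),
                                seqToAssembly = c(x = "A"))), 0L)
  expect_equal(nrow(readRnaHits(write_tmp(c("# a", "# b", "# c")),
                                seqToAssembly = c(x = "A"))), 0L)
})

test_that("a tblout record parses field-for-field", {
  f <- write_tmp(tblout_line(target = "seqA", score = 412.3, trunc = "no",
                             strand = "+", from = 100L, to = 705L))
  h <- readRnaHits(f, seqToAssembly = c(seqA = "ASM1"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$bit_score, 412.3)
  expect_equal(h$truncation, "none")
  expect_equal(h$seq_from, 100L)
  expect_equal(h$seq_to, 705L)
  expect_equal(h$strand, "plus")
  expect_equal(h$assembly_id, "ASM1")
  expect_equal(h$e_value, 1.2e-110)
  expect_equal(h$description, "contig description")
})

test_that("every truncation token maps to its flag and unknown tokens fail", {
  toks <- c("no" = "none", "5'" = "trunc5", "3'" = "trunc3", "5'&3'" = "both")
  for (tk in names(toks)) {
    h <- readRnaHits(write_tmp(tblout_line(trunc = tk)),
                     seqToAssembly = c(seq1 = "A"))
    expect_equal(h$truncation, unname(toks[tk]))
  }
  expect_error(readRnaHits(write_tmp(tblout_line(trunc = "maybe")),
                           seqToAssembly = c(seq1 = "A")),
               "truncation")
})

test_that("malformed tblout lines fail with the line number", {
  f <- write_tmp(c("# header", tblout_line(), "too few fields here"))
  expect_error(readRnaHits(f, seqToAssembly = c(seq1 = "A")), "line 3")
})

test_that("assembly ids can come from a mapping table or a prefix rule", {
  f <- write_tmp(tblout_line(target = "ASMX_ctg1"))
  h1 <- readRnaHits(f, seqToAssembly = c(ASMX_ctg1 = "ASMX"))
  h2 <- readRnaHits(f, assemblyFromSeqId = function(x) sub("_.*", "", x))
  expect_equal(h1$assembly_id, "ASMX")
  expect_equal(h2$assembly_id, "ASMX")
  expect_error(readRnaHits(f, seqToAssembly = c(other = "Y")), "mapping")
})

test_that("12-column protein tables parse and preserve duplicate alignments", {
  expect_equal(nrow(readProteinHits(write_tmp(character()),
                                    proteinToAssembly = c(s1 = "A"))), 0L)
  h <- readProteinHits(write_tmp(blast6_line(evalue = "1e-50",
                                             bitscore = "210.5")),
                       proteinToAssembly = c(s1 = "A"))
  expect_equal(h$e_value, 1e-50)
  expect_equal(h$bit_score, 210.5)
  expect_equal(h$subject_assembly_id, "A")
  # two local alignments of the same pair stay two records
  two <- readProteinHits(write_tmp(c(blast6_line(), blast6_line(evalue = "1e-20"))),
                         proteinToAssembly = c(s1 = "A"))
  expect_equal(nrow(two), 2L)
  # scientific notation with or without leading digit
  sci <- readProteinHits(write_tmp(c(blast6_line(evalue = "1e-10"),
                                     blast6_line(evalue = "1.0E-10"))),
                         proteinToAssembly = c(s1 = "A"))
  expect_equal(sci$e_value, c(1e-10, 1e-10))
})

test_that("protein table column-count errors and unmappable subjects are handled", {
  expect_error(readProteinHits(write_tmp("q1\ts1\tonly three"),
                               proteinToAssembly = c(s1 = "A")),
               "12 columns")
  f <- write_tmp(c(blast6_line(subject = "s1"), blast6_line(subject = "s2")))
  expect_error(readProteinHits(f, proteinToAssembly = c(s1 = "A")), "s2")
  expect_warning(h <- readProteinHits(f, proteinToAssembly = c(s1 = "A"),
                                      onUnmapped = "skip"),
                 "skipped")
  expect_equal(h$subject_id, "s1")
})

test_that("profile-HMM per-target tables yield model-named hits", {
  expect_equal(nrow(readHmmHits(write_tmp("# comments only"),
                                proteinToAssembly = c(x = "A"))), 0L)
  line <- "t1 - MODEL1 - 3.2e-30 87.2 0.1 - - - - - - - - - - - desc"
  h <- readHmmHits(write_tmp(c("# hmmsearch tblout", line)),
                   proteinToAssembly = c(t1 = "ASM9"))
  expect_equal(h$query_id, "MODEL1")
  expect_equal(h$subject_id, "t1")
  expect_equal(h$bit_score, 87.2)
  expect_equal(h$e_value, 3.2e-30)
  expect_equal(h$subject_assembly_id, "ASM9")
})

test_that("cluster maps group members by representative", {
  cm <- readClusterMap(write_tmp(c("A\tA", "A\tB", "C\tC")))
  expect_equal(cm, list(A = c("A", "B"), C = "C"))
  expect_length(readClusterMap(write_tmp(character())), 0L)
  # representative self-membership is restored when the self line is missing
  cm2 <- readClusterMap(write_tmp(c("A\tB")))
  expect_equal(cm2$A, c("A", "B"))
  expect_error(readClusterMap(write_tmp(c("A\tB", "C\tB"))), "disjoint")
})

test_that("newick trees parse with unique tips and fail on duplicates", {
  f <- write_tmp("((A,B),(C,D));")
  tr <- readSpeciesTree(f)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_error(readSpeciesTree(write_tmp("((A,B),(A,C));")), "duplicate")
  expect_error(readSpeciesTree(write_tmp("((A,B),(C,D);")))
})

test_that("presence matrices and trees round-trip through their writers", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    k <- sample(1:6, 1)
    m <- matrix(rpois(n * k, 2), n, k,
                dimnames = list(sprintf("ASM%02d", seq_len(n)),
                                sprintf("FAM%02d", seq_len(k))))
    storage.mode(m) <- "integer"
    f <- tempfile()
    writePresenceMatrix(m, f)
    expect_identical(readPresenceMatrix(f), m)
  }
  tr <- ape::rtree(8)
  f <- tempfile()
  writeSpeciesTree(tr, f)
  tr2 <- readSpeciesTree(f)
  expect_true(ape::all.equal.phylo(tr, tr2))
})

test_that("prepending blank or comment lines never changes a parse", {
  noise <- c("", "# tool header", "   ", "# another comment")
  f1 <- write_tmp(tblout_line())
  f2 <- write_tmp(c(noise, tblout_line()))
  expect_identical(readRnaHits(f1, seqToAssembly = c(seq1 = "A")),
                   readRnaHits(f2, seqToAssembly = c(seq1 = "A")))
  g1 <- write_tmp(blast6_line())
  g2 <- write_tmp(c(noise, blast6_line()))
  expect_identical(readProteinHits(g1, proteinToAssembly = c(s1 = "A")),
                   readProteinHits(g2, proteinToAssembly = c(s1 = "A")))
  c1 <- write_tmp("A\tB")
  c2 <- write_tmp(c(noise, "A\tB"))
  expect_identical(readClusterMap(c1), readClusterMap(c2))
})

test_that("id maps read two columns and reject duplicate ids", {
  mp <- readIdMap(write_tmp(c("# comment", "p1\tA", "p2\tB")))
  expect_equal(mp, c(p1 = "A", p2 = "B"))
  expect_error(readIdMap(write_tmp(c("p1\tA", "p1\tB"))), "duplicate")
})
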