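test_that("joint counts cross family presence with the partition and ignore exclusions", {
  part <- CohortPartition(positive = c("A", "B"), negative = c("C", "D"),
                          excluded = c(E = "variant_carrier"))
  jc <- jointCounts(c("A", "C"), part)
  expect_equal(jointCells(jc), c(n00 = 1L, n01 = 1L, n10 = 1L, n11 = 1L))
  # present everywhere
  expect_equal(jointCells(jointCounts(c("A", "B", "C", "D"), part))[c("n10", "n00")],
               c(n10 = 0L, n00 = 0L))
  # members only in an excluded assembly are invisible
  expect_equal(jointCells(jointCounts("E", part))[c("n11", "n01")],
               c(n11 = 0L, n01 = 0L))
  # works on ProteinFamily objects too
  fam <- ProteinFamily("F", c("A", "E"), c("p1", "p2"))
  expect_equal(jointCells(jointCounts(fam, part))[["n11"]], 1L)
  expect_error(jointCounts("A", CohortPartition(positive = "A")), "non-empty")
})

test_that("group fractions are cohort proportions with at least one member", {
  fr <- groupFractions(JointCounts(n00 = 8, n01 = 2, n10 = 1, n11 = 9))
  expect_equal(fr, c(f_pos = 0.9, f_neg = 0.2))
  expect_equal(groupFractions(JointCounts(5, 0, 5, 0)),
               c(f_pos = 0, f_neg = 0))
  expect_equal(groupFractions(JointCounts(0, 5, 0, 5)),
               c(f_pos = 1, f_neg = 1))
  expect_error(groupFractions(JointCounts(1, 1, 0, 0)), "cohort sizes")
})

test_that("mutual information matches hand-computed values in both zero modes", {
  # exact independence: 0 bits in either mode
  expect_identical(mutualInformation(JointCounts(25, 25, 25, 25)), 0)
  expect_identical(mutualInformation(JointCounts(25, 25, 25, 25), "limit"), 0)
  # perfect association: 1 bit in limit mode, discarded under the
  # zero-operand rule
  expect_equal(mutualInformation(JointCounts(50, 0, 0, 50), "limit"), 1)
  expect_true(is.na(mutualInformation(JointCounts(50, 0, 0, 50), "discard")))
  # frozen value computed independently from the four-term sum at full
  # precision (0.8*log2(1.6) + 0.2*log2(0.4)) and cross-checked against the
  # entropy decomposition
  expect_equal(mutualInformation(JointCounts(40, 10, 10, 40)),
               0.27807190511263774, tolerance = 1e-14)
  expect_equal(mi_entropy_oracle(40, 10, 10, 40), 0.27807190511263774,
               tolerance = 1e-12)
  expect_error(mutualInformation(JointCounts(0, 0, 0, 0)), "N")
})

test_that("the discard rule triggers on any zero cell or margin", {
  expect_true(is.na(mutualInformation(JointCounts(10, 0, 5, 5))))
  expect_true(is.na(mutualInformation(JointCounts(0, 10, 10, 10))))
  expect_false(is.na(mutualInformation(JointCounts(1, 1, 1, 1))))
  # limit mode: a degenerate margin gives exactly 0
  expect_equal(mutualInformation(JointCounts(10, 0, 10, 0), "limit"), 0)
})

test_that("MI is symmetric, bounded by the marginal entropies, and agrees with the entropy form", {
  set.seed(2024)
  H2 <- function(p) if (p %in% c(0, 1)) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
  for (i in 1:300) {
    jc <- random_table()
    n <- jointCells(jc)
    mi <- mutualInformation(jc, "limit")
    expect_gte(mi, 0)
    N <- sum(n)
    hx <- H2((n[["n10"]] + n[["n11"]]) / N)
    hy <- H2((n[["n01"]] + n[["n11"]]) / N)
    expect_lte(mi, min(hx, hy) + 1e-12)
    # transpose symmetry: swap the roles of marker and family
    expect_lt(abs(mutualInformation(JointCounts(n[["n00"]], n[["n10"]],
                                                n[["n01"]], n[["n11"]]),
                                    "limit") - mi), 1e-12)
    # expanded four-term sum vs entropy decomposition
    expect_lt(abs(mi - mi_entropy_oracle(n[["n00"]], n[["n01"]],
                                         n[["n10"]], n[["n11"]])), 1e-12)
  }
})

test_that("moving mass from discordant to concordant cells never decreases MI", {
  for (N in c(8L, 12L)) {
    grids <- expand.grid(n00 = 0:N, n01 = 0:N, n10 = 0:N)
    grids$n11 <- N - grids$n00 - grids$n01 - grids$n10
    grids <- grids[grids$n11 >= 0, ]
    for (r in sample(nrow(grids), 150)) {
      g <- grids[r, ]
      if (g$n01 < 1 || g$n10 < 1) next
      # only from independence onward: in an anticorrelated table the same
      # move heads toward independence and MI rightly falls
      if (g$n00 * g$n11 < g$n01 * g$n10) next
      base <- mutualInformation(JointCounts(g$n00, g$n01, g$n10, g$n11),
                                "limit")
      moved <- mutualInformation(JointCounts(g$n00 + 1, g$n01 - 1,
                                             g$n10 - 1, g$n11 + 1), "limit")
      expect_gte(moved, base - 1e-12)
    }
  }
})

test_that("ranking is MI-descending with deterministic tie-breaks and NA tail", {
  prof <- data.frame(
    family_id = c("b", "a", "d", "c", "e"),
    f_pos = c(0.5, 0.9, 0.8, 0.3, 1.0),
    f_neg = c(0.5, 0.1, 0.8, 0.3, 0.0),
    mi_bits = c(0.1, 0.9, 0.5, 0.5, NA),
    stringsAsFactors = FALSE)
  r <- rankProfiles(prof)
  expect_equal(r$family_id, c("a", "c", "d", "b", "e"))
  expect_equal(r$rank, 1:5)
  # equal MI: larger |f_pos - f_neg| first
  tie <- data.frame(family_id = c("b", "a"), f_pos = c(0.3, 0.8),
                    f_neg = c(0.3, 0.3), mi_bits = c(0.2, 0.2))
  expect_equal(rankProfiles(tie)$family_id, c("a", "b"))
  # equal everything: lexicographic id
  tie2 <- data.frame(family_id = c("z", "y"), f_pos = 0.5, f_neg = 0.1,
                     mi_bits = 0.2)
  expect_equal(rankProfiles(tie2)$family_id, c("y", "z"))
})

test_that("profiles carry direction consistent with the fraction gap", {
  part <- CohortPartition(positive = c("A", "B"), negative = c("C", "D"))
  fams <- list(ProteinFamily("cor", c("A", "B"), c("p1", "p2")),
               ProteinFamily("anti", c("C", "D"), c("p3", "p4")),
               ProteinFamily("neu", c("A", "C"), c("p5", "p6")))
  prof <- profileFamilies(fams, part, zeroMode = "limit")
  dir <- structure(prof$direction, names = prof$family_id)
  expect_equal(dir[["cor"]], "correlated")
  expect_equal(dir[["anti"]], "anticorrelated")
  expect_equal(dir[["neu"]], "neutral")
  expect_true(all(sign(prof$f_pos - prof$f_neg) ==
                    c(correlated = 1, anticorrelated = -1, neutral = 0)[prof$direction]))
  # discarded-MI families stay in the output, flagged not dropped
  prof_d <- profileFamilies(fams, part, zeroMode = "discard")
  expect_equal(nrow(prof_d), 3L)
  expect_true(any(is.na(prof_d$mi_bits)))
})

test_that("scatter and violin exports carry plot-ready coordinates", {
  part <- CohortPartition(positive = "A", negative = c("B", "C"))
  prof <- data.frame(family_id = "F", f_pos = 1, f_neg = 0, mi_bits = 0.5)
  sc <- scatterData(prof)
  expect_equal(sc$f_neg, 0)
  expect_equal(sc$f_pos, 1)
  vd <- violinData(c(A = 2L, B = 0L, C = 8L), part)
  expect_equal(vd$count[vd$cohort == "positive"], 2L)
  expect_setequal(vd$count[vd$cohort == "negative"], c(0L, 8L))
  # excluded assemblies are omitted
  part2 <- CohortPartition(positive = "A", negative = "B",
                           excluded = c(C = "variant_carrier"))
  vd2 <- violinData(c(A = 1L, B = 1L, C = 5L), part2)
  expect_false("C" %in% vd2$assembly_id)
  expect_equal(nrow(violinData(structure(integer(), names = character()),
                               part)), 0L)
})

test_that("matrix profiling equals family profiling on the same data", {
  part <- CohortPartition(positive = c("A", "B"), negative = c("C", "D"))
  fams <- list(ProteinFamily("F1", c("A", "B", "C"), c("p1", "p2", "p3")),
               ProteinFamily("F2", "D", "p4"))
  m <- presenceMatrixFromFamilies(fams, c("A", "B", "C", "D"))
  expect_equal(profilePresenceMatrix(m, part, "limit"),
               profileFamilies(fams, part, "limit"))
})
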