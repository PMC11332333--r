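# Independent oracles and fixture builders shared across test files.

# Entropy-form mutual information: H(X) + H(Y) - H(X,Y), in bits.
# Independent of the expanded four-term evaluation in the package.
mi_entropy_oracle <- function(n00, n01, n10, n11) {
  N <- n00 + n01 + n10 + n11
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  p <- c(n00, n01, n10, n11) / N
  hx <- H(c(p[1] + p[2], p[3] + p[4]))
  hy <- H(c(p[1] + p[3], p[2] + p[4]))
  hx + hy - H(p)
}

# Brute-force MRCA clade by root-to-tip path intersection.
# Returns the tip labels of the clade below the MRCA of `marked`.
mrca_clade_oracle <- function(tree, marked) {
  root <- ape::Ntip(tree) + 1L
  tip_idx <- match(marked, tree$tip.label)
  paths <- lapply(tip_idx, function(i) ape::nodepath(tree, root, i))
  common <- Reduce(intersect, paths)
  mrca <- common[length(common)]  # deepest shared node on root->tip paths
  all_paths <- lapply(seq_len(ape::Ntip(tree)),
                      function(i) ape::nodepath(tree, root, i))
  keep <- vapply(all_paths, function(p) mrca %in% p, TRUE)
  tree$tip.label[keep]
}

# One Infernal-tblout-style record with the given score/trunc/strand.
tblout_line <- function(target = "seq1", score = 412.3, trunc = "no",
                        strand = "+", from = 100L, to = 705L,
                        evalue = "1.2e-110", desc = "contig description") {
  paste("", collapse = "")
  paste(target, "-", "MARKER_RNA", "-", "cm", 1, 600, from, to, strand,
        trunc, 1, 0.49, 0.0, score, evalue, "!", desc)
}

# One 12-column protein hit line.
blast6_line <- function(query = "q1", subject = "s1", evalue = "1e-50",
                        bitscore = "210.5", pident = "45.5") {
  paste(query, subject, pident, 200, 10, 1, 1, 200, 1, 200, evalue, bitscore,
        sep = "\t")
}

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# An RNA hit data.frame row in the package's parsed layout.
rna_hit <- function(bit, trunc = "none", target = "t1", assembly = "A") {
  data.frame(target_seq_id = target, assembly_id = assembly,
             model_name = "M", bit_score = bit, e_value = 1e-20,
             seq_from = 1L, seq_to = 600L, strand = "plus",
             truncation = trunc, description = "", stringsAsFactors = FALSE)
}

# Random non-degenerate 2x2 table (all marginals positive).
random_table <- function() {
  repeat {
    n <- stats::rpois(4, lambda = stats::runif(1, 2, 40))
    if ((n[1] + n[2]) > 0 && (n[3] + n[4]) > 0 &&
        (n[1] + n[3]) > 0 && (n[2] + n[4]) > 0)
      return(JointCounts(n[1], n[2], n[3], n[4]))
  }
}

# Standard small simulation used by several files.
demo_spec <- function(seed = 7, ...) {
  simSpec(nPos = 6, nNeg = 10, nNullFamilies = 3,
          planted = data.frame(
            family_id = c("FAM_COR", "FAM_ANTI"),
            p_pos = c(0.9, 0.1), p_neg = c(0.1, 0.9),
            paralog_mean = c(1, 0)),
          nDecoyVariant = 2, nDecoyOutside = 2, seed = seed, ...)
}

run_sim_pipeline <- function(spec, dir = tempfile()) {
  co <- simulateCohort(spec)
  pl <- plantFamilies(spec, co)
  paths <- emitFixtures(co, pl, dir)
  cfg <- runConfig(paths[["rna_hits"]], paths[["seq2asm"]],
                   paths[["protein_hits"]], paths[["prot2asm"]],
                   paths[["tree"]], paths[["taxonomy"]],
                   file.path(dir, "out"))
  list(cohort = co, planted = pl, paths = paths, result = runProfile(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
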