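# Seeded synthetic cohorts, trees, planted families and format-faithful
# mock search-output files. The generator emulates the statistical
# structure the profiling analysis assumes: two cohorts of assemblies on a
# species tree, marker presence concentrated in a few clades, families
# present with cohort-conditional probabilities, and per-assembly paralog
# counts. It does not simulate sequences or sequence evolution.

#' Specification of a synthetic profiling study
#'
#' Collects every knob of the simulator. All randomness downstream derives
#' from the single integer \code{seed}; the same spec always regenerates
#' identical cohorts, matrices and fixture files.
#'
#' @param nPos,nNeg number of marker-positive / marker-negative assemblies
#'   (both >= 1). The study design this emulates is asymmetric (far more
#'   marker-negative genomes), but any sizes are allowed.
#' @param planted data.frame of planted families with columns
#'   \code{family_id}, \code{p_pos} (presence probability given
#'   marker-positive), \code{p_neg} (given marker-negative), and
#'   \code{paralog_mean} (mean number of extra copies when present; the
#'   per-assembly copy count is 1 + Poisson(\code{paralog_mean}), so
#'   presence always implies at least one member). May be empty.
#' @param nNullFamilies number of null families with presence probability
#'   \code{nullP} in both cohorts.
#' @param nullP,nullParalogMean parameters of the null families.
#' @param cladeStructure logical; when TRUE marker-positive tips occupy
#'   \code{nPosClades} monophyletic groups on the tree, mimicking a marker
#'   confined to distinct clades scattered through a phylum; when FALSE
#'   positives are interleaved at random.
#' @param nPosClades number of marker-positive clades (capped at
#'   \code{nPos}).
#' @param nDecoyVariant number of decoy variant-RNA carriers (excluded from
#'   both cohorts downstream with reason \code{variant_carrier}).
#' @param nDecoyOutside number of decoy marker carriers placed outside the
#'   allowed phylum (excluded with reason \code{outside_taxon}).
#' @param seed single integer seed.
#' @return a validated list of class \code{"SimSpec"}.
#' @examples
#' sp <- simSpec(nPos = 5, nNeg = 10, nNullFamilies = 3,
#'               planted = data.frame(family_id = "FAM_COR", p_pos = 0.9,
#'                                    p_neg = 0.1, paralog_mean = 0),
#'               seed = 42)
#' @export
simSpec <- function(nPos, nNeg, planted = NULL, nNullFamilies = 0L,
                    nullP = 0.5, nullParalogMean = 0,
                    cladeStructure = TRUE, nPosClades = 3L,
                    nDecoyVariant = 0L, nDecoyOutside = 0L, seed = 1L) {
  if (is.null(planted))
    planted <- data.frame(family_id = character(), p_pos = numeric(),
                          p_neg = numeric(), paralog_mean = numeric(),
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(planted),
            all(c("family_id", "p_pos", "p_neg", "paralog_mean") %in%
                  names(planted)))
  if (nPos < 1L || nNeg < 1L) stop("'nPos' and 'nNeg' must be >= 1")
  if (any(planted$p_pos < 0 | planted$p_pos > 1) ||
      any(planted$p_neg < 0 | planted$p_neg > 1) ||
      nullP < 0 || nullP > 1)
    stop("presence probabilities must lie in [0, 1]")
  if (any(planted$paralog_mean < 0) || nullParalogMean < 0)
    stop("paralog means must be >= 0")
  if (anyDuplicated(planted$family_id)) stop("duplicate planted family ids")
  if (nNullFamilies < 0L || nDecoyVariant < 0L || nDecoyOutside < 0L)
    stop("counts must be non-negative")
  if (length(seed) != 1L || is.na(seed) || seed != as.integer(seed))
    stop("'seed' must be a single integer")
  structure(list(nPos = as.integer(nPos), nNeg = as.integer(nNeg),
                 planted = planted, nNullFamilies = as.integer(nNullFamilies),
                 nullP = nullP, nullParalogMean = nullParalogMean,
                 cladeStructure = isTRUE(cladeStructure),
                 nPosClades = max(1L, as.integer(nPosClades)),
                 nDecoyVariant = as.integer(nDecoyVariant),
                 nDecoyOutside = as.integer(nDecoyOutside),
                 seed = as.integer(seed)),
            class = "SimSpec")
}

# newick text of a random subtree over the given labels (no trailing ';')
.subtree_newick <- function(labels) {
  if (length(labels) == 1L) return(labels)
  tr <- ape::rtree(length(labels), tip.label = labels)
  sub(";\\s*$", "", ape::write.tree(tr))
}

#' Simulate a two-cohort assembly set on a random species tree
#'
#' Draws a random bifurcating tree over the marker-positive,
#' marker-negative and decoy assemblies. With \code{cladeStructure}, the
#' positive tips form \code{nPosClades} monophyletic clades grafted into a
#' backbone of the remaining tips. Per-assembly RNA hit plans (bit scores
#' and truncation flags consistent with each assembly's intended category)
#' are drawn here so that fixture emission is deterministic.
#'
#' @param spec a [simSpec()] object.
#' @return list of class \code{"SimCohort"} with elements \code{tree}
#'   (\code{ape::phylo}), \code{statuses} (the per-assembly status table
#'   the classifier should reproduce), \code{taxonomy},
#'   \code{rnaHitPlan} (internal hit-level plan used by [emitFixtures()]),
#'   \code{truth} (list: \code{positive}, \code{negative}, \code{excluded}
#'   reasons), and \code{spec}.
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed)
  pos <- sprintf("POS%04d", seq_len(spec$nPos))
  neg <- sprintf("NEG%04d", seq_len(spec$nNeg))
  var <- if (spec$nDecoyVariant) sprintf("VAR%04d", seq_len(spec$nDecoyVariant)) else character()
  out <- if (spec$nDecoyOutside) sprintf("OUT%04d", seq_len(spec$nDecoyOutside)) else character()
  backbone_others <- c(neg, var, out)

  # The first marker-positive clade is grafted as sister to everything
  # else, so the marker spans the root of the simulated phylum (a marker
  # scattered in clades throughout the phylum): the minimal clade
  # containing all positives is then the whole simulated tree.
  if (spec$cladeStructure) {
    k <- min(max(spec$nPosClades, 2L), spec$nPos)  # >= 2 clades: the marker
    # must span the phylum root, or the universe would collapse to one clade
    groups <- split(pos, sort(rep_len(seq_len(k), spec$nPos)))
    ph <- sprintf("ZPH%04d", seq_len(k))
    backbone_tips <- sample(c(backbone_others, ph[-1L]))
    bb <- if (length(backbone_tips) >= 2L) {
      sub(";\\s*$", "",
          ape::write.tree(ape::rtree(length(backbone_tips),
                                     tip.label = backbone_tips)))
    } else backbone_tips
    nwk <- paste0("(", ph[1L], ":1,", bb, ":1);")
    for (i in seq_len(k))
      nwk <- sub(ph[i], .subtree_newick(groups[[i]]), nwk, fixed = TRUE)
    tree <- ape::read.tree(text = nwk)
  } else {
    others <- sample(c(pos[-1L], backbone_others))
    bb <- if (length(others) >= 2L) {
      sub(";\\s*$", "",
          ape::write.tree(ape::rtree(length(others), tip.label = others)))
    } else others
    tree <- ape::read.tree(text = paste0("(", pos[1L], ":1,", bb, ":1);"))
  }

  # hit-level plan: scores drawn inside the intended category's interval
  plan_full <- function(a) data.frame(
    assembly_id = a, target_seq_id = paste0(a, "_ctg1"),
    bit_score = round(stats::runif(length(a), 395, 480), 1),
    trunc_token = "no", category = "full_length", stringsAsFactors = FALSE)
  plan_v1 <- function(a) data.frame(
    assembly_id = a, target_seq_id = paste0(a, "_ctg1"),
    bit_score = round(stats::runif(length(a), 312, 388), 1),
    trunc_token = "no", category = "variant1", stringsAsFactors = FALSE)
  plan_v2 <- function(a) {
    truncated <- seq_along(a) %% 2L == 1L  # alternate the two v2 routes
    data.frame(
      assembly_id = a, target_seq_id = paste0(a, "_ctg1"),
      bit_score = round(ifelse(truncated, stats::runif(length(a), 240, 460),
                               stats::runif(length(a), 240, 308)), 1),
      trunc_token = ifelse(truncated,
                           rep_len(c("5'", "3'", "5'&3'"), length(a)), "no"),
      category = "variant2", stringsAsFactors = FALSE)
  }
  nv <- length(var)
  v1 <- var[seq_len(ceiling(nv / 2))]
  v2 <- setdiff(var, v1)
  plan <- rbind(plan_full(pos),
                if (length(v1)) plan_v1(v1),
                if (length(v2)) plan_v2(v2),
                if (length(out)) plan_full(out))
  # low-score noise hits on a few negatives: classified nowhere
  noise <- utils::head(neg, 3L)
  if (length(noise))
    plan <- rbind(plan, data.frame(
      assembly_id = noise, target_seq_id = paste0(noise, "_ctg1"),
      bit_score = round(stats::runif(length(noise), 20, 230), 1),
      trunc_token = "no", category = "unclassified", stringsAsFactors = FALSE))
  # a secondary truncated hit on the first positive: exercises best-hit calls
  plan <- rbind(plan, data.frame(
    assembly_id = pos[1L], target_seq_id = paste0(pos[1L], "_ctg2"),
    bit_score = round(plan$bit_score[1L] - 100, 1), trunc_token = "5'",
    category = "variant2", stringsAsFactors = FALSE))
  rownames(plan) <- NULL

  best <- plan[plan$category != "unclassified", , drop = FALSE]
  best <- best[order(-best$bit_score, best$target_seq_id), , drop = FALSE]
  best <- best[!duplicated(best$assembly_id), , drop = FALSE]
  statuses <- data.frame(assembly_id = best$assembly_id,
                         status = best$category,
                         best_bit_score = best$bit_score,
                         best_target = best$target_seq_id,
                         stringsAsFactors = FALSE)
  statuses <- statuses[order(statuses$assembly_id), , drop = FALSE]
  rownames(statuses) <- NULL

  all_ids <- c(pos, neg, var, out)
  taxonomy <- data.frame(
    assembly_id = all_ids,
    phylum = c(rep("Bacillota", length(pos) + length(neg) + length(var)),
               rep("Pseudomonadota", length(out))),
    class = c(sample(c("Bacilli", "Clostridia"),
                     length(pos) + length(neg) + length(var), replace = TRUE),
              rep("Gammaproteobacteria", length(out))),
    stringsAsFactors = FALSE)

  truth <- list(
    positive = pos, negative = neg,
    excluded = c(structure(rep("variant_carrier", length(var)), names = var),
                 structure(rep("outside_taxon", length(out)), names = out)))
  structure(list(tree = tree, statuses = statuses, taxonomy = taxonomy,
                 rnaHitPlan = plan, truth = truth, spec = spec),
            class = "SimCohort")
}

#' Plant protein families with cohort-conditional presence
#'
#' Draws each family's presence independently per assembly with
#' probability \code{p_pos} in marker-positive assemblies and \code{p_neg}
#' everywhere else (marker-negative assemblies and decoys). Present
#' assemblies get \code{1 + Poisson(paralog_mean)} member proteins, so a
#' present family always has at least one member.
#'
#' @param spec a [simSpec()] object.
#' @param cohort the matching [simulateCohort()] result.
#' @return list with \code{matrix} (integer assembly x family count
#'   matrix over all simulated assemblies, decoys included) and
#'   \code{familyTable} (per-family true parameters with a \code{planted}
#'   flag).
#' @export
plantFamilies <- function(spec, cohort) {
  stopifnot(inherits(spec, "SimSpec"), inherits(cohort, "SimCohort"))
  set.seed(spec$seed + 1L)
  fam <- rbind(
    if (spec$nNullFamilies)
      data.frame(family_id = sprintf("FAM_NULL_%04d", seq_len(spec$nNullFamilies)),
                 p_pos = spec$nullP, p_neg = spec$nullP,
                 paralog_mean = spec$nullParalogMean, planted = FALSE,
                 stringsAsFactors = FALSE),
    if (nrow(spec$planted))
      data.frame(spec$planted[, c("family_id", "p_pos", "p_neg", "paralog_mean")],
                 planted = TRUE, stringsAsFactors = FALSE))
  if (is.null(fam) || nrow(fam) == 0L)
    stop("spec defines no families (nNullFamilies = 0 and empty 'planted')")
  if (anyDuplicated(fam$family_id)) stop("family ids collide with null family ids")
  assemblies <- c(cohort$truth$positive, cohort$truth$negative,
                  names(cohort$truth$excluded))
  is_pos <- assemblies %in% cohort$truth$positive
  m <- matrix(0L, nrow = length(assemblies), ncol = nrow(fam),
              dimnames = list(assemblies, fam$family_id))
  for (j in seq_len(nrow(fam))) {
    p <- ifelse(is_pos, fam$p_pos[j], fam$p_neg[j])
    present <- stats::rbinom(length(assemblies), 1L, p) == 1L
    counts <- integer(length(assemblies))
    counts[present] <- 1L + stats::rpois(sum(present), fam$paralog_mean[j])
    m[, j] <- counts
  }
  list(matrix = m, familyTable = fam)
}

.fixture_evalue <- function(i) {
  # deterministic passing e-values; the very first member sits exactly on
  # the inclusive 1e-10 cutoff
  if (i == 1L) "1.0e-10" else sprintf("1e-%d", 12L + (i %% 40L))
}

#' Write format-faithful fixture files for a simulated study
#'
#' Emits the complete input set of a profiling run, every file parseable by
#' the formats readers: a covariance-model tblout with the planned RNA hits
#' (scores and truncation flags consistent with each assembly's category,
#' plus sub-threshold noise hits), a 12-column protein hit table realizing
#' the planted family memberships (including duplicate local alignments,
#' one hit exactly on the inclusive e-value cutoff, and per-family decoy
#' hits failing it), a per-target HMM hit table for the planted families
#' (members above, decoys below, the bit cutoff recorded in the truth), a
#' cluster TSV whose clusters equal the families plus one undersized decoy
#' cluster, the newick tree, the taxonomy table, and the id-to-assembly
#' maps. A \code{truth.json} and the true count matrix are written
#' alongside. Writing is deterministic: re-emitting the same simulation
#' gives byte-identical files.
#'
#' @param cohort a [simulateCohort()] result.
#' @param planted the matching [plantFamilies()] result.
#' @param dir output directory (created if needed).
#' @param hmmBitMin bit-score cutoff separating planted HMM members from
#'   decoy targets in the emitted HMM table (recorded in the truth).
#' @return named character vector of the file paths, invisibly usable with
#'   [runProfile()].
#' @export
emitFixtures <- function(cohort, planted, dir, hmmBitMin = 50) {
  stopifnot(inherits(cohort, "SimCohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", sQuote(dir))
  paths <- c(rna_hits = file.path(dir, "rna_hits.tbl"),
             seq2asm = file.path(dir, "seq2asm.tsv"),
             protein_hits = file.path(dir, "protein_hits.tsv"),
             prot2asm = file.path(dir, "prot2asm.tsv"),
             hmm_hits = file.path(dir, "hmm_hits.tbl"),
             clusters = file.path(dir, "clusters.tsv"),
             tree = file.path(dir, "tree.nwk"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"),
             truth_matrix = file.path(dir, "truth_matrix.tsv"))

  plan <- cohort$rnaHitPlan
  strand <- rep_len(c("+", "-"), nrow(plan))
  rna_lines <- sprintf(
    "%s - MARKER_RNA - cm 1 600 %d %d %s %s 1 0.49 0.0 %.1f %.2e ! synthetic contig",
    plan$target_seq_id, ifelse(strand == "+", 101L, 700L),
    ifelse(strand == "+", 700L, 101L), strand, plan$trunc_token,
    plan$bit_score, 10^(-plan$bit_score / 5))
  writeLines(c("# synthetic covariance-model search tblout", rna_lines),
             paths[["rna_hits"]])
  writeLines(sprintf("%s\t%s", plan$target_seq_id, plan$assembly_id),
             paths[["seq2asm"]])

  m <- planted$matrix
  prot_lines <- character(0)
  prot_map <- character(0)
  clu_lines <- character(0)
  hmm_lines <- character(0)
  fam_planted <- planted$familyTable$family_id[planted$familyTable$planted]
  i_ev <- 0L
  for (f in colnames(m)) {
    asms <- rownames(m)[m[, f] > 0L]
    prots <- unlist(lapply(asms, function(a)
      sprintf("%s|%s|p%02d", a, f, seq_len(m[a, f]))), use.names = FALSE)
    prot_asm <- rep(asms, times = m[asms, f])
    for (k in seq_along(prots)) {
      i_ev <- i_ev + 1L
      prot_lines <- c(prot_lines, sprintf(
        "%s\t%s\t%.1f\t200\t%d\t1\t1\t200\t1\t200\t%s\t%.1f",
        f, prots[k], 35 + (i_ev %% 60), 5L + (i_ev %% 20L),
        .fixture_evalue(i_ev), 150 + (i_ev %% 100)))
    }
    # duplicate local alignment for the first member of each family
    if (length(prots))
      prot_lines <- c(prot_lines, sprintf(
        "%s\t%s\t%.1f\t150\t%d\t1\t30\t180\t30\t180\t%s\t%.1f",
        f, prots[1L], 33.0, 9L, "2e-15", 120.0))
    # a decoy hit failing the e-value cutoff, on the first assembly
    decoy <- sprintf("%s|%s|decoy", rownames(m)[1L], f)
    prot_lines <- c(prot_lines,
                    sprintf("%s\t%s\t28.0\t90\t40\t3\t1\t90\t1\t90\t1e-5\t35.2",
                            f, decoy))
    prot_map <- c(prot_map, sprintf("%s\t%s", c(prots, decoy),
                                    c(prot_asm, rownames(m)[1L])))
    if (length(prots)) {
      rep_id <- sort(prots)[1L]
      clu_lines <- c(clu_lines, sprintf("%s\t%s", rep_id, sort(prots)))
    }
    if (f %in% fam_planted) {
      if (length(prots))
        hmm_lines <- c(hmm_lines, sprintf(
          "%s - %s - %s %.1f 0.1 - - - - - - - - - - - synthetic target",
          prots, f, sprintf("%.1e", 1e-30), hmmBitMin + 25.3))
      hmm_lines <- c(hmm_lines, sprintf(
        "%s|%s|decoy - %s - 1.2e-02 %.1f 0.0 - - - - - - - - - - - synthetic target",
        rownames(m)[1L], f, f, max(hmmBitMin - 30, 1)))
    }
  }
  # undersized decoy cluster (below the min-cluster-size filter)
  small <- sprintf("%s|SMALLCLU|p%02d", rownames(m)[1L], 1:2)
  clu_lines <- c(clu_lines, sprintf("%s\t%s", small[1L], small))
  prot_map <- c(prot_map, sprintf("%s\t%s", small, rownames(m)[1L]))

  writeLines(prot_lines, paths[["protein_hits"]])
  writeLines(prot_map, paths[["prot2asm"]])
  writeLines(c("# synthetic profile-HMM search tblout", hmm_lines),
             paths[["hmm_hits"]])
  writeLines(clu_lines, paths[["clusters"]])
  writeSpeciesTree(cohort$tree, paths[["tree"]])
  utils::write.table(cohort$taxonomy, paths[["taxonomy"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writePresenceMatrix(m, paths[["truth_matrix"]])
  jsonlite::write_json(
    list(positive = cohort$truth$positive,
         negative = cohort$truth$negative,
         excluded = as.list(cohort$truth$excluded),
         families = planted$familyTable,
         hmm_bit_min = hmmBitMin,
         seed = cohort$spec$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}
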