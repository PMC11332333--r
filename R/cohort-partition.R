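# Cohort construction: taxonomic filtering, marker-positive/negative
# partitioning, and pruning the species tree to the minimal clade spanning
# the marker-positive assemblies.

#' Filter assembly statuses by phylum
#'
#' Assemblies whose taxonomy places them outside the allowed phylum are
#' removed from the analysis and reported as excluded with reason
#' \code{outside_taxon}. This mirrors dropping marker hits in distant phyla
#' that likely stem from assembly or taxonomy-assignment errors.
#'
#' @param statuses status data.frame from [assemblyStatuses()].
#' @param taxonomy data.frame from [readTaxonomy()]; every status assembly
#'   must appear in it (missing rows are an error listing the ids).
#' @param allowedPhylum single phylum name, e.g. \code{"Bacillota"}.
#' @return list with \code{retained} (status rows inside the phylum) and
#'   \code{excluded} (character vector of assembly ids outside it).
#' @export
filterByTaxon <- function(statuses, taxonomy, allowedPhylum = "Bacillota") {
  stopifnot(is.data.frame(statuses), is.data.frame(taxonomy),
            length(allowedPhylum) == 1L)
  if (nrow(statuses) == 0L)
    return(list(retained = statuses, excluded = character()))
  phylum <- taxonomy$phylum[match(statuses$assembly_id, taxonomy$assembly_id)]
  if (anyNA(phylum))
    stop("assemblies missing from the taxonomy table: ",
         paste(statuses$assembly_id[is.na(phylum)], collapse = ", "))
  inside <- phylum == allowedPhylum
  list(retained = {
         r <- statuses[inside, , drop = FALSE]; rownames(r) <- NULL; r
       },
       excluded = statuses$assembly_id[!inside])
}

#' Partition a universe of assemblies into marker cohorts
#'
#' Sorts the assemblies of the analysis universe into the marker-positive
#' cohort (status \code{full_length}), the marker-negative cohort (status
#' \code{absent}, or no status row at all), and the excluded set: carriers
#' of a variant-category RNA belong to neither cohort (reason
#' \code{variant_carrier}), since they carry the gene but not its
#' full-length form.
#'
#' @param statuses status data.frame ([assemblyStatuses()]); every status
#'   assembly must lie inside \code{universe}.
#' @param universe character vector of assembly ids defining the analysis
#'   universe (the denominator of the marker-negative fraction).
#' @return A [CohortPartition-class].
#' @examples
#' st <- data.frame(assembly_id = c("A", "B", "C"),
#'                  status = c("full_length", "absent", "variant1"))
#' partitionCohorts(st, universe = c("A", "B", "C", "D"))
#' @export
partitionCohorts <- function(statuses, universe) {
  stopifnot(is.data.frame(statuses))
  universe <- unique(as.character(universe))
  outside <- setdiff(statuses$assembly_id, universe)
  if (length(outside))
    stop("status records outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  status <- structure(statuses$status, names = statuses$assembly_id)
  s <- status[universe]
  s[is.na(s)] <- "absent"
  bad <- setdiff(s, c("full_length", "variant1", "variant2", "absent"))
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  variant <- universe[s %in% c("variant1", "variant2")]
  CohortPartition(
    positive = universe[s == "full_length"],
    negative = universe[s == "absent"],
    excluded = structure(rep("variant_carrier", length(variant)),
                         names = variant))
}

#' Compose the full cohort construction from statuses, taxonomy and tree
#'
#' Runs the complete cohort logic in one call: filter statuses to the
#' allowed phylum ([filterByTaxon()]), drop tree tips without taxonomy,
#' prune the tree to the minimal clade spanning the marker-positive
#' assemblies ([mrcaSubtree()]), fix the analysis universe, and partition
#' it ([partitionCohorts()]). The returned partition also records the
#' assemblies excluded as \code{outside_taxon} (wrong phylum) and
#' \code{not_in_universe} (right phylum, outside the pruned subtree).
#'
#' @param statuses status data.frame from [assemblyStatuses()].
#' @param taxonomy data.frame from [readTaxonomy()].
#' @param tree \code{ape::phylo} species tree with assembly-accession tips.
#' @param allowedPhylum phylum kept in the analysis.
#' @param universeMode \code{"pruned_subtree"} (default): the universe is
#'   every allowed-phylum assembly inside the minimal clade spanning the
#'   marker-positive assemblies, which reproduces the strong positive <<
#'   negative cohort asymmetry; \code{"whole_phylum"}: every allowed-phylum
#'   assembly in the taxonomy table.
#' @return list with \code{partition} ([CohortPartition-class]),
#'   \code{universe} (character) and \code{prunedTree} (\code{ape::phylo}).
#' @export
makeCohorts <- function(statuses, taxonomy, tree,
                        allowedPhylum = "Bacillota",
                        universeMode = c("pruned_subtree", "whole_phylum")) {
  universeMode <- match.arg(universeMode)
  stopifnot(inherits(tree, "phylo"))
  flt <- filterByTaxon(statuses, taxonomy, allowedPhylum)
  unknown_tips <- setdiff(tree$tip.label, taxonomy$assembly_id)
  if (length(unknown_tips)) {
    warning(length(unknown_tips),
            " tree tip(s) absent from the taxonomy table dropped")
    tree <- ape::drop.tip(tree, unknown_tips)
  }
  phylum_asm <- taxonomy$assembly_id[taxonomy$phylum == allowedPhylum]
  pos <- flt$retained$assembly_id[flt$retained$status == "full_length"]
  pruned <- tree
  if (universeMode == "whole_phylum") {
    universe <- phylum_asm
  } else {
    pos_on_tree <- intersect(pos, tree$tip.label)
    if (length(pos_on_tree) == 0L)
      stop("no marker-positive assembly on the tree; cannot prune")
    if (length(pos_on_tree) >= 2L) pruned <- mrcaSubtree(tree, pos_on_tree)
    universe <- intersect(pruned$tip.label, phylum_asm)
  }
  in_uni <- flt$retained$assembly_id %in% universe
  base <- partitionCohorts(flt$retained[in_uni, , drop = FALSE], universe)
  if (!length(positiveAssemblies(base)))
    stop("marker-positive cohort is empty")
  if (!length(negativeAssemblies(base)))
    stop("marker-negative cohort is empty")
  not_in_uni <- setdiff(phylum_asm, universe)
  partition <- CohortPartition(
    positive = positiveAssemblies(base),
    negative = negativeAssemblies(base),
    excluded = c(excludedAssemblies(base),
                 structure(rep("outside_taxon", length(flt$excluded)),
                           names = flt$excluded),
                 structure(rep("not_in_universe", length(not_in_uni)),
                           names = not_in_uni)))
  list(partition = partition, universe = universe, prunedTree = pruned)
}

#' Prune a species tree to the minimal clade spanning marked tips
#'
#' Returns the clade rooted at the most recent common ancestor (MRCA) of
#' \code{markedTips}: the smallest subtree containing all of them. All tips
#' descending from the MRCA are retained, marked or not, and branch lengths
#' are preserved; this is how the analysis universe is restricted to the
#' part of the tree where the marker occurs.
#'
#' @param tree an \code{ape::phylo} tree with unique tip labels.
#' @param markedTips character vector of at least two tip labels, all
#'   present in the tree. (The clade spanned by a single tip is just that
#'   tip and cannot be represented as a tree.)
#' @return an \code{ape::phylo} tree; the whole tree when the MRCA is the
#'   root. Idempotent: pruning the pruned tree with the same tips returns
#'   an identical tree.
#' @examples
#' tr <- ape::read.tree(text = "(((A,B),C),D);")
#' mrcaSubtree(tr, c("A", "C"))$tip.label  # A, B, C
#' @export
mrcaSubtree <- function(tree, markedTips) {
  stopifnot(inherits(tree, "phylo"))
  markedTips <- unique(as.character(markedTips))
  if (length(markedTips) == 0L) stop("'markedTips' must be non-empty")
  missing <- setdiff(markedTips, tree$tip.label)
  if (length(missing))
    stop("marked tip(s) absent from tree: ", paste(missing, collapse = ", "))
  if (length(markedTips) < 2L)
    stop("need at least two marked tips to define an MRCA clade")
  mrca <- ape::getMRCA(tree, markedTips)
  root <- ape::Ntip(tree) + 1L
  if (mrca == root) return(tree)
  ape::extract.clade(tree, mrca)
}
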