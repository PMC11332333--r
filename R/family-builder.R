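# Protein family construction from homology hits, cluster maps and
# profile-HMM hits, and per-assembly paralog counting.

#' Build protein families from reference-query homology hits
#'
#' For each distinct query, the set of all its hits passing the e-value
#' cutoff is taken as one protein family; members are distinct
#' (assembly, subject) pairs, so repeated local alignments of the same pair
#' collapse to one member. The cutoff is inclusive (\code{e_value <=
#' evalueMax}), matching the search tools' own \code{--evalue} semantics.
#' Queries are deliberately not merged when their hit sets overlap: one
#' family per query. A query whose hits all fail the cutoff yields no
#' family and is reported with a warning.
#'
#' @param hits data.frame from [readProteinHits()].
#' @param evalueMax inclusive e-value cutoff (default \code{1e-10}).
#' @return named list of [ProteinFamily-class] objects, one per query with
#'   at least one passing hit, ordered by family id.
#' @export
familiesFromHits <- function(hits, evalueMax = 1e-10) {
  stopifnot(is.data.frame(hits))
  if (length(evalueMax) != 1L || is.na(evalueMax) || evalueMax <= 0)
    stop("'evalueMax' must be a single positive number")
  if (nrow(hits) == 0L) return(structure(list(), names = character()))
  pass <- hits[hits$e_value <= evalueMax, , drop = FALSE]
  dropped <- setdiff(unique(hits$query_id), unique(pass$query_id))
  if (length(dropped))
    warning(length(dropped), " quer", if (length(dropped) == 1L) "y" else "ies",
            " with no hit passing e <= ", format(evalueMax),
            " yielded no family")
  fams <- lapply(split(pass, pass$query_id), function(h)
    ProteinFamily(h$query_id[1L], h$subject_assembly_id, h$subject_id))
  fams[order(names(fams))]
}

#' Build protein families from a cluster membership map
#'
#' Each cluster with at least \code{minClusterSize} member proteins becomes
#' a family named after its representative; smaller clusters are discarded
#' and counted. The discarded representatives are attached to the result as
#' \code{attr(, "discarded")}.
#'
#' @param cmap named list from [readClusterMap()].
#' @param proteinToAssembly named character vector mapping protein id to
#'   assembly id.
#' @param minClusterSize minimum member count to keep a cluster (default 5).
#' @param onUnmapped \code{"error"} (default) or \code{"skip"} unresolvable
#'   members.
#' @return named list of [ProteinFamily-class]; \code{attr(, "discarded")}
#'   holds the representatives of discarded small clusters.
#' @export
familiesFromClusters <- function(cmap, proteinToAssembly,
                                 minClusterSize = 5L,
                                 onUnmapped = c("error", "skip")) {
  onUnmapped <- match.arg(onUnmapped)
  stopifnot(is.list(cmap))
  if (length(minClusterSize) != 1L || is.na(minClusterSize) || minClusterSize < 1)
    stop("'minClusterSize' must be a single integer >= 1")
  keep <- vapply(cmap, length, 0L) >= minClusterSize
  discarded <- names(cmap)[!keep]
  fams <- lapply(names(cmap)[keep], function(rep_id) {
    members <- cmap[[rep_id]]
    asm <- unname(proteinToAssembly[members])
    if (anyNA(asm)) {
      if (onUnmapped == "error")
        stop("cluster ", sQuote(rep_id), " has member(s) with no assembly mapping: ",
             paste(utils::head(members[is.na(asm)], 5L), collapse = ", "))
      warning(sum(is.na(asm)), " unmappable member(s) skipped in cluster ",
              sQuote(rep_id))
      members <- members[!is.na(asm)]
      asm <- asm[!is.na(asm)]
    }
    if (!length(members)) return(NULL)
    ProteinFamily(rep_id, asm, members)
  })
  names(fams) <- names(cmap)[keep]
  fams <- fams[!vapply(fams, is.null, TRUE)]
  if (length(fams)) fams <- fams[order(names(fams))]
  attr(fams, "discarded") <- discarded
  fams
}

#' Build one protein family from profile-HMM hits above a bit-score cutoff
#'
#' Members are the distinct (assembly, target) pairs whose full-sequence
#' bit score is at least \code{bitMin} (inclusive). Per-model cutoffs are
#' explicit inputs: they encode a judgment made from the score histogram
#' ([scoreHistogram()]) and gene context, which this package does not
#' automate.
#'
#' @param hits data.frame from [readHmmHits()]; records for one model.
#' @param model the model name; hits with a different \code{query_id} are
#'   an error.
#' @param bitMin required inclusive bit-score cutoff for this model.
#' @return A [ProteinFamily-class], or \code{NULL} (with a warning) when no
#'   hit passes.
#' @export
familyFromHmmHits <- function(hits, model, bitMin) {
  stopifnot(is.data.frame(hits), length(model) == 1L)
  if (missing(bitMin) || length(bitMin) != 1L || is.na(bitMin))
    stop("a bit-score cutoff ('bitMin') must be set for model ", sQuote(model))
  if (nrow(hits) && !all(hits$query_id == model))
    stop("hits contain records for other models than ", sQuote(model))
  pass <- hits[hits$bit_score >= bitMin, , drop = FALSE]
  if (nrow(pass) == 0L) {
    warning("no hit of model ", sQuote(model), " passes bit score >= ", bitMin,
            "; empty family dropped")
    return(NULL)
  }
  ProteinFamily(model, pass$subject_assembly_id, pass$subject_id)
}

#' Count paralogs of a family per genome assembly
#'
#' For each assembly of the universe, the number of distinct member
#' proteins the family has in that assembly; assemblies with no member get
#' an explicit 0. There is no cap on the count. Members whose assembly lies
#' outside the universe are dropped with a warning.
#'
#' @param family a [ProteinFamily-class].
#' @param universe character vector of assembly ids.
#' @return named integer vector over \code{universe}.
#' @examples
#' fam <- ProteinFamily("q1", c("A", "A", "B"), c("p1", "p2", "p3"))
#' countParalogs(fam, universe = c("A", "B", "C"))
#' @export
countParalogs <- function(family, universe) {
  stopifnot(is(family, "ProteinFamily"))
  universe <- unique(as.character(universe))
  m <- familyMembers(family)
  outside <- setdiff(unique(m$assembly_id), universe)
  if (length(outside)) {
    warning("dropping ", sum(m$assembly_id %in% outside),
            " member(s) in assemblies outside the universe: ",
            paste(utils::head(outside, 5L), collapse = ", "))
    m <- m[!m$assembly_id %in% outside, , drop = FALSE]
  }
  counts <- structure(integer(length(universe)), names = universe)
  if (nrow(m)) {
    tab <- table(m$assembly_id)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Assemble a presence/count matrix from a list of families
#'
#' Rows are the universe assemblies, columns the families, cells the
#' per-assembly paralog counts ([countParalogs()]); presence for profiling
#' is count >= 1, so the same matrix serves presence and paralog analyses.
#'
#' @param families list of [ProteinFamily-class] objects.
#' @param universe character vector of assembly ids.
#' @return integer matrix (assemblies x families).
#' @export
presenceMatrixFromFamilies <- function(families, universe) {
  universe <- unique(as.character(universe))
  ids <- vapply(families, familyId, "")
  m <- matrix(0L, nrow = length(universe), ncol = length(families),
              dimnames = list(universe, ids))
  for (j in seq_along(families))
    m[, j] <- suppressWarnings(countParalogs(families[[j]], universe))
  m
}
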