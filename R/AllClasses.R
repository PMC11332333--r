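#' @import methods
NULL

#' Cohort partition of genome assemblies around an RNA marker
#'
#' An S4 container holding the two analysis cohorts of a marker-anchored
#' phylogenetic-profiling run: assemblies carrying a full-length copy of the
#' marker RNA gene (\code{positive}), assemblies carrying no copy of any
#' category (\code{negative}), and assemblies set aside from both cohorts
#' with an explicit reason (\code{excluded}).
#'
#' The three sets are pairwise disjoint and together cover every assembly
#' that entered the analysis. Exclusion reasons are one of
#' \code{"variant_carrier"} (the assembly carries a variant-category RNA,
#' so it belongs to neither cohort), \code{"outside_taxon"} (outside the
#' allowed phylum) or \code{"not_in_universe"} (inside the phylum but
#' outside the analysis universe, e.g. outside the pruned species subtree).
#'
#' @slot positive character vector of marker-positive assembly accessions.
#' @slot negative character vector of marker-negative assembly accessions.
#' @slot excluded named character vector; names are assembly accessions,
#'   values are exclusion reasons.
#'
#' @seealso [partitionCohorts()], [makeCohorts()], [jointCounts()]
#' @export
setClass("CohortPartition",
  representation(
    positive = "character",
    negative = "character",
    excluded = "character"
  )
)

.validCohortPartition <- function(object) {
  msgs <- character()
  pos <- object@positive
  neg <- object@negative
  exc <- names(object@excluded)
  if (anyDuplicated(pos)) msgs <- c(msgs, "duplicate assemblies in 'positive'")
  if (anyDuplicated(neg)) msgs <- c(msgs, "duplicate assemblies in 'negative'")
  if (anyDuplicated(exc)) msgs <- c(msgs, "duplicate assemblies in 'excluded'")
  if (length(intersect(pos, neg)) ||
      length(intersect(pos, exc)) ||
      length(intersect(neg, exc))) {
    msgs <- c(msgs, "'positive', 'negative' and 'excluded' must be pairwise disjoint")
  }
  bad <- setdiff(object@excluded,
                 c("variant_carrier", "outside_taxon", "not_in_universe"))
  if (length(bad)) {
    msgs <- c(msgs, paste0("unknown exclusion reason(s): ",
                           paste(unique(bad), collapse = ", ")))
  }
  if (length(object@excluded) && is.null(names(object@excluded))) {
    msgs <- c(msgs, "'excluded' must be named by assembly id")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("CohortPartition", .validCohortPartition)

#' Construct a CohortPartition
#'
#' @param positive character vector of marker-positive assembly ids.
#' @param negative character vector of marker-negative assembly ids.
#' @param excluded named character vector mapping assembly id to exclusion
#'   reason (\code{"variant_carrier"}, \code{"outside_taxon"} or
#'   \code{"not_in_universe"}).
#' @return A [CohortPartition-class] object.
#' @examples
#' CohortPartition(positive = "A", negative = c("B", "D"),
#'                 excluded = c(C = "variant_carrier"))
#' @export
CohortPartition <- function(positive = character(), negative = character(),
                            excluded = character()) {
  if (length(excluded) && is.null(names(excluded)))
    stop("'excluded' must be a named character vector (assembly -> reason)")
  new("CohortPartition",
      positive = as.character(positive),
      negative = as.character(negative),
      excluded = structure(as.character(excluded), names = names(excluded)))
}

#' @describeIn CohortPartition-class marker-positive assembly ids
#' @param x,object a \code{CohortPartition}
#' @export
setGeneric("positiveAssemblies", function(x) standardGeneric("positiveAssemblies"))
#' @export
setMethod("positiveAssemblies", "CohortPartition", function(x) x@positive)

#' @describeIn CohortPartition-class marker-negative assembly ids
#' @export
setGeneric("negativeAssemblies", function(x) standardGeneric("negativeAssemblies"))
#' @export
setMethod("negativeAssemblies", "CohortPartition", function(x) x@negative)

#' @describeIn CohortPartition-class named vector of exclusion reasons
#' @export
setGeneric("excludedAssemblies", function(x) standardGeneric("excludedAssemblies"))
#' @export
setMethod("excludedAssemblies", "CohortPartition", function(x) x@excluded)

setMethod("show", "CohortPartition", function(object) {
  cat("CohortPartition\n")
  cat("  positive:", length(object@positive), "assemblies\n")
  cat("  negative:", length(object@negative), "assemblies\n")
  if (length(object@excluded)) {
    tab <- table(object@excluded)
    cat("  excluded:", length(object@excluded), "(",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        ")\n")
  } else {
    cat("  excluded: 0\n")
  }
})

#' A protein family: a named set of (assembly, protein) members
#'
#' Families arise three ways in this package: from all homology-search hits
#' of one reference query at an e-value cutoff
#' ([familiesFromHits()]), from a cluster map
#' ([familiesFromClusters()]), or from profile-HMM hits above a bit-score
#' threshold ([familyFromHmmHits()]). In every case the family is a set:
#' duplicate (assembly, protein) pairs are collapsed.
#'
#' @slot familyId single character: the reference query id, the cluster
#'   representative id, or the HMM model name.
#' @slot members data.frame with character columns \code{assembly_id} and
#'   \code{protein_id}; rows are unique pairs and there is at least one row.
#'
#' @seealso [countParalogs()], [jointCounts()]
#' @export
setClass("ProteinFamily",
  representation(
    familyId = "character",
    members = "data.frame"
  )
)

.validProteinFamily <- function(object) {
  msgs <- character()
  if (length(object@familyId) != 1L || is.na(object@familyId) ||
      !nzchar(object@familyId))
    msgs <- c(msgs, "'familyId' must be a single non-empty string")
  m <- object@members
  if (!all(c("assembly_id", "protein_id") %in% names(m))) {
    msgs <- c(msgs, "'members' needs columns assembly_id, protein_id")
  } else {
    if (nrow(m) == 0L) msgs <- c(msgs, "family must have at least one member")
    if (anyDuplicated(m[, c("assembly_id", "protein_id")]))
      msgs <- c(msgs, "duplicate (assembly_id, protein_id) members")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("ProteinFamily", .validProteinFamily)

#' Construct a ProteinFamily
#'
#' @param familyId single character id.
#' @param assembly_id,protein_id parallel character vectors of members;
#'   duplicate pairs are collapsed.
#' @return A [ProteinFamily-class] object.
#' @examples
#' fam <- ProteinFamily("q1", c("A", "A", "B"), c("p1", "p2", "p3"))
#' familySize(fam)
#' @export
ProteinFamily <- function(familyId, assembly_id, protein_id) {
  m <- unique(data.frame(assembly_id = as.character(assembly_id),
                         protein_id = as.character(protein_id),
                         stringsAsFactors = FALSE))
  m <- m[order(m$assembly_id, m$protein_id), , drop = FALSE]
  rownames(m) <- NULL
  new("ProteinFamily", familyId = as.character(familyId), members = m)
}

#' @describeIn ProteinFamily-class the family id
#' @param x,object a \code{ProteinFamily}
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @export
setMethod("familyId", "ProteinFamily", function(x) x@familyId)

#' @describeIn ProteinFamily-class member table (assembly_id, protein_id)
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))
#' @export
setMethod("familyMembers", "ProteinFamily", function(x) x@members)

#' @describeIn ProteinFamily-class number of member proteins
#' @export
setGeneric("familySize", function(x) standardGeneric("familySize"))
#' @export
setMethod("familySize", "ProteinFamily", function(x) nrow(x@members))

#' @describeIn ProteinFamily-class assemblies with at least one member
#' @export
setGeneric("familyAssemblies", function(x) standardGeneric("familyAssemblies"))
#' @export
setMethod("familyAssemblies", "ProteinFamily",
          function(x) unique(x@members$assembly_id))

setMethod("show", "ProteinFamily", function(object) {
  cat("ProteinFamily", sQuote(object@familyId), "\n")
  cat("  ", nrow(object@members), " proteins in ",
      length(unique(object@members$assembly_id)), " assemblies\n", sep = "")
})

#' The 2x2 marker/family presence contingency table
#'
#' Cell \code{nXY} counts assemblies where the marker-presence indicator X
#' takes value x and the family-presence indicator Y takes value y
#' (1 = present, 0 = absent). \code{n11} is the number of marker-positive
#' assemblies with at least one family member; \code{n10} marker-positive
#' without; \code{n01} marker-negative with; \code{n00} marker-negative
#' without. Assemblies excluded from the partition contribute to no cell.
#'
#' @slot n00,n01,n10,n11 single non-negative integers.
#' @seealso [jointCounts()], [groupFractions()], [mutualInformation()]
#' @export
setClass("JointCounts",
  representation(n00 = "integer", n01 = "integer",
                 n10 = "integer", n11 = "integer")
)

.validJointCounts <- function(object) {
  n <- c(object@n00, object@n01, object@n10, object@n11)
  if (length(n) != 4L || anyNA(n)) return("all four cells must be single integers")
  if (any(n < 0L)) return("cell counts must be non-negative")
  TRUE
}
setValidity("JointCounts", .validJointCounts)

#' Construct a JointCounts table
#'
#' @param n00,n01,n10,n11 non-negative integer cell counts; \code{nXY} is
#'   the number of assemblies with marker status x and family status y.
#' @return A [JointCounts-class] object.
#' @examples
#' jc <- JointCounts(n00 = 40, n01 = 10, n10 = 10, n11 = 40)
#' mutualInformation(jc)
#' @export
JointCounts <- function(n00, n01, n10, n11) {
  as_count <- function(v, what) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != as.integer(v))
      stop("'", what, "' must be a single non-negative integer")
    as.integer(v)
  }
  new("JointCounts",
      n00 = as_count(n00, "n00"), n01 = as_count(n01, "n01"),
      n10 = as_count(n10, "n10"), n11 = as_count(n11, "n11"))
}

#' @describeIn JointCounts-class cells as a named integer vector
#' @param x,object a \code{JointCounts}
#' @export
setGeneric("jointCells", function(x) standardGeneric("jointCells"))
#' @export
setMethod("jointCells", "JointCounts", function(x)
  c(n00 = x@n00, n01 = x@n01, n10 = x@n10, n11 = x@n11))

#' @describeIn JointCounts-class total number of assemblies N
#' @export
setGeneric("totalN", function(x) standardGeneric("totalN"))
#' @export
setMethod("totalN", "JointCounts", function(x)
  x@n00 + x@n01 + x@n10 + x@n11)

setMethod("show", "JointCounts", function(object) {
  m <- matrix(c(object@n00, object@n01, object@n10, object@n11),
              nrow = 2, byrow = TRUE,
              dimnames = list(marker = c("0", "1"), family = c("0", "1")))
  cat("JointCounts (N =", totalN(object), ")\n")
  print(m)
})
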