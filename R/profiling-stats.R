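# Per-family cohort presence fractions, the 2x2 joint distribution against
# marker status, binary mutual information (log base 2), and plot-ready
# rankings.

#' Tabulate family presence against marker status
#'
#' Crosses a family's presence/absence pattern with the cohort partition
#' into the 2x2 contingency table: \code{n11} marker-positive assemblies
#' containing at least one family member, \code{n10} marker-positive
#' without, \code{n01}/\code{n00} likewise for the marker-negative cohort.
#' Excluded assemblies (variant carriers etc.) contribute to no cell.
#'
#' @param family a [ProteinFamily-class], or a character vector of assembly
#'   ids in which the family is present.
#' @param partition a [CohortPartition-class]; both cohorts must be
#'   non-empty.
#' @return A [JointCounts-class].
#' @export
jointCounts <- function(family, partition) {
  stopifnot(is(partition, "CohortPartition"))
  pos <- positiveAssemblies(partition)
  neg <- negativeAssemblies(partition)
  if (!length(pos) || !length(neg))
    stop("both cohorts must be non-empty to form a contingency table")
  present <- if (is(family, "ProteinFamily")) familyAssemblies(family)
             else unique(as.character(family))
  n11 <- length(intersect(pos, present))
  n01 <- length(intersect(neg, present))
  JointCounts(n00 = length(neg) - n01, n01 = n01,
              n10 = length(pos) - n11, n11 = n11)
}

#' Fractional presence in each cohort
#'
#' The proportion of marker-positive and of marker-negative assemblies that
#' contain at least one family member; the coordinates of the fractional
#' presence scatter.
#'
#' @param jc a [JointCounts-class]; both cohort sizes must be >= 1.
#' @return named numeric vector \code{c(f_pos =, f_neg =)}, both in [0, 1].
#' @examples
#' groupFractions(JointCounts(n00 = 8, n01 = 2, n10 = 1, n11 = 9))
#' @export
groupFractions <- function(jc) {
  stopifnot(is(jc, "JointCounts"))
  npos <- jc@n11 + jc@n10
  nneg <- jc@n01 + jc@n00
  if (npos == 0L || nneg == 0L) stop("cohort sizes must both be >= 1")
  c(f_pos = jc@n11 / npos, f_neg = jc@n01 / nneg)
}

#' Binary mutual information of a 2x2 table, in bits
#'
#' Evaluates \deqn{I(X;Y) = \sum_{x,y \in \{0,1\}} p_{x,y} \log_2
#' \frac{p_{x,y}}{p(x)\,p(y)}}{I(X;Y) = sum p_xy log2(p_xy / (p(x) p(y)))}
#' with \eqn{p_{x,y} = n_{x,y}/N} and marginals summed from the table, as
#' the expanded four-term sum. Log base 2 throughout, so the result is in
#' bits and, for binary variables, lies in [0, 1].
#'
#' Two conventions for vanishing cells:
#' \describe{
#'   \item{\code{"discard"} (default)}{if any term's logarithm operand is
#'     zero or undefined — any \eqn{p_{x,y} = 0}, or a zero marginal — the
#'     whole calculation is discarded and \code{NA} is returned. Note this
#'     silences exactly the strongest, perfect-association tables.}
#'   \item{\code{"limit"}}{the usual information-theoretic limit
#'     \eqn{0 \log 0 = 0}: zero-probability terms contribute 0, and a
#'     degenerate marginal gives I = 0.}
#' }
#'
#' @param jc a [JointCounts-class] with N >= 1.
#' @param zeroMode \code{"discard"} or \code{"limit"}.
#' @return mutual information in bits, or \code{NA_real_} under the discard
#'   rule.
#' @examples
#' mutualInformation(JointCounts(25, 25, 25, 25))            # 0 (independent)
#' mutualInformation(JointCounts(50, 0, 0, 50), zeroMode = "limit")   # 1 bit
#' mutualInformation(JointCounts(50, 0, 0, 50))                       # NA
#' @export
mutualInformation <- function(jc, zeroMode = c("discard", "limit")) {
  stopifnot(is(jc, "JointCounts"))
  zeroMode <- match.arg(zeroMode)
  N <- totalN(jc)
  if (N == 0L) stop("empty table: N must be >= 1")
  p00 <- jc@n00 / N; p01 <- jc@n01 / N
  p10 <- jc@n10 / N; p11 <- jc@n11 / N
  px0 <- p00 + p01; px1 <- p10 + p11   # marker marginal
  py0 <- p00 + p10; py1 <- p01 + p11   # family marginal
  p <- c(p00, p01, p10, p11)
  marg <- c(px0 * py0, px0 * py1, px1 * py0, px1 * py1)
  if (zeroMode == "discard") {
    if (any(p == 0) || any(c(px0, px1, py0, py1) == 0)) return(NA_real_)
    return(.clamp_mi(sum(p * log2(p / marg))))
  }
  nz <- p > 0
  .clamp_mi(sum(p[nz] * log2(p[nz] / marg[nz])))
}

# the four-term sum can land a few ulp below zero on exactly independent
# tables; MI is non-negative, so snap such round-off to 0
.clamp_mi <- function(v) if (v < 0 && v > -1e-9) 0 else v

#' Profile a set of families against the cohort partition
#'
#' Computes, for every family, the 2x2 joint counts, the cohort presence
#' fractions, the mutual information in bits, and the direction of the
#' association: \code{correlated} when the family is proportionally more
#' common among marker-positive assemblies (f_pos > f_neg),
#' \code{anticorrelated} when less common, \code{neutral} when equal.
#' Families whose MI is discarded under the \code{"discard"} rule are kept
#' in the output with \code{mi_bits = NA}, not dropped, so scatter plots
#' stay complete. Rows are ranked by [rankProfiles()].
#'
#' @param families list of [ProteinFamily-class] objects.
#' @param partition a [CohortPartition-class].
#' @param zeroMode passed to [mutualInformation()].
#' @return data.frame with columns \code{family_id}, \code{f_pos},
#'   \code{f_neg}, \code{n11}, \code{n10}, \code{n01}, \code{n00},
#'   \code{mi_bits}, \code{direction}, \code{rank}, ordered by rank.
#' @export
profileFamilies <- function(families, partition,
                            zeroMode = c("discard", "limit")) {
  zeroMode <- match.arg(zeroMode)
  stopifnot(is(partition, "CohortPartition"))
  rows <- lapply(families, function(fam) {
    jc <- jointCounts(fam, partition)
    fr <- groupFractions(jc)
    data.frame(family_id = familyId(fam),
               f_pos = fr[["f_pos"]], f_neg = fr[["f_neg"]],
               n11 = jc@n11, n10 = jc@n10, n01 = jc@n01, n00 = jc@n00,
               mi_bits = mutualInformation(jc, zeroMode),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), f_pos = numeric(), f_neg = numeric(),
               n11 = integer(), n10 = integer(), n01 = integer(),
               n00 = integer(), mi_bits = numeric(), stringsAsFactors = FALSE)
  out$direction <- ifelse(out$f_pos > out$f_neg, "correlated",
                          ifelse(out$f_pos < out$f_neg, "anticorrelated",
                                 "neutral"))
  rankProfiles(out)
}

#' Profile the columns of a presence/count matrix
#'
#' Same computation as [profileFamilies()], but starting from an
#' assembly-by-family count matrix (e.g. a simulated one from
#' [plantFamilies()], or [presenceMatrixFromFamilies()] output): a family
#' is present in an assembly when its cell is >= 1.
#'
#' @param m integer matrix, rows = assemblies, columns = families.
#' @param partition a [CohortPartition-class].
#' @param zeroMode passed to [mutualInformation()].
#' @return ranked data.frame as [profileFamilies()].
#' @export
profilePresenceMatrix <- function(m, partition,
                                  zeroMode = c("discard", "limit")) {
  zeroMode <- match.arg(zeroMode)
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)),
            is(partition, "CohortPartition"))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    jc <- jointCounts(rownames(m)[m[, j] >= 1L], partition)
    fr <- groupFractions(jc)
    data.frame(family_id = colnames(m)[j],
               f_pos = fr[["f_pos"]], f_neg = fr[["f_neg"]],
               n11 = jc@n11, n10 = jc@n10, n01 = jc@n01, n00 = jc@n00,
               mi_bits = mutualInformation(jc, zeroMode),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), f_pos = numeric(), f_neg = numeric(),
               n11 = integer(), n10 = integer(), n01 = integer(),
               n00 = integer(), mi_bits = numeric(), stringsAsFactors = FALSE)
  out$direction <- ifelse(out$f_pos > out$f_neg, "correlated",
                          ifelse(out$f_pos < out$f_neg, "anticorrelated",
                                 "neutral"))
  rankProfiles(out)
}

#' Rank profiled families by mutual information
#'
#' Orders descending by \code{mi_bits}; ties are broken by the absolute
#' fraction gap \code{|f_pos - f_neg|} descending, then by family id, so
#' the ranking is deterministic. Families with undefined (discarded) MI are
#' segregated to the tail, ordered by the same tie-breaks.
#'
#' @param profiles data.frame with columns \code{family_id}, \code{f_pos},
#'   \code{f_neg}, \code{mi_bits} (others are carried through).
#' @return the same data.frame ordered, with a \code{rank} column (1-based).
#' @export
rankProfiles <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("family_id", "f_pos", "f_neg", "mi_bits") %in% names(profiles)))
  gap <- abs(profiles$f_pos - profiles$f_neg)
  mi_key <- ifelse(is.na(profiles$mi_bits), -Inf, profiles$mi_bits)
  ord <- order(is.na(profiles$mi_bits), -mi_key, -gap, profiles$family_id)
  out <- profiles[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Plot-ready coordinates for the fractional-presence scatter
#'
#' One point per family: x = fraction of marker-negative assemblies with a
#' member, y = the marker-positive fraction. Correlated families sit above
#' the diagonal, anticorrelated below.
#'
#' @param profiles output of [profileFamilies()].
#' @return data.frame with columns \code{f_neg}, \code{f_pos},
#'   \code{family_id}.
#' @export
scatterData <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("family_id", "f_pos", "f_neg") %in% names(profiles)))
  data.frame(f_neg = profiles$f_neg, f_pos = profiles$f_pos,
             family_id = profiles$family_id, stringsAsFactors = FALSE)
}

#' Plot-ready paralog-count multisets per cohort
#'
#' The per-assembly paralog counts of one family, split by cohort — the
#' data behind a violin/strip plot of copy number categorized by marker
#' presence. Excluded assemblies are omitted.
#'
#' @param counts named integer vector from [countParalogs()].
#' @param partition a [CohortPartition-class].
#' @return data.frame with columns \code{cohort}
#'   (\code{"positive"}/\code{"negative"}), \code{assembly_id},
#'   \code{count}.
#' @export
violinData <- function(counts, partition) {
  stopifnot(is(partition, "CohortPartition"), !is.null(names(counts)))
  pick <- function(ids, label) {
    ids <- intersect(ids, names(counts))
    data.frame(cohort = rep(label, length(ids)), assembly_id = ids,
               count = as.integer(counts[ids]), stringsAsFactors = FALSE)
  }
  out <- rbind(pick(positiveAssemblies(partition), "positive"),
               pick(negativeAssemblies(partition), "negative"))
  rownames(out) <- NULL
  out
}
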