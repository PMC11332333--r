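# Bit-score/truncation classification of covariance-model RNA hits and
# per-assembly status calls.

#' Category thresholds for RNA hit classification
#'
#' The three bit-score cutoffs separating full-length hits from the two
#' shorter variant categories. Defaults are the cutoffs chosen from the
#' bit-score histogram of the marker RNA search: nontruncated hits scoring
#' at least 390 bits are full-length, at least 310 and below 390 variant 1,
#' and at least 235 and below 310 variant 2; truncated hits scoring at
#' least 235 are variant 2 regardless of score. Lower bounds are inclusive,
#' upper bounds exclusive.
#'
#' @param fullMin,v1Min,v2Min bit-score lower bounds; must satisfy
#'   \code{fullMin > v1Min > v2Min > 0}.
#' @return named numeric vector of class \code{"RnaThresholds"}.
#' @examples
#' rnaThresholds()
#' classifyHits(data.frame(bit_score = 400, truncation = "none"))
#' @export
rnaThresholds <- function(fullMin = 390.0, v1Min = 310.0, v2Min = 235.0) {
  t <- c(fullMin = fullMin, v1Min = v1Min, v2Min = v2Min)
  if (anyNA(t) || !all(is.finite(t)))
    stop("thresholds must be finite numbers")
  if (!(fullMin > v1Min && v1Min > v2Min && v2Min > 0))
    stop("thresholds must satisfy fullMin > v1Min > v2Min > 0")
  structure(t, class = "RnaThresholds")
}

#' Classify RNA hits into full-length / variant categories
#'
#' Applies the bit-score and truncation rules: a nontruncated hit is
#' \code{"full_length"} at or above \code{fullMin} bits, \code{"variant1"}
#' in \code{[v1Min, fullMin)}, \code{"variant2"} in \code{[v2Min, v1Min)};
#' a truncated hit (clipped at the 5', 3' or both sequence ends) at or
#' above \code{v2Min} is \code{"variant2"} whatever its score, since a
#' clipped alignment cannot be assumed full length. Anything below
#' \code{v2Min} is \code{"unclassified"} and is treated downstream as no
#' marker evidence. Classification depends only on the bit score and the
#' truncation flag.
#'
#' @param hits data.frame with columns \code{bit_score} (finite numeric)
#'   and \code{truncation} (\code{"none"}, \code{"trunc5"}, \code{"trunc3"}
#'   or \code{"both"}), as returned by [readRnaHits()].
#' @param thresholds an [rnaThresholds()] object.
#' @return character vector, one of \code{"full_length"}, \code{"variant1"},
#'   \code{"variant2"}, \code{"unclassified"} per hit.
#' @export
classifyHits <- function(hits, thresholds = rnaThresholds()) {
  stopifnot(is.data.frame(hits),
            all(c("bit_score", "truncation") %in% names(hits)))
  bit <- hits$bit_score
  if (anyNA(bit) || !all(is.finite(bit))) stop("bit scores must be finite")
  ok <- hits$truncation %in% c("none", "trunc5", "trunc3", "both")
  if (!all(ok))
    stop("unknown truncation flag(s): ",
         paste(unique(hits$truncation[!ok]), collapse = ", "))
  trunc <- hits$truncation != "none"
  out <- rep("unclassified", nrow(hits))
  out[!trunc & bit >= thresholds[["fullMin"]]] <- "full_length"
  out[!trunc & bit >= thresholds[["v1Min"]] & bit < thresholds[["fullMin"]]] <- "variant1"
  out[!trunc & bit >= thresholds[["v2Min"]] & bit < thresholds[["v1Min"]]] <- "variant2"
  out[trunc & bit >= thresholds[["v2Min"]]] <- "variant2"
  out
}

.category_rank <- c(full_length = 1L, variant1 = 2L, variant2 = 3L)

#' Call one RNA status per assembly from its hits
#'
#' Classifies every hit, drops unclassified ones, and calls the status of
#' the best remaining hit: highest bit score, ties broken by category
#' precedence (full_length > variant1 > variant2), then by target sequence
#' id, so the call is deterministic and independent of input order. An
#' assembly with no classified hit is \code{"absent"}.
#'
#' @param hits data.frame of RNA hits for a single assembly
#'   (all \code{assembly_id} equal), as from [readRnaHits()].
#' @param thresholds an [rnaThresholds()] object.
#' @return one-row data.frame: \code{assembly_id}, \code{status}
#'   (\code{full_length}/\code{variant1}/\code{variant2}/\code{absent}),
#'   \code{best_bit_score}, \code{best_target} (NA when absent).
#' @seealso [assemblyStatuses()] for a whole hit table at once.
#' @export
assignAssemblyStatus <- function(hits, thresholds = rnaThresholds()) {
  stopifnot(is.data.frame(hits))
  aid <- unique(hits$assembly_id)
  if (length(aid) > 1L)
    stop("hits span multiple assemblies: ", paste(aid, collapse = ", "))
  if (length(aid) == 0L) stop("no hits and no assembly id; use assemblyStatuses()")
  cat_ <- classifyHits(hits, thresholds)
  keep <- cat_ != "unclassified"
  if (!any(keep)) {
    return(data.frame(assembly_id = aid, status = "absent",
                      best_bit_score = NA_real_, best_target = NA_character_,
                      stringsAsFactors = FALSE))
  }
  h <- hits[keep, , drop = FALSE]
  k <- cat_[keep]
  ord <- order(-h$bit_score, .category_rank[k], h$target_seq_id)
  best <- ord[1L]
  data.frame(assembly_id = aid, status = k[best],
             best_bit_score = h$bit_score[best],
             best_target = h$target_seq_id[best], stringsAsFactors = FALSE)
}

#' Per-assembly RNA status table for a full hit set
#'
#' Applies [assignAssemblyStatus()] to each assembly appearing in the hit
#' table. Assemblies with no hits at all do not appear; downstream the
#' partition treats any universe assembly without a status row as
#' marker-negative.
#'
#' @inheritParams assignAssemblyStatus
#' @param hits data.frame of RNA hits (any number of assemblies).
#' @return data.frame with one row per assembly, columns as
#'   [assignAssemblyStatus()], ordered by \code{assembly_id}.
#' @export
assemblyStatuses <- function(hits, thresholds = rnaThresholds()) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L)
    return(data.frame(assembly_id = character(), status = character(),
                      best_bit_score = numeric(), best_target = character(),
                      stringsAsFactors = FALSE))
  pieces <- lapply(split(hits, hits$assembly_id), assignAssemblyStatus,
                   thresholds = thresholds)
  out <- do.call(rbind, pieces)
  out <- out[order(out$assembly_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of hit bit scores
#'
#' Bins are half-open \code{[edge, edge + binWidth)} with edges at integer
#' multiples of \code{binWidth}, the binning used to choose category
#' cutoffs from the score distribution. Truncated and nontruncated hits can
#' be histogrammed separately, mirroring how the cutoffs were picked from
#' the nontruncated distribution.
#'
#' @param hits data.frame with \code{bit_score} (and \code{truncation} when
#'   \code{truncatedSeparately}).
#' @param binWidth positive bin width in bits.
#' @param truncatedSeparately logical; when TRUE, return one histogram per
#'   truncation group.
#' @return data.frame with columns \code{bin_lower} and \code{count}
#'   (plus \code{group} = \code{"nontruncated"}/\code{"truncated"} when
#'   split); only non-empty bins are listed.
#' @export
scoreHistogram <- function(hits, binWidth, truncatedSeparately = FALSE) {
  if (length(binWidth) != 1L || is.na(binWidth) || binWidth <= 0)
    stop("'binWidth' must be a single positive number")
  one <- function(scores, group = NULL) {
    if (!length(scores)) {
      out <- data.frame(bin_lower = numeric(), count = integer())
    } else {
      edges <- floor(scores / binWidth) * binWidth
      tab <- table(edges)
      out <- data.frame(bin_lower = as.numeric(names(tab)),
                        count = as.integer(tab))
      out <- out[order(out$bin_lower), , drop = FALSE]
    }
    if (!is.null(group) && nrow(out)) out$group <- group
    if (!is.null(group) && !nrow(out)) out$group <- character()
    out
  }
  if (!truncatedSeparately) {
    out <- one(hits$bit_score)
  } else {
    trunc <- hits$truncation != "none"
    out <- rbind(one(hits$bit_score[!trunc], "nontruncated"),
                 one(hits$bit_score[trunc], "truncated"))
  }
  rownames(out) <- NULL
  out
}
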