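# Readers/writers for the external tabular and tree formats the pipeline
# touches. All line-oriented readers skip blank lines and '#' comment lines,
# so synthetic fixtures and real tool outputs parse identically.

.read_lines <- function(con) {
  if (inherits(con, "connection")) readLines(con) else readLines(con)
}

.data_lines <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.parse_error <- function(file, lineno, what) {
  stop(sprintf("parse error at line %d%s: %s", lineno,
               if (is.null(file)) "" else paste0(" of ", sQuote(file)), what),
       call. = FALSE)
}

.map_ids <- function(ids, map, mapper, what, onUnmapped = c("error", "skip")) {
  onUnmapped <- match.arg(onUnmapped)
  if (!is.null(mapper)) {
    out <- as.character(mapper(ids))
    if (length(out) != length(ids))
      stop("the id-mapping function must be vectorized (one output per input)")
    return(list(assembly = out, keep = rep(TRUE, length(ids))))
  }
  if (is.null(map)) stop("supply either a named mapping vector or a mapping function for ", what)
  out <- unname(map[ids])
  miss <- is.na(out)
  if (any(miss)) {
    if (onUnmapped == "error")
      stop("no assembly mapping for ", what, ": ",
           paste(utils::head(unique(ids[miss]), 5L), collapse = ", "),
           if (sum(miss) > 5L) ", ..." else "")
    warning(sum(miss), " record(s) with unmappable ", what, " skipped")
  }
  list(assembly = out, keep = !miss)
}

.trunc_tokens <- c("no" = "none", "5'" = "trunc5", "3'" = "trunc3",
                   "5'&3'" = "both")

#' Read covariance-model RNA search hits (Infernal tblout dialect)
#'
#' Parses the whitespace-columnar per-hit table written by \code{cmsearch
#' --tblout}. The first 17 whitespace-separated fields are positional; the
#' remainder of each line is kept verbatim as a free-text description.
#' Coordinates are kept 1-based inclusive as emitted by the search tool.
#'
#' @param file path or connection to the tblout file.
#' @param seqToAssembly named character vector mapping target sequence id to
#'   assembly accession (e.g. from [readIdMap()]).
#' @param assemblyFromSeqId alternatively, a vectorized function deriving the
#'   assembly accession from the target sequence id (a prefix rule).
#' @return data.frame with one row per hit: \code{target_seq_id},
#'   \code{assembly_id}, \code{model_name}, \code{bit_score}, \code{e_value},
#'   \code{seq_from}, \code{seq_to}, \code{strand} (\code{"plus"}/\code{"minus"}),
#'   \code{truncation} (\code{"none"}, \code{"trunc5"}, \code{"trunc3"},
#'   \code{"both"}) and \code{description}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("# cmsearch tblout",
#'   "seqA - MARKER - cm 1 600 100 705 + no 1 0.49 0.0 412.3 1.2e-110 ! ctg"),
#'   tf)
#' readRnaHits(tf, seqToAssembly = c(seqA = "ASM1"))
#' @export
readRnaHits <- function(file, seqToAssembly = NULL, assemblyFromSeqId = NULL) {
  dl <- .data_lines(.read_lines(file))
  cols <- c("target_seq_id", "assembly_id", "model_name", "bit_score",
            "e_value", "seq_from", "seq_to", "strand", "truncation",
            "description")
  empty <- data.frame(target_seq_id = character(), assembly_id = character(),
                      model_name = character(), bit_score = numeric(),
                      e_value = numeric(), seq_from = integer(),
                      seq_to = integer(), strand = character(),
                      truncation = character(), description = character(),
                      stringsAsFactors = FALSE)
  if (!length(dl$lines)) return(empty)
  fname <- if (is.character(file)) file else NULL
  rows <- vector("list", length(dl$lines))
  for (i in seq_along(dl$lines)) {
    f <- strsplit(trimws(dl$lines[[i]]), "\\s+")[[1L]]
    if (length(f) < 17L)
      .parse_error(fname, dl$lineno[i],
                   sprintf("expected at least 17 fields, found %d", length(f)))
    trunc <- .trunc_tokens[f[11L]]
    if (is.na(trunc))
      .parse_error(fname, dl$lineno[i],
                   paste0("unknown truncation token ", sQuote(f[11L])))
    strand <- switch(f[10L], "+" = "plus", "-" = "minus",
                     .parse_error(fname, dl$lineno[i],
                                  paste0("unknown strand ", sQuote(f[10L]))))
    bit <- suppressWarnings(as.numeric(f[15L]))
    ev <- suppressWarnings(as.numeric(f[16L]))
    from <- suppressWarnings(as.integer(f[8L]))
    to <- suppressWarnings(as.integer(f[9L]))
    if (anyNA(c(bit, ev, from, to)))
      .parse_error(fname, dl$lineno[i], "non-numeric score/e-value/coordinate")
    rows[[i]] <- data.frame(
      target_seq_id = f[1L], assembly_id = NA_character_, model_name = f[3L],
      bit_score = bit, e_value = ev, seq_from = from, seq_to = to,
      strand = strand, truncation = unname(trunc),
      description = if (length(f) > 17L) paste(f[-seq_len(17L)], collapse = " ")
                    else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  mp <- .map_ids(out$target_seq_id, seqToAssembly, assemblyFromSeqId,
                 "target sequence id")
  out$assembly_id <- mp$assembly
  out <- out[mp$keep, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read 12-column tabular protein homology hits (BLAST/DIAMOND dialect)
#'
#' Expects the classic 12 columns (query, subject, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore), tab- or
#' whitespace-separated. Columns 4--10 are validated as numeric but not
#' retained. Duplicate (query, subject) records from multiple local
#' alignments are preserved; deduplication is the family builder's job.
#'
#' @param file path or connection.
#' @param proteinToAssembly named character vector mapping subject protein id
#'   to assembly accession.
#' @param assemblyFromProteinId alternatively a vectorized mapping function.
#' @param onUnmapped \code{"error"} (default) or \code{"skip"} (drop records
#'   whose subject cannot be mapped, with a warning).
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{subject_assembly_id}, \code{percent_identity}, \code{bit_score},
#'   \code{e_value}.
#' @export
readProteinHits <- function(file, proteinToAssembly = NULL,
                            assemblyFromProteinId = NULL,
                            onUnmapped = c("error", "skip")) {
  onUnmapped <- match.arg(onUnmapped)
  dl <- .data_lines(.read_lines(file))
  empty <- data.frame(query_id = character(), subject_id = character(),
                      subject_assembly_id = character(),
                      percent_identity = numeric(), bit_score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE)
  if (!length(dl$lines)) return(empty)
  fname <- if (is.character(file)) file else NULL
  parts <- strsplit(trimws(dl$lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    j <- which(nf != 12L)[1L]
    .parse_error(fname, dl$lineno[j],
                 sprintf("expected 12 columns, found %d", nf[j]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    j <- which(apply(is.na(num), 1L, any))[1L]
    .parse_error(fname, dl$lineno[j], "non-numeric value in columns 3-12")
  }
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    subject_assembly_id = NA_character_,
                    percent_identity = num[, 1L], bit_score = num[, 10L],
                    e_value = num[, 9L], stringsAsFactors = FALSE)
  if (any(out$e_value < 0) || any(out$percent_identity < 0 | out$percent_identity > 100))
    stop("invalid e-value or percent identity outside [0, 100]")
  mp <- .map_ids(out$subject_id, proteinToAssembly, assemblyFromProteinId,
                 "subject protein id", onUnmapped)
  out$subject_assembly_id <- mp$assembly
  out <- out[mp$keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read profile-HMM per-target search hits (HMMER tblout dialect)
#'
#' Parses the per-target table written by \code{hmmsearch --tblout}; the
#' target id (column 1), model name (column 3) and the full-sequence e-value
#' and bit score (columns 5 and 6) are extracted. The model name becomes the
#' \code{query_id}, matching the protein-hit table layout.
#'
#' @inheritParams readProteinHits
#' @return data.frame as [readProteinHits()] (\code{percent_identity} is
#'   \code{NA} for HMM hits).
#' @export
readHmmHits <- function(file, proteinToAssembly = NULL,
                        assemblyFromProteinId = NULL,
                        onUnmapped = c("error", "skip")) {
  onUnmapped <- match.arg(onUnmapped)
  dl <- .data_lines(.read_lines(file))
  empty <- data.frame(query_id = character(), subject_id = character(),
                      subject_assembly_id = character(),
                      percent_identity = numeric(), bit_score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE)
  if (!length(dl$lines)) return(empty)
  fname <- if (is.character(file)) file else NULL
  parts <- strsplit(trimws(dl$lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 6L)) {
    j <- which(nf < 6L)[1L]
    .parse_error(fname, dl$lineno[j],
                 sprintf("expected at least 6 fields, found %d", nf[j]))
  }
  target <- vapply(parts, `[`, "", 1L)
  model <- vapply(parts, `[`, "", 3L)
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 5L)))
  bit <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 6L)))
  if (anyNA(ev) || anyNA(bit)) {
    j <- which(is.na(ev) | is.na(bit))[1L]
    .parse_error(fname, dl$lineno[j], "non-numeric full-sequence e-value/score")
  }
  out <- data.frame(query_id = model, subject_id = target,
                    subject_assembly_id = NA_character_,
                    percent_identity = NA_real_, bit_score = bit,
                    e_value = ev, stringsAsFactors = FALSE)
  mp <- .map_ids(out$subject_id, proteinToAssembly, assemblyFromProteinId,
                 "target protein id", onUnmapped)
  out$subject_assembly_id <- mp$assembly
  out <- out[mp$keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column cluster membership map (MMseqs2 createtsv dialect)
#'
#' Each line is \code{representative<TAB>member}. Members are grouped by
#' representative; a representative is always a member of its own cluster
#' (a missing self line is tolerated and restored). A member listed under
#' two different representatives violates cluster disjointness and is an
#' error.
#'
#' @param file path or connection.
#' @return named list of character vectors: representative id to sorted
#'   member ids.
#' @export
readClusterMap <- function(file) {
  dl <- .data_lines(.read_lines(file))
  if (!length(dl$lines)) return(structure(list(), names = character()))
  fname <- if (is.character(file) && length(file) == 1L) file else NULL
  parts <- strsplit(dl$lines, "\t", fixed = TRUE)
  # tolerate whitespace-separated fixtures too
  short <- lengths(parts) != 2L
  parts[short] <- strsplit(trimws(dl$lines[short]), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    j <- which(nf != 2L)[1L]
    .parse_error(fname, dl$lineno[j],
                 sprintf("expected 2 columns, found %d", nf[j]))
  }
  rep_id <- vapply(parts, `[`, "", 1L)
  member <- vapply(parts, `[`, "", 2L)
  cmap <- lapply(split(member, rep_id), unique)
  cmap <- mapply(function(r, m) sort(unique(c(r, m))), names(cmap), cmap,
                 SIMPLIFY = FALSE)
  all_members <- unlist(cmap, use.names = FALSE)
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup))
    stop("cluster map violates disjointness; member(s) under two representatives: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  cmap[order(names(cmap))]
}

#' Read and write species trees (newick)
#'
#' Thin wrappers over \pkg{ape} that enforce the pipeline's invariants:
#' tip labels (assembly accessions) must be unique, and a file must contain
#' exactly one tree.
#'
#' @param file path to a newick file.
#' @return \code{readSpeciesTree}: an \code{ape::phylo} tree.
#' @export
readSpeciesTree <- function(file) {
  tr <- tryCatch(ape::read.tree(file),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("newick parse error: no tree in ", sQuote(file))
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected exactly one tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @rdname readSpeciesTree
#' @param tree an \code{ape::phylo} object.
#' @export
writeSpeciesTree <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Read and write an assembly-by-family presence/count matrix (TSV)
#'
#' The TSV has a header row naming an \code{assembly_id} column followed by
#' one column per family, and one row per assembly; cells are non-negative
#' integer member counts. \code{readPresenceMatrix(writePresenceMatrix(x))}
#' is the identity.
#'
#' @param file path.
#' @return \code{readPresenceMatrix}: integer matrix, rownames = assembly
#'   ids, colnames = family ids.
#' @export
readPresenceMatrix <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"assembly_id" %in% names(df))
    stop("presence matrix TSV must have an 'assembly_id' column")
  m <- as.matrix(df[, setdiff(names(df), "assembly_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 0L)) stop("presence matrix cells must be non-negative integers")
  rownames(m) <- df$assembly_id
  if (anyDuplicated(rownames(m))) stop("duplicate assembly ids in presence matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate family ids in presence matrix")
  m
}

#' @rdname readPresenceMatrix
#' @param m integer matrix (assemblies x families).
#' @export
writePresenceMatrix <- function(m, file) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have assembly rownames and family colnames")
  df <- data.frame(assembly_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an assembly taxonomy table (TSV: assembly_id, phylum, class)
#'
#' @param file path.
#' @return data.frame with character columns \code{assembly_id},
#'   \code{phylum}, \code{class}; assembly ids must be unique.
#' @export
readTaxonomy <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  need <- c("assembly_id", "phylum", "class")
  if (!all(need %in% names(df)))
    stop("taxonomy TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$assembly_id))
    stop("duplicate assembly ids in taxonomy table")
  df[, need]
}

#' Read a two-column id-to-assembly mapping (TSV)
#'
#' Used for both sequence-to-assembly and protein-to-assembly maps; hit
#' tables carry only sequence/protein ids, so the mapping is an explicit
#' input.
#'
#' @param file path; lines are \code{id<TAB>assembly_id}, '#' comments
#'   allowed.
#' @return named character vector (id to assembly id).
#' @export
readIdMap <- function(file) {
  dl <- .data_lines(.read_lines(file))
  if (!length(dl$lines)) return(structure(character(), names = character()))
  parts <- strsplit(dl$lines, "\t", fixed = TRUE)
  short <- lengths(parts) != 2L
  parts[short] <- strsplit(trimws(dl$lines[short]), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    j <- which(nf != 2L)[1L]
    .parse_error(if (is.character(file)) file else NULL, dl$lineno[j],
                 sprintf("expected 2 columns, found %d", nf[j]))
  }
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids)) {
    d <- unique(ids[duplicated(ids)])
    stop("duplicate id(s) in mapping: ", paste(utils::head(d, 5L), collapse = ", "))
  }
  structure(vapply(parts, `[`, "", 2L), names = ids)
}
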