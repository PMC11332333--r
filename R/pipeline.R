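# End-to-end orchestration: parse -> classify -> partition -> build
# families -> joint counts -> fractions -> MI -> rank, with a run manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

#' Configuration of a profiling run
#'
#' Bundles the input paths and parameters of [runProfile()] and validates
#' that every referenced file exists.
#'
#' @param rnaHits path to the covariance-model tblout file.
#' @param seqToAssembly path to the sequence-to-assembly TSV map.
#' @param proteinHits path to the 12-column protein hit table.
#' @param proteinToAssembly path to the protein-to-assembly TSV map.
#' @param tree path to the newick species tree.
#' @param taxonomy path to the taxonomy TSV.
#' @param outDir output directory for the report files.
#' @param thresholds an [rnaThresholds()] object.
#' @param evalueMax inclusive e-value cutoff for family building.
#' @param allowedPhylum phylum retained by the taxonomic filter.
#' @param zeroMode MI convention, \code{"discard"} or \code{"limit"}.
#' @param universeMode \code{"pruned_subtree"} (default): the
#'   marker-negative denominator is every allowed-phylum assembly inside
#'   the minimal clade spanning the marker-positive assemblies;
#'   \code{"whole_phylum"}: every allowed-phylum assembly in the taxonomy.
#' @return a validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(rnaHits, seqToAssembly, proteinHits, proteinToAssembly,
                      tree, taxonomy, outDir,
                      thresholds = rnaThresholds(), evalueMax = 1e-10,
                      allowedPhylum = "Bacillota",
                      zeroMode = c("discard", "limit"),
                      universeMode = c("pruned_subtree", "whole_phylum")) {
  files <- c(rnaHits = rnaHits, seqToAssembly = seqToAssembly,
             proteinHits = proteinHits, proteinToAssembly = proteinToAssembly,
             tree = tree, taxonomy = taxonomy)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(list(files = files, outDir = outDir, thresholds = thresholds,
                 evalueMax = evalueMax, allowedPhylum = allowedPhylum,
                 zeroMode = match.arg(zeroMode),
                 universeMode = match.arg(universeMode)),
            class = "RunConfig")
}

#' Run the full marker-anchored profiling analysis
#'
#' Executes every stage from raw search-output files to the ranked profile
#' report: parse the RNA and protein hit tables, classify RNA hits and call
#' per-assembly statuses, filter by phylum, prune the species tree to the
#' minimal clade spanning marker-positive assemblies, partition the
#' universe into cohorts, build protein families at the e-value cutoff,
#' and profile every family (joint counts, cohort fractions, mutual
#' information, ranking). Writes \code{profile.tsv}, \code{cohorts.json},
#' \code{presence_matrix.tsv} and \code{manifest.json} to the output
#' directory. The run is deterministic: rerunning an identical config on
#' identical inputs reproduces the report byte for byte. Any stage error
#' aborts the run with the stage name; no partial report is written.
#'
#' @param config a [runConfig()] object.
#' @return (invisibly) list with \code{profile} (ranked data.frame),
#'   \code{partition} ([CohortPartition-class]), \code{families},
#'   \code{presence} (count matrix over the universe), \code{manifest} and
#'   \code{paths}.
#' @export
runProfile <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  f <- config$files

  seq2asm <- .stage("read", readIdMap(f[["seqToAssembly"]]))
  prot2asm <- .stage("read", readIdMap(f[["proteinToAssembly"]]))
  rna <- .stage("read", readRnaHits(f[["rnaHits"]], seqToAssembly = seq2asm))
  prot <- .stage("read", readProteinHits(f[["proteinHits"]],
                                         proteinToAssembly = prot2asm))
  tree <- .stage("read", readSpeciesTree(f[["tree"]]))
  taxonomy <- .stage("read", readTaxonomy(f[["taxonomy"]]))

  statuses <- .stage("classify", assemblyStatuses(rna, config$thresholds))

  cohorts <- .stage("partition",
                    makeCohorts(statuses, taxonomy, tree,
                                allowedPhylum = config$allowedPhylum,
                                universeMode = config$universeMode))
  partition <- cohorts$partition
  universe <- cohorts$universe

  families <- .stage("families", familiesFromHits(prot, config$evalueMax))
  presence <- .stage("presence",
                     presenceMatrixFromFamilies(families, universe))
  profile <- .stage("profile",
                    profileFamilies(families, partition, config$zeroMode))

  manifest <- list(
    inputs = lapply(as.list(f), function(p)
      list(path = unname(p), md5 = unname(tools::md5sum(p)))),
    config = list(thresholds = as.list(unclass(config$thresholds)),
                  evalueMax = config$evalueMax,
                  allowedPhylum = config$allowedPhylum,
                  zeroMode = config$zeroMode,
                  universeMode = config$universeMode),
    counts = list(
      rna_hits_parsed = nrow(rna),
      protein_hits_parsed = nrow(prot),
      assemblies_with_status = nrow(statuses),
      status_table = as.list(table(statuses$status)),
      universe_size = length(universe),
      n_positive = length(positiveAssemblies(partition)),
      n_negative = length(negativeAssemblies(partition)),
      excluded_by_reason = as.list(table(excludedAssemblies(partition))),
      families_built = length(families),
      families_undefined_mi = sum(is.na(profile$mi_bits))))
  stopifnot(manifest$counts$n_positive + manifest$counts$n_negative +
              sum(excludedAssemblies(partition) == "variant_carrier") ==
              manifest$counts$universe_size)

  if (!dir.exists(config$outDir))
    dir.create(config$outDir, recursive = TRUE)
  paths <- c(profile = file.path(config$outDir, "profile.tsv"),
             cohorts = file.path(config$outDir, "cohorts.json"),
             presence = file.path(config$outDir, "presence_matrix.tsv"),
             manifest = file.path(config$outDir, "manifest.json"))
  .write_profile_tsv(profile, paths[["profile"]])
  jsonlite::write_json(
    list(positive = positiveAssemblies(partition),
         negative = negativeAssemblies(partition),
         excluded = as.list(excludedAssemblies(partition))),
    paths[["cohorts"]], auto_unbox = TRUE, pretty = TRUE)
  writePresenceMatrix(presence, paths[["presence"]])
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(profile = profile, partition = partition,
                 families = families, presence = presence,
                 manifest = manifest, paths = paths))
}

# floats printed with 6 significant digits; full precision kept internally
.write_profile_tsv <- function(profile, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
  lines <- c(paste(names(profile), collapse = "\t"),
             do.call(paste, c(list(sep = "\t"),
               list(profile$family_id, fmt(profile$f_pos), fmt(profile$f_neg),
                    profile$n11, profile$n10, profile$n01, profile$n00,
                    fmt(profile$mi_bits), profile$direction, profile$rank))))
  if (nrow(profile) == 0L) lines <- lines[1L]
  writeLines(lines, path)
  invisible(path)
}
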