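#' Read a pipeline run configuration
#'
#' Reads a YAML key-value configuration, fills in documented defaults for
#' every omitted parameter, and resolves all input paths relative to the
#' config file location. The fully resolved parameter set is echoed into the
#' design report, so a report is a complete provenance record.
#'
#' @param path path to a YAML config file (see the example emitted by
#'   \code{\link{writeFixture}} for the schema).
#' @return a named list with class \code{epigraftConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  defaults <- list(
    seed = 1L, k = 9L, probe_radius = 1.4, n_points = 960L,
    bsa_threshold = 1.0, min_partners = 2L, gap_merge = 2L,
    alignment = list(matrix = "BLOSUM62", gap_opening = 11,
                     gap_extension = 1),
    min_count = 1L, max_mutations = 50L,
    locked_positions = integer(0), liability_variants = character(0),
    scaffold_row = 1L, out_dir = "out")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$alignment))
    if (is.null(cfg$alignment[[nm]]))
      cfg$alignment[[nm]] <- defaults$alignment[[nm]]
  needed <- c("donor", "scaffold", "proteome", "msa", "complexes")
  miss <- needed[!needed %in% names(cfg)]
  if (length(miss))
    stop("config lacks required field(s): ", paste(miss, collapse = ", "))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  for (nm in c("donor", "scaffold", "proteome", "msa"))
    cfg[[nm]] <- resolve(cfg[[nm]])
  for (pid in names(cfg$complexes))
    cfg$complexes[[pid]]$path <- resolve(cfg$complexes[[pid]]$path)
  if (!grepl("^/", cfg$out_dir)) cfg$out_dir <- file.path(base, cfg$out_dir)
  cfg$locked_positions <- as.integer(unlist(cfg$locked_positions))
  cfg$liability_variants <- as.character(unlist(cfg$liability_variants))
  stopifnot(cfg$k >= 1L, cfg$n_points >= 64L, cfg$probe_radius >= 0,
            cfg$bsa_threshold >= 0, cfg$min_partners >= 1L,
            cfg$gap_merge >= 0L, cfg$min_count >= 1L,
            cfg$max_mutations >= 0L)
  class(cfg) <- c("epigraftConfig", "list")
  cfg
}

#' Checksum the input files of a run configuration
#'
#' Stable md5 content digests of every referenced input, recorded in the
#' design report (the reference proteome release, in particular, is an
#' input, not a constant).
#'
#' @param config an \code{epigraftConfig} (or path to one).
#' @return named character vector path -> digest.
#' @export
checksumInputs <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  paths <- c(config$donor, config$scaffold, config$proteome, config$msa,
             vapply(config$complexes, function(cx) cx$path, ""))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not readable: ", paste(missing, collapse = ", "))
  sums <- tools::md5sum(paths)
  names(sums) <- paths
  sums
}

#' Run the full epitope-grafting design pipeline
#'
#' Executes the five stages in order — footprint computation, stretch
#' selection, grafting, deimmunization, liability-variant application —
#' from a single configuration, writing the final construct FASTA, TSV/JSON
#' stage reports, and a log into the configured output directory. Stage
#' errors are re-signalled with the stage name and leave a \code{FAILED}
#' marker next to any partial outputs. The run is fully deterministic for
#' fixed inputs and configuration.
#'
#' @param config an \code{epigraftConfig} or a path to a YAML config.
#' @param outDir optional override of the configured output directory.
#' @param verbose also echo log lines to stderr.
#' @return a list report (class \code{epigraftReport}) with the config echo,
#'   input checksums, selected stretches, graft plan, design candidate,
#'   final sequence, humanness summary and status.
#' @export
runPipeline <- function(config, outDir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(outDir)) config$out_dir <- outDir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0)
  logf <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    if (verbose) message(line)
  }
  warnings <- character(0)
  stage <- function(name, expr) {
    logf("[stage %s] start", name)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        writeLines(c(logLines, paste("FAILED at stage", name, ":",
                                     conditionMessage(e))),
                   file.path(config$out_dir, "FAILED"))
        stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warnings <<- c(warnings, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  checksums <- stage("checksum", checksumInputs(config))
  donor <- stage("inputs", unname(readFastaSequences(config$donor)[1]))
  scaffold <- stage("inputs", unname(readFastaSequences(config$scaffold)[1]))

  profile <- stage("footprint", {
    complexes <- lapply(config$complexes, function(cx) list(
      model = loadStructure(cx$path),
      partition = chainPartition(unlist(cx$target_chains),
                                 unlist(cx$partner_chains))))
    buildFootprint(complexes, donor, probeRadius = config$probe_radius,
                   nPoints = config$n_points)
  })
  logf("footprint: %d partners, donor length %d",
       length(partnerIds(profile)), nchar(donor))

  stretches <- stage("stretches", {
    cs <- contactSets(profile, bsaThreshold = config$bsa_threshold)
    selectEpitopeStretches(cs, minPartners = config$min_partners,
                           gapMerge = config$gap_merge, donor = donor)
  })
  if (length(stretches) == 0L)
    stage("graft", stop("no epitope stretches selected ",
                        "(thresholds too strict?)"))
  logf("stretches: %d selected", length(stretches))

  graft <- stage("graft", {
    aln <- alignDonorScaffold(donor, scaffold,
                              matrix = config$alignment$matrix,
                              gapOpening = config$alignment$gap_opening,
                              gapExtension = config$alignment$gap_extension)
    transplantStretches(scaffold, donor, stretches, aln)
  })
  logf("graft: %d transplanted positions, grafted length %d",
       length(transplantedPositions(graft$plan)), nchar(graft$sequence))

  candidate <- stage("dehumanize", {
    index <- buildKmerIndex(config$proteome, k = config$k)
    pool <- buildSubstitutionPool(
      config$msa, graft$sequence, minCount = config$min_count,
      scaffoldRow = config$scaffold_row,
      positionMap = graft$plan@positionMap)
    immutable <- sort(union(transplantedPositions(graft$plan),
                            config$locked_positions))
    dehumanize(graft$sequence, index, pool, immutable = immutable,
               maxMutations = config$max_mutations, plan = graft$plan,
               queryId = "design")
  })
  logf("dehumanize: status %s after %d mutation(s)", designStatus(candidate),
       nrow(mutationTable(candidate)))

  final <- stage("variants", {
    if (length(config$liability_variants))
      applyVariants(candidateSequence(candidate), config$liability_variants)
    else candidateSequence(candidate)
  })
  index <- buildKmerIndex(config$proteome, k = config$k)
  finalScan <- scanSequence(final, index, queryId = "final_construct")
  evalReport <- evaluateDesign(candidate, index, graft$plan, donor = donor)

  report <- list(
    config = unclass(config), checksums = as.list(checksums),
    stretches = stretches, graft_plan = graft$plan,
    candidate = candidate, final_sequence = final,
    humanness = list(n_windows = finalScan@nWindows,
                     n_matched_windows = nMatchedWindows(finalScan),
                     distinct_proteins_hit = distinctProteinsHit(finalScan),
                     proteome_md5 = finalScan@proteomeDigest),
    evaluation = evalReport, status = designStatus(candidate),
    warnings = warnings)
  class(report) <- c("epigraftReport", "list")

  od <- config$out_dir
  writeFastaSequences(c(final_construct = final),
                      file.path(od, "final_construct.fasta"))
  writeFootprintTsv(profile, file.path(od, "footprint.tsv"))
  writeStretches(stretches, file.path(od, "stretches.tsv"), "tsv")
  writeStretches(stretches, file.path(od, "stretches.json"), "json")
  writeGraftPlan(graft$plan, file.path(od, "graft_plan.json"))
  writeMutationsTsv(candidate, file.path(od, "mutations.tsv"))
  writeHumannessReport(finalScan, file.path(od, "humanness.tsv"),
                       file.path(od, "humanness.json"))
  jsonlite::write_json(reportAsJson(report),
                       file.path(od, "design_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(logLines,
               sprintf("run completed at %s", format(Sys.time()))),
             file.path(od, "run.log"))
  logf("pipeline done: status %s", report$status)
  report
}

## JSON-serializable view of a report (timestamps excluded so repeated runs
## on identical inputs are byte-identical).
reportAsJson <- function(report) {
  cand <- report$candidate
  list(
    config = report$config,
    input_md5 = report$checksums,
    stretches = stretchesAsData(report$stretches),
    transplanted_positions = transplantedPositions(report$graft_plan),
    mutations = mutationTable(cand),
    status = report$status,
    epitope_intact = epitopeIntact(cand),
    final_sequence = report$final_sequence,
    humanness = report$humanness,
    warnings = report$warnings)
}

#' @export
print.epigraftReport <- function(x, ...) {
  cat("epigraft design report\n")
  cat("  status:         ", x$status, "\n", sep = "")
  cat("  stretches:      ", length(x$stretches), "\n", sep = "")
  cat("  mutations:      ", nrow(mutationTable(x$candidate)), "\n", sep = "")
  cat("  residual self windows: ", x$humanness$n_matched_windows, "/",
      x$humanness$n_windows, "\n", sep = "")
  cat("  epitope intact: ", epitopeIntact(x$candidate), "\n", sep = "")
  cat("  final length:   ", nchar(x$final_sequence), "\n", sep = "")
  invisible(x)
}
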