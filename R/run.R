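## End-to-end orchestration: configuration, the count -> fitness -> group
## summary pipeline, and deterministic TSV outputs.

#' Read a run configuration
#'
#' The YAML configuration describes one screen: the phosphosite scheme, the
#' region FASTA, either a FASTQ manifest or a precomputed count TSV, and
#' pipeline options.  Recognized keys:
#' \describe{
#'   \item{scheme}{\code{sites} (list with \code{label}, \code{position},
#'     \code{wt} each), \code{region_span}, \code{codon_map}; omit to use
#'     the built-in [hcm1Scheme()].}
#'   \item{allowed_states}{e.g. \code{["A", "E"]}.}
#'   \item{reference_genotype}{genotype string (default all-W).}
#'   \item{background}{optional fixed-background label.}
#'   \item{region_fasta}{FASTA with the region/amplicon sequence.}
#'   \item{counts_tsv}{long-format count table, or}
#'   \item{fastq_manifest}{TSV with replicate, timepoint_h, r1, r2.}
#'   \item{pseudocount, read_length, seed}{pipeline options.}
#' }
#'
#' @param path YAML file path.
#' @return A named list (class \code{RunConfig}).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("region_fasta", "counts_tsv", "fastq_manifest"))
    if (!is.null(cfg[[k]]) && !grepl("^/", cfg[[k]]))
      cfg[[k]] <- file.path(base, cfg[[k]])
  structure(cfg, class = "RunConfig")
}

## materialize scheme/spec/region from a config list
configScheme <- function(cfg) {
  if (is.null(cfg$scheme)) return(hcm1Scheme())
  s <- cfg$scheme
  cm <- if (is.null(s$codon_map)) defaultCodonMap()
        else lapply(s$codon_map, unlist)
  phosphositeScheme(
    siteLabels = vapply(s$sites, `[[`, "", "label"),
    positions = vapply(s$sites, function(x) as.integer(x$position), 0L),
    wtResidues = vapply(s$sites, `[[`, "", "wt"),
    regionSpan = as.integer(unlist(s$region_span)),
    codonMap = cm)
}

configSpec <- function(cfg, scheme = configScheme(cfg)) {
  librarySpec(scheme,
              allowedStates = if (is.null(cfg$allowed_states)) c("A", "E")
                              else unlist(cfg$allowed_states),
              referenceGenotype = cfg$reference_genotype,
              background = if (is.null(cfg$background)) "" else
                cfg$background)
}

configRegion <- function(cfg) {
  if (is.null(cfg$region_fasta)) return(hcm1Region())
  Biostrings::readDNAStringSet(cfg$region_fasta)[[1]]
}

#' Run a full screen analysis
#'
#' Orchestrates the pipeline: exact-match counting (when a FASTQ manifest
#' is given) or count-table import, selection-coefficient estimation,
#' enrichment matrix and group summaries; writes all tables plus a run log
#' (package version, parameters, library hash) to \code{outdir}.
#' Deterministic for fixed inputs and seeds: re-running reproduces
#' byte-identical outputs.
#'
#' @param config a list / \code{RunConfig} (see [readRunConfig()]).
#' @param outdir output directory, created if needed.
#' @return Invisibly, a list with \code{counts} ([ScreenCounts-class]),
#'   \code{fitness} ([FitnessTable-class]), \code{enrichment},
#'   \code{byCount}, \code{bySite}, \code{cdf} and the output paths.
#' @export
runScreen <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "configuration"
  res <- list()
  tryCatch({
    scheme <- configScheme(config)
    spec <- configSpec(config, scheme)
    reference <- referenceGenotype(spec)
    pseudocount <- if (is.null(config$pseudocount)) 0.5 else
      as.numeric(config$pseudocount)

    stage <- "count"
    if (!is.null(config$fastq_manifest)) {
      manifest <- if (is.data.frame(config$fastq_manifest))
        config$fastq_manifest
      else read.delim(config$fastq_manifest, stringsAsFactors = FALSE)
      region <- configRegion(config)
      readLength <- if (is.null(config$read_length)) 150L else
        as.integer(config$read_length)
      matcher <- buildMatcher(alleleReferences(spec, region), readLength)
      counts <- countScreen(manifest, matcher)
    } else if (!is.null(config$counts_tsv)) {
      counts <- readCountTable(config$counts_tsv)
    } else if (is(config$counts, "ScreenCounts")) {
      counts <- config$counts
    } else stop("config needs fastq_manifest, counts_tsv or counts")
    writeCountTable(counts, file.path(outdir, "counts.tsv"))

    stage <- "fitness"
    fit <- estimateSC(counts, reference, pseudocount)
    writeFitnessTable(fit, file.path(outdir, "fitness.tsv"))
    enr <- enrichmentMatrix(counts, reference, pseudocount)
    write.table(data.frame(genotype = rownames(enr$mean),
                           enr$mean, check.names = FALSE),
                file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "groups"
    lib <- enumerateLibrary(spec)
    states <- unique(unlist(spec@allowedStates))
    byState <- setdiff(states, "W")
    if (length(byState) == 0) byState <- "W"
    byCount <- groupByCount(fit, byState[1], genotypes = lib)
    bySite <- groupBySite(fit, scheme, genotypes = lib)
    cdf <- cumulativeSC(fit, genotypes = lib)
    write.table(byCount, file.path(outdir, "groups_by_count.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(bySite, file.path(outdir, "groups_by_site.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cdf, file.path(outdir, "cdf.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "log"
    log <- c(
      paste0("PhosphoScan ", as.character(packageVersion("PhosphoScan"))),
      paste0("reference: ", reference),
      paste0("pseudocount: ", pseudocount),
      paste0("seed: ", if (is.null(config$seed)) "none" else config$seed),
      paste0("library_hash: ", metadata(counts)$library_hash),
      paste0("genotypes: ", nrow(counts)),
      paste0("samples: ", ncol(counts))
    )
    writeLines(log, file.path(outdir, "run_log.txt"))
    res <- list(counts = counts, fitness = fit, enrichment = enr,
                byCount = byCount, bySite = bySite, cdf = cdf,
                outdir = outdir)
  }, error = function(e) {
    writeLines(paste0("FAILED at stage ", stage, ": ",
                      conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
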