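## Pooled serial-dilution competition simulator.
##
## Expectation layer: between dilutions each genotype grows exponentially,
## N_g(t + dt) = N_g(t) * 2^((r0 + s_g) * dt), where r0 is the reference
## growth rate in doublings/hour and s_g the genotype's selection
## coefficient in log2-fraction units per hour (s_reference = 0).  Optional
## stochastic layers, each seeded: a multinomial bottleneck at every
## dilution and multinomial read sampling at every timepoint.  Because
## fitness is parameterized directly on the log2-fraction-slope scale,
## simulator inputs and pipeline outputs share the same units and r0 cancels
## from every selection coefficient.

#' Pooled competition model
#'
#' @slot genotypes character, pool members.
#' @slot s named numeric, true selection coefficients (log2 fraction change
#'   per hour); the reference genotype has s = 0.
#' @slot n0 named numeric, initial cell counts per genotype.
#' @slot dt numeric, hours between dilutions (cycle length).
#' @slot nCycles integer, number of dilution cycles (timepoints are
#'   0, dt, ..., nCycles * dt).
#' @slot r0 numeric, reference growth rate in doublings/hour.
#' @slot bottleneck numeric, cells kept at each dilution.
#' @slot depth numeric, read pairs sequenced per timepoint.
#' @slot readLength integer, sequencing read length (bp).
#' @slot errorRate numeric, per-base substitution error rate for emitted
#'   reads.
#' @exportClass CompetitionModel
setClass("CompetitionModel",
  representation(
    genotypes = "character", s = "numeric", n0 = "numeric",
    dt = "numeric", nCycles = "integer", r0 = "numeric",
    bottleneck = "numeric", depth = "numeric", readLength = "integer",
    errorRate = "numeric"
  )
)

setValidity("CompetitionModel", function(object) {
  msg <- character()
  if (length(object@s) != length(object@genotypes) ||
      length(object@n0) != length(object@genotypes))
    msg <- c(msg, "s and n0 must have one value per genotype")
  if (any(object@n0 < 0)) msg <- c(msg, "initial counts must be non-negative")
  if (object@dt <= 0 || object@nCycles < 1)
    msg <- c(msg, "need dt > 0 and at least one cycle")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a pooled competition model
#'
#' Defaults reproduce the canonical screen conditions: 12-h dilution cycles
#' for 72 h (7 timepoints), a 1e7-cell bottleneck, 1e6 read pairs per
#' timepoint, PE150 reads and a 0.25 doublings/h reference growth rate
#' (~2.8-h doubling; its value cancels from all selection coefficients).
#'
#' @param genotypes character vector of pool members.
#' @param s true selection coefficients (log2/h), recycled or named; the
#'   reference entry should be 0.
#' @param n0 initial cell counts (default equal).
#' @param dt cycle length in hours.
#' @param nCycles number of dilution cycles.
#' @param r0 reference growth rate, doublings/h.
#' @param bottleneck cells kept per dilution.
#' @param depth read pairs per timepoint.
#' @param readLength read length in bp.
#' @param errorRate per-base substitution error rate for [emitFastq()].
#' @return A [CompetitionModel-class].
#' @examples
#' m <- competitionModel(c("A", "B"), s = c(A = 0, B = 0.1), depth = 1e4)
#' @export
competitionModel <- function(genotypes, s = 0, n0 = NULL, dt = 12,
                             nCycles = 6L, r0 = 0.25, bottleneck = 1e7,
                             depth = 1e6, readLength = 150L,
                             errorRate = 0) {
  n <- length(genotypes)
  s <- rep_len(s, n)
  if (is.null(names(s))) names(s) <- genotypes else s <- s[genotypes]
  if (is.null(n0)) n0 <- rep(1, n)
  n0 <- rep_len(n0, n)
  if (is.null(names(n0))) names(n0) <- genotypes else n0 <- n0[genotypes]
  new("CompetitionModel", genotypes = genotypes, s = s, n0 = n0,
      dt = dt, nCycles = as.integer(nCycles), r0 = r0,
      bottleneck = bottleneck, depth = depth,
      readLength = as.integer(readLength), errorRate = errorRate)
}

setMethod("show", "CompetitionModel", function(object) {
  cat("CompetitionModel:", length(object@genotypes), "genotypes,",
      object@nCycles, "cycles of", object@dt, "h\n")
  cat("  s in [", min(object@s), ",", max(object@s), "] log2/h; r0 =",
      object@r0, "doublings/h\n")
  cat("  bottleneck", format(object@bottleneck, big.mark = ","),
      "cells; depth", format(object@depth, big.mark = ","),
      "pairs/timepoint\n")
})

#' @describeIn CompetitionModel-class true selection coefficients.
#' @param x a \code{CompetitionModel}.
#' @export
trueSC <- function(x) x@s

## per-replicate RNG stream seeds, kept below 2^31
replicateSeed <- function(seed, rep) (as.integer(seed) + 7919L * rep) %% 2147483629L

#' Simulate a pooled competition screen
#'
#' Runs the expectation layer (exponential growth per genotype) and, when
#' \code{noise = TRUE}, the stochastic layers: one multinomial draw of the
#' initial pool (the pre-selection outgrowth), a multinomial bottleneck at
#' every dilution, and multinomial read sampling of the configured depth at
#' every timepoint.  Each replicate uses an independent RNG stream derived
#' from \code{seed}.  With \code{noise = FALSE} the returned "counts" are
#' exact expected read numbers (depth times true fraction, not rounded), so
#' that downstream estimation recovers \code{s} to numerical precision.
#'
#' @param model a [CompetitionModel-class].
#' @param nReplicates number of biological replicates.
#' @param noise logical, enable the stochastic layers.
#' @param seed integer seed, mandatory when \code{noise = TRUE}.
#' @return A [ScreenCounts-class] with the true \code{s} stored in
#'   \code{metadata(x)$true_sc}.
#' @examples
#' m <- competitionModel(c("ref", "mut"), s = c(0, 0.1), depth = 1e4)
#' sc <- simulatePool(m, nReplicates = 1, noise = FALSE)
#' @export
simulatePool <- function(model, nReplicates = 3L, noise = TRUE,
                         seed = NULL) {
  stopifnot(is(model, "CompetitionModel"))
  if (noise && is.null(seed))
    stop("stochastic simulation requires a seed")
  if (noise && (model@bottleneck <= 0 || model@depth <= 0))
    stop("bottleneck and depth must be positive with stochastic layers")
  tps <- seq(0, by = model@dt, length.out = model@nCycles + 1L)
  nG <- length(model@genotypes)
  growth <- 2^((model@r0 + model@s) * model@dt)
  res <- lapply(seq_len(nReplicates), function(rep) {
    if (noise) set.seed(replicateSeed(seed, rep))
    N <- if (noise)
      drop(rmultinom(1, model@bottleneck, prob = model@n0))
    else model@n0 / sum(model@n0) * model@bottleneck
    reads <- matrix(0, nG, length(tps))
    for (ti in seq_along(tps)) {
      if (ti > 1) {
        N <- N * growth                       # grow one cycle
        if (noise) N <- drop(rmultinom(1, model@bottleneck, prob = N))
        else N <- N / sum(N) * model@bottleneck  # deterministic dilution
      }
      reads[, ti] <- if (noise) drop(rmultinom(1, model@depth, prob = N))
                     else N / sum(N) * model@depth
    }
    reads
  })
  counts <- do.call(cbind, res)
  rownames(counts) <- model@genotypes
  out <- screenCounts(counts,
                      timepoints = rep(tps, times = nReplicates),
                      replicates = rep(seq_len(nReplicates),
                                       each = length(tps)))
  metadata(out)$true_sc <- model@s
  metadata(out)$model <- list(dt = model@dt, r0 = model@r0,
                              nCycles = model@nCycles, noise = noise,
                              seed = seed)
  out
}

#' Simulate a pairwise co-culture assay
#'
#' The two-genotype special case read out by flow cytometry: per timepoint,
#' the percent composition of the mutant strain from a 5000-cell binomial
#' draw of the true mixture.
#'
#' @param s selection coefficient of the mutant versus the reference
#'   (log2/h).
#' @param dt,nCycles,r0 as in [competitionModel()].
#' @param cells cells measured per timepoint.
#' @param noise logical; \code{FALSE} returns exact percentages.
#' @param seed RNG seed (required when \code{noise = TRUE}).
#' @return data.frame with \code{timepoint_h}, \code{pct_mut},
#'   \code{pct_ref}.
#' @examples
#' simulatePairwise(0.02, noise = FALSE)
#' @export
simulatePairwise <- function(s, dt = 12, nCycles = 6L, r0 = 0.25,
                             cells = 5000L, noise = TRUE, seed = NULL) {
  m <- competitionModel(c("ref", "mut"), s = c(ref = 0, mut = s),
                        dt = dt, nCycles = nCycles, r0 = r0)
  tps <- seq(0, by = dt, length.out = nCycles + 1L)
  fmut <- 0.5 * 2^(s * tps) / (0.5 * 2^(s * tps) + 0.5)
  if (noise) {
    if (is.null(seed)) stop("stochastic simulation requires a seed")
    set.seed(replicateSeed(seed, 1L))
    k <- rbinom(length(tps), cells, fmut)
    fmut <- k / cells
  }
  data.frame(timepoint_h = tps, pct_mut = 100 * fmut,
             pct_ref = 100 * (1 - fmut))
}

## introduce per-base substitution errors at rate eps into reads (character
## vector); only reads drawn to contain >= 1 error are touched
addReadErrors <- function(reads, eps) {
  if (eps <= 0 || length(reads) == 0) return(reads)
  rl <- nchar(reads[1])
  nerr <- rbinom(length(reads), rl, eps)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(rl, nerr[i])
    ch <- strsplit(reads[i], "")[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    reads[i] <- paste0(ch, collapse = "")
  }
  reads
}

#' Emit paired FASTQ files for simulated counts
#'
#' Realizes the sequencing layer: for every (replicate, timepoint) sample,
#' each genotype contributes exactly its read count of pairs; mate 1 is the
#' first \code{readLength} bases of the allele amplicon, mate 2 the reverse
#' complement of its last \code{readLength} bases, with independent
#' per-base substitution errors at rate \code{errorRate} and fixed
#' placeholder qualities.  Refuses amplicons longer than the paired
#' coverage (sites would be unobserved).
#'
#' @param counts a [ScreenCounts-class] with integer counts.
#' @param alleles named \code{DNAStringSet} of amplicons covering every
#'   genotype in \code{counts}.
#' @param dir output directory for the FASTQ files.
#' @param readLength read length (bp).
#' @param errorRate per-base substitution probability.
#' @param seed RNG seed (used for error placement and read shuffling).
#' @return Manifest data.frame (\code{replicate}, \code{timepoint_h},
#'   \code{r1}, \code{r2}) suitable for [countScreen()].
#' @export
emitFastq <- function(counts, alleles, dir, readLength = 150L,
                      errorRate = 0, seed = 1L) {
  len <- unique(Biostrings::width(alleles))
  stopifnot(length(len) == 1)
  if (len > 2L * readLength)
    stop("amplicon (", len, " bp) longer than paired coverage: sites would ",
         "be unobserved")
  g <- rownames(counts)
  if (!all(g %in% names(alleles)))
    stop("every genotype needs an allele reference")
  pre <- setNames(as.character(
    Biostrings::subseq(alleles, 1L, readLength)), names(alleles))
  suf <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::subseq(alleles, len - readLength + 1L, len))),
    names(alleles))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- assay(counts, "counts")
  if (any(m != round(m))) stop("emitFastq needs integer counts")
  set.seed(replicateSeed(seed, 0L))
  qual <- strrep("I", readLength)
  manifest <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    n <- m[, j]
    ids <- rep(g, n)
    r1 <- addReadErrors(rep(pre[g], n), errorRate)
    r2 <- addReadErrors(rep(suf[g], n), errorRate)
    ord <- sample.int(length(ids))  # shuffle read order within the sample
    base <- sprintf("rep%s_t%03d", replicates(counts)[j],
                    as.integer(timepoints(counts)[j]))
    f1 <- file.path(dir, paste0(base, "_R1.fastq"))
    f2 <- file.path(dir, paste0(base, "_R2.fastq"))
    hdr <- sprintf("@%s_%06d", ids[ord], seq_along(ord))
    writeLines(rbind(hdr, r1[ord], "+", qual), f1)
    writeLines(rbind(hdr, r2[ord], "+", qual), f2)
    data.frame(replicate = replicates(counts)[j],
               timepoint_h = timepoints(counts)[j], r1 = f1, r2 = f2)
  }))
  rownames(manifest) <- NULL
  manifest
}
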