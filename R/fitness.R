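## Selection-coefficient estimation.
##
## For each replicate, the slope of log2 read fraction versus time (hours)
## is fit by unweighted OLS over all timepoints for every genotype; the
## selection coefficient (SC) is that slope minus the reference genotype's
## slope, so SC(reference) = 0 exactly in every replicate.  Replicates are
## fit independently, then averaged.

#' Fitness table
#'
#' Per-genotype selection coefficients: one SC per replicate, the mean and
#' SD across replicates, and per-replicate fit diagnostics.
#'
#' @slot genotype character, row identity.
#' @slot sc matrix genotype x replicate of selection coefficients (log2/h).
#' @slot scMean,scSD numeric, mean and standard deviation across replicates.
#' @slot nReplicates integer, replicates contributing per genotype.
#' @slot diagnostics list of matrices \code{slope}, \code{intercept},
#'   \code{rss} (raw per-replicate OLS fits, before reference subtraction).
#' @slot reference character, the reference genotype.
#' @slot timepoints numeric, the fitted timepoints (hours).
#' @seealso [estimateSC()]
#' @exportClass FitnessTable
setClass("FitnessTable",
  representation(
    genotype = "character", sc = "matrix", scMean = "numeric",
    scSD = "numeric", nReplicates = "integer", diagnostics = "list",
    reference = "character", timepoints = "numeric"
  )
)

setValidity("FitnessTable", function(object) {
  msg <- character()
  n <- length(object@genotype)
  if (nrow(object@sc) != n || length(object@scMean) != n ||
      length(object@scSD) != n)
    msg <- c(msg, "per-genotype slots must align")
  if (!object@reference %in% object@genotype)
    msg <- c(msg, "reference genotype must be a table row")
  ref <- object@sc[match(object@reference, object@genotype), ]
  if (any(abs(ref[!is.na(ref)]) > 1e-12))
    msg <- c(msg, "SC of the reference must be 0 in every replicate")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FitnessTable", function(object) {
  cat("FitnessTable:", length(object@genotype), "genotypes,",
      ncol(object@sc), "replicates; reference", object@reference, "\n")
  cat("  mean SC range: [", signif(min(object@scMean), 3), ",",
      signif(max(object@scMean), 3), "] log2/h\n")
})

#' @describeIn FitnessTable-class genotype x replicate SC matrix.
#' @param x a \code{FitnessTable}.
#' @export
sc <- function(x) x@sc

#' @describeIn FitnessTable-class mean SC across replicates, named by
#'   genotype.
#' @export
scMean <- function(x) setNames(x@scMean, x@genotype)

#' @describeIn FitnessTable-class SD of SC across replicates.
#' @export
scSD <- function(x) setNames(x@scSD, x@genotype)

#' @export
setMethod("as.data.frame", "FitnessTable",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(genotype = x@genotype, x@sc, mean_sc = x@scMean,
             sd_sc = x@scSD, n = x@nReplicates, row.names = NULL)
})

#' Log2 read fractions per replicate
#'
#' Converts counts into log2 fractions with a symmetric pseudocount:
#' f_g(t) = (count_g + pc) / sum_h (count_h + pc).  The pseudocount keeps
#' zero-count genotypes finite; with \code{pseudocount = 0} fractions are
#' raw and zero counts give \code{-Inf}.
#'
#' @param counts a [ScreenCounts-class].
#' @param pseudocount number added to every genotype at every timepoint
#'   before forming fractions (default 0.5).
#' @return 3-d array genotype x timepoint x replicate of log2 fractions;
#'   dimnames carry genotypes, timepoints (hours) and replicate labels.
#' @examples
#' m <- competitionModel(c("a", "b"), s = c(0, 0.1), depth = 1e4)
#' lf <- log2Fractions(simulatePool(m, 1, noise = FALSE), pseudocount = 0)
#' @export
log2Fractions <- function(counts, pseudocount = 0.5) {
  m <- assay(counts, "counts")
  if (any(colSums(m) == 0))
    stop("all-zero timepoint: sample missing")
  reps <- unique(replicates(counts))
  tps <- sort(unique(timepoints(counts)))
  arr <- array(NA_real_, dim = c(nrow(m), length(tps), length(reps)),
               dimnames = list(rownames(m), tps, reps))
  for (r in seq_along(reps)) {
    j <- which(replicates(counts) == reps[r])
    j <- j[order(timepoints(counts)[j])]
    sub <- m[, j, drop = FALSE] + pseudocount
    arr[, , r] <- log2(sweep(sub, 2, colSums(sub), "/"))
  }
  arr
}

## OLS slopes of every row of y against x (closed form); returns slope,
## intercept and residual sum of squares per row
rowOLS <- function(y, x) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- drop(y %*% xc) / sxx
  intercept <- rowMeans(y) - slope * mean(x)
  fit <- outer(slope, x) + intercept
  list(slope = slope, intercept = intercept,
       rss = rowSums((y - fit)^2))
}

#' Estimate selection coefficients
#'
#' Per replicate, fits the OLS slope of log2 read fraction versus time for
#' every genotype over all timepoints and subtracts the reference
#' genotype's slope; reports the per-replicate SCs, their mean and SD.
#'
#' @param counts a [ScreenCounts-class].
#' @param reference reference genotype string (e.g. \code{"WWWWWWWW"}).
#' @param pseudocount see [log2Fractions()].
#' @return A [FitnessTable-class].
#' @examples
#' m <- competitionModel(c("WWWWWWWW", "EEEEEEEE"), s = c(0, 0.016),
#'                       depth = 1e4)
#' fit <- estimateSC(simulatePool(m, 2, noise = FALSE), "WWWWWWWW",
#'                   pseudocount = 0)
#' scMean(fit)
#' @export
estimateSC <- function(counts, reference, pseudocount = 0.5) {
  lf <- log2Fractions(counts, pseudocount)
  genotypes <- dimnames(lf)[[1]]
  if (!reference %in% genotypes)
    stop("reference genotype ", reference, " missing from the count table")
  tps <- as.numeric(dimnames(lf)[[2]])
  if (length(tps) < 2) stop("need at least two timepoints")
  reps <- dimnames(lf)[[3]]
  scm <- slope <- inter <- rss <- matrix(
    NA_real_, length(genotypes), length(reps),
    dimnames = list(genotypes, reps))
  for (r in seq_along(reps)) {
    ols <- rowOLS(lf[, , r], tps)
    slope[, r] <- ols$slope
    inter[, r] <- ols$intercept
    rss[, r] <- ols$rss
    scm[, r] <- ols$slope - ols$slope[match(reference, genotypes)]
  }
  nrep <- rowSums(!is.na(scm))
  new("FitnessTable",
      genotype = genotypes, sc = scm,
      scMean = rowMeans(scm, na.rm = TRUE),
      scSD = apply(scm, 1, sd, na.rm = TRUE),
      nReplicates = as.integer(nrep),
      diagnostics = list(slope = slope, intercept = inter, rss = rss),
      reference = reference, timepoints = tps)
}

#' Enrichment matrix (log2 fold change versus time zero, reference-normalized)
#'
#' E_g(t) = [log2 f_g(t) - log2 f_g(0)] - [log2 f_ref(t) - log2 f_ref(0)]:
#' the quantity shown in screen heatmaps.  The t = 0 column is identically
#' zero, as is the reference row.
#'
#' @param counts a [ScreenCounts-class] including the t = 0 sample.
#' @param reference reference genotype.
#' @param pseudocount see [log2Fractions()].
#' @return List with \code{perReplicate} (3-d array genotype x timepoint x
#'   replicate) and \code{mean} (genotype x timepoint, replicate-averaged).
#' @export
enrichmentMatrix <- function(counts, reference, pseudocount = 0.5) {
  lf <- log2Fractions(counts, pseudocount)
  tps <- as.numeric(dimnames(lf)[[2]])
  if (tps[1] != 0) stop("missing t0 sample")
  genotypes <- dimnames(lf)[[1]]
  ri <- match(reference, genotypes)
  if (is.na(ri)) stop("reference genotype missing from the count table")
  E <- lf
  for (r in seq_len(dim(lf)[3])) {
    d <- lf[, , r] - lf[, 1, r]             # vs time zero
    E[, , r] <- sweep(d, 2, d[ri, ], "-")   # vs reference
  }
  list(perReplicate = E, mean = apply(E, c(1, 2), mean))
}

#' Selection coefficient from a pairwise co-culture assay
#'
#' OLS slope of log2(percent mutant / percent reference) versus time, the
#' two-strain analogue of the pooled estimate.
#'
#' @param percentages data.frame with columns \code{timepoint_h},
#'   \code{pct_mut}, \code{pct_ref}; the two strains must sum to 100 and
#'   both lie strictly inside (0, 100) at every timepoint.
#' @return Selection coefficient (log2/h).
#' @examples
#' pairwiseSC(simulatePairwise(0.02, noise = FALSE))
#' @export
pairwiseSC <- function(percentages) {
  p <- percentages
  stopifnot(all(c("timepoint_h", "pct_mut", "pct_ref") %in% names(p)))
  if (any(abs(p$pct_mut + p$pct_ref - 100) > 1e-6))
    stop("the two strains must sum to 100% at every timepoint")
  if (any(p$pct_mut <= 0 | p$pct_mut >= 100))
    stop("0% or 100% composition: log ratio undefined; truncate the ",
         "time course to timepoints where both strains are observed")
  y <- log2(p$pct_mut / p$pct_ref)
  rowOLS(matrix(y, 1), p$timepoint_h)$slope
}

#' Write a fitness table as TSV
#'
#' @param x a [FitnessTable-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeFitnessTable <- function(x, path) {
  df <- as.data.frame(x)
  names(df)[2:(1 + ncol(x@sc))] <- paste0("sc_rep", colnames(x@sc))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
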