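## Phosphorylation-code summaries.
##
## Groups pool replicate-level SC values (not per-genotype means): a k-of-n
## group over an n-site two-state library holds choose(n, k) genotypes and
## choose(n, k) * nReplicates values.  Boxplot statistics follow the Tukey
## convention (whiskers at the most extreme point within 1.5 x IQR of the
## quartiles, points beyond are outliers); quartiles use type-7 linear
## interpolation, R's boxplot() default.

## Tukey box stats on a numeric vector
tukeyStats <- function(v) {
  v <- v[!is.na(v)]
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- v[v >= lo & v <= hi]
  list(n = length(v), median = q[2], q25 = q[1], q75 = q[3],
       whisker_lo = if (length(inside)) min(inside) else NA_real_,
       whisker_hi = if (length(inside)) max(inside) else NA_real_,
       outliers = v[v < lo | v > hi])
}

## library-membership mask: SC values (replicate-level) for a genotype subset
poolValues <- function(fitness, genotypes) {
  as.vector(fitness@sc[match(genotypes, fitness@genotype), , drop = FALSE])
}

#' Median SC by number of sites in a state
#'
#' For k = 0..nSites, pools all replicate-level selection coefficients of
#' genotypes carrying exactly k sites in the given state (e.g. k
#' phosphomimetic substitutions) and reports Tukey boxplot summaries.
#'
#' @param fitness a [FitnessTable-class].
#' @param state state letter counted per genotype (\code{"E"}, \code{"W"}
#'   or \code{"A"}).
#' @param genotypes genotypes to group; defaults to all library rows whose
#'   string contains no other information (all rows of the table).
#' @return data.frame with one row per k: \code{k}, \code{n_genotypes},
#'   \code{n_values}, \code{median}, \code{q25}, \code{q75},
#'   \code{whisker_lo}, \code{whisker_hi}, \code{n_outliers}; the outlier
#'   values are attached as \code{attr(res, "outliers")}.
#' @examples
#' ## median SC rises with the number of phosphomimetic sites when fitness
#' ## is additive in E count
#' @export
groupByCount <- function(fitness, state = "E", genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- fitness@genotype
  k <- countState(genotypes, state)
  nsites <- nchar(genotypes[1])
  rows <- list()
  outliers <- list()
  for (kk in 0:nsites) {
    g <- genotypes[k == kk]
    if (length(g) == 0) next
    st <- tukeyStats(poolValues(fitness, g))
    rows[[length(rows) + 1L]] <- data.frame(
      k = kk, n_genotypes = length(g), n_values = st$n,
      median = st$median, q25 = st$q25, q75 = st$q75,
      whisker_lo = st$whisker_lo, whisker_hi = st$whisker_hi,
      n_outliers = length(st$outliers))
    outliers[[as.character(kk)]] <- st$outliers
  }
  res <- do.call(rbind, rows)
  attr(res, "outliers") <- outliers
  attr(res, "state") <- state
  res
}

#' Median SC by site and state
#'
#' For every site and every state observed there, pools the replicate-level
#' selection coefficients of all genotypes carrying that state at that site
#' (the half-library of 2^(n-1) genotypes for a two-state library) and
#' reports Tukey summaries.
#'
#' @param fitness a [FitnessTable-class].
#' @param scheme the [PhosphositeScheme-class] giving site labels.
#' @param genotypes genotypes to group (default: all table rows).
#' @return data.frame with columns \code{site}, \code{state},
#'   \code{n_genotypes}, \code{n_values}, \code{median}, \code{q25},
#'   \code{q75}, \code{whisker_lo}, \code{whisker_hi}, \code{n_outliers}.
#' @export
groupBySite <- function(fitness, scheme, genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- fitness@genotype
  stMat <- do.call(rbind, strsplit(genotypes, ""))
  rows <- list()
  for (j in seq_len(ncol(stMat))) {
    for (state in intersect(STATE_ALPHABET, unique(stMat[, j]))) {
      g <- genotypes[stMat[, j] == state]
      st <- tukeyStats(poolValues(fitness, g))
      rows[[length(rows) + 1L]] <- data.frame(
        site = scheme@siteLabels[j], state = state,
        n_genotypes = length(g), n_values = st$n, median = st$median,
        q25 = st$q25, q75 = st$q75, whisker_lo = st$whisker_lo,
        whisker_hi = st$whisker_hi, n_outliers = length(st$outliers))
    }
  }
  do.call(rbind, rows)
}

#' Empirical cumulative distribution of selection coefficients
#'
#' Right-continuous empirical CDF over all replicate-level SC values: the
#' fraction of values less than or equal to each observed SC.
#'
#' @param fitness a [FitnessTable-class].
#' @param genotypes optional genotype subset.
#' @return data.frame with sorted unique \code{sc} and \code{fraction},
#'   monotone nondecreasing from >0 to 1.
#' @export
cumulativeSC <- function(fitness, genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- fitness@genotype
  v <- sort(poolValues(fitness, genotypes))
  v <- v[!is.na(v)]
  x <- unique(v)
  data.frame(sc = x, fraction = cumsum(tabulate(match(v, x))) / length(v))
}

#' Pairwise replicate correlations
#'
#' Pearson correlation of the per-replicate SC vectors for every replicate
#' pair — the standard screen-reproducibility check.
#'
#' @param fitness a [FitnessTable-class] with >= 2 replicates.
#' @return Symmetric correlation matrix, replicates x replicates.
#' @export
replicateCorrelation <- function(fitness) {
  if (ncol(fitness@sc) < 2) stop("need at least two replicates")
  if (any(apply(fitness@sc, 2, sd, na.rm = TRUE) == 0))
    stop("zero-variance replicate: correlation undefined")
  cor(fitness@sc, use = "pairwise.complete.obs")
}

#' Boxplot of SC by substitution count
#'
#' Tukey box-and-whisker plot of replicate-level selection coefficients
#' grouped by the number of sites in a state, mirroring the standard screen
#' summary figure.
#'
#' @param fitness a [FitnessTable-class].
#' @param state state letter to count.
#' @param ... passed to [graphics::boxplot()].
#' @return Invisibly, the [groupByCount()] table.
#' @export
plotGroupSC <- function(fitness, state = "E", ...) {
  k <- countState(fitness@genotype, state)
  vals <- lapply(sort(unique(k)), function(kk)
    poolValues(fitness, fitness@genotype[k == kk]))
  names(vals) <- sort(unique(k))
  boxplot(vals, range = 1.5,
          xlab = paste0("number of ", state, " sites"),
          ylab = "selection coefficient (log2/h)", ...)
  invisible(groupByCount(fitness, state))
}

#' Cumulative-frequency plot of selection coefficients
#'
#' Overlays the empirical SC CDFs of one or more screens on a shared axis.
#'
#' @param ... named [FitnessTable-class] objects.
#' @param col line colors.
#' @return Invisibly, a list of [cumulativeSC()] tables.
#' @export
plotCumulativeSC <- function(..., col = NULL) {
  fits <- list(...)
  tabs <- lapply(fits, cumulativeSC)
  if (is.null(col)) col <- seq_along(tabs)
  xr <- range(unlist(lapply(tabs, `[[`, "sc")))
  plot(NA, xlim = xr, ylim = c(0, 1), xlab = "selection coefficient",
       ylab = "cumulative fraction of mutants")
  for (i in seq_along(tabs))
    lines(tabs[[i]]$sc, tabs[[i]]$fraction, type = "s", col = col[i])
  if (!is.null(names(fits)))
    legend("bottomright", legend = names(fits), col = col, lty = 1)
  invisible(tabs)
}
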