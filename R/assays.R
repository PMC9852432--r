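## Accessory computations: Cks1 priming spacing, beta-galactosidase units
## and doubling times.

#' Cks1 priming rule
#'
#' Cks1, the CDK phosphoadaptor, binds phosphorylated threonines (not
#' serines) located 12-30 residues upstream of further CDK consensus sites,
#' driving processive N-to-C multisite phosphorylation.  Spacing is counted
#' as the difference of phosphoacceptor residue indices, inclusive at both
#' bounds.
#'
#' @param minSpacing,maxSpacing spacing bounds in residues.
#' @return List with class \code{PrimingRule}.
#' @export
primingRule <- function(minSpacing = 12L, maxSpacing = 30L) {
  stopifnot(minSpacing <= maxSpacing)
  structure(list(minSpacing = as.integer(minSpacing),
                 maxSpacing = as.integer(maxSpacing),
                 primingResidue = "T"),
            class = "PrimingRule")
}

#' Candidate Cks1 priming pairs
#'
#' Enumerates ordered site pairs (i upstream of j) where site i is a
#' threonine and the phosphoacceptor spacing position(j) - position(i) lies
#' within the rule's bounds — the candidate priming relationships of a
#' multisite domain.
#'
#' @param scheme a [PhosphositeScheme-class] (positions must be known for
#'   all sites considered).
#' @param rule a [primingRule()].
#' @return data.frame with columns \code{primer}, \code{target} (site
#'   labels), \code{primer_pos}, \code{target_pos}, \code{spacing}; zero
#'   rows if no pair qualifies.
#' @examples
#' sites <- phosphositeScheme(
#'   c("T428", "T440", "T447", "T460", "S471"),
#'   c(428L, 440L, 447L, 460L, 471L), c("T", "T", "T", "T", "S"),
#'   c(415L, 504L))
#' candidatePrimingPairs(sites)
#' @export
candidatePrimingPairs <- function(scheme, rule = primingRule()) {
  n <- nSites(scheme)
  rows <- list()
  if (n >= 2) for (i in seq_len(n - 1L)) {
    if (wtResidues(scheme)[i] != rule$primingResidue) next
    for (j in seq.int(i + 1L, n)) {
      sp <- sitePositions(scheme)[j] - sitePositions(scheme)[i]
      if (sp >= rule$minSpacing && sp <= rule$maxSpacing)
        rows[[length(rows) + 1L]] <- data.frame(
          primer = siteLabels(scheme)[i], target = siteLabels(scheme)[j],
          primer_pos = sitePositions(scheme)[i],
          target_pos = sitePositions(scheme)[j], spacing = sp)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(primer = character(), target = character(),
                  primer_pos = integer(), target_pos = integer(),
                  spacing = integer())
}

#' Beta-galactosidase units
#'
#' Units = 1000 * OD405 / (OD600 * volume [mL] * reaction time [min]), the
#' standard normalization of the colorimetric lacZ reporter assay.
#'
#' @param od405 absorbance of the stopped reaction at 405 nm.
#' @param od600 culture density at 600 nm.
#' @param volumeML reaction volume in mL.
#' @param minutes reaction time in minutes.
#' @return Beta-galactosidase units.
#' @examples
#' betaGalUnits(0.5, 1.0, 1, 100)  # 5
#' @export
betaGalUnits <- function(od405, od600, volumeML = 1, minutes) {
  if (any(od600 <= 0) || any(volumeML <= 0) || any(minutes <= 0))
    stop("od600, volume and reaction time must be positive")
  1000 * od405 / (od600 * volumeML * minutes)
}

#' Doubling time from an OD600 growth curve
#'
#' Fits log2(OD) versus time by OLS restricted to points inside the
#' exponential window (bounds inclusive) and returns 1/slope in hours.  A
#' non-positive slope is reported as non-growing (\code{NA} with a
#' warning).  The window is absolute OD, so the result is not invariant to
#' rescaling the OD values.
#'
#' @param time numeric, hours.
#' @param od numeric, OD600 readings parallel to \code{time}.
#' @param window numeric(2), inclusive OD bounds of the fitted window.
#' @return Doubling time in hours (\code{NA} if non-growing).
#' @examples
#' t <- seq(0, 10, by = 1 / 3)
#' doublingTime(t, 0.01 * 2^(t / 2))  # 2 h
#' @export
doublingTime <- function(time, od, window = c(0.2, 0.5)) {
  stopifnot(length(time) == length(od))
  keep <- od >= window[1] & od <= window[2]
  if (sum(keep) < 2)
    stop("fewer than two points inside the OD window [",
         window[1], ", ", window[2], "]")
  slope <- rowOLS(matrix(log2(od[keep]), 1), time[keep])$slope
  if (slope <= 0) {
    warning("non-positive growth slope: culture reported as non-growing")
    return(NA_real_)
  }
  1 / slope
}
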