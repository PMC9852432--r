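## Default fixture: the Hcm1 transactivation domain (TAD) scheme and a
## synthetic coding region.  The TAD carries eight CDK consensus sites; the
## five N-terminal ones have published residue numbers (T428, T440, T447,
## T460, S471).  The three C-terminal sites are unnumbered in the literature,
## so they are labelled S6/S7/S8 with placeholder positions (482, 489, 496)
## used only by the simulator fixture — non-authoritative.

#' Hcm1 TAD phosphosite scheme
#'
#' The default eight-site scheme for the Hcm1 transactivation domain:
#' threonines T428, T440, T447, T460 and serine S471 at their published
#' positions, plus three C-terminal serines at placeholder positions 482,
#' 489 and 496 (their exact residue numbers are not published; the
#' placeholders are only used to anchor them in the synthetic fixture
#' region).
#'
#' @param codonMap per-state codon replacements, see [defaultCodonMap()].
#' @return A [PhosphositeScheme-class] spanning residues 415-504.
#' @examples
#' hcm1Scheme()
#' @export
hcm1Scheme <- function(codonMap = defaultCodonMap()) {
  phosphositeScheme(
    siteLabels = c("T428", "T440", "T447", "T460", "S471",
                   "S6", "S7", "S8"),
    positions = c(428L, 440L, 447L, 460L, 471L, 482L, 489L, 496L),
    wtResidues = c("T", "T", "T", "T", "S", "S", "S", "S"),
    regionSpan = c(415L, 504L),
    codonMap = codonMap
  )
}

## Wild-type codon choices for the synthetic region.  ACC/TCC + CCT are
## chosen so that each site's wild-type codon pair differs from both mutant
## pairs (GCT CCA, GAA GAA) at >= 2 bases; this guarantees that no single
## sequencing error can convert one allele's read window into another's.
.WT_SITE_CODONS <- c(S = "TCC", T = "ACC")
.WT_P_CODON <- "CCT"

#' Synthetic Hcm1 TAD region sequence
#'
#' A deterministic, synthetic 270-bp (90-codon) stand-in for the mutated
#' region of the Hcm1 TAD: the real sequence is not bundled, so this region
#' encodes the eight S/T-P sites of [hcm1Scheme()] at the correct relative
#' spacing inside a fixed filler backbone.  All package fixtures and the
#' simulator use this synthetic region; analyses of real data should supply
#' the true amplicon via the \code{region} FASTA of the run configuration.
#'
#' @param scheme the scheme to embed; defaults to [hcm1Scheme()].
#' @return A \code{DNAString} of length 270.
#' @examples
#' length(hcm1Region())
#' @export
hcm1Region <- function(scheme = hcm1Scheme()) {
  nres <- regionSpan(scheme)[2] - regionSpan(scheme)[1] + 1L
  filler <- c("GAT", "TTG", "AAA", "TCT", "GGT", "CAA", "AAT", "GAA",
              "CCA", "GTT")
  codons <- rep(filler, length.out = nres)
  off <- sitePositions(scheme) - regionSpan(scheme)[1] + 1L
  codons[off] <- .WT_SITE_CODONS[wtResidues(scheme)]
  codons[off + 1L] <- .WT_P_CODON
  Biostrings::DNAString(paste0(codons, collapse = ""))
}

#' Canonical Hcm1 library specifications
#'
#' The four 256-member screen libraries: \code{"AE"} (every site A or E),
#' \code{"WA"} (wild type or A), \code{"WE"} (wild type or E) and
#' \code{"3N-AE"} (A/E states on the stabilized \code{hcm1-3N} phosphodegron
#' background).  References follow the screen design: the all-W genotype for
#' the W-containing libraries; for the fixed-state libraries the reference
#' allele (WT, or \emph{hcm1-3N}) is spiked into the pool alongside the
#' library and selection coefficients are normalized to it.
#'
#' @param type one of \code{"AE"}, \code{"WA"}, \code{"WE"}, \code{"3N-AE"}.
#' @param scheme the phosphosite scheme, default [hcm1Scheme()].
#' @return A [LibrarySpec-class].
#' @examples
#' hcm1LibrarySpec("WA")
#' @export
hcm1LibrarySpec <- function(type = c("AE", "WA", "WE", "3N-AE"),
                            scheme = hcm1Scheme()) {
  type <- match.arg(type)
  n <- nSites(scheme)
  wt <- strrep("W", n)
  switch(type,
    "AE" = librarySpec(scheme, c("A", "E"), referenceGenotype = wt),
    "WA" = librarySpec(scheme, c("W", "A"), referenceGenotype = wt),
    "WE" = librarySpec(scheme, c("W", "E"), referenceGenotype = wt),
    "3N-AE" = librarySpec(scheme, c("A", "E"), referenceGenotype = wt,
                          background = "3N")
  )
}
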