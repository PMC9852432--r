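## Phosphosite scheme, genotypes and library enumeration.
##
## A "scheme" describes the mutable S/T-P sites of a multisite-phosphorylated
## region: where they sit in the protein, what the wild-type phosphoacceptor
## is, and which two-codon DNA replacement realizes each mutant state.  A
## "genotype" is one library member, written as a string of per-site states
## in N->C order (e.g. "AAAEEAAA" = E-E at sites 4 and 5, A-P elsewhere).

STATE_ALPHABET <- c("W", "A", "E")

#' Phosphosite scheme
#'
#' Describes the mutable phosphosites of a scanned region.  Each site is an
#' S/T-P CDK consensus motif occupying two codons: the phosphoacceptor codon
#' and the following proline codon.  Mutant states replace this codon pair:
#' state \code{"A"} gives unphosphorylatable A-P, state \code{"E"} gives the
#' phosphomimetic E-E pair, and state \code{"W"} retains the wild-type
#' sequence byte-for-byte.
#'
#' @slot siteLabels character, one label per site (e.g. \code{"T428"}).
#' @slot positions integer, 1-based protein residue index of each
#'   phosphoacceptor; strictly increasing.
#' @slot wtResidues character, wild-type phosphoacceptor per site
#'   (\code{"S"} or \code{"T"}).
#' @slot regionSpan integer of length 2, first and last protein residue of
#'   the mutated region.
#' @slot codonMap named list; for each non-wild-type state, a character
#'   vector of two codons replacing the (phosphoacceptor, proline) pair.
#'
#' @seealso [phosphositeScheme()], [hcm1Scheme()], [enumerateLibrary()]
#' @exportClass PhosphositeScheme
setClass("PhosphositeScheme",
  representation(
    siteLabels = "character",
    positions = "integer",
    wtResidues = "character",
    regionSpan = "integer",
    codonMap = "list"
  )
)

setValidity("PhosphositeScheme", function(object) {
  msg <- character()
  n <- length(object@positions)
  if (length(object@siteLabels) != n || length(object@wtResidues) != n)
    msg <- c(msg, "siteLabels, positions and wtResidues must have equal length")
  if (n > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (!all(object@wtResidues %in% c("S", "T")))
    msg <- c(msg, "wild-type residues must be S or T")
  if (length(object@regionSpan) != 2 || object@regionSpan[1] > object@regionSpan[2])
    msg <- c(msg, "regionSpan must be two ordered residue indices")
  ## each site occupies the phosphoacceptor codon and the adjacent P codon,
  ## so position + 1 must also lie inside the region
  if (n > 0 && (any(object@positions < object@regionSpan[1]) ||
                any(object@positions + 1L > object@regionSpan[2])))
    msg <- c(msg, "every site codon pair must fall within regionSpan")
  bad <- vapply(object@codonMap, function(x)
    length(x) != 2 || !all(grepl("^[ACGT]{3}$", x)), logical(1))
  if (any(bad))
    msg <- c(msg, "codonMap entries must be two ACGT codons each")
  if (length(msg)) msg else TRUE
})

#' Construct a phosphosite scheme
#'
#' @param siteLabels character vector of site labels, N->C order.
#' @param positions integer vector of 1-based phosphoacceptor residue
#'   positions, strictly increasing.
#' @param wtResidues character vector of wild-type phosphoacceptors
#'   (\code{"S"}/\code{"T"}).
#' @param regionSpan integer(2), first/last residue of the mutated region.
#' @param codonMap named list of two-codon replacements per mutant state.
#'   The default realizes A-P as \code{GCT CCA} and E-E as \code{GAA GAA}.
#' @return A [PhosphositeScheme-class] object.
#' @examples
#' sch <- phosphositeScheme(c("T2", "T5"), c(2L, 5L), c("T", "T"), c(1L, 7L))
#' nSites(sch)
#' @export
phosphositeScheme <- function(siteLabels, positions, wtResidues, regionSpan,
                              codonMap = defaultCodonMap()) {
  new("PhosphositeScheme",
    siteLabels = as.character(siteLabels),
    positions = as.integer(positions),
    wtResidues = as.character(wtResidues),
    regionSpan = as.integer(regionSpan),
    codonMap = codonMap
  )
}

#' Default two-codon replacements for mutant phosphosite states
#'
#' One fixed codon choice per state, frozen so that genotype -> DNA is
#' deterministic: A-P as \code{GCT CCA}, E-E as \code{GAA GAA}.  Configurable
#' because real libraries may vary codon usage per oligo.
#'
#' @return Named list with elements \code{A} and \code{E}.
#' @export
defaultCodonMap <- function() {
  list(A = c("GCT", "CCA"), E = c("GAA", "GAA"))
}

#' @describeIn PhosphositeScheme-class number of phosphosites.
#' @param object,x a \code{PhosphositeScheme}.
#' @export
nSites <- function(x) length(x@positions)

#' @describeIn PhosphositeScheme-class site labels.
#' @export
siteLabels <- function(x) x@siteLabels

#' @describeIn PhosphositeScheme-class phosphoacceptor residue positions.
#' @export
sitePositions <- function(x) x@positions

#' @describeIn PhosphositeScheme-class wild-type phosphoacceptor residues.
#' @export
wtResidues <- function(x) x@wtResidues

#' @describeIn PhosphositeScheme-class first/last residue of the region.
#' @export
regionSpan <- function(x) x@regionSpan

#' @describeIn PhosphositeScheme-class per-state codon replacements.
#' @export
codonMap <- function(x) x@codonMap

setMethod("show", "PhosphositeScheme", function(object) {
  cat("PhosphositeScheme with", nSites(object), "sites over residues",
      paste(object@regionSpan, collapse = "-"), "\n")
  cat("  ", paste0(object@siteLabels, " (", object@wtResidues,
                   object@positions, "-P)", collapse = ", "), "\n", sep = "")
})

#' Library specification
#'
#' Binds a scheme to the per-site allowed state alphabets (e.g. \{A, E\} at
#' every site for the A/E library), an optional fixed-background label for
#' invariant mutations outside the scanned region (e.g. \code{"3N"} for the
#' stabilized phosphodegron background), and the reference genotype to which
#' selection coefficients are normalized.
#'
#' @slot scheme a [PhosphositeScheme-class].
#' @slot allowedStates list of character vectors, one per site, each a
#'   non-empty subset of \code{c("W","A","E")}.
#' @slot background character, fixed-background label (\code{""} if none).
#' @slot referenceGenotype character, a member of the enumerated library.
#' @exportClass LibrarySpec
setClass("LibrarySpec",
  representation(
    scheme = "PhosphositeScheme",
    allowedStates = "list",
    background = "character",
    referenceGenotype = "character"
  )
)

setValidity("LibrarySpec", function(object) {
  msg <- character()
  n <- nSites(object@scheme)
  if (length(object@allowedStates) != n)
    msg <- c(msg, "need one allowed-state set per site")
  bad <- vapply(object@allowedStates, function(x)
    length(x) == 0 || !all(x %in% STATE_ALPHABET), logical(1))
  if (any(bad))
    msg <- c(msg, "allowed states must be non-empty subsets of {W, A, E}")
  if (length(object@referenceGenotype) != 1 ||
      nchar(object@referenceGenotype) != n ||
      !all(strsplit(object@referenceGenotype, "")[[1]] %in% STATE_ALPHABET))
    msg <- c(msg, "referenceGenotype must be one genotype string over W/A/E")
  if (length(msg)) msg else TRUE
})

#' Construct a library specification
#'
#' @param scheme a [PhosphositeScheme-class].
#' @param allowedStates either a single character vector applied to every
#'   site (e.g. \code{c("A","E")}) or a list with one vector per site.
#' @param referenceGenotype genotype string the selection coefficients are
#'   normalized to; defaults to the all-wild-type genotype.  If it is not a
#'   member of the combinatorial library (as for the fixed-state A/E
#'   libraries, where the WT or \emph{hcm1-3N} control plasmid is spiked into
#'   the pool), it is carried as an extra pool member — see
#'   [poolGenotypes()].
#' @param background optional fixed-background label (e.g. \code{"3N"}).
#' @return A [LibrarySpec-class] object.
#' @examples
#' spec <- librarySpec(hcm1Scheme(), c("A", "E"), referenceGenotype = NULL)
#' length(enumerateLibrary(spec))
#' @export
librarySpec <- function(scheme, allowedStates, referenceGenotype = NULL,
                        background = "") {
  n <- nSites(scheme)
  if (!is.list(allowedStates))
    allowedStates <- rep(list(as.character(allowedStates)), n)
  if (any(lengths(allowedStates) == 0))
    stop("configuration error: empty allowed state set at a site")
  if (is.null(referenceGenotype))
    referenceGenotype <- strrep("W", n)
  new("LibrarySpec", scheme = scheme, allowedStates = allowedStates,
      background = background, referenceGenotype = referenceGenotype)
}

setMethod("show", "LibrarySpec", function(object) {
  sizes <- lengths(object@allowedStates)
  cat("LibrarySpec:", prod(sizes), "genotypes over", nSites(object@scheme),
      "sites\n")
  cat("  per-site states:",
      paste(vapply(object@allowedStates, paste0, "", collapse = "/"),
            collapse = ", "), "\n")
  cat("  reference:", object@referenceGenotype,
      if (nzchar(object@background)) paste0("(background ", object@background,
                                            ")") else "", "\n")
})

## Cartesian product of per-site state sets, lexicographic order (first site
## varies slowest).  Core enumeration shared by librarySpec validation and
## enumerateLibrary().
enumerateStates <- function(allowedStates) {
  grids <- lapply(rev(allowedStates), function(x) sort(as.character(x)))
  g <- expand.grid(grids, stringsAsFactors = FALSE)
  apply(g[, rev(seq_along(allowedStates)), drop = FALSE], 1, paste0,
        collapse = "")
}

#' Enumerate all genotypes of a library
#'
#' Returns the full Cartesian product of the per-site allowed states, in
#' lexicographic order.  For the canonical 8-site two-state libraries this
#' yields the 256 combinatorial phosphomutants.
#'
#' @param spec a [LibrarySpec-class].
#' @return Character vector of genotype strings, lexicographically sorted,
#'   without duplicates.
#' @examples
#' enumerateLibrary(librarySpec(hcm1Scheme(), c("A", "E")))[1:4]
#' @export
enumerateLibrary <- function(spec) {
  stopifnot(is(spec, "LibrarySpec"))
  sort(enumerateStates(spec@allowedStates))
}

#' Genotypes present in the screened pool
#'
#' The enumerated combinatorial library plus the reference genotype.  For
#' W-containing libraries the reference (all-W) is already a library member;
#' for fixed-state libraries (A/E) the reference control plasmid is spiked
#' into the pool and appears here as an extra member.
#'
#' @param spec a [LibrarySpec-class].
#' @return Sorted character vector of genotype strings.
#' @export
poolGenotypes <- function(spec) {
  sort(unique(c(enumerateLibrary(spec), spec@referenceGenotype)))
}

#' Reference genotype of a library
#'
#' @param spec a [LibrarySpec-class].
#' @return Genotype string.
#' @export
referenceGenotype <- function(spec) spec@referenceGenotype

#' Parse a genotype string into per-site states
#'
#' @param genotype genotype string (e.g. \code{"AAAEEAAA"}).
#' @param scheme a [PhosphositeScheme-class] (for length checking).
#' @return Character vector of single-letter states.
#' @export
genotypeStates <- function(genotype, scheme) {
  st <- strsplit(genotype, "")[[1]]
  if (length(st) != nSites(scheme))
    stop("genotype length ", length(st), " does not match the ",
         nSites(scheme), "-site scheme")
  if (!all(st %in% STATE_ALPHABET))
    stop("genotype characters must be one of W, A, E")
  st
}

#' Count sites in a given state
#'
#' Number of sites carrying a particular state in each genotype, e.g. the
#' number of phosphomimetic (E) substitutions.
#'
#' @param genotypes character vector of genotype strings.
#' @param state single state letter (\code{"W"}, \code{"A"} or \code{"E"}).
#' @return Integer vector parallel to \code{genotypes}.
#' @examples
#' countState(c("AAAEEAAA", "EEEEEEEE"), "E")
#' @export
countState <- function(genotypes, state) {
  stopifnot(state %in% STATE_ALPHABET)
  vapply(strsplit(genotypes, ""), function(x) sum(x == state), integer(1))
}

#' Apply a genotype to a protein region
#'
#' Realizes a genotype at the protein level: state W leaves the S/T-P motif
#' intact, A yields A-P, E yields E-E; all other residues are unchanged.
#'
#' @param regionProtein amino-acid string (or \code{AAString}) of the mutated
#'   region, covering \code{regionSpan(scheme)}.
#' @param scheme a [PhosphositeScheme-class].
#' @param genotype genotype string.
#' @return Amino-acid string of the same length.
#' @examples
#' sch <- phosphositeScheme(c("T2", "T5"), c(2L, 5L), c("T", "T"), c(1L, 7L))
#' applyGenotype("STPQTPA", sch, "EE")
#' @export
applyGenotype <- function(regionProtein, scheme, genotype) {
  aa <- strsplit(as.character(regionProtein), "")[[1]]
  st <- genotypeStates(genotype, scheme)
  off <- scheme@positions - scheme@regionSpan[1] + 1L
  if (any(off < 1L) || any(off + 1L > length(aa)))
    stop("region does not cover all scheme sites")
  for (k in seq_along(off)) {
    i <- off[k]
    if (aa[i] != scheme@wtResidues[k])
      stop("reference mismatch at site ", scheme@siteLabels[k], ": expected ",
           scheme@wtResidues[k], ", found ", aa[i])
    if (aa[i + 1L] != "P")
      stop("reference mismatch at site ", scheme@siteLabels[k],
           ": no proline following the phosphoacceptor")
    if (st[k] == "A") {
      aa[i] <- "A"
    } else if (st[k] == "E") {
      aa[i] <- "E"
      aa[i + 1L] <- "E"
    }
  }
  paste0(aa, collapse = "")
}

#' Realize a genotype at the DNA level
#'
#' Replaces the two codons of each non-wild-type site with the codon pair
#' from the scheme's \code{codonMap}; wild-type sites keep their original
#' codons byte-for-byte.  Translation of the output equals
#' [applyGenotype()] of the translation of the input.
#'
#' @param regionDNA in-frame DNA string (or \code{DNAString}) encoding the
#'   mutated region.
#' @param scheme a [PhosphositeScheme-class].
#' @param genotype genotype string.
#' @return DNA string of the same length.
#' @examples
#' sch <- phosphositeScheme("T1", 1L, "T", c(1L, 2L))
#' genotypeToDNA("ACTCCA", sch, "A")
#' @export
genotypeToDNA <- function(regionDNA, scheme, genotype) {
  dna <- as.character(regionDNA)
  if (nchar(dna) %% 3 != 0)
    stop("regionDNA is not in frame (length not divisible by 3)")
  st <- genotypeStates(genotype, scheme)
  off <- scheme@positions - scheme@regionSpan[1] + 1L
  for (k in seq_along(off)) {
    if (st[k] == "W") next
    rep <- scheme@codonMap[[st[k]]]
    if (is.null(rep))
      stop("codonMap has no entry for state ", st[k])
    start <- 3L * (off[k] - 1L) + 1L
    substr(dna, start, start + 5L) <- paste0(rep, collapse = "")
  }
  dna
}

#' Build the allele reference set of a library
#'
#' Maps every genotype to its exact DNA amplicon sequence — the set used for
#' exact-match counting and for simulation.
#'
#' @param spec a [LibrarySpec-class].
#' @param regionDNA in-frame DNA of the mutated region (the amplicon).
#' @return Named \code{DNAStringSet}, one amplicon per genotype.
#' @examples
#' al <- alleleReferences(librarySpec(hcm1Scheme(), c("A", "E")), hcm1Region())
#' length(al)
#' @export
alleleReferences <- function(spec, regionDNA) {
  g <- poolGenotypes(spec)
  seqs <- vapply(g, function(x) genotypeToDNA(regionDNA, spec@scheme, x), "")
  Biostrings::DNAStringSet(setNames(seqs, g))
}

#' Read back the genotype encoded by a mutant region
#'
#' Inverse of [genotypeToDNA()] at the protein level: translates each site's
#' codon pair and classifies it as W (wild-type S/T-P), A (A-P) or E (E-E).
#'
#' @param regionDNA in-frame DNA of a (possibly mutant) region.
#' @param scheme a [PhosphositeScheme-class].
#' @return Genotype string.
#' @export
readGenotype <- function(regionDNA, scheme) {
  dna <- Biostrings::DNAString(as.character(regionDNA))
  off <- scheme@positions - scheme@regionSpan[1] + 1L
  st <- vapply(seq_along(off), function(k) {
    start <- 3L * (off[k] - 1L) + 1L
    pair <- as.character(Biostrings::translate(
      Biostrings::subseq(dna, start, start + 5L)))
    if (pair == paste0(scheme@wtResidues[k], "P")) "W"
    else if (pair == "AP") "A"
    else if (pair == "EE") "E"
    else stop("unrecognized state '", pair, "' at site ",
              scheme@siteLabels[k])
  }, "")
  paste0(st, collapse = "")
}
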