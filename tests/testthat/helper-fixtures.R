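## Shared fixtures and independent oracles for the test suite.

fixScheme <- hcm1Scheme()
fixRegion <- hcm1Region()
fixAESpec <- hcm1LibrarySpec("AE")
fixAlleles <- alleleReferences(fixAESpec, fixRegion)

## the five TAD sites with published residue numbers
printedSites <- function() {
  phosphositeScheme(
    siteLabels = c("T428", "T440", "T447", "T460", "S471"),
    positions = c(428L, 440L, 447L, 460L, 471L),
    wtResidues = c("T", "T", "T", "T", "S"),
    regionSpan = c(415L, 504L))
}

## brute-force Cartesian product by explicit nested loops (enumeration oracle)
bruteEnumerate <- function(allowedStates) {
  out <- ""
  for (states in allowedStates) {
    out <- unlist(lapply(out, function(prefix)
      paste0(prefix, sort(states))))
  }
  sort(out)
}

## sort-and-pick median oracle (no quantile())
sortMedian <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

## type-7 quartile by direct interpolation on the sorted vector
sortQuantile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

## format priming pairs as position strings, robust to zero rows
pairStrings <- function(pp) {
  if (nrow(pp) == 0) return(character())
  sort(paste0(pp$primer_pos, "->", pp$target_pos))
}

## O(n^2) priming-pair oracle
brutePrimingPairs <- function(positions, residues, minS = 12, maxS = 30) {
  hits <- character()
  n <- length(positions)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || positions[i] >= positions[j]) next
    if (residues[i] != "T") next
    d <- positions[j] - positions[i]
    if (d >= minS && d <= maxS)
      hits <- c(hits, paste0(positions[i], "->", positions[j]))
  }
  sort(hits)
}

## tiny two-genotype pool for fitness arithmetic tests
toyCounts <- function(mat, timepoints, replicates) {
  screenCounts(mat, timepoints, replicates)
}

## write one FASTQ record block
writeFastq <- function(path, seqs, ids = sprintf("read%04d", seq_along(seqs))) {
  qual <- strrep("I", if (length(seqs)) nchar(seqs[1]) else 0L)
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

## mate windows of an allele amplicon
mateWindows <- function(amplicon, readLength = 150L) {
  len <- nchar(amplicon)
  list(
    r1 = substr(amplicon, 1, readLength),
    r2 = as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(amplicon, len - readLength + 1, len)))))
}
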