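## Exact-match paired-end allele counting.
##
## A read pair is assigned to an allele only if mate 1 equals the first
## readLength bases of that allele's amplicon AND mate 2 equals the reverse
## complement of its last readLength bases, with zero mismatches.  Exactness
## is the only filter: no trimming, no quality filtering, no fuzzy matching.
## Anything else is discarded and tallied by reason.

DISCARD_REASONS <- c("mate1_mismatch", "mate2_mismatch", "bad_length",
                     "bad_characters")

#' Screen count table
#'
#' Read counts per genotype (rows) and sample (columns; one sample per
#' timepoint per replicate), stored as a \linkS4class{SummarizedExperiment}
#' with a \code{counts} assay and \code{colData} columns \code{timepoint_h}
#' and \code{replicate}.  Per-sample discard tallies (reads not assigned to
#' any allele, by reason) live in \code{metadata(x)$discards}.
#'
#' @seealso [screenCounts()], [countReads()], [readCountTable()]
#' @exportClass ScreenCounts
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "must carry a 'counts' assay")
  else if (any(assay(object, "counts") < 0))
    msg <- c(msg, "counts must be non-negative")
  if (!all(c("timepoint_h", "replicate") %in% colnames(colData(object))))
    msg <- c(msg, "colData must have timepoint_h and replicate")
  if (is.null(rownames(object)))
    msg <- c(msg, "rows must be named by genotype")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts numeric matrix, genotypes x samples.  Column order must
#'   match \code{timepoints}/\code{replicates}.
#' @param timepoints numeric vector of sampling times in hours, one per
#'   column.
#' @param replicates vector of replicate labels, one per column.
#' @param discards optional data.frame of per-sample discard tallies.
#' @return A [ScreenCounts-class].
#' @export
screenCounts <- function(counts, timepoints, replicates, discards = NULL) {
  counts <- as.matrix(counts)
  colnames(counts) <- paste0("rep", replicates, "_t", timepoints)
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts),
    colData = DataFrame(timepoint_h = as.numeric(timepoints),
                        replicate = as.character(replicates),
                        row.names = colnames(counts))
  )
  obj <- new("ScreenCounts", se)
  if (!is.null(discards)) metadata(obj)$discards <- discards
  metadata(obj)$library_hash <- libraryHash(rownames(counts))
  obj
}

#' @describeIn ScreenCounts-class sampling timepoints (hours) per column.
#' @param x a \code{ScreenCounts}.
#' @export
timepoints <- function(x) colData(x)$timepoint_h

#' @describeIn ScreenCounts-class replicate label per column.
#' @export
replicates <- function(x) colData(x)$replicate

#' @describeIn ScreenCounts-class per-sample discard tallies (or NULL).
#' @export
discardSummary <- function(x) metadata(x)$discards

## hash of the sorted genotype list: guards against scheme drift between the
## counting and fitness stages
libraryHash <- function(genotypes) {
  g <- sort(genotypes)
  ## small rolling polynomial hash; stable across platforms
  h <- 0
  for (ch in utf8ToInt(paste(g, collapse = "|")))
    h <- (h * 31 + ch) %% 2147483647
  sprintf("%d:%x", length(g), h)
}

#' Exact-match paired-end allele matcher
#'
#' Lookup structure keyed jointly on (first \code{readLength} bases of the
#' amplicon, reverse complement of its last \code{readLength} bases).  Built
#' once per allele set; construction fails if two distinct genotypes are
#' indistinguishable within the two windows.
#'
#' @param alleles named \code{DNAStringSet} of equal-length amplicons (names
#'   are genotypes), e.g. from [alleleReferences()].
#' @param readLength sequencing read length (bp); the paired windows must
#'   jointly cover the amplicon (amplicon length <= 2 * readLength).
#' @return An object of class \code{AlleleMatcher}.
#' @examples
#' al <- alleleReferences(hcm1LibrarySpec("AE"), hcm1Region())
#' m <- buildMatcher(al, 150L)
#' @export
buildMatcher <- function(alleles, readLength = 150L) {
  len <- unique(Biostrings::width(alleles))
  if (length(len) != 1)
    stop("allele amplicons must all have equal length")
  pre <- as.character(Biostrings::subseq(alleles, 1L, readLength))
  suf <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(alleles, len - readLength + 1L, len)))
  key <- paste(pre, suf, sep = "+")
  dup <- duplicated(key)
  if (any(dup)) {
    clash <- names(alleles)[key %in% key[dup]]
    stop("ambiguity error: alleles indistinguishable within the read ",
         "windows: ", paste(clash, collapse = ", "))
  }
  structure(
    list(key = key, genotype = names(alleles), prefix = pre,
         readLength = as.integer(readLength), ampliconLength = len),
    class = "AlleleMatcher"
  )
}

#' @export
print.AlleleMatcher <- function(x, ...) {
  cat("AlleleMatcher:", length(x$key), "alleles,", x$ampliconLength,
      "bp amplicon, PE", x$readLength, "windows\n")
  invisible(x)
}

## Minimal FASTQ reader returning the sequence lines as a character vector.
## Biostrings::readDNAStringSet(format = "fastq") would coerce letters to
## the DNA alphabet and reject arbitrary characters; exact-match counting
## must instead *discard* such records, so sequences are taken verbatim.
readFastqSeqs <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (record count not a multiple of 4): ", path)
  lines[seq(2L, length(lines), by = 4L)]
}

#' Count allele-assigned read pairs in one FASTQ pair
#'
#' A pair increments exactly one genotype iff mate 1 exactly equals that
#' allele's prefix window and mate 2 exactly equals the same allele's
#' reverse-complement suffix window.  Everything else is discarded and
#' tallied: wrong read length, non-ACGT characters (N never matches), a
#' mate-1 window matching no allele, or a mate-1 match whose mate 2 does not
#' complete the joint key.
#'
#' @param r1,r2 paths to the mate-1 and mate-2 FASTQ files (record-aligned).
#' @param matcher an \code{AlleleMatcher} from [buildMatcher()].
#' @return List with \code{counts} (named integer vector over all matcher
#'   genotypes, zeros allowed), \code{discards} (named integer vector over
#'   discard reasons) and \code{total} (pairs processed).
#' @export
countReads <- function(r1, r2, matcher) {
  s1 <- readFastqSeqs(r1)
  s2 <- readFastqSeqs(r2)
  if (length(s1) != length(s2))
    stop("mate files have unequal record counts (", length(s1), " vs ",
         length(s2), ")")
  total <- length(s1)
  discards <- setNames(integer(length(DISCARD_REASONS)), DISCARD_REASONS)
  rl <- matcher$readLength
  lenOK <- nchar(s1) == rl & nchar(s2) == rl
  discards["bad_length"] <- sum(!lenOK)
  s1 <- s1[lenOK]; s2 <- s2[lenOK]
  charOK <- !grepl("[^ACGT]", s1) & !grepl("[^ACGT]", s2)
  discards["bad_characters"] <- sum(!charOK)
  s1 <- s1[charOK]; s2 <- s2[charOK]
  idx <- match(paste(s1, s2, sep = "+"), matcher$key)
  hit <- !is.na(idx)
  pre1 <- s1[!hit] %in% matcher$prefix
  discards["mate1_mismatch"] <- sum(!pre1)
  discards["mate2_mismatch"] <- sum(pre1)
  counts <- setNames(integer(length(matcher$genotype)), matcher$genotype)
  if (any(hit)) {
    tab <- tabulate(idx[hit], nbins = length(matcher$genotype))
    counts[] <- tab
  }
  stopifnot(sum(counts) + sum(discards) == total)
  list(counts = counts, discards = discards, total = total)
}

#' Count a whole screen from a FASTQ manifest
#'
#' Applies [countReads()] to every (replicate, timepoint) FASTQ pair of a
#' manifest and assembles a [ScreenCounts-class] table.
#'
#' @param manifest data.frame with columns \code{replicate},
#'   \code{timepoint_h}, \code{r1}, \code{r2}; rows uniquely keyed by
#'   (replicate, timepoint).
#' @param matcher an \code{AlleleMatcher}.
#' @return A [ScreenCounts-class].
#' @export
countScreen <- function(manifest, matcher) {
  need <- c("replicate", "timepoint_h", "r1", "r2")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns ", paste(need, collapse = ", "))
  key <- paste(manifest$replicate, manifest$timepoint_h)
  if (anyDuplicated(key))
    stop("manifest rows must be uniquely keyed by (replicate, timepoint)")
  manifest <- manifest[order(manifest$replicate, manifest$timepoint_h), ]
  res <- lapply(seq_len(nrow(manifest)), function(i)
    countReads(manifest$r1[i], manifest$r2[i], matcher))
  counts <- vapply(res, `[[`, numeric(length(matcher$genotype)), "counts")
  rownames(counts) <- matcher$genotype
  disc <- data.frame(
    replicate = manifest$replicate, timepoint_h = manifest$timepoint_h,
    total = vapply(res, `[[`, 0, "total"),
    assigned = colSums(counts),
    t(vapply(res, `[[`, numeric(length(DISCARD_REASONS)), "discards"))
  )
  screenCounts(counts, manifest$timepoint_h, manifest$replicate,
               discards = disc)
}

#' Read / write count tables as TSV
#'
#' The interchange schema is long format with columns \code{genotype},
#' \code{replicate}, \code{timepoint_h}, \code{count}.  Deposited tables
#' with other column names can be mapped in via \code{columns}.
#'
#' @param path TSV path.
#' @param columns named character vector renaming adapter: names are the
#'   schema names, values the column names found in the file.
#' @return [readCountTable()] a [ScreenCounts-class]; [writeCountTable()]
#'   the path, invisibly.
#' @export
readCountTable <- function(path, columns = c(genotype = "genotype",
                                             replicate = "replicate",
                                             timepoint_h = "timepoint_h",
                                             count = "count")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(columns), names(df))
  if (length(miss))
    stop("count table lacks columns: ", paste(miss, collapse = ", "))
  df <- data.frame(genotype = df[[columns["genotype"]]],
                   replicate = as.character(df[[columns["replicate"]]]),
                   timepoint_h = as.numeric(df[[columns["timepoint_h"]]]),
                   count = df[[columns["count"]]])
  samp <- unique(df[c("replicate", "timepoint_h")])
  samp <- samp[order(samp$replicate, samp$timepoint_h), ]
  genotypes <- sort(unique(df$genotype))
  counts <- matrix(0, length(genotypes), nrow(samp),
                   dimnames = list(genotypes, NULL))
  si <- match(paste(df$replicate, df$timepoint_h),
              paste(samp$replicate, samp$timepoint_h))
  gi <- match(df$genotype, genotypes)
  counts[cbind(gi, si)] <- df$count
  screenCounts(counts, samp$timepoint_h, samp$replicate)
}

#' @rdname readCountTable
#' @param x a [ScreenCounts-class].
#' @export
writeCountTable <- function(x, path) {
  m <- assay(x, "counts")
  df <- data.frame(
    genotype = rep(rownames(m), ncol(m)),
    replicate = rep(replicates(x), each = nrow(m)),
    timepoint_h = rep(timepoints(x), each = nrow(m)),
    count = as.vector(m)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
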