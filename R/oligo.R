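## Mutagenic oligo tiling and overlap-extension assembly.
##
## Libraries are built from pooled overlapping oligos spanning the mutated
## region; consecutive oligos share a fixed overlap window and each carries
## every state combination of the phosphosites it covers.  Annealing,
## fill-in and ligation are abstracted to exact overlap-merge on the sense
## strand: the computational content is the combinatorial product, not the
## chemistry.

#' Tile plan
#'
#' Coordinates of the oligo tiles over the region, their overlap windows and
#' (after [addTileVariants()]) the variant sequences of each tile.
#'
#' @slot tiles an \code{IRanges} of tile coordinates (1-based, inclusive) on
#'   the region.
#' @slot overlaps an \code{IRanges} of the windows shared by consecutive
#'   tiles.
#' @slot region the reference region DNA (character).
#' @slot siteIndex list mapping each tile to the scheme site indices whose
#'   codons it contains.
#' @slot variants list of named \code{DNAStringSet}s, one per tile (empty
#'   until [addTileVariants()] is called); names are the per-tile state
#'   combinations.
#' @slot scheme the [PhosphositeScheme-class] used for the design.
#' @include scheme.R
#' @exportClass TilePlan
setClass("TilePlan",
  representation(
    tiles = "IRanges",
    overlaps = "IRanges",
    region = "character",
    siteIndex = "list",
    variants = "list",
    scheme = "PhosphositeScheme"
  )
)

setValidity("TilePlan", function(object) {
  msg <- character()
  n <- length(object@tiles)
  if (length(object@overlaps) != max(n - 1L, 0L))
    msg <- c(msg, "need exactly one overlap window per adjacent tile pair")
  if (n > 0 && (start(object@tiles)[1] != 1L ||
                end(object@tiles)[n] != nchar(object@region)))
    msg <- c(msg, "tiles must cover the region exactly")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TilePlan", function(object) {
  cat("TilePlan:", length(object@tiles), "tiles over a",
      nchar(object@region), "bp region\n")
  df <- as.data.frame(tilePlanTable(object))
  print(df, row.names = FALSE)
})

## DNA coordinates (1-based) of the two codons of site k, relative to the
## region start.
siteCodonRange <- function(scheme, k) {
  off <- scheme@positions[k] - scheme@regionSpan[1] + 1L
  start <- 3L * (off - 1L) + 1L
  c(start, start + 5L)
}

#' Plan oligo tiles over a region
#'
#' Splits the region DNA into \code{nTiles} overlapping tiles such that
#' consecutive tiles share an overlap window within \code{overlapRange} and
#' every phosphosite codon pair lies strictly inside exactly one tile (never
#' inside an overlap window, so all variants of adjacent tiles share
#' identical overlap sequence and anneal without bias).  Placement is
#' deterministic: overlaps are placed leftmost-feasible at maximal width,
#' with backtracking only as needed for global feasibility.
#'
#' @param regionDNA region DNA string or \code{DNAString}.
#' @param scheme a [PhosphositeScheme-class].
#' @param nTiles number of tiles.
#' @param overlapRange integer(2), minimum and maximum overlap width in bp.
#' @param maxSitesPerTile optional cap on phosphosites per tile.
#' @return A [TilePlan-class] (without variants).
#' @examples
#' plan <- tileRegion(hcm1Region(), hcm1Scheme(), 6, c(21, 27))
#' tilePlanTable(plan)
#' @export
tileRegion <- function(regionDNA, scheme, nTiles, overlapRange = c(21L, 27L),
                       maxSitesPerTile = Inf) {
  region <- as.character(regionDNA)
  L <- nchar(region)
  nOv <- nTiles - 1L
  if (nTiles < 1L) stop("need at least one tile")
  if (L < nTiles * overlapRange[1])
    stop("region too short for ", nTiles, " tiles with overlaps >= ",
         overlapRange[1])
  ## bases occupied by site codons: overlap windows must avoid them
  siteSpans <- lapply(seq_len(nSites(scheme)), function(k)
    siteCodonRange(scheme, k))
  blocked <- logical(L)
  for (sp in siteSpans) blocked[sp[1]:sp[2]] <- TRUE
  if (nOv == 0L) {
    plan <- new("TilePlan", tiles = IRanges::IRanges(1L, L),
                overlaps = IRanges::IRanges(), region = region,
                siteIndex = list(seq_len(nSites(scheme))), variants = list(),
                scheme = scheme)
    return(plan)
  }
  okWindow <- function(p, v) {
    p >= 2L && (p + v - 1L) <= (L - 1L) && !any(blocked[p:(p + v - 1L)])
  }
  ## depth-first search, trying positions left to right and widths from the
  ## maximum down, so the first solution found is the leftmost/maximal one
  solve <- function(j, minStart) {
    if (j > nOv) return(list())
    for (p in minStart:(L - overlapRange[1])) {
      for (v in seq(overlapRange[2], overlapRange[1])) {
        if (!okWindow(p, v)) next
        rest <- solve(j + 1L, p + v + 1L)
        if (!is.null(rest)) return(c(list(c(p, v)), rest))
      }
    }
    NULL
  }
  sol <- solve(1L, 2L)
  if (is.null(sol))
    stop("design error: no feasible tiling (a site may be too close to a ",
         "forced boundary)")
  ovStart <- vapply(sol, `[`, 0, 1)
  ovWidth <- vapply(sol, `[`, 0, 2)
  tileStart <- c(1L, as.integer(ovStart))
  tileEnd <- c(as.integer(ovStart + ovWidth - 1L), L)
  siteIndex <- lapply(seq_len(nTiles), function(i) {
    which(vapply(siteSpans, function(sp)
      sp[1] > tileStart[i] && sp[2] < tileEnd[i], logical(1)))
  })
  hits <- table(unlist(siteIndex))
  if (length(hits) < nSites(scheme) || any(hits != 1L)) {
    bad <- setdiff(seq_len(nSites(scheme)), as.integer(names(hits[hits == 1L])))
    stop("design error: site ", paste(scheme@siteLabels[bad], collapse = ", "),
         " is not interior to exactly one tile")
  }
  if (any(lengths(siteIndex) > maxSitesPerTile))
    stop("design error: a tile covers more than ", maxSitesPerTile, " sites")
  new("TilePlan",
      tiles = IRanges::IRanges(tileStart, tileEnd),
      overlaps = IRanges::IRanges(as.integer(ovStart),
                                  as.integer(ovStart + ovWidth - 1L)),
      region = region, siteIndex = siteIndex, variants = list(),
      scheme = scheme)
}

#' Tabular view of a tile plan
#'
#' @param plan a [TilePlan-class].
#' @return \code{data.frame} with tile index, start, end, covered sites and
#'   variant count (0 before [addTileVariants()]).
#' @export
tilePlanTable <- function(plan) {
  n <- length(plan@tiles)
  data.frame(
    tile = seq_len(n),
    start = start(plan@tiles),
    end = end(plan@tiles),
    n_sites = lengths(plan@siteIndex),
    sites = vapply(plan@siteIndex, function(i)
      paste(plan@scheme@siteLabels[i], collapse = ","), ""),
    n_variants = if (length(plan@variants)) lengths(plan@variants)
                 else rep(0L, n)
  )
}

#' Generate the variant set of every tile
#'
#' For each tile, produces one sequence per state combination of the sites
#' it covers, under the per-site allowed states of the library spec.  All
#' variants of a tile have identical length and identical overlap flanks
#' (site codons never fall inside overlaps).
#'
#' @param plan a [TilePlan-class] from [tileRegion()].
#' @param spec a [LibrarySpec-class] over the same scheme.
#' @return The plan with its \code{variants} slot filled.
#' @export
addTileVariants <- function(plan, spec) {
  stopifnot(identical(plan@scheme@positions, spec@scheme@positions))
  scheme <- spec@scheme
  plan@variants <- lapply(seq_along(plan@tiles), function(i) {
    sites <- plan@siteIndex[[i]]
    from <- start(plan@tiles)[i]
    to <- end(plan@tiles)[i]
    if (length(sites) == 0) {
      combos <- ""
      seqs <- substr(plan@region, from, to)
    } else {
      combos <- enumerateStates(spec@allowedStates[sites])
      full <- strrep("W", nSites(scheme))
      seqs <- vapply(combos, function(cb) {
        g <- full
        st <- strsplit(cb, "")[[1]]
        for (j in seq_along(sites))
          substr(g, sites[j], sites[j]) <- st[j]
        substr(genotypeToDNA(plan@region, scheme, g), from, to)
      }, "")
    }
    Biostrings::DNAStringSet(setNames(seqs, combos))
  })
  validObject(plan)
  plan
}

#' Enumerate overlap-extension assembly products
#'
#' Concatenates one variant per tile, merging consecutive tiles on their
#' overlap windows.  A combination whose overlap sequences do not match
#' exactly cannot anneal and is excluded (and counted).  With a valid plan
#' the product count is the product of per-tile variant counts and the
#' products, translated at the site codons, reproduce the enumerated
#' library.
#'
#' @param plan a [TilePlan-class] with variants ([addTileVariants()]).
#' @return List with \code{products}, a named \code{DNAStringSet} (names are
#'   the genotypes read back from the assembled DNA), and
#'   \code{nImpossible}, the number of overlap-mismatch combinations.
#' @examples
#' plan <- addTileVariants(tileRegion(hcm1Region(), hcm1Scheme(), 6),
#'                         hcm1LibrarySpec("AE"))
#' length(enumerateAssemblyProducts(plan)$products)
#' @export
enumerateAssemblyProducts <- function(plan) {
  if (length(plan@variants) != length(plan@tiles))
    stop("plan has no variants; call addTileVariants() first")
  nT <- length(plan@tiles)
  tStart <- start(plan@tiles)
  tEnd <- end(plan@tiles)
  varChar <- lapply(plan@variants, as.character)
  ## assemble left to right, keeping partial products as character vectors
  partial <- varChar[[1]]
  impossible <- 0L
  if (nT > 1) for (i in 2:nT) {
    ovLen <- tEnd[i - 1L] - tStart[i] + 1L
    nxt <- varChar[[i]]
    grid <- expand.grid(a = seq_along(partial), b = seq_along(nxt))
    left <- partial[grid$a]
    right <- nxt[grid$b]
    ok <- substr(left, nchar(left) - ovLen + 1L, nchar(left)) ==
      substr(right, 1L, ovLen)
    impossible <- impossible + sum(!ok) *
      prod(lengths(varChar[seq.int(i + 1L, length.out = nT - i)]))
    partial <- paste0(left[ok], substr(right[ok], ovLen + 1L,
                                       nchar(right[ok])))
  }
  genotypes <- vapply(partial, readGenotype, "", scheme = plan@scheme,
                      USE.NAMES = FALSE)
  list(products = Biostrings::DNAStringSet(setNames(partial, genotypes)),
       nImpossible = impossible)
}

#' Write a tile plan to disk
#'
#' Serializes the plan as a TSV of tile coordinates plus a FASTA of all tile
#' variants (named \code{tile<i>_<states>}).
#'
#' @param plan a [TilePlan-class].
#' @param tsv,fasta output paths.
#' @return Invisibly, the TSV path.
#' @export
writeTilePlan <- function(plan, tsv, fasta = NULL) {
  write.table(tilePlanTable(plan), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fasta) && length(plan@variants)) {
    all <- do.call(c, lapply(seq_along(plan@variants), function(i) {
      v <- plan@variants[[i]]
      names(v) <- paste0("tile", i, "_", names(v))
      v
    }))
    Biostrings::writeXStringSet(all, fasta)
  }
  invisible(tsv)
}
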