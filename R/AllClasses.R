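#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement PDict matchPDict vmatchPattern
#'   extractAt width
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importFrom IRanges IRanges start end
#' @importFrom S4Vectors elementNROWS
#' @importFrom stats rnorm runif median cor
#' @importFrom utils write.table read.table
NULL

#' Assembly: a named collection of scaffolds
#'
#' An `Assembly` wraps a [Biostrings::DNAStringSet] of scaffold sequences
#' (alphabet `A`, `C`, `G`, `T`, `N` after normalization) together with an
#' assembly name and a composition table tracing every current scaffold back
#' to the original input contigs it was built from. The composition table is
#' what makes truth-based recovery scoring possible after several rounds of
#' joining: each row records one member contig of one scaffold, its relative
#' orientation (`F`/`R`) and its ordinal position inside the scaffold.
#'
#' @slot name single character, the assembly label (e.g. `"strainA"`).
#' @slot seqs [Biostrings::DNAStringSet] of scaffold sequences; names are the
#'   scaffold identifiers and must be unique.
#' @slot composition `data.frame` with columns `scaffold`, `member`,
#'   `orient`, `ord`.
#'
#' @seealso [readAssembly()], [assemblyStats()], [buildScaffolds()]
#' @export
setClass("Assembly",
  representation(name = "character", seqs = "DNAStringSet",
                 composition = "data.frame"))

setValidity("Assembly", function(object) {
  msg <- character()
  ids <- names(object@seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all scaffolds must be named")
  else if (anyDuplicated(ids))
    msg <- c(msg, "scaffold ids must be unique within an assembly")
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  comp <- object@composition
  need <- c("scaffold", "member", "orient", "ord")
  if (!all(need %in% names(comp)))
    msg <- c(msg, "composition must have columns scaffold/member/orient/ord")
  else if (!all(comp$scaffold %in% ids))
    msg <- c(msg, "composition refers to unknown scaffold ids")
  if (length(msg)) msg else TRUE
})

#' Construct an Assembly
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector)
#'   of scaffold sequences.
#' @param name assembly label.
#' @param composition optional composition `data.frame`; by default each
#'   scaffold is its own sole member in forward orientation.
#' @return an [Assembly-class] object.
#' @examples
#' a <- Assembly(c(s1 = "ACGT", s2 = "GGGTTT"), name = "toy")
#' nScaffolds(a)
#' @export
Assembly <- function(seqs, name = "assembly", composition = NULL) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (is.null(composition)) {
    composition <- data.frame(scaffold = names(seqs), member = names(seqs),
                              orient = "F", ord = 1L,
                              stringsAsFactors = FALSE)
  }
  new("Assembly", name = name, seqs = seqs, composition = composition)
}

#' Assembly contiguity statistics
#'
#' Holder for the usual draft-assembly summary numbers. `n50` is the length
#' of the scaffold at which the descending cumulative length first reaches
#' half of the total assembly length; `l50` is the number of scaffolds
#' contributing to that cumulative sum. N bases count toward all lengths.
#'
#' @slot totalLength,nScaffolds,longest,n50,l50,pctN numeric scalars.
#' @seealso [assemblyStats()]
#' @export
setClass("AssemblyStats",
  representation(totalLength = "numeric", nScaffolds = "numeric",
                 longest = "numeric", n50 = "numeric", l50 = "numeric",
                 pctN = "numeric"))

setValidity("AssemblyStats", function(object) {
  msg <- character()
  if (object@nScaffolds >= 1 && object@l50 < 1)
    msg <- c(msg, "l50 must be >= 1 for a non-empty assembly")
  if (object@n50 > object@longest) msg <- c(msg, "n50 cannot exceed longest")
  if (object@pctN < 0 || object@pctN > 100)
    msg <- c(msg, "pctN must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Mate-pair library specification
#'
#' Parameters of one simulated mate-pair library: target insert (fragment)
#' size, its standard deviation, the read length, the number of pairs and
#' the RNG seed making the library reproducible.
#'
#' @slot insertSize,insertSd,readLength,nPairs,seed numeric scalars.
#' @seealso [librarySpec()], [simulateLibrary()]
#' @export
setClass("LibrarySpec",
  representation(insertSize = "numeric", insertSd = "numeric",
                 readLength = "numeric", nPairs = "numeric",
                 seed = "numeric"))

setValidity("LibrarySpec", function(object) {
  msg <- character()
  if (object@readLength < 20) msg <- c(msg, "readLength must be >= 20")
  if (object@insertSize < 2 * object@readLength)
    msg <- c(msg, "insertSize must be >= 2 * readLength")
  if (!is.na(object@nPairs) && object@nPairs < 0)
    msg <- c(msg, "nPairs must be >= 0")
  if (object@insertSd < 0) msg <- c(msg, "insertSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a mate-pair library specification
#'
#' @param insertSize target fragment length in bases.
#' @param insertSd standard deviation of the fragment length; default 5% of
#'   `insertSize`.
#' @param readLength read length in bases (default 50).
#' @param nPairs number of pairs to draw. The default, `NA`, is resolved by
#'   [simulateLibrary()] to 1x read coverage of the source assembly,
#'   i.e. `totalLength / (2 * readLength)`.
#' @param seed integer RNG seed.
#' @return a [LibrarySpec-class] object.
#' @examples
#' librarySpec(1000, seed = 7)
#' @export
librarySpec <- function(insertSize, insertSd = 0.05 * insertSize,
                        readLength = 50, nPairs = NA_real_, seed = 1) {
  new("LibrarySpec", insertSize = insertSize, insertSd = insertSd,
      readLength = readLength, nPairs = as.numeric(nPairs), seed = seed)
}

#' k-mer searchable index of an assembly
#'
#' Internally the scaffolds are concatenated into a single subject sequence
#' separated by runs of N longer than a read, so one pattern search covers
#' the whole assembly and no read can match across a scaffold boundary.
#'
#' @slot subject concatenated [Biostrings::DNAString].
#' @slot offsets 0-based start of each scaffold inside `subject`.
#' @slot widths,ids per-scaffold lengths and identifiers.
#' @slot spacer spacer length between scaffolds.
#' @seealso [buildTargetIndex()], [placePairs()]
#' @export
setClass("TargetIndex",
  representation(subject = "DNAString", offsets = "numeric",
                 widths = "numeric", ids = "character", spacer = "numeric"))

#' One stitched chromosome arm
#'
#' The ordered, oriented scaffolds of one chromosome arm together with the
#' stitched pseudomolecule sequence (scaffolds separated by 1000-N spacers).
#'
#' @slot arm arm label (e.g. `"2R"`).
#' @slot members `data.frame` with columns `scaffold`, `orientation`
#'   (`F`/`R`/`unknown`), `meanRank`, `length`, `offset` (0-based start of
#'   the scaffold inside the stitched sequence).
#' @slot seq stitched [Biostrings::DNAString].
#' @seealso [stitchArms()], [writeAgp()]
#' @export
setClass("ArmBuild",
  representation(arm = "character", members = "data.frame", seq = "DNAString"))

setValidity("ArmBuild", function(object) {
  m <- object@members
  if (nrow(m) == 0) return(TRUE)
  expect <- sum(m$length) + 1000 * (nrow(m) - 1)
  if (length(object@seq) != expect)
    return(sprintf("stitched length %d != sum(lengths) + 1000*(n-1) = %d",
                   length(object@seq), expect))
  if (is.unsorted(m$meanRank)) return("members must be sorted by meanRank")
  TRUE
})
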