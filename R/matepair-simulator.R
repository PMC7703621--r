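# Error-free mate-pair simulation. Pairs follow the forward-reverse
# ("innie") convention: mate1 is the forward substring at the fragment
# start, mate2 the reverse complement of the substring at the fragment end.

# draw n fragments (scaffold index + 0-based start + length); returns a
# data.frame, possibly with fewer than n rows when draws fit nowhere
.drawFragments <- function(widths, n, insert, sd, rlen) {
  fl <- round(rnorm(n, insert, sd))
  fl <- pmax(fl, 2 * rlen)
  # draws that fit in no scaffold are discarded, not shrunk: a clamped
  # fragment no longer follows the declared insert distribution and
  # would poison downstream gap estimates
  fl <- fl[fl <= max(widths)]
  if (length(fl) == 0) return(data.frame(scaf = integer(),
                                         start = numeric(),
                                         len = numeric()))
  # eligible-position total per draw, accumulated scaffold by scaffold
  tot <- numeric(n)
  for (w in widths) tot <- tot + pmax(w - fl + 1, 0)
  ok <- tot > 0
  if (!any(ok)) return(data.frame(scaf = integer(), start = numeric(),
                                  len = numeric()))
  fl <- fl[ok]; tot <- tot[ok]
  u <- runif(length(fl)) * tot
  choice <- integer(length(u))
  cum <- numeric(length(u))
  for (i in seq_along(widths)) {
    e <- pmax(widths[i] - fl + 1, 0)
    hit <- choice == 0L & u < cum + e
    choice[hit] <- i
    cum <- cum + e
  }
  # float edge: u == total; the longest scaffold is always eligible
  choice[choice == 0L] <- which.max(widths)
  start <- floor(runif(length(u)) * (widths[choice] - fl + 1))
  data.frame(scaf = choice, start = start, len = fl)
}

.extractMates <- function(seqs, frag, rlen) {
  n <- nrow(frag)
  m1 <- character(n); m2 <- character(n)
  for (i in unique(frag$scaf)) {
    j <- which(frag$scaf == i)
    s1 <- extractAt(seqs[[i]], IRanges(frag$start[j] + 1, width = rlen))
    s2 <- extractAt(seqs[[i]],
                    IRanges(frag$start[j] + frag$len[j] - rlen + 1,
                            width = rlen))
    m1[j] <- as.character(s1)
    m2[j] <- as.character(reverseComplement(s2))
  }
  list(mate1 = m1, mate2 = m2)
}

#' Simulate an error-free mate-pair library
#'
#' Fragment lengths are drawn from a normal distribution (mean
#' `insertSize`, sd `insertSd`), rounded and clamped below at
#' `2 * readLength`; draws longer than every scaffold are discarded. Each
#' fragment is placed uniformly over the eligible start positions of the
#' assembly, scaffolds being weighted by their eligible-position count,
#' so fragments never cross a scaffold boundary. Reads are exact copies of the source
#' (zero errors). Fragments whose two mates both fall entirely inside runs
#' of N are rejected and redrawn (up to 3 refill passes, then skipped).
#' The library is deterministic given `spec@seed`.
#'
#' @param source an [Assembly-class] to simulate from.
#' @param spec a [LibrarySpec-class]. `nPairs = NA` (the default of
#'   [librarySpec()]) resolves to 1x read coverage,
#'   `totalLength / (2 * readLength)`.
#' @return a `data.frame` with columns `id`, `scaffold`, `start` (0-based
#'   fragment start), `fragLen`, `mate1`, `mate2`, carrying the spec as
#'   attribute `"spec"`. Zero rows (with a warning) if no scaffold can hold
#'   the insert.
#' @examples
#' a <- Assembly(c(s = paste(rep("ACGT", 500), collapse = "")), "toy")
#' lib <- simulateLibrary(a, librarySpec(200, insertSd = 0, seed = 1,
#'                                       nPairs = 10))
#' nrow(lib)
#' @export
simulateLibrary <- function(source, spec) {
  stopifnot(is(source, "Assembly"), is(spec, "LibrarySpec"))
  validObject(spec)
  seqs <- scaffolds(source)
  widths <- as.numeric(width(seqs))
  rlen <- spec@readLength
  n <- spec@nPairs
  if (is.na(n)) n <- round(sum(widths) / (2 * rlen))
  set.seed(spec@seed)
  empty <- data.frame(id = character(), scaffold = character(),
                      start = numeric(), fragLen = numeric(),
                      mate1 = character(), mate2 = character(),
                      stringsAsFactors = FALSE)
  if (max(widths) < 2 * rlen || n == 0) {
    warning("no scaffold long enough for any fragment; empty library")
    attr(empty, "spec") <- spec
    return(empty)
  }
  if (max(widths) < spec@insertSize)
    warning(sprintf(
      "insert %g exceeds longest scaffold (%g); most draws will not fit",
      spec@insertSize, max(widths)))
  keep <- NULL
  want <- n
  for (pass in 1:4) {
    frag <- .drawFragments(widths, want, spec@insertSize, spec@insertSd, rlen)
    if (nrow(frag) == 0) break
    mates <- .extractMates(seqs, frag, rlen)
    allN <- grepl("^N+$", mates$mate1) & grepl("^N+$", mates$mate2)
    ok <- data.frame(scaf = frag$scaf, start = frag$start, len = frag$len,
                     mate1 = mates$mate1, mate2 = mates$mate2,
                     stringsAsFactors = FALSE)[!allN, , drop = FALSE]
    keep <- rbind(keep, ok)
    want <- n - nrow(keep)
    if (want <= 0) break
  }
  if (is.null(keep) || nrow(keep) == 0) {
    warning("no placeable fragments; empty library")
    attr(empty, "spec") <- spec
    return(empty)
  }
  out <- data.frame(id = sprintf("p%07d", seq_len(nrow(keep))),
                    scaffold = names(seqs)[keep$scaf], start = keep$start,
                    fragLen = keep$len, mate1 = keep$mate1,
                    mate2 = keep$mate2, stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}

#' Write a mate-pair library as paired FASTQ
#'
#' Two files, `<prefix>_1.fq` and `<prefix>_2.fq`, read ids suffixed
#' `/1` and `/2`, fixed quality `I`.
#'
#' @param pairs data.frame from [simulateLibrary()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeLibraryFastq <- function(pairs, prefix) {
  f1 <- paste0(prefix, "_1.fq"); f2 <- paste0(prefix, "_2.fq")
  q <- strrep("I", if (nrow(pairs)) nchar(pairs$mate1[1]) else 0)
  writeLines(as.vector(rbind(paste0("@", pairs$id, "/1"), pairs$mate1,
                             "+", q)), f1)
  writeLines(as.vector(rbind(paste0("@", pairs$id, "/2"), pairs$mate2,
                             "+", q)), f2)
  invisible(c(f1, f2))
}
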