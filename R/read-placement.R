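# Seed-and-extend placement of simulated mate pairs on the partner
# assembly, and filtering down to confident concordant evidence.
#
# The matcher requires an exact k-mer seed at one end of the read (both
# ends are tried, on both strands) and extends over the full read counting
# mismatches, ungapped. A read is "unique" when a single location attains
# the minimal mismatch count and no other location lies within the
# uniqueness margin of 2 mismatches; with the search capped at
# `maxMismatch`, runner-ups beyond the cap are invisible, so a read with a
# single visible hit is classed unique.

#' Build a searchable index of an assembly
#'
#' Concatenates all scaffolds into one subject separated by `spacer` Ns
#' (longer than a read), so a single search covers the assembly and no
#' read can match across a scaffold boundary.
#'
#' @param assembly an [Assembly-class].
#' @param spacer inter-scaffold N-run length; must exceed the read length.
#' @return a [TargetIndex-class].
#' @export
buildTargetIndex <- function(assembly, spacer = 100) {
  stopifnot(is(assembly, "Assembly"))
  seqs <- scaffolds(assembly)
  w <- as.numeric(width(seqs))
  offsets <- cumsum(c(0, head(w + spacer, -1)))
  subject <- DNAString(paste(as.character(seqs),
                             collapse = strrep("N", spacer)))
  new("TargetIndex", subject = subject, offsets = offsets, widths = w,
      ids = names(seqs), spacer = spacer)
}

# all (pattern, start) hits of a constant-width DNAStringSet against the
# index subject with <= maxMismatch mismatches and an exact k-mer seed at
# either end of the pattern; returns data.frame(pat, start, mism)
.seedExtendHits <- function(pats, index, k, maxMismatch) {
  wd <- unique(nchar(as.character(pats)))
  stopifnot(length(wd) == 1, wd >= k)
  subject <- index@subject
  hits <- vector("list", 2)
  bands <- list(c(1, k), c(wd - k + 1, wd))
  for (b in seq_along(bands)) {
    pd <- PDict(pats, tb.start = bands[[b]][1], tb.end = bands[[b]][2])
    m <- matchPDict(pd, subject, max.mismatch = maxMismatch)
    cnt <- elementNROWS(m)
    if (sum(cnt) == 0) next
    ir <- unlist(m)
    hits[[b]] <- data.frame(pat = rep(seq_along(cnt), cnt), start = start(ir))
  }
  h <- do.call(rbind, hits)
  if (is.null(h) || nrow(h) == 0)
    return(data.frame(pat = integer(), start = integer(), mism = integer()))
  h <- h[!duplicated(h[c("pat", "start")]), , drop = FALSE]
  # with mismatches allowed outside the trusted band, matches may overhang
  # the subject edges; those are not placements
  h <- h[h$start >= 1 & h$start + wd - 1 <= length(subject), , drop = FALSE]
  if (nrow(h) == 0)
    return(data.frame(pat = integer(), start = integer(), mism = integer()))
  # drop hits not fully inside one scaffold (can only graze a spacer edge)
  scaf <- findInterval(h$start - 1, index@offsets)
  inside <- (h$start - 1 >= index@offsets[scaf]) &
    (h$start - 1 + wd <= index@offsets[scaf] + index@widths[scaf])
  h <- h[inside, , drop = FALSE]
  if (nrow(h) == 0)
    return(data.frame(pat = integer(), start = integer(), mism = integer()))
  win <- extractAt(subject, IRanges(h$start, width = wd))
  h$mism <- rowSums(as.matrix(win) != as.matrix(pats[h$pat]))
  h[h$mism <= maxMismatch, , drop = FALSE]
}

# classify hits of one strand-combined read set: returns per-read
# best scaffold/pos/strand/mism and class in {unique, multi, unplaced}
.classifyReads <- function(reads, index, k, maxMismatch) {
  n <- length(reads)
  out <- data.frame(scaffold = rep(NA_character_, n), pos = NA_real_,
                    strand = NA_character_, mism = NA_real_,
                    class = "unplaced", stringsAsFactors = FALSE)
  ok <- !grepl("N", reads, fixed = TRUE) & nchar(reads) >= k
  if (!any(ok)) return(out)
  idx <- which(ok)
  fwd <- DNAStringSet(reads[idx])
  rev <- reverseComplement(fwd)
  hf <- .seedExtendHits(fwd, index, k, maxMismatch)
  hr <- .seedExtendHits(rev, index, k, maxMismatch)
  hf$strand <- rep("+", nrow(hf)); hr$strand <- rep("-", nrow(hr))
  h <- rbind(hf, hr)
  if (nrow(h) == 0) return(out)
  # per-read uniqueness: one best location, margin 2 (see header comment)
  o <- order(h$pat, h$mism, h$start, h$strand)
  h <- h[o, , drop = FALSE]
  first <- !duplicated(h$pat)
  nh <- tabulate(h$pat, nbins = length(idx))
  best <- h[first, , drop = FALSE]
  minm <- best$mism[match(h$pat, best$pat)]
  close2 <- tapply(h$mism <= minm + 1, h$pat, sum)
  cls <- ifelse(nh[best$pat] == 1L, "unique",
                ifelse(close2[as.character(best$pat)] == 1, "unique", "multi"))
  scaf <- findInterval(best$start - 1, index@offsets)
  rows <- idx[best$pat]
  out$scaffold[rows] <- index@ids[scaf]
  out$pos[rows] <- best$start - 1 - index@offsets[scaf]  # 0-based local
  out$strand[rows] <- best$strand
  out$mism[rows] <- best$mism
  out$class[rows] <- cls
  out
}

#' Place mate pairs on a target assembly
#'
#' Both mates of every pair are placed independently with the
#' seed-and-extend matcher (exact `k`-mer seed at either read end, both
#' strands, ungapped extension counting mismatches). Reads containing `N`
#' are classed unplaced.
#'
#' @param pairs data.frame from [simulateLibrary()].
#' @param index a [TargetIndex-class] of the assembly being scaffolded.
#' @param k seed length (default 21).
#' @param maxMismatch maximum mismatches per read (default 2).
#' @return the input data.frame augmented with, per mate `i` in 1:2,
#'   columns `scaffold<i>`, `pos<i>` (0-based start on the scaffold's
#'   forward strand), `strand<i>`, `mism<i>`, `class<i>`
#'   (`unique`/`multi`/`unplaced`).
#' @export
placePairs <- function(pairs, index, k = 21, maxMismatch = 2) {
  stopifnot(is(index, "TargetIndex"))
  for (i in 1:2) {
    p <- .classifyReads(pairs[[paste0("mate", i)]], index, k, maxMismatch)
    pairs[[paste0("scaffold", i)]] <- p$scaffold
    pairs[[paste0("pos", i)]] <- p$pos
    pairs[[paste0("strand", i)]] <- p$strand
    pairs[[paste0("mism", i)]] <- p$mism
    pairs[[paste0("class", i)]] <- p$class
  }
  pairs
}

#' Filter placed pairs to concordant evidence
#'
#' Keeps pairs with both mates uniquely placed and orientation compatible
#' with the forward-reverse convention. Pairs with both mates on one
#' scaffold ("internal") must additionally satisfy
#' `|span - insertSize| <= tau * insertSize`. Pairs bridging two scaffolds
#' ("linking") are the scaffolding currency: their span across the unknown
#' gap is not computable, so they are kept whenever the implied join
#' geometry is feasible (each mate within an insert of the linked scaffold
#' end, i.e. implied gap > `-tau * insertSize`).
#'
#' For a linking pair the implied join reads left-to-right in fragment
#' direction: mate1's scaffold joins through its tail if mate1 is on `+`
#' (head if `-`), mate2's scaffold joins through its head if mate2 is on
#' `-` (tail if `+`). The per-pair gap estimate is
#' `insert - dA - dB` where `dA`/`dB` are the distances from each mate's
#' outer edge to the linked scaffold end.
#'
#' @param placed data.frame from [placePairs()] (spec attribute intact).
#' @param index the [TargetIndex-class] used for placement (for scaffold
#'   lengths).
#' @param tau insert-size tolerance as a fraction in (0, 1); default 0.25.
#' @return a `data.frame` with columns `id`, `class`
#'   (`internal`/`linking`), `scafA`, `endA`, `scafB`, `endB`, `gap`,
#'   `span`, `insert`. For internal pairs `scafA == scafB` and `gap` is
#'   `NA`.
#' @export
filterPairs <- function(placed, index, tau = 0.25) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  spec <- attr(placed, "spec")
  if (is.null(spec)) stop("placed pairs lack the library spec attribute")
  insert <- spec@insertSize
  rlen <- spec@readLength
  wid <- stats::setNames(index@widths, index@ids)

  empty <- data.frame(id = character(), class = character(),
                      scafA = character(), endA = character(),
                      scafB = character(), endB = character(),
                      gap = numeric(), span = numeric(), insert = numeric(),
                      stringsAsFactors = FALSE)
  attr(empty, "insert") <- insert
  attr(empty, "insertSd") <- spec@insertSd
  attr(empty, "readLength") <- rlen
  keep <- placed$class1 == "unique" & placed$class2 == "unique"
  p <- placed[keep, , drop = FALSE]
  if (nrow(p) == 0) return(empty)

  same <- p$scaffold1 == p$scaffold2
  out <- list()

  ## internal pairs: FR orientation + span window
  s <- p[same, , drop = FALSE]
  if (nrow(s)) {
    fr1 <- s$strand1 == "+" & s$strand2 == "-" & s$pos1 <= s$pos2
    fr2 <- s$strand1 == "-" & s$strand2 == "+" & s$pos2 <= s$pos1
    span <- ifelse(fr1, s$pos2 + rlen - s$pos1,
                   ifelse(fr2, s$pos1 + rlen - s$pos2, NA_real_))
    okspan <- !is.na(span) & abs(span - insert) <= tau * insert
    s <- s[okspan, , drop = FALSE]; span <- span[okspan]
    if (nrow(s))
      out$internal <- data.frame(id = s$id, class = "internal",
                                 scafA = s$scaffold1, endA = NA_character_,
                                 scafB = s$scaffold2, endB = NA_character_,
                                 gap = NA_real_, span = span,
                                 insert = insert, stringsAsFactors = FALSE)
  }

  ## linking pairs: derive join geometry and per-pair gap
  l <- p[!same, , drop = FALSE]
  if (nrow(l)) {
    endA <- ifelse(l$strand1 == "+", "tail", "head")
    endB <- ifelse(l$strand2 == "-", "head", "tail")
    dA <- ifelse(l$strand1 == "+", wid[l$scaffold1] - l$pos1, l$pos1 + rlen)
    dB <- ifelse(l$strand2 == "-", l$pos2 + rlen, wid[l$scaffold2] - l$pos2)
    gap <- insert - dA - dB
    feas <- gap > -tau * insert
    l <- l[feas, , drop = FALSE]
    if (nrow(l)) {
      lk <- data.frame(id = l$id, class = "linking",
                       scafA = l$scaffold1, endA = endA[feas],
                       scafB = l$scaffold2, endB = endB[feas],
                       gap = gap[feas], span = NA_real_, insert = insert,
                       stringsAsFactors = FALSE)
      # canonical order within the pair: smaller scaffold id first
      sw <- lk$scafB < lk$scafA
      tmp <- lk[sw, ]
      lk[sw, c("scafA", "endA")] <- tmp[, c("scafB", "endB")]
      lk[sw, c("scafB", "endB")] <- tmp[, c("scafA", "endA")]
      out$linking <- lk
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "insert") <- insert
  attr(res, "insertSd") <- spec@insertSd
  attr(res, "readLength") <- rlen
  res
}
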