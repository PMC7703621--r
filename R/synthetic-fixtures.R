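# Synthetic two-strain fixtures with truth tables, and recovery scoring.
# The generator emulates the real use case at desk scale: one ancestral
# chromosome, two strain drafts that each carry independent substitutions
# and independent fragmentation breakpoints, and a regularly spaced
# physical-marker track with arm labels and ranks.

.BASES <- c("A", "C", "G", "T")

# substitute positions of a base vector at `rate`, never to the same base
.mutate <- function(v, rate) {
  idx <- which(runif(length(v)) < rate)
  if (length(idx)) {
    bi <- match(v[idx], .BASES)
    v[idx] <- .BASES[((bi - 1 + sample.int(3, length(idx), replace = TRUE))
                      %% 4) + 1]
  }
  v
}

# cut [0, L) into tiles with exponentially distributed lengths
# (mean meanContig, minimum 500); returns data.frame(start, end)
.tile <- function(L, meanContig) {
  lens <- numeric()
  while (sum(lens) < L)
    lens <- c(lens, pmax(round(rexp(ceiling(L / meanContig) + 10,
                                    1 / meanContig)), 500))
  cs <- cumsum(lens)
  n <- which(cs >= L)[1]
  lens <- lens[seq_len(n)]
  lens[n] <- L - sum(lens[-n])
  if (n > 1 && lens[n] < 500) {  # fold a short tail into its neighbour
    lens[n - 1] <- lens[n - 1] + lens[n]
    lens <- lens[-n]
  }
  ends <- cumsum(lens)
  data.frame(start = c(0, head(ends, -1)), end = ends)
}

#' Generate a pair of diverged, fragmented strain drafts with truth
#'
#' A uniform random ancestor of the given length is drawn; each draft then
#' receives independent substitutions at rate `divergence` and independent
#' fragmentation breakpoints (exponential spacing with mean `meanContig`,
#' minimum contig 500 bp). Contigs are shuffled and randomly
#' strand-flipped. The truth table records each contig's ancestral
#' interval (0-based half-open) and strand. Everything is deterministic
#' given `seed`.
#'
#' @param length ancestor length in bases (>= 10 * `meanContig`).
#' @param divergence per-base substitution rate in \[0, 0.05\].
#' @param meanContig mean contig length in bases.
#' @param seed integer RNG seed.
#' @param fragmentB if `FALSE`, draft B is the (mutated) ancestor in one
#'   piece — the idealized "unfragmented partner" limit.
#' @return a list with elements `A`, `B` ([Assembly-class] drafts),
#'   `truth` (data.frame `contig`, `draft`, `ancStart`, `ancEnd`,
#'   `strand`) and `ancestor` (character).
#' @examples
#' fx <- makeStrainPair(50000, divergence = 0, meanContig = 5000, seed = 1)
#' nScaffolds(fx$A)
#' @export
makeStrainPair <- function(length = 2e6, divergence = 0.01,
                           meanContig = 1e4, seed = 1, fragmentB = TRUE) {
  if (length < 10 * meanContig)
    stop("length must be >= 10 * meanContig")
  if (divergence < 0 || divergence > 0.05)
    stop("divergence must lie in [0, 0.05]")
  set.seed(seed)
  anc <- sample(.BASES, length, replace = TRUE)
  truth <- list()
  drafts <- list()
  for (d in c("A", "B")) {
    v <- .mutate(anc, divergence)
    tiles <- if (d == "B" && !fragmentB)
      data.frame(start = 0, end = length) else .tile(length, meanContig)
    n <- nrow(tiles)
    ids <- sprintf("%s_c%04d", d, seq_len(n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    if (n == 1) strand <- "+"
    seqs <- vapply(seq_len(n), function(i) {
      s <- paste(v[(tiles$start[i] + 1):tiles$end[i]], collapse = "")
      if (strand[i] == "-")
        s <- as.character(reverseComplement(DNAString(s)))
      s
    }, "")
    ord <- sample.int(n)
    drafts[[d]] <- Assembly(stats::setNames(DNAStringSet(seqs[ord]),
                                            ids[ord]),
                            name = paste0("strain", d))
    truth[[d]] <- data.frame(contig = ids, draft = d,
                             ancStart = tiles$start, ancEnd = tiles$end,
                             strand = strand, stringsAsFactors = FALSE)
  }
  list(A = drafts$A, B = drafts$B,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       ancestor = paste(anc, collapse = ""))
}

#' Excise a regularly spaced marker track from an ancestor
#'
#' Markers are taken verbatim from the ancestor every `spacing` bases and
#' labelled with a chromosome arm (by ancestral position relative to
#' `armBoundaries`) and a rank ascending along each arm — the synthetic
#' analogue of a low-resolution physical map.
#'
#' @param ancestor ancestor sequence (character).
#' @param spacing distance between marker starts in bases
#'   (> `markerLen`, < ancestor length).
#' @param markerLen marker length in bases.
#' @param armBoundaries named numeric vector: 0-based ancestral start of
#'   each arm, in ascending order. Default: two arms `2R`/`2L` split at
#'   the midpoint.
#' @return data.frame `id`, `arm`, `rank`, `ancStart` (0-based),
#'   `sequence`.
#' @examples
#' fx <- makeStrainPair(1e5, 0, 1e4, seed = 1)
#' mk <- makeMarkerSet(fx$ancestor, spacing = 2e4, markerLen = 500)
#' nrow(mk)  # floor(1e5 / 2e4) = 5
#' @export
makeMarkerSet <- function(ancestor, spacing = 2e4, markerLen = 500,
                          armBoundaries = NULL) {
  L <- nchar(ancestor)
  if (spacing >= L) stop("spacing must be smaller than the ancestor")
  if (spacing <= markerLen) stop("spacing must exceed markerLen")
  if (is.null(armBoundaries))
    armBoundaries <- stats::setNames(c(0, floor(L / 2)), c("2R", "2L"))
  if (is.unsorted(armBoundaries)) stop("armBoundaries must be ascending")
  starts <- seq(0, L - markerLen, by = spacing)
  arm <- names(armBoundaries)[findInterval(starts, armBoundaries)]
  rank <- stats::ave(starts, arm, FUN = seq_along)
  data.frame(id = sprintf("m%04d", seq_along(starts)), arm = arm,
             rank = as.integer(rank), ancStart = starts,
             sequence = substring(ancestor, starts + 1, starts + markerLen),
             stringsAsFactors = FALSE)
}

#' Score reconstruction accuracy against the truth table
#'
#' Uses the assembly's composition table (original contig ids survive
#' every joining round) to compare each join made by the scaffolder with
#' ancestral adjacency. A join between consecutive members `u`, `v` is
#' correct when their effective ancestral directions agree and `v`'s
#' ancestral interval abuts `u`'s on the appropriate side. Orientation
#' accuracy is the fraction of members of multi-member scaffolds whose
#' effective direction agrees with their scaffold's majority direction.
#'
#' @param result an [Assembly-class] whose composition members are truth
#'   contigs.
#' @param truth truth data.frame from [makeStrainPair()] (rows of the
#'   relevant draft).
#' @return list `adjacencyAccuracy`, `orientationAccuracy`, `misjoins`,
#'   `joins`, `contigsInJoins`.
#' @export
scoreRecovery <- function(result, truth) {
  stopifnot(is(result, "Assembly"))
  comp <- composition(result)
  unknown <- setdiff(comp$member, truth$contig)
  if (length(unknown))
    stop("composition members missing from truth: ",
         paste(head(unknown, 5), collapse = ", "))
  ts <- truth[match(comp$member, truth$contig), ]
  # effective ancestral direction of each member in its output scaffold
  comp$dir <- ifelse((ts$strand == "+") == (comp$orient == "F"), "+", "-")
  comp$as <- ts$ancStart
  comp$ae <- ts$ancEnd
  joins <- 0; correct <- 0
  orientTot <- 0; orientOk <- 0
  for (sc in unique(comp$scaffold)) {
    m <- comp[comp$scaffold == sc, , drop = FALSE]
    m <- m[order(m$ord), , drop = FALSE]
    if (nrow(m) < 2) next
    for (i in seq_len(nrow(m) - 1)) {
      u <- m[i, ]; v <- m[i + 1, ]
      ok <- u$dir == v$dir &&
        ((u$dir == "+" && u$ae == v$as) || (u$dir == "-" && u$as == v$ae))
      joins <- joins + 1
      correct <- correct + ok
    }
    maj <- names(which.max(table(m$dir)))
    orientTot <- orientTot + nrow(m)
    orientOk <- orientOk + sum(m$dir == maj)
  }
  list(adjacencyAccuracy = if (joins) correct / joins else NA_real_,
       orientationAccuracy = if (orientTot) orientOk / orientTot
         else NA_real_,
       misjoins = joins - correct, joins = joins,
       contigsInJoins = orientTot)
}
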