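# Physical-marker anchoring of scaffolds, chromosome-arm assignment with
# conflict resolution, orientation/ordering by marker rank, and stitching
# of pseudomolecules with 1000-N spacers.
#
# The default alignment engine is a built-in k-mer-anchored ungapped
# aligner: exact 21-mer anchors locate each marker on either strand and
# the full marker is then compared base-by-base, clipped at scaffold
# edges. Identity, a blastn-like ungapped bit-score (+1 match / -2
# mismatch; lambda = 1.33, K = 0.621) and the Karlin-Altschul e-value are
# reported, so any tabular local aligner could stand in.

.KA_LAMBDA <- 1.33
.KA_K <- 0.621

#' Read a marker set from FASTA
#'
#' Headers carry the structured form `>id|arm|rank`.
#'
#' @param path FASTA path.
#' @return data.frame `id`, `arm`, `rank`, `sequence`.
#' @export
readMarkers <- function(path) {
  seqs <- readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("marker headers must be 'id|arm|rank'")
  data.frame(id = unname(vapply(parts, `[`, "", 1)),
             arm = unname(vapply(parts, `[`, "", 2)),
             rank = as.integer(vapply(parts, `[`, "", 3)),
             sequence = unname(.normalizeSeq(as.character(seqs))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a marker set to FASTA
#'
#' @param markers data.frame with columns `id`, `arm`, `rank`, `sequence`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMarkers <- function(markers, path) {
  s <- DNAStringSet(markers$sequence)
  names(s) <- paste(markers$id, markers$arm, markers$rank, sep = "|")
  writeXStringSet(s, path, width = 60L)
  invisible(path)
}

#' Map physical markers onto an assembly
#'
#' Each marker is aligned on both strands with the built-in anchored
#' aligner; the single best-scoring local hit is retained if and only if
#' it passes the stringency gates (`evalue`, `minIdentity`, `minLen`).
#' Markers failing all gates are reported unmapped.
#'
#' @param markers data.frame `id`, `arm`, `rank`, `sequence`.
#' @param assembly an [Assembly-class].
#' @param evalue maximum e-value (default 1e-25).
#' @param minIdentity minimum percent identity (default 90).
#' @param minLen minimum alignment length in bp (default 100).
#' @param k anchor k-mer length (default 21).
#' @return list with `hits` (data.frame `marker`, `scaffold`, `start`,
#'   `end` 1-based inclusive on the scaffold forward strand, `strand`,
#'   `identity`, `evalue`, `alen`, `bits`) and `unmapped` (character ids).
#' @export
mapMarkers <- function(markers, assembly, evalue = 1e-25, minIdentity = 90,
                       minLen = 100, k = 21) {
  stopifnot(is(assembly, "Assembly"))
  if (nrow(markers) == 0) stop("empty marker set")
  index <- buildTargetIndex(assembly)
  subjChr <- as.character(index@subject)
  nTotal <- sum(index@widths)
  hits <- list(); unmapped <- character()
  for (i in seq_len(nrow(markers))) {
    mseq <- markers$sequence[i]
    len <- nchar(mseq)
    pats <- c("+" = mseq,
              "-" = as.character(reverseComplement(DNAString(mseq))))
    offs <- unique(pmax(1, c(1, floor((len - k) / 2) + 1, len - k + 1)))
    cand <- NULL
    for (st in names(pats)) {
      for (o in offs) {
        seed <- substr(pats[[st]], o, o + k - 1)
        if (grepl("N", seed, fixed = TRUE)) next
        mp <- Biostrings::matchPattern(DNAString(seed), index@subject)
        if (length(mp) == 0) next
        cand <- rbind(cand, data.frame(start = start(mp) - (o - 1),
                                       strand = st,
                                       stringsAsFactors = FALSE))
      }
    }
    if (is.null(cand)) { unmapped <- c(unmapped, markers$id[i]); next }
    cand <- cand[!duplicated(cand), , drop = FALSE]
    best <- NULL
    for (j in seq_len(nrow(cand))) {
      s <- cand$start[j]                      # 1-based on subject
      sc <- findInterval(s - 1 + len / 2, index@offsets)
      lo <- index@offsets[sc] + 1; hi <- index@offsets[sc] + index@widths[sc]
      ws <- max(s, lo); we <- min(s + len - 1, hi)
      alen <- we - ws + 1
      if (alen < 1) next
      pat <- substr(pats[[cand$strand[j]]], ws - s + 1, we - s + 1)
      subj <- substr(subjChr, ws, we)
      mism <- sum(utf8ToInt(pat) != utf8ToInt(subj))
      score <- (alen - mism) - 2 * mism
      bits <- (.KA_LAMBDA * score - log(.KA_K)) / log(2)
      ev <- len * nTotal * 2^(-bits)
      h <- data.frame(marker = markers$id[i], scaffold = index@ids[sc],
                      start = ws - index@offsets[sc],
                      end = we - index@offsets[sc],
                      strand = cand$strand[j],
                      identity = 100 * (alen - mism) / alen,
                      evalue = ev, alen = alen, bits = bits,
                      stringsAsFactors = FALSE)
      if (is.null(best) || h$bits > best$bits) best <- h
    }
    if (!is.null(best) && best$evalue <= evalue &&
        best$identity >= minIdentity && best$alen >= minLen)
      hits[[length(hits) + 1]] <- best
    else unmapped <- c(unmapped, markers$id[i])
  }
  list(hits = if (length(hits)) do.call(rbind, hits) else
         data.frame(marker = character(), scaffold = character(),
                    start = numeric(), end = numeric(),
                    strand = character(), identity = numeric(),
                    evalue = numeric(), alen = numeric(), bits = numeric(),
                    stringsAsFactors = FALSE),
       unmapped = unmapped)
}

# strict monotonicity of rank along scaffold coordinate for a block
.isLinear <- function(rank, start) {
  if (length(rank) < 3) return(TRUE)
  tau <- suppressWarnings(cor(rank, start, method = "kendall"))
  !is.na(tau) && abs(tau) > 0.99
}

#' Assign scaffolds to chromosome arms, resolving conflicts
#'
#' Scaffolds whose markers all come from one arm take that arm. A
#' multi-arm scaffold goes to the arm with the most markers; ties are
#' broken by the larger sum of identity x alignment length. When the
#' minority markers form a terminal block, both arm blocks are internally
#' linear, and the two arms belong to the same chromosome, the scaffold
#' is classed centromere-spanning (status `centromere`): it keeps its
#' majority arm, whose rank ordering places it at the centromere-proximal
#' junction. Any other multi-arm scaffold is flagged `conflict`.
#'
#' @param hits data.frame from [mapMarkers()].
#' @param markers marker data.frame (for `arm` and `rank`).
#' @return list with `assignment` (data.frame `scaffold`, `arm`,
#'   `nMarkers`, `status`) and `conflicts` (data.frame `scaffold`, `arm`,
#'   `nMarkers`, `note` for every minority block).
#' @export
assignArms <- function(hits, markers) {
  h <- merge(hits, markers[c("id", "arm", "rank")],
             by.x = "marker", by.y = "id")
  assign <- list(); conflicts <- list()
  for (sc in sort(unique(h$scaffold))) {
    hs <- h[h$scaffold == sc, , drop = FALSE]
    hs <- hs[order(hs$start), , drop = FALSE]
    cnt <- sort(table(hs$arm), decreasing = TRUE)
    if (length(cnt) == 1) {
      assign[[sc]] <- data.frame(scaffold = sc, arm = names(cnt),
                                 nMarkers = as.integer(cnt),
                                 status = "assigned",
                                 stringsAsFactors = FALSE)
      next
    }
    # majority, ties by sum(identity * alen)
    topN <- names(cnt)[cnt == max(cnt)]
    if (length(topN) > 1) {
      wt <- vapply(topN, function(a)
        sum(hs$identity[hs$arm == a] * hs$alen[hs$arm == a]), 0)
      major <- topN[order(-wt, topN)][1]
    } else major <- topN[1]
    minor <- setdiff(names(cnt), major)
    sameChrom <- length(minor) == 1 &&
      sub("[RL]$", "", minor) == sub("[RL]$", "", major) &&
      minor != major
    isMin <- hs$arm != major
    terminal <- all(which(isMin) == seq_len(sum(isMin))) ||
      all(which(isMin) == (nrow(hs) - sum(isMin) + 1):nrow(hs))
    linear <- .isLinear(hs$rank[!isMin], hs$start[!isMin]) &&
      .isLinear(hs$rank[isMin], hs$start[isMin])
    status <- if (sameChrom && terminal && linear) "centromere"
      else "conflict"
    assign[[sc]] <- data.frame(scaffold = sc, arm = major,
                               nMarkers = as.integer(sum(!isMin)),
                               status = status, stringsAsFactors = FALSE)
    for (a in minor)
      conflicts[[paste(sc, a)]] <- data.frame(
        scaffold = sc, arm = a, nMarkers = sum(hs$arm == a),
        note = if (status == "centromere") "centromere-spanning block"
          else "minority markers flagged", stringsAsFactors = FALSE)
  }
  list(assignment = do.call(rbind, c(assign, make.row.names = FALSE)),
       conflicts = if (length(conflicts))
         do.call(rbind, c(conflicts, make.row.names = FALSE))
       else data.frame(scaffold = character(), arm = character(),
                       nMarkers = integer(), note = character(),
                       stringsAsFactors = FALSE))
}

#' Orient scaffolds and rank them along their arm
#'
#' Orientation is the sign of the Kendall tau between marker rank and hit
#' start coordinate over the scaffold's assigned-arm markers: `F` for
#' positive, `R` for negative, `unknown` for tau = 0 or a single marker
#' (such scaffolds are kept in the given orientation and flagged — the
#' "pseudo inversion" behaviour). The scaffold's position on the arm is
#' the mean of its member marker ranks.
#'
#' @param hits data.frame from [mapMarkers()].
#' @param markers marker data.frame.
#' @param assignment data.frame from [assignArms()].
#' @return data.frame `scaffold`, `arm`, `orientation`, `meanRank`,
#'   `nMarkers`.
#' @export
orientAndRank <- function(hits, markers, assignment) {
  h <- merge(hits, markers[c("id", "arm", "rank")],
             by.x = "marker", by.y = "id")
  out <- list()
  for (i in seq_len(nrow(assignment))) {
    sc <- assignment$scaffold[i]; arm <- assignment$arm[i]
    hs <- h[h$scaffold == sc & h$arm == arm, , drop = FALSE]
    if (nrow(hs) == 0) next
    if (nrow(hs) == 1) { ornt <- "unknown"; tau <- NA_real_ }
    else {
      tau <- suppressWarnings(cor(hs$rank, hs$start, method = "kendall"))
      ornt <- if (is.na(tau) || tau == 0) "unknown"
        else if (tau > 0) "F" else "R"
    }
    out[[sc]] <- data.frame(scaffold = sc, arm = arm, orientation = ornt,
                            meanRank = mean(hs$rank),
                            nMarkers = nrow(hs), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Stitch chromosome arms into pseudomolecules
#'
#' Within each arm, scaffolds are sorted by mean marker rank and
#' concatenated with 1000-N spacers; `R` scaffolds are
#' reverse-complemented, `unknown` ones kept forward. Scaffolds not
#' placed on any arm are returned untouched as a separate assembly.
#'
#' @param orientation data.frame from [orientAndRank()].
#' @param assembly the [Assembly-class] the scaffolds come from.
#' @param arms optional character vector of all expected arms; arms with
#'   zero scaffolds produce a warning and no build.
#' @return list with `builds` (named list of [ArmBuild-class]) and
#'   `unplaced` ([Assembly-class] or `NULL`).
#' @export
stitchArms <- function(orientation, assembly, arms = NULL) {
  stopifnot(is(assembly, "Assembly"))
  if (anyDuplicated(orientation$scaffold))
    stop("a scaffold is referenced by more than one arm")
  seqs <- scaffolds(assembly)
  missing <- setdiff(orientation$scaffold, names(seqs))
  if (length(missing)) stop("unknown scaffolds: ",
                            paste(missing, collapse = ", "))
  if (is.null(arms)) arms <- unique(orientation$arm)
  builds <- list()
  for (a in arms) {
    m <- orientation[orientation$arm == a, , drop = FALSE]
    if (nrow(m) == 0) {
      warning("no scaffolds assigned to arm ", a)
      next
    }
    m <- m[order(m$meanRank, m$scaffold), , drop = FALSE]
    m$length <- as.numeric(width(seqs[m$scaffold]))
    m$offset <- cumsum(c(0, head(m$length + 1000, -1)))
    pieces <- as.character(seqs[m$scaffold])
    flip <- m$orientation == "R"
    pieces[flip] <- as.character(reverseComplement(
      DNAStringSet(pieces[flip])))
    builds[[a]] <- new("ArmBuild", arm = a,
                       members = m[c("scaffold", "orientation", "meanRank",
                                     "length", "offset")],
                       seq = DNAString(paste(pieces,
                                             collapse = strrep("N", 1000))))
  }
  rest <- setdiff(names(seqs), orientation$scaffold)
  unplaced <- if (length(rest))
    Assembly(seqs[rest], name = paste0(assemblyName(assembly), "_unplaced"),
             composition = composition(assembly)[
               composition(assembly)$scaffold %in% rest, , drop = FALSE])
  else NULL
  list(builds = builds, unplaced = unplaced)
}

#' Marker-order linearity of a stitched arm
#'
#' Relocates every retained marker of the arm into pseudomolecule
#' coordinates by offset arithmetic and reports the Kendall tau between
#' marker rank and position, plus the fraction of adjacent rank pairs in
#' order.
#'
#' @param build an [ArmBuild-class].
#' @param hits data.frame from [mapMarkers()].
#' @param markers marker data.frame.
#' @return list `arm`, `tau`, `adjacentFrac`, `nMarkers`; `tau` is `NA`
#'   when fewer than two of the arm's markers are placed.
#' @export
linearityScore <- function(build, hits, markers) {
  stopifnot(is(build, "ArmBuild"))
  m <- armMembers(build)
  h <- merge(hits, markers[c("id", "arm", "rank")],
             by.x = "marker", by.y = "id")
  h <- h[h$arm == armName(build) & h$scaffold %in% m$scaffold, ,
         drop = FALSE]
  if (nrow(h) < 2)
    return(list(arm = armName(build), tau = NA_real_,
                adjacentFrac = NA_real_, nMarkers = nrow(h)))
  mi <- match(h$scaffold, m$scaffold)
  pos <- ifelse(m$orientation[mi] == "R",
                m$offset[mi] + (m$length[mi] - h$end + 1),
                m$offset[mi] + h$start)
  o <- order(h$rank)
  tau <- suppressWarnings(cor(h$rank, pos, method = "kendall"))
  adj <- mean(diff(pos[o]) > 0)
  list(arm = armName(build), tau = tau, adjacentFrac = adj,
       nMarkers = nrow(h))
}
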