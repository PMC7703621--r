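# Aggregation of linking pairs into bundles and greedy joining of
# scaffolds into super-scaffolds with estimated gaps.

#' Per-pair gap estimate for a linking mate pair
#'
#' `gap = insert - dA - dB`, where `dA` is the distance from mate1's outer
#' edge to the linked end of its scaffold and `dB` the distance from the
#' linked end of the partner scaffold to mate2's outer edge. The estimate
#' is signed; negative values imply overlap and are floored at emission
#' time.
#'
#' @param insert library insert size in bases.
#' @param dA,dB distances as defined above.
#' @return signed gap estimate in bases.
#' @examples
#' estimateGap(1000, 300, 200)  # 500
#' @export
estimateGap <- function(insert, dA, dB) insert - dA - dB

#' Aggregate linking pairs into link bundles
#'
#' Linking pairs are grouped by their join signature: the ordered pair of
#' (scaffold, end) they connect, which fixes the implied relative
#' orientation (tail-head joins read forward-forward, and so on). Pairs
#' implying a partner forward versus reverse-complement fall in distinct
#' bundles. The bundle gap is the median of the member per-pair gap
#' estimates. Bundles with fewer than `minLinks` supporting pairs are
#' discarded, as are bundles whose median implied overlap exceeds the
#' gap-estimate noise floor (`2 * readLength + 3 * insertSd /
#' sqrt(support)`): a coherent large negative gap is containment evidence
#' (the partner lies inside the other scaffold's span), not a join.
#'
#' @param conc data.frame from [filterPairs()]; only rows with
#'   `class == "linking"` are used.
#' @param minLinks minimum supporting pairs per bundle (default 5).
#' @return a `data.frame` with columns `scafA`, `endA`, `scafB`, `endB`,
#'   `support`, `gap`, `insert`.
#' @export
bundleLinks <- function(conc, minLinks = 5) {
  insertSd <- attr(conc, "insertSd")
  rlen <- attr(conc, "readLength")
  l <- conc[conc$class == "linking", , drop = FALSE]
  if (nrow(l) == 0)
    return(data.frame(scafA = character(), endA = character(),
                      scafB = character(), endB = character(),
                      support = numeric(), gap = numeric(),
                      insert = numeric(), stringsAsFactors = FALSE))
  key <- paste(l$scafA, l$endA, l$scafB, l$endB, sep = "\r")
  sp <- split(seq_len(nrow(l)), key)
  b <- do.call(rbind, lapply(sp, function(ix) {
    data.frame(scafA = l$scafA[ix[1]], endA = l$endA[ix[1]],
               scafB = l$scafB[ix[1]], endB = l$endB[ix[1]],
               support = length(ix), gap = median(l$gap[ix]),
               insert = l$insert[ix[1]], stringsAsFactors = FALSE)
  }))
  rownames(b) <- NULL
  b <- b[b$support >= minLinks, , drop = FALSE]
  if (is.null(insertSd)) insertSd <- 0.05 * b$insert
  if (is.null(rlen)) rlen <- 50
  floorGap <- -(2 * rlen + 3 * insertSd / sqrt(b$support))
  b[b$gap >= floorGap, , drop = FALSE]
}

# Transitive reallocation of "skip" evidence. A strong bundle A--B whose
# gap is wide enough to hold a scaffold P that weaker bundles place
# exactly inside it (gap(A,P) + len(P) + gap(P,B) matching gap(A,B)
# within slack) is not independent evidence for joining A to B: every one
# of its pairs is equally evidence for the chain A-P-B. Its support is
# added to the two nested bundles and the skip bundle is dropped. This
# lets short scaffolds — whose own link windows are too small to reach
# the support threshold — be rescued by the long-range pairs that see
# past them, instead of being skipped over.
.reallocateNested <- function(b, scafLen, minLinks, slackFrac) {
  opp <- c(head = "tail", tail = "head")
  for (pass in 1:3) {
    if (nrow(b) < 3) return(b)
    sig <- paste(b$scafA, b$endA, b$scafB, b$endB, sep = "\r")
    keyA <- paste(b$scafA, b$endA, sep = "\r")
    keyB <- paste(b$scafB, b$endB, sep = "\r")
    incid <- split(rep(seq_len(nrow(b)), 2), c(keyA, keyB))
    strong <- which(b$support >= minLinks)
    strong <- strong[order(-b$support[strong], abs(b$gap[strong]),
                           sig[strong])]
    changed <- FALSE; drop <- logical(nrow(b))
    for (i in strong) {
      if (drop[i]) next
      slack <- slackFrac * b$insert[i]
      if (b$gap[i] <= slack) next             # gap too small to hide anything
      found <- NULL
      for (side in 1:2) {
        ka <- if (side == 1) keyA[i] else keyB[i]
        kb <- if (side == 1) keyB[i] else keyA[i]
        for (j in setdiff(incid[[ka]], i)) {
          if (drop[j]) next
          # partner P entered through end e1 in bundle j
          if (paste(b$scafA[j], b$endA[j], sep = "\r") == ka) {
            P <- b$scafB[j]; e1 <- b$endB[j]
          } else { P <- b$scafA[j]; e1 <- b$endA[j] }
          kp <- paste(P, opp[[e1]], sep = "\r")
          for (k in setdiff(incid[[kp]], c(i, j))) {
            if (drop[k]) next
            other <- if (paste(b$scafA[k], b$endA[k], sep = "\r") == kp)
              paste(b$scafB[k], b$endB[k], sep = "\r") else
              paste(b$scafA[k], b$endA[k], sep = "\r")
            if (other != kb) next
            if (abs(b$gap[j] + scafLen[[P]] + b$gap[k] - b$gap[i]) > slack)
              next
            cand <- list(j = j, k = k, sup = b$support[j] + b$support[k])
            if (is.null(found) || cand$sup > found$sup ||
                (cand$sup == found$sup && sig[cand$j] < sig[found$j]))
              found <- cand
          }
        }
      }
      if (!is.null(found)) {
        b$support[found$j] <- b$support[found$j] + b$support[i]
        b$support[found$k] <- b$support[found$k] + b$support[i]
        drop[i] <- TRUE; changed <- TRUE
      }
    }
    b <- b[!drop, , drop = FALSE]
    if (!changed) break
  }
  b
}

#' Greedily join scaffolds along link bundles
#'
#' Bundles are considered in order of descending support (ties broken by
#' smaller absolute gap, then lexicographic signature). When several
#' bundles compete for one scaffold end, their gap estimates are examined
#' first: if the candidate partners can be ordered along the implied gap
#' axis so that each fits before the next (within a `slackFrac * insert`
#' tolerance), the candidates are positionally compatible — a long insert
#' seeing past a short intervening scaffold — and only the nearest-gap
#' bundle competes for the end, the farther ones being satisfied
#' transitively. Otherwise the candidates genuinely conflict and the
#' ambiguity rule applies: the end is only joinable through its
#' top-supported bundle, and only if the second-best support is at most
#' `ratio` times the best. A join is made when the bundle is the
#' effective candidate at both of its ends, neither end is already
#' occupied, and the join does not close a cycle; paths are simple
#' chains.
#'
#' Before any of this, skip evidence is reallocated: a strong bundle
#' whose gap exactly accommodates a scaffold that weaker bundles place
#' inside it donates its support to those nested bundles and is dropped
#' (see the package vignette). Passing bundles built with `minLinks = 1`
#' therefore lets short scaffolds be rescued by the long-range pairs that
#' see past them; the `minLinks` threshold is applied here afterwards. Joined members are reverse-complemented
#' as their orientation requires and separated by `max(gap, gapFloor)` Ns.
#' Unjoined scaffolds pass through unchanged, so the non-N base multiset
#' is conserved. Output scaffolds are sorted by id, making the result
#' independent of input scaffold order.
#'
#' @param assembly the [Assembly-class] being scaffolded.
#' @param bundles data.frame from [bundleLinks()].
#' @param minLinks minimum support (re-applied; default 5).
#' @param ratio ambiguity ratio threshold (default 0.7).
#' @param gapFloor minimum emitted gap in Ns (default 10).
#' @param slackFrac positional-compatibility tolerance as a fraction of
#'   the library insert (default 0.25).
#' @return a list with elements `assembly` (the super-scaffolded
#'   [Assembly-class]) and `paths` (data.frame `path`, `member`,
#'   `orientation`, `gapAfter` describing every multi-member output
#'   scaffold).
#' @export
buildScaffolds <- function(assembly, bundles, minLinks = 5, ratio = 0.7,
                           gapFloor = 10, slackFrac = 0.25) {
  stopifnot(is(assembly, "Assembly"))
  seqs <- scaffolds(assembly)
  ids <- names(seqs)
  scafLen <- stats::setNames(as.numeric(width(seqs)), ids)
  b <- bundles
  if (nrow(b)) {
    bad <- setdiff(c(b$scafA, b$scafB), ids)
    if (length(bad))
      stop("bundles reference unknown scaffolds: ",
           paste(head(bad, 5), collapse = ", "))
    b <- b[b$scafA != b$scafB, , drop = FALSE]  # self-links are unusable
    b <- .reallocateNested(b, scafLen, minLinks, slackFrac)
    b <- b[b$support >= minLinks, , drop = FALSE]
  }

  joins <- NULL
  if (nrow(b)) {
    sig <- paste(b$scafA, b$endA, b$scafB, b$endB, sep = "\r")
    ord <- order(-b$support, abs(b$gap), sig)
    b <- b[ord, , drop = FALSE]
    keyA <- paste(b$scafA, b$endA, sep = "\r")
    keyB <- paste(b$scafB, b$endB, sep = "\r")
    # static effective candidate per end (row index in sorted b), or NA
    # when the end's candidates conflict beyond the ambiguity ratio
    endTab <- data.frame(key = c(keyA, keyB),
                         row = rep(seq_len(nrow(b)), 2),
                         partner = c(b$scafB, b$scafA))
    byEnd <- split(endTab[c("row", "partner")], endTab$key)
    effective <- vapply(byEnd, function(e) {
      r <- e$row
      if (length(r) == 1) return(r)
      g <- b$gap[r]; plen <- scafLen[e$partner]
      slack <- slackFrac * b$insert[r[1]]
      o <- order(g, r)
      compatible <- all(g[o][-1] - (g[o] + plen[o])[-length(r)] >= -slack)
      if (compatible) return(r[o][1])      # chain nearest-first
      r <- sort(r)                         # b is sorted by support already
      if (b$support[r[2]] / b$support[r[1]] > ratio) return(NA_real_)
      r[1]
    }, 1)
    usedEnd <- character()
    parent <- stats::setNames(ids, ids)
    ufFind <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
    acc <- logical(nrow(b))
    for (i in seq_len(nrow(b))) {
      ka <- keyA[i]; kb <- keyB[i]
      if (is.na(effective[[ka]]) || effective[[ka]] != i) next
      if (is.na(effective[[kb]]) || effective[[kb]] != i) next
      if (ka %in% usedEnd || kb %in% usedEnd) next
      ra <- ufFind(b$scafA[i]); rb <- ufFind(b$scafB[i])
      if (ra == rb) next  # would close a cycle
      parent[[ra]] <- rb
      usedEnd <- c(usedEnd, ka, kb)
      acc[i] <- TRUE
    }
    joins <- b[acc, , drop = FALSE]
  }

  chr <- as.character(seqs)
  comp <- composition(assembly)
  outSeq <- character(); outComp <- list(); paths <- list()
  if (!is.null(joins) && nrow(joins)) {
    # adjacency lookup: end key -> join row
    jkeyA <- paste(joins$scafA, joins$endA, sep = "\r")
    jkeyB <- paste(joins$scafB, joins$endB, sep = "\r")
    lookup <- c(stats::setNames(seq_len(nrow(joins)), jkeyA),
                stats::setNames(seq_len(nrow(joins)), jkeyB))
    joined <- unique(c(joins$scafA, joins$scafB))
    degree <- table(c(joins$scafA, joins$scafB))
    terminals <- sort(names(degree)[degree == 1])
    visited <- character()
    for (t in terminals) {
      if (t %in% visited) next
      # orientation of the start scaffold: exit through its joined end
      exitEnd <- if (paste(t, "tail", sep = "\r") %in% names(lookup))
        "tail" else "head"
      o <- if (exitEnd == "tail") "F" else "R"
      members <- t; orients <- o; gaps <- numeric()
      cur <- t; curOr <- o
      repeat {
        e <- if (curOr == "F") "tail" else "head"
        jrow <- lookup[paste(cur, e, sep = "\r")]
        if (is.na(jrow)) break
        j <- joins[jrow, ]
        if (j$scafA == cur && j$endA == e) {
          nxt <- j$scafB; nend <- j$endB
        } else { nxt <- j$scafA; nend <- j$endA }
        gaps <- c(gaps, max(round(j$gap), gapFloor))
        nOr <- if (nend == "head") "F" else "R"
        members <- c(members, nxt); orients <- c(orients, nOr)
        # consume this join so the walk cannot bounce back
        lookup <- lookup[-which(lookup == jrow)]
        cur <- nxt; curOr <- nOr
      }
      visited <- c(visited, members)
      pieces <- ifelse(orients == "F", chr[members],
                       as.character(reverseComplement(
                         DNAStringSet(chr[members]))))
      glue <- c(vapply(gaps, function(g) strrep("N", g), ""), "")
      newid <- paste0(members[1], ".j", length(members))
      while (newid %in% c(ids, names(outSeq))) newid <- paste0(newid, "x")
      outSeq[newid] <- paste0(paste0(pieces, glue), collapse = "")
      cl <- lapply(seq_along(members), function(k) {
        mc <- comp[comp$scaffold == members[k], , drop = FALSE]
        mc <- mc[order(mc$ord), , drop = FALSE]
        if (orients[k] == "R") {
          mc <- mc[rev(seq_len(nrow(mc))), , drop = FALSE]
          mc$orient <- ifelse(mc$orient == "F", "R", "F")
        }
        mc
      })
      cl <- do.call(rbind, cl)
      cl$scaffold <- newid; cl$ord <- seq_len(nrow(cl))
      outComp[[newid]] <- cl
      paths[[newid]] <- data.frame(path = newid, member = members,
                                   orientation = orients,
                                   gapAfter = c(gaps, NA),
                                   stringsAsFactors = FALSE)
    }
    pass <- setdiff(ids, visited)
  } else pass <- ids

  outSeq <- c(outSeq, stats::setNames(chr[pass], pass))
  passComp <- comp[comp$scaffold %in% pass, , drop = FALSE]
  newComp <- rbind(do.call(rbind, outComp), passComp)
  ord <- order(names(outSeq))
  res <- DNAStringSet(outSeq[ord])
  rownames(newComp) <- NULL
  pathsDf <- if (length(paths)) do.call(rbind, c(paths, make.row.names = FALSE))
    else data.frame(path = character(), member = character(),
                    orientation = character(), gapAfter = numeric(),
                    stringsAsFactors = FALSE)
  list(assembly = Assembly(res, name = assemblyName(assembly),
                           composition = newComp),
       paths = pathsDf)
}
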