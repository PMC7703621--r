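test_that("linking pairs aggregate into bundles by join signature", {
  cc <- linkingDf("A", "tail", "B", "head", gaps = rep(10, 7))
  b <- bundleLinks(cc)
  expect_equal(nrow(b), 1)
  expect_equal(b$support, 7)

  # below the support threshold the bundle is discarded
  cc4 <- linkingDf("A", "tail", "B", "head", gaps = rep(10, 4))
  expect_equal(nrow(bundleLinks(cc4, minLinks = 5)), 0)

  # bundle gap is the median of the member estimates
  cc3 <- linkingDf("A", "tail", "B", "head", gaps = c(480, 500, 520, 510,
                                                      490))
  expect_equal(bundleLinks(cc3)$gap, 500)

  # opposite implied orientations are distinct bundles
  mix <- rbind(linkingDf("A", "tail", "B", "head", gaps = rep(0, 5)),
               linkingDf("A", "tail", "B", "tail", gaps = rep(0, 5)))
  attr(mix, "insert") <- 1000
  attr(mix, "insertSd") <- 50; attr(mix, "readLength") <- 50
  expect_equal(nrow(bundleLinks(mix)), 2)
})

test_that("coherent large negative gaps are discarded as containment", {
  cc <- linkingDf("A", "tail", "B", "head", gaps = rep(-3000, 8),
                  insert = 10000, insertSd = 500)
  expect_equal(nrow(bundleLinks(cc)), 0)
  # small negative gaps (true abutting joins) survive
  cc2 <- linkingDf("A", "tail", "B", "head", gaps = rep(-40, 8),
                   insert = 10000, insertSd = 500)
  expect_equal(nrow(bundleLinks(cc2)), 1)
})

test_that("an unambiguous chain joins with estimated gaps and floors", {
  set.seed(41)
  a <- Assembly(c(s1 = randSeq(100), s2 = randSeq(120), s3 = randSeq(90)),
                "toy")
  b <- rbind(
    data.frame(scafA = "s1", endA = "tail", scafB = "s2", endB = "head",
               support = 10, gap = 20, insert = 1000),
    data.frame(scafA = "s2", endA = "tail", scafB = "s3", endB = "head",
               support = 8, gap = -50, insert = 1000))
  res <- buildScaffolds(a, b)
  expect_equal(nScaffolds(res$assembly), 1L)
  sq <- as.character(scaffolds(res$assembly)[[1]])
  s <- as.character(scaffolds(a))
  # negative gap floored at 10 Ns
  expect_equal(sq, paste0(s["s1"], strrep("N", 20), s["s2"],
                          strrep("N", 10), s["s3"]))
  expect_equal(res$paths$member, c("s1", "s2", "s3"))
  expect_equal(res$paths$orientation, c("F", "F", "F"))
  expect_true(all(res$paths$gapAfter[1:2] >= 10))
})

test_that("tail-tail joins reverse-complement the partner", {
  set.seed(42)
  a <- Assembly(c(s1 = randSeq(100), s2 = randSeq(100)), "toy")
  b <- data.frame(scafA = "s1", endA = "tail", scafB = "s2", endB = "tail",
                  support = 10, gap = 15, insert = 1000)
  res <- buildScaffolds(a, b)
  sq <- as.character(scaffolds(res$assembly)[[1]])
  s <- as.character(scaffolds(a))
  expect_equal(sq, paste0(s["s1"], strrep("N", 15), revcomp(s["s2"])))
  comp <- composition(res$assembly)
  expect_equal(comp$orient[comp$member == "s2"], "R")
})

test_that("conflicting evidence within the ambiguity ratio blocks a join", {
  set.seed(43)
  a <- Assembly(c(s1 = randSeq(1000), s2 = randSeq(1000),
                  s3 = randSeq(1000)), "toy")
  # both partners claim the same position at tail(s1): 18/20 > 0.7
  b <- rbind(
    data.frame(scafA = "s1", endA = "tail", scafB = "s2", endB = "head",
               support = 20, gap = 0, insert = 1000),
    data.frame(scafA = "s1", endA = "tail", scafB = "s3", endB = "head",
               support = 18, gap = 0, insert = 1000))
  res <- buildScaffolds(a, b)
  expect_equal(nScaffolds(res$assembly), 3L)
  expect_equal(nrow(res$paths), 0)
})

test_that("positionally compatible candidates chain nearest-first", {
  set.seed(44)
  # s2 is short; a long-insert bundle sees past it to s3
  a <- Assembly(c(s1 = randSeq(2000), s2 = randSeq(300),
                  s3 = randSeq(2000)), "toy")
  b <- rbind(
    data.frame(scafA = "s1", endA = "tail", scafB = "s3", endB = "head",
               support = 20, gap = 320, insert = 5000),
    data.frame(scafA = "s1", endA = "tail", scafB = "s2", endB = "head",
               support = 8, gap = 5, insert = 5000),
    data.frame(scafA = "s2", endA = "tail", scafB = "s3", endB = "head",
               support = 8, gap = 10, insert = 5000))
  res <- buildScaffolds(a, b)
  expect_equal(nScaffolds(res$assembly), 1L)
  expect_equal(res$paths$member, c("s1", "s2", "s3"))
})

test_that("skip support is reallocated to nested sub-threshold bundles", {
  set.seed(45)
  a <- Assembly(c(s1 = randSeq(2000), s2 = randSeq(300),
                  s3 = randSeq(2000)), "toy")
  # direct evidence for tiny s2 is below minLinks on both sides, but the
  # skip bundle's gap exactly fits s2 between them
  b <- rbind(
    data.frame(scafA = "s1", endA = "tail", scafB = "s3", endB = "head",
               support = 9, gap = 315, insert = 1000),
    data.frame(scafA = "s1", endA = "tail", scafB = "s2", endB = "head",
               support = 3, gap = 5, insert = 1000),
    data.frame(scafA = "s2", endA = "tail", scafB = "s3", endB = "head",
               support = 4, gap = 10, insert = 1000))
  res <- buildScaffolds(a, b, minLinks = 5)
  expect_equal(nScaffolds(res$assembly), 1L)
  expect_equal(res$paths$member, c("s1", "s2", "s3"))
})

test_that("greedy joining matches a naive re-derivation on a 5-contig case", {
  set.seed(46)
  ids <- paste0("c", 1:5)
  a <- Assembly(stats::setNames(
    Biostrings::DNAStringSet(vapply(1:5, function(i) randSeq(2000), "")),
    ids), "toy")
  b <- rbind(
    data.frame(scafA = "c1", endA = "tail", scafB = "c2", endB = "head",
               support = 20, gap = 10, insert = 1000),
    data.frame(scafA = "c2", endA = "tail", scafB = "c3", endB = "head",
               support = 15, gap = 5, insert = 1000),
    data.frame(scafA = "c3", endA = "tail", scafB = "c4", endB = "head",
               support = 12, gap = 0, insert = 1000),
    data.frame(scafA = "c4", endA = "tail", scafB = "c5", endB = "head",
               support = 11, gap = 8, insert = 1000),
    data.frame(scafA = "c1", endA = "tail", scafB = "c3", endB = "head",
               support = 6, gap = 12, insert = 1000),
    data.frame(scafA = "c2", endA = "tail", scafB = "c5", endB = "tail",
               support = 4, gap = 0, insert = 1000),
    data.frame(scafA = "c1", endA = "head", scafB = "c5", endB = "head",
               support = 11, gap = 0, insert = 1000),
    data.frame(scafA = "c1", endA = "head", scafB = "c4", endB = "tail",
               support = 9, gap = 0, insert = 1000))

  # naive oracle: plain loops re-deriving the decision rules (no nesting
  # or compatibility applies here: all partners are 2000 bp, gaps ~0)
  naive <- function(b, ratio = 0.7, minLinks = 5) {
    b <- b[b$support >= minLinks, ]
    b <- b[order(-b$support, abs(b$gap),
                 paste(b$scafA, b$endA, b$scafB, b$endB)), ]
    ends <- unique(c(paste(b$scafA, b$endA), paste(b$scafB, b$endB)))
    eff <- list()
    for (e in ends) {
      rows <- which(paste(b$scafA, b$endA) == e | paste(b$scafB, b$endB) == e)
      eff[[e]] <- if (length(rows) >= 2 &&
                      b$support[rows[2]] / b$support[rows[1]] > ratio)
        NA else rows[1]
    }
    used <- character(); grp <- stats::setNames(seq_len(5), paste0("c", 1:5))
    acc <- integer()
    for (i in seq_len(nrow(b))) {
      ea <- paste(b$scafA[i], b$endA[i]); eb <- paste(b$scafB[i], b$endB[i])
      if (is.na(eff[[ea]]) || eff[[ea]] != i) next
      if (is.na(eff[[eb]]) || eff[[eb]] != i) next
      if (ea %in% used || eb %in% used) next
      if (grp[b$scafA[i]] == grp[b$scafB[i]]) next
      grp[grp == grp[b$scafB[i]]] <- grp[b$scafA[i]]
      used <- c(used, ea, eb); acc <- c(acc, i)
    }
    sort(paste(b$scafA[acc], b$endA[acc], b$scafB[acc], b$endB[acc]))
  }
  want <- naive(b)
  res <- buildScaffolds(a, b)
  got <- character()
  for (p in unique(res$paths$path)) {
    m <- res$paths[res$paths$path == p, ]
    for (i in seq_len(nrow(m) - 1)) {
      eA <- if (m$orientation[i] == "F") "tail" else "head"
      eB <- if (m$orientation[i + 1] == "F") "head" else "tail"
      pair <- sort(c(paste(m$member[i], eA), paste(m$member[i + 1], eB)))
      got <- c(got, paste(pair[1], pair[2]))
    }
  }
  expect_setequal(got, want)
})

test_that("base content is conserved and ids partition across outputs", {
  # joined members may be emitted reverse-complemented, which exchanges
  # A with T and C with G: the strand-canonical multiset is the invariant
  canonical <- function(x) {
    f <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
    c(AT = f[["A"]] + f[["T"]], CG = f[["C"]] + f[["G"]])
  }
  for (seed in c(51, 52)) {
    fx <- makeStrainPair(1e5, divergence = 0, meanContig = 1e4,
                         seed = seed, fragmentB = FALSE)
    out <- scaffoldRound(fx$A, fx$B, scaffoldConfig(), seedBase = 1)
    expect_equal(canonical(scaffolds(out)), canonical(scaffolds(fx$A)))
    # every input id appears exactly once in the composition
    expect_setequal(composition(out)$member, names(scaffolds(fx$A)))
    expect_equal(anyDuplicated(composition(out)$member), 0L)
    # joining can only improve contiguity
    expect_lte(l50(assemblyStats(out)), l50(assemblyStats(fx$A)))
  }
})

test_that("results are invariant under input scaffold order", {
  fx <- makeStrainPair(1e5, divergence = 0.01, meanContig = 1e4, seed = 53)
  cfg <- scaffoldConfig()
  out1 <- scaffoldRound(fx$A, fx$B, cfg, seedBase = 2)
  set.seed(99)
  perm <- sample(nScaffolds(fx$A))
  Ap <- Assembly(scaffolds(fx$A)[perm], name = assemblyName(fx$A))
  out2 <- scaffoldRound(Ap, fx$B, cfg, seedBase = 2)
  expect_identical(as.character(scaffolds(out1)),
                   as.character(scaffolds(out2)))
})

test_that("bundles naming unknown scaffolds are rejected", {
  a <- Assembly(c(s1 = "ACGTACGTAC"), "toy")
  b <- data.frame(scafA = "s1", endA = "tail", scafB = "ghost",
                  endB = "head", support = 9, gap = 0, insert = 1000)
  expect_error(buildScaffolds(a, b), "unknown")
})
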