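test_that("marker FASTA round trip preserves the structured headers", {
  mk <- data.frame(id = c("m1", "m2"), arm = c("2R", "2L"), rank = c(1, 1),
                   sequence = c(randSeq(120, 71), randSeq(120)),
                   stringsAsFactors = FALSE)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeMarkers(mk, fa)
  expect_equal(readMarkers(fa), mk)
  writeLines(c(">broken_header", "ACGT"), fa)
  expect_error(readMarkers(fa), "id\\|arm\\|rank")
})

test_that("verbatim markers map at full identity to their true location", {
  anc <- randSeq(30000, seed = 72)
  a <- Assembly(c(s1 = substr(anc, 1, 15000), s2 = substr(anc, 15001, 30000)),
                "asm")
  mk <- data.frame(id = c("hit1", "hit2", "absent"),
                   arm = "2R", rank = 1:3,
                   sequence = c(substr(anc, 2001, 2500),
                                substr(anc, 21001, 21500),
                                randSeq(500)),
                   stringsAsFactors = FALSE)
  mm <- mapMarkers(mk, a)
  expect_equal(mm$unmapped, "absent")
  h1 <- mm$hits[mm$hits$marker == "hit1", ]
  expect_equal(h1$scaffold, "s1")
  expect_equal(h1$start, 2001)
  expect_equal(h1$end, 2500)
  expect_equal(h1$identity, 100)
  expect_equal(h1$strand, "+")
  expect_lt(h1$evalue, 1e-25)
  h2 <- mm$hits[mm$hits$marker == "hit2", ]
  expect_equal(h2$scaffold, "s2")
  expect_equal(h2$start, 6001)
  expect_error(mapMarkers(mk[0, ], a), "empty")
})

test_that("markers on a reversed scaffold map to the minus strand", {
  anc <- randSeq(8000, seed = 73)
  a <- Assembly(c(rc = revcomp(anc)), "asm")
  mk <- data.frame(id = "m", arm = "2R", rank = 1,
                   sequence = substr(anc, 3001, 3500),
                   stringsAsFactors = FALSE)
  h <- mapMarkers(mk, a)$hits
  expect_equal(h$strand, "-")
  expect_equal(h$start, 8000 - 3500 + 1)
  expect_equal(h$identity, 100)
})

test_that("only the best-scoring of two candidate loci is retained", {
  anc <- randSeq(6000, seed = 74)
  marker <- substr(anc, 1001, 1500)
  copy <- marker
  substr(copy, 100, 100) <- chartr("ACGT", "CAGT", substr(copy, 100, 100))
  a <- Assembly(c(exact = paste0(substr(anc, 1, 3000), randSeq(50)),
                  nearby = paste0(randSeq(1000), copy, randSeq(1000))),
                "asm")
  h <- mapMarkers(data.frame(id = "m", arm = "2R", rank = 1,
                             sequence = marker, stringsAsFactors = FALSE),
                  a)$hits
  expect_equal(nrow(h), 1)
  expect_equal(h$scaffold, "exact")
  expect_equal(h$identity, 100)
})

test_that("arm assignment follows majority, weight tie-break and", {
  hit <- function(marker, scaffold, start, identity = 100, alen = 500)
    data.frame(marker = marker, scaffold = scaffold, start = start,
               end = start + alen - 1, strand = "+", identity = identity,
               evalue = 1e-60, alen = alen, bits = 900,
               stringsAsFactors = FALSE)
  mk <- data.frame(id = sprintf("m%02d", 1:12),
                   arm = c(rep("2R", 5), rep("3R", 4), rep("3L", 2), "2L"),
                   rank = c(1:5, 1:4, 1:2, 1),
                   sequence = "x", stringsAsFactors = FALSE)

  # all markers from one arm
  hits <- do.call(rbind, lapply(1:5, function(i)
    hit(sprintf("m%02d", i), "scafU", i * 1000)))
  asg <- assignArms(hits, mk)
  expect_equal(asg$assignment$arm, "2R")
  expect_equal(asg$assignment$status, "assigned")

  # 4 consecutive 3R ranks then 2 consecutive 3L ranks: centromere span
  hits2 <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      hit(sprintf("m%02d", 5 + i), "scafC", i * 1000))),
    hit("m10", "scafC", 5000), hit("m11", "scafC", 6000))
  asg2 <- assignArms(hits2, mk)
  expect_equal(asg2$assignment$arm, "3R")
  expect_equal(asg2$assignment$status, "centromere")
  expect_equal(asg2$conflicts$arm, "3L")

  # 2 vs 2 tie: larger sum(identity * alen) wins
  hits3 <- rbind(hit("m01", "scafT", 1000, identity = 99, alen = 400),
                 hit("m02", "scafT", 2000, identity = 99, alen = 400),
                 hit("m10", "scafT", 3000, identity = 100, alen = 500),
                 hit("m11", "scafT", 4000, identity = 100, alen = 500))
  asg3 <- assignArms(hits3, mk)
  expect_equal(asg3$assignment$arm, "3L")

  # interleaved arms on different chromosomes: flagged conflict
  hits4 <- rbind(hit("m01", "scafX", 1000), hit("m06", "scafX", 2000),
                 hit("m02", "scafX", 3000), hit("m07", "scafX", 4000),
                 hit("m03", "scafX", 5000))
  asg4 <- assignArms(hits4, mk)
  expect_equal(asg4$assignment$status, "conflict")
  expect_equal(asg4$assignment$arm, "2R")
})

test_that("orientation is the sign of rank-coordinate concordance", {
  mk <- data.frame(id = c("a", "b", "c", "solo"), arm = "2R",
                   rank = c(5, 6, 7, 9), sequence = "x",
                   stringsAsFactors = FALSE)
  hit <- function(marker, scaffold, start)
    data.frame(marker = marker, scaffold = scaffold, start = start,
               end = start + 499, strand = "+", identity = 100,
               evalue = 1e-60, alen = 500, bits = 900,
               stringsAsFactors = FALSE)
  hits <- rbind(hit("a", "fwd", 1000), hit("b", "fwd", 2000),
                hit("c", "fwd", 3000),
                hit("a", "rev", 3000), hit("b", "rev", 2000),
                hit("c", "rev", 1000),
                hit("solo", "single", 500))
  asg <- data.frame(scaffold = c("fwd", "rev", "single"), arm = "2R",
                    stringsAsFactors = FALSE)
  ort <- orientAndRank(hits, mk, asg)
  expect_equal(ort$orientation[ort$scaffold == "fwd"], "F")
  expect_equal(ort$orientation[ort$scaffold == "rev"], "R")
  expect_equal(ort$orientation[ort$scaffold == "single"], "unknown")
  expect_equal(ort$meanRank[ort$scaffold == "fwd"], 6)
})

test_that("stitching concatenates ordered scaffolds with 1000-N spacers", {
  set.seed(75)
  a <- Assembly(c(x = randSeq(100), y = randSeq(200), z = randSeq(300)),
                "asm")
  ort <- data.frame(scaffold = c("x", "y", "z"), arm = "2R",
                    orientation = c("F", "R", "F"), meanRank = 1:3,
                    stringsAsFactors = FALSE)
  st <- stitchArms(ort, a)
  b <- st$builds[["2R"]]
  expect_equal(length(armSequence(b)), 100 + 200 + 300 + 2 * 1000)
  sq <- as.character(armSequence(b))
  s <- as.character(scaffolds(a))
  expect_equal(substr(sq, 1, 100), s[["x"]])
  # R members are reverse-complemented in the stitched sequence
  expect_equal(substr(sq, 1101, 1300), revcomp(s[["y"]]))
  expect_null(st$unplaced)

  # unplaced scaffolds pass through untouched
  st2 <- stitchArms(ort[1:2, ], a)
  expect_equal(names(scaffolds(st2$unplaced)), "z")

  expect_error(stitchArms(rbind(ort, ort[1, ]), a), "more than one arm")
  expect_warning(stitchArms(ort, a, arms = c("2R", "2L")), "2L")
})

test_that("linearity tau matches a brute-force pair-count oracle", {
  set.seed(76)
  n <- 10
  a <- Assembly(stats::setNames(
    Biostrings::DNAStringSet(vapply(1:n, function(i) randSeq(2000), "")),
    paste0("s", 1:n)), "asm")
  ort <- data.frame(scaffold = paste0("s", 1:n), arm = "2R",
                    orientation = "F", meanRank = 1:n,
                    stringsAsFactors = FALSE)
  st <- stitchArms(ort, a)
  mk <- data.frame(id = paste0("m", 1:n), arm = "2R", rank = 1:n,
                   sequence = "x", stringsAsFactors = FALSE)
  hit <- function(marker, scaffold, start)
    data.frame(marker = marker, scaffold = scaffold, start = start,
               end = start + 499, strand = "+", identity = 100,
               evalue = 1e-60, alen = 500, bits = 900,
               stringsAsFactors = FALSE)
  # perfect order
  hits <- do.call(rbind, lapply(1:n, function(i)
    hit(paste0("m", i), paste0("s", i), 500)))
  ls <- linearityScore(st$builds[["2R"]], hits, mk)
  expect_equal(ls$tau, 1)
  expect_equal(ls$adjacentFrac, 1)

  # fully reversed order
  hitsR <- do.call(rbind, lapply(1:n, function(i)
    hit(paste0("m", i), paste0("s", n + 1 - i), 500)))
  expect_equal(linearityScore(st$builds[["2R"]], hitsR, mk)$tau, -1)

  # one swapped adjacent pair among 10: tau equals the pair-count oracle
  mk2 <- mk
  mk2$rank <- c(1, 2, 3, 5, 4, 6, 7, 8, 9, 10)
  ls2 <- linearityScore(st$builds[["2R"]], hits, mk2)
  pos <- vapply(1:n, function(i)
    armMembers(st$builds[["2R"]])$offset[i] + 500, 0)
  expect_equal(ls2$tau, bruteKendall(mk2$rank, pos))
  expect_equal(ls2$adjacentFrac, 8 / 9)

  # fewer than two placed markers: undefined, reported absent
  expect_true(is.na(linearityScore(st$builds[["2R"]], hits[1, ], mk)$tau))
})
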