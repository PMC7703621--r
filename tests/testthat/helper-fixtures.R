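# shared helpers: tiny sequence fixtures and independent oracles

randSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# substitute bases at `rate`, never to the same base
mutateSeq <- function(x, rate) {
  v <- strsplit(x, "")[[1]]
  idx <- which(runif(length(v)) < rate)
  bases <- c("A", "C", "G", "T")
  if (length(idx)) {
    bi <- match(v[idx], bases)
    v[idx] <- bases[((bi - 1 + sample.int(3, length(idx), TRUE)) %% 4) + 1]
  }
  paste(v, collapse = "")
}

# brute-force N50/L50 oracle: sort descending, scan until half the total
bruteStats <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  tot <- sum(lens)
  run <- 0
  for (i in seq_along(lens)) {
    run <- run + lens[i]
    if (run >= tot / 2) return(list(n50 = lens[i], l50 = i))
  }
}

# brute-force Kendall tau oracle: signed concordant/discordant pair count
bruteKendall <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  s / choose(n, 2)
}

# a concordant-pairs data.frame suitable for bundleLinks, with the
# library attributes filterPairs would attach
linkingDf <- function(scafA, endA, scafB, endB, gaps, insert = 1000,
                      insertSd = 0.05 * insert, readLength = 50) {
  df <- data.frame(id = sprintf("p%03d", seq_along(gaps)),
                   class = "linking", scafA = scafA, endA = endA,
                   scafB = scafB, endB = endB, gap = gaps, span = NA_real_,
                   insert = insert, stringsAsFactors = FALSE)
  attr(df, "insert") <- insert
  attr(df, "insertSd") <- insertSd
  attr(df, "readLength") <- readLength
  df
}
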