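# FASTA input/output, contiguity statistics and AGP emission.
# Internal coordinates are 0-based half-open; AGP output is 1-based inclusive.

.normalizeSeq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' Read an assembly from FASTA
#'
#' Reads a (multi-)FASTA file into an [Assembly-class]. Sequences are
#' uppercased and every IUPAC ambiguity code other than `N` is mapped to
#' `N`, so downstream code only ever sees the five-letter alphabet.
#' Headers are truncated at the first whitespace.
#'
#' @param path path to a FASTA file.
#' @param name assembly label; defaults to the file name without extension.
#' @return an [Assembly-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtn"), fa)
#' readAssembly(fa)
#' @export
readAssembly <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate scaffold ids in ", path)
  out <- DNAStringSet(.normalizeSeq(as.character(seqs)))
  names(out) <- ids
  Assembly(out, name = name)
}

#' Write an assembly to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param assembly an [Assembly-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAssembly <- function(assembly, path) {
  stopifnot(is(assembly, "Assembly"))
  writeXStringSet(scaffolds(assembly), path, width = 60L)
  invisible(path)
}

#' Compute assembly contiguity statistics
#'
#' N50 is the length of the scaffold at which the cumulative length of
#' scaffolds sorted in descending order first reaches half of the total
#' assembly length; L50 is the number of scaffolds contributing to that
#' cumulative sum. N bases are counted in all lengths.
#'
#' @param assembly an [Assembly-class], or a numeric vector of scaffold
#'   lengths (then `pctN` is reported as 0).
#' @return an [AssemblyStats-class].
#' @examples
#' assemblyStats(c(40, 30, 20, 10))  # N50 30, L50 2
#' @export
assemblyStats <- function(assembly) {
  if (is(assembly, "Assembly")) {
    if (nScaffolds(assembly) == 0) stop("empty assembly")
    lens <- as.numeric(width(scaffolds(assembly)))
    nN <- sum(as.numeric(Biostrings::letterFrequency(scaffolds(assembly),
                                                     letters = "N")))
  } else {
    lens <- as.numeric(assembly)
    if (length(lens) == 0) stop("empty assembly")
    nN <- 0
  }
  total <- sum(lens)
  s <- sort(lens, decreasing = TRUE)
  cs <- cumsum(s)
  i <- which(cs >= total / 2)[1]
  new("AssemblyStats", totalLength = total, nScaffolds = length(lens),
      longest = s[1], n50 = s[i], l50 = i, pctN = 100 * nN / total)
}

# AGP 2.0 spacer between scaffolds within an arm
.AGP_GAP <- 1000

#' Write an AGP 2.0 file describing pseudomolecule composition
#'
#' Arms are grouped into whole chromosomes in the AGP object naming only
#' (`2R` + `2L` become object `2`, R arm first); the arm boundary is
#' recorded as a `centromere` gap row. Scaffold components are `W` rows
#' with 1-based inclusive coordinates; spacers between scaffolds are 1000
#' base `N` rows with gap type `scaffold` and linkage `yes`. Scaffolds with
#' unknown orientation are emitted with orientation `na`.
#'
#' @param builds a list of [ArmBuild-class] objects.
#' @param path output path.
#' @return invisibly, a `data.frame` of the emitted rows.
#' @export
writeAgp <- function(builds, path) {
  stopifnot(all(vapply(builds, is, TRUE, "ArmBuild")))
  arms <- vapply(builds, armName, "")
  if (anyDuplicated(arms)) stop("duplicate arm builds")
  chrom <- sub("[RL]$", "", arms)
  rows <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    # R arm before L arm within a chromosome
    ord <- order(match(sub("^.*?([RL])$", "\\1", arms[idx]), c("R", "L")))
    idx <- idx[ord]
    pos <- 0; part <- 0
    for (j in seq_along(idx)) {
      b <- builds[[idx[j]]]
      m <- armMembers(b)
      if (j > 1) {  # arm boundary: centromere gap
        part <- part + 1
        rows[[length(rows) + 1]] <- data.frame(
          object = ch, object_beg = pos + 1, object_end = pos + .AGP_GAP,
          part_number = part, component_type = "N", col6 = .AGP_GAP,
          col7 = "centromere", col8 = "no", col9 = "na",
          stringsAsFactors = FALSE)
        pos <- pos + .AGP_GAP
      }
      for (k in seq_len(nrow(m))) {
        if (k > 1) {
          part <- part + 1
          rows[[length(rows) + 1]] <- data.frame(
            object = ch, object_beg = pos + 1, object_end = pos + .AGP_GAP,
            part_number = part, component_type = "N", col6 = .AGP_GAP,
            col7 = "scaffold", col8 = "yes", col9 = "map",
            stringsAsFactors = FALSE)
          pos <- pos + .AGP_GAP
        }
        part <- part + 1
        ornt <- switch(m$orientation[k], F = "+", R = "-", unknown = "na")
        rows[[length(rows) + 1]] <- data.frame(
          object = ch, object_beg = pos + 1, object_end = pos + m$length[k],
          part_number = part, component_type = "W", col6 = m$scaffold[k],
          col7 = 1, col8 = m$length[k], col9 = ornt,
          stringsAsFactors = FALSE)
        pos <- pos + m$length[k]
      }
    }
  }
  agp <- do.call(rbind, rows)
  # internal consistency: object coordinates must tile without overlap
  for (ch in unique(agp$object)) {
    a <- agp[agp$object == ch, ]
    if (any(a$object_beg[-1] != a$object_end[-nrow(a)] + 1))
      stop("internal error: overlapping object coordinates in AGP")
  }
  con <- file(path, "w")
  writeLines("##agp-version\t2.0", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(agp)
}
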