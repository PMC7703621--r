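# The alternating improvement loop: simulate mate pairs from one draft,
# scaffold the other, swap roles, repeat until contiguity stops improving.

#' Default configuration for the co-iteration pipeline
#'
#' Every threshold of the pipeline in one list. The insert ladder spans
#' 1 kb to 5 Mb; libraries are applied hierarchically in ascending insert
#' size, each updating the assembly before the next is placed. Inserts
#' larger than the longest scaffold simply yield empty libraries and are
#' skipped.
#'
#' @param inserts insert-size ladder in bases.
#' @param readLength simulated read length (bases).
#' @param insertSdFrac fragment-length sd as a fraction of the insert.
#' @param pairsPerLibrary pairs per library; `NA` means 1x read coverage
#'   of the source.
#' @param tau insert-size tolerance fraction for concordance.
#' @param k seed length for placement.
#' @param maxMismatch maximum mismatches per placed read.
#' @param minLinks minimum supporting pairs per link bundle.
#' @param ratio ambiguity ratio for greedy joining.
#' @param gapFloor minimum emitted gap (Ns).
#' @param epsilon relative L50/N50 improvement below which an assembly is
#'   considered converged.
#' @param maxRounds maximum alternating rounds.
#' @param seed master RNG seed; per-library seeds are derived from it.
#' @return a named list.
#' @export
scaffoldConfig <- function(inserts = c(1e3, 5e3, 1e4, 5e4, 1e5, 5e5, 1e6,
                                       2e6, 5e6),
                           readLength = 50, insertSdFrac = 0.05,
                           pairsPerLibrary = NA, tau = 0.25, k = 21,
                           maxMismatch = 2, minLinks = 5, ratio = 0.7,
                           gapFloor = 10, epsilon = 0.05, maxRounds = 6,
                           seed = 1) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (maxRounds < 1) stop("maxRounds must be >= 1")
  list(inserts = sort(inserts), readLength = readLength,
       insertSdFrac = insertSdFrac, pairsPerLibrary = pairsPerLibrary,
       tau = tau, k = k, maxMismatch = maxMismatch, minLinks = minLinks,
       ratio = ratio, gapFloor = gapFloor, epsilon = epsilon,
       maxRounds = maxRounds, seed = seed)
}

#' One directional scaffolding round
#'
#' Simulates the configured library ladder from `source` and uses it to
#' super-scaffold `target`, smallest insert first, the target updating
#' between libraries.
#'
#' @param target the [Assembly-class] being improved.
#' @param source the partner [Assembly-class] the libraries are simulated
#'   from.
#' @param config list from [scaffoldConfig()].
#' @param seedBase integer offset mixed into per-library seeds (the driver
#'   passes a per-round value).
#' @return the updated target [Assembly-class].
#' @export
scaffoldRound <- function(target, source, config = scaffoldConfig(),
                          seedBase = 0) {
  longestSrc <- max(width(scaffolds(source)))
  for (li in seq_along(config$inserts)) {
    ins <- config$inserts[li]
    # gap arithmetic assumes fragment length ~ insert; skip libraries
    # whose insert distribution cannot fit unclamped in the source
    if (ins * (1 + 3 * config$insertSdFrac) > longestSrc) next
    spec <- librarySpec(ins, insertSd = config$insertSdFrac * ins,
                        readLength = config$readLength,
                        nPairs = if (is.na(config$pairsPerLibrary))
                          NA_real_ else config$pairsPerLibrary,
                        seed = config$seed * 1000 + seedBase * 100 + li)
    lib <- withCallingHandlers(simulateLibrary(source, spec),
                               warning = function(w)
                                 invokeRestart("muffleWarning"))
    if (nrow(lib) == 0) next
    index <- buildTargetIndex(target)
    placed <- placePairs(lib, index, k = config$k,
                         maxMismatch = config$maxMismatch)
    conc <- filterPairs(placed, index, tau = config$tau)
    # keep weak bundles: buildScaffolds uses them for nested-skip
    # reallocation and applies the support threshold itself
    bundles <- bundleLinks(conc, minLinks = 1)
    if (nrow(bundles) == 0) next
    target <- buildScaffolds(target, bundles, minLinks = config$minLinks,
                             ratio = config$ratio,
                             gapFloor = config$gapFloor)$assembly
  }
  target
}

#' Run the alternating improvement loop to convergence
#'
#' Round 1 simulates from `B` and scaffolds `A`; round 2 simulates from
#' the updated `A` and scaffolds `B`; and so on, alternating. An assembly
#' is converged once an update round improves both its L50 and its N50 by
#' less than `epsilon` (relative); the loop stops when both assemblies
#' have converged or after `maxRounds` rounds.
#'
#' @param A,B the two draft [Assembly-class] objects.
#' @param config list from [scaffoldConfig()].
#' @param outdir optional directory; when given, every intermediate
#'   assembly is archived as `<name>_round<r>.fa`.
#' @return a list with elements `A`, `B` (final assemblies) and `history`,
#'   a data.frame with one row per round: `round`, `direction`, `updated`,
#'   and the updated assembly's `l50Before`, `l50After`, `n50Before`,
#'   `n50After`, `nScaffoldsAfter`, `longestAfter`.
#' @export
runUntilConverged <- function(A, B, config = scaffoldConfig(),
                              outdir = NULL) {
  stopifnot(is(A, "Assembly"), is(B, "Assembly"))
  if (nScaffolds(A) == 0 || nScaffolds(B) == 0)
    stop("both assemblies must be non-empty")
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  asm <- list(A = A, B = B)
  converged <- c(A = FALSE, B = FALSE)
  hist <- list()
  for (r in seq_len(config$maxRounds)) {
    tgt <- if (r %% 2 == 1) "A" else "B"
    src <- setdiff(c("A", "B"), tgt)
    before <- assemblyStats(asm[[tgt]])
    asm[[tgt]] <- scaffoldRound(asm[[tgt]], asm[[src]], config,
                                seedBase = r)
    after <- assemblyStats(asm[[tgt]])
    hist[[r]] <- data.frame(
      round = r, direction = paste0(src, "->", tgt), updated = tgt,
      l50Before = l50(before), l50After = l50(after),
      n50Before = n50(before), n50After = n50(after),
      nScaffoldsAfter = nScaffolds(after), longestAfter =
        longestScaffold(after), stringsAsFactors = FALSE)
    if (!is.null(outdir))
      writeAssembly(asm[[tgt]],
                    file.path(outdir, sprintf("%s_round%d.fa",
                                              assemblyName(asm[[tgt]]), r)))
    relL50 <- (l50(before) - l50(after)) / l50(before)
    relN50 <- (n50(after) - n50(before)) / n50(before)
    if (relL50 < config$epsilon && relN50 < config$epsilon)
      converged[tgt] <- TRUE
    if (all(converged)) break
  }
  list(A = asm$A, B = asm$B, history = do.call(rbind, hist))
}
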