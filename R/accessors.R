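#' @rdname Assembly-class
#' @export
setMethod("scaffolds", "Assembly", function(x) x@seqs)

#' @rdname Assembly-class
#' @export
setMethod("assemblyName", "Assembly", function(x) x@name)

#' @rdname Assembly-class
#' @export
setMethod("composition", "Assembly", function(x) x@composition)

#' @rdname Assembly-class
#' @export
setMethod("nScaffolds", "Assembly", function(x) length(x@seqs))

#' @rdname Assembly-class
#' @param object an `Assembly`.
#' @export
setMethod("show", "Assembly", function(object) {
  cat(sprintf("Assembly '%s': %d scaffold(s), %s bases\n", object@name,
              length(object@seqs),
              format(sum(as.numeric(width(object@seqs))), big.mark = ",")))
})

#' @rdname AssemblyStats-class
#' @export
setMethod("totalLength", "AssemblyStats", function(x) x@totalLength)

#' @rdname AssemblyStats-class
#' @export
setMethod("nScaffolds", "AssemblyStats", function(x) x@nScaffolds)

#' @rdname AssemblyStats-class
#' @export
setMethod("longestScaffold", "AssemblyStats", function(x) x@longest)

#' @rdname AssemblyStats-class
#' @export
setMethod("n50", "AssemblyStats", function(x) x@n50)

#' @rdname AssemblyStats-class
#' @export
setMethod("l50", "AssemblyStats", function(x) x@l50)

#' @rdname AssemblyStats-class
#' @export
setMethod("pctN", "AssemblyStats", function(x) x@pctN)

#' @rdname AssemblyStats-class
#' @param object an `AssemblyStats`.
#' @export
setMethod("show", "AssemblyStats", function(object) {
  cat(sprintf(paste0("AssemblyStats: total %s bp in %d scaffold(s); ",
                     "longest %s; N50 %s; L50 %d; %.2f%% N\n"),
              format(object@totalLength, big.mark = ","),
              as.integer(object@nScaffolds),
              format(object@longest, big.mark = ","),
              format(object@n50, big.mark = ","),
              as.integer(object@l50), object@pctN))
})

#' @rdname ArmBuild-class
#' @export
setMethod("armName", "ArmBuild", function(x) x@arm)

#' @rdname ArmBuild-class
#' @export
setMethod("armMembers", "ArmBuild", function(x) x@members)

#' @rdname ArmBuild-class
#' @export
setMethod("armSequence", "ArmBuild", function(x) x@seq)

#' @rdname ArmBuild-class
#' @param object an `ArmBuild`.
#' @export
setMethod("show", "ArmBuild", function(object) {
  cat(sprintf("ArmBuild %s: %d scaffold(s), %s bases\n", object@arm,
              nrow(object@members),
              format(length(object@seq), big.mark = ",")))
})

#' @rdname LibrarySpec-class
#' @param object a `LibrarySpec`.
#' @export
setMethod("show", "LibrarySpec", function(object) {
  np <- if (is.na(object@nPairs)) "1x coverage" else
    format(object@nPairs, big.mark = ",")
  cat(sprintf("LibrarySpec: insert %s +/- %s, reads %d bp, pairs %s, seed %d\n",
              format(object@insertSize, big.mark = ","),
              format(object@insertSd, big.mark = ","),
              as.integer(object@readLength), np, as.integer(object@seed)))
})
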