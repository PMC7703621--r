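#' @rdname Assembly-class
#' @param x an object.
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))

#' @rdname Assembly-class
#' @export
setGeneric("assemblyName", function(x) standardGeneric("assemblyName"))

#' @rdname Assembly-class
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))

#' @rdname Assembly-class
#' @export
setGeneric("nScaffolds", function(x) standardGeneric("nScaffolds"))

#' @rdname AssemblyStats-class
#' @param x an object.
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname AssemblyStats-class
#' @export
setGeneric("longestScaffold", function(x) standardGeneric("longestScaffold"))

#' @rdname AssemblyStats-class
#' @export
setGeneric("n50", function(x) standardGeneric("n50"))

#' @rdname AssemblyStats-class
#' @export
setGeneric("l50", function(x) standardGeneric("l50"))

#' @rdname AssemblyStats-class
#' @export
setGeneric("pctN", function(x) standardGeneric("pctN"))

#' @rdname ArmBuild-class
#' @param x an object.
#' @export
setGeneric("armName", function(x) standardGeneric("armName"))

#' @rdname ArmBuild-class
#' @export
setGeneric("armMembers", function(x) standardGeneric("armMembers"))

#' @rdname ArmBuild-class
#' @export
setGeneric("armSequence", function(x) standardGeneric("armSequence"))
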