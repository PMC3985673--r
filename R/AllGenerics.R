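#' @rdname Network-class
#' @param x a `Network` or `ModuleMap` object.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname Network-class
#' @export
setGeneric("networkMode", function(x) standardGeneric("networkMode"))

#' @rdname Network-class
#' @export
setGeneric("isWeighted", function(x) standardGeneric("isWeighted"))

#' @rdname ModuleMap-class
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @rdname ModuleMap-class
#' @export
setGeneric("mapLinks", function(x) standardGeneric("mapLinks"))

#' @rdname InitialSolution-class
#' @param x an object with seed sets.
#' @export
setGeneric("seedSets", function(x) standardGeneric("seedSets"))

#' @rdname InitialSolution-class
#' @export
setGeneric("seedLinks", function(x) standardGeneric("seedLinks"))

setMethod("nodes", "Network", function(x) x@nodes)
setMethod("networkMode", "Network", function(x) x@mode)
setMethod("isWeighted", "Network",
          function(x) identical(x@mode, "weighted"))
setMethod("modules", "ModuleMap", function(x) x@modules)
setMethod("mapLinks", "ModuleMap", function(x) x@links)
setMethod("nodes", "ModuleMap",
          function(x) sort(unlist(x@modules, use.names = FALSE)))
setMethod("seedSets", "InitialSolution", function(x) x@sets)
setMethod("seedLinks", "InitialSolution", function(x) x@seedLinks)
setMethod("seedSets", "ImproverState", function(x) x@sets)
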