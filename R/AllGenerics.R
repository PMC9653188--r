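#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @export
setGeneric("accessionInfo", function(x) standardGeneric("accessionInfo"))

#' @export
setGeneric("coreMarkers", function(x) standardGeneric("coreMarkers"))

#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @export
setGeneric("perChromSummary", function(x) standardGeneric("perChromSummary"))

#' @export
setGeneric("platformTotals", function(x) standardGeneric("platformTotals"))

#' @export
setGeneric("summarizePlatform",
           function(x, ...) standardGeneric("summarizePlatform"))

#' @export
setGeneric("markerEffects", function(object) standardGeneric("markerEffects"))

#' @export
setGeneric("varianceComponents",
           function(object) standardGeneric("varianceComponents"))

#' @export
setGeneric("heritability", function(object) standardGeneric("heritability"))
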