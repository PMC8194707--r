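#' @rdname encode
#' @export
setGeneric("encode", function(layer, x) standardGeneric("encode"))

#' @rdname encode
#' @export
setGeneric("decode", function(layer, z) standardGeneric("decode"))

#' @rdname accessors
#' @export
setGeneric("riskLabels", function(x) standardGeneric("riskLabels"))

#' @rdname accessors
#' @export
setGeneric("tugTimes", function(x) standardGeneric("tugTimes"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname tfTransform
#' @export
setGeneric("tfTransform",
  function(signal, samplingRate, grid) standardGeneric("tfTransform"))

#' @rdname renderImage
#' @export
setGeneric("renderImage",
  function(tfr, height = 28L, width = 28L, normalize = c("image", "global"),
           globalRange = NULL, sourceAxis = NA_character_)
    standardGeneric("renderImage"))

#' @rdname confusion
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname confusion
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname confusion
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname reportToTables
#' @export
setGeneric("reportToTables", function(report) standardGeneric("reportToTables"))
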