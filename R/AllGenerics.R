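# Accessor generics for the S4 containers. Slot access from user code should
# go through these, never through `@`.

#' @rdname EnhancementResult-class
#' @param object an object of the documented class.
#' @export
setGeneric("enhancedImage", function(object) standardGeneric("enhancedImage"))
#' @rdname EnhancementResult-class
#' @export
setGeneric("weightMap", function(object) standardGeneric("weightMap"))
#' @rdname EnhancementResult-class
#' @export
setGeneric("exposureRatio", function(object) standardGeneric("exposureRatio"))
#' @rdname EnhancementResult-class
#' @export
setGeneric("syntheticExposure", function(object) standardGeneric("syntheticExposure"))
#' @rdname GradientMap-class
#' @param object an object of the documented class.
#' @export
setGeneric("gradientValues", function(object) standardGeneric("gradientValues"))
#' @rdname MongoosePopulation-class
#' @param object an object of the documented class.
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname MongoosePopulation-class
#' @export
setGeneric("fitnessValues", function(object) standardGeneric("fitnessValues"))
#' @rdname MongoosePopulation-class
#' @export
setGeneric("alphaIndex", function(object) standardGeneric("alphaIndex"))
#' @rdname MongoosePopulation-class
#' @export
setGeneric("evaluationCount", function(object) standardGeneric("evaluationCount"))

#' @rdname EnhancementResult-class
#' @export
setMethod("enhancedImage", "EnhancementResult", function(object) object@enhanced)
#' @rdname EnhancementResult-class
#' @export
setMethod("weightMap", "EnhancementResult", function(object) object@weightMap)
#' @rdname EnhancementResult-class
#' @export
setMethod("exposureRatio", "EnhancementResult", function(object) object@exposureRatio)
#' @rdname EnhancementResult-class
#' @export
setMethod("syntheticExposure", "EnhancementResult", function(object) object@syntheticExposure)
#' @rdname GradientMap-class
#' @export
setMethod("gradientValues", "GradientMap", function(object) object@values)
#' @rdname MongoosePopulation-class
#' @export
setMethod("positions", "MongoosePopulation", function(object) object@X)
#' @rdname MongoosePopulation-class
#' @export
setMethod("fitnessValues", "MongoosePopulation", function(object) object@fitness)
#' @rdname MongoosePopulation-class
#' @export
setMethod("alphaIndex", "MongoosePopulation", function(object) object@alphaIndex)
#' @rdname MongoosePopulation-class
#' @export
setMethod("evaluationCount", "MongoosePopulation", function(object) object@evaluations)
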