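#' @import methods
#' @importFrom BiocGenerics start end strand width
NULL

#' @export
setGeneric("context", function(x, ...) standardGeneric("context"))

#' @export
setGeneric("cCount", function(x, ...) standardGeneric("cCount"))

#' @export
setGeneric("totalCount", function(x, ...) standardGeneric("totalCount"))

#' @export
setGeneric("conversionRate", function(x, ...) standardGeneric("conversionRate"))

#' @export
setGeneric("weightedLevel", function(x, ...) standardGeneric("weightedLevel"))

#' @export
setGeneric("binLevels", function(x, ...) standardGeneric("binLevels"))

#' @export
setGeneric("empiricalP", function(x, ...) standardGeneric("empiricalP"))
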