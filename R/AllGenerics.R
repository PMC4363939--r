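#' @export
setGeneric("vipScores", function(object, ...) standardGeneric("vipScores"))

#' @export
setGeneric("worked", function(object) standardGeneric("worked"))

#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))

#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @export
setGeneric("entries", function(object) standardGeneric("entries"))

#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @export
setGeneric("responseMatrix", function(object) standardGeneric("responseMatrix"))
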