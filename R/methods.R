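# Accessors and show methods.

#' @describeIn MasterList-class entries accessor.
#' @param object a MasterList.
#' @export
setMethod("entries", "MasterList", function(object) object@entries)

#' @describeIn PLSDesign-class predictor matrix accessor.
#' @param object a PLSDesign.
#' @export
setMethod("designMatrix", "PLSDesign", function(object) object@X)

#' @describeIn PLSDesign-class response matrix accessor.
#' @export
setMethod("responseMatrix", "PLSDesign", function(object) object@Y)

#' @describeIn TrainedSignature-class Q2-gate accessor.
#' @param object a TrainedSignature.
#' @export
setMethod("worked", "TrainedSignature", function(object) object@worked)

#' @describeIn TrainedSignature-class selected-gene accessor.
#' @export
setMethod("signatureGenes", "TrainedSignature", function(object) object@genes)

#' @describeIn TrainedSignature-class diagnostics accessor.
#' @export
setMethod("diagnostics", "TrainedSignature", function(object) object@diagnostics)

#' @describeIn GroundTruth-class planted-gene accessor.
#' @param object a GroundTruth.
#' @export
setMethod("signatureGenes", "GroundTruth", function(object) object@signatureGenes)

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@groups), "groups x",
      length(object@weeks), "weeks x", object@nReplicates, "replicates\n")
  cat("  groups:", paste(object@groups, collapse = ", "), "\n")
  cat("  genes:", object@nGenes, "(", object@nSignature, "signature )\n")
  cat("  noise SD:", object@noiseSd, " seed:", object@seed, "\n")
})

setMethod("show", "MasterList", function(object) {
  cat("MasterList (week", object@week, "):", nrow(object@entries),
      "genes\n")
  cls <- table(object@entries$class)
  if (length(cls)) cat("  ", paste(names(cls), cls, sep = "=", collapse = "  "),
                       "\n")
})

setMethod("show", "PLSDesign", function(object) {
  cat("PLSDesign (", object@protocol, "): ", nrow(object@X), " rows x ",
      ncol(object@X), " genes, ", ncol(object@Y), " response(s)\n", sep = "")
  if (anyNA(object@X))
    cat("  missing cells:", sum(is.na(object@X)), "\n")
})

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", object@ncomp, "component(s),",
      nrow(object@weights), "variables,",
      nrow(object@loadingsY), "response(s)\n")
})

setMethod("show", "PLSDiagnostics", function(object) {
  a <- length(object@q2)
  cat("PLSDiagnostics (", object@cvFolds, "-fold CV):\n", sep = "")
  cat("  R2Y:", round(object@r2y[a], 3), " Q2:", round(max(object@q2), 3),
      "over", a, "component(s)\n")
})

setMethod("show", "TrainedSignature", function(object) {
  cat("TrainedSignature:", object@spec@tissue, "/", object@spec@parameter,
      "\n")
  cat("  protocol:", object@protocolUsed,
      " genes:", length(object@genes),
      " Q2:", round(max(object@diagnostics@q2), 3),
      " worked:", object@worked, "\n")
})

setMethod("show", "LinearConversion", function(object) {
  cat("LinearConversion: reference = ", object@m, " * new + ", object@c,
      "\n", sep = "")
})

setMethod("show", "Cutpoints", function(object) {
  cat("Cutpoints: normal <= ", object@lower, " < borderline <= ",
      object@upper, " < disease\n", sep = "")
})

setMethod("show", "InteractionGraph", function(object) {
  g <- object@graph
  nSig <- sum(lengths(object@annotation) > 0)
  cat("InteractionGraph:", igraph::vcount(g), "nodes (", nSig,
      "signature ),", igraph::ecount(g), "edges\n")
})
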