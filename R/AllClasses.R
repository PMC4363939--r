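#' Study design for the synthetic generator
#'
#' Describes the shape of a diet-intervention time-course study: the diet
#' groups, the sampling weeks, the number of replicate arrays per
#' tissue/group/week cell, and the gene-level composition of the simulated
#' arrays (how many genes, how many carry planted predictive signal, what
#' fraction of genes appear under duplicate probes, what fraction of probes
#' have an inconsistent replicate).
#'
#' @slot groups character vector of diet group labels; the first is the
#'   control diet against which log2 ratios are expressed.
#' @slot weeks strictly increasing integer sampling weeks.
#' @slot nReplicates integer, replicate arrays per cell.
#' @slot nGenes integer, genes per array.
#' @slot nSignature integer, planted predictive genes (<= nGenes).
#' @slot duplicateProbeFraction fraction in [0,1) of genes measured by a
#'   second probe with its own p-value.
#' @slot inconsistentReplicateFraction fraction in [0,1) of probes with one
#'   sign-flipped replicate (mixed regulation classes).
#' @slot noiseSd standard deviation of replicate noise, log2 units.
#' @slot seed integer RNG seed.
#' @slot tissue tissue label stamped on the generated tables.
#' @slot groupSeverity named numeric disease-severity per group in [0,1]
#'   (0 = control); groups without a stated severity get a seeded uniform
#'   draw.
#' @export
setClass("StudyDesign", representation(
  groups = "character",
  weeks = "integer",
  nReplicates = "integer",
  nGenes = "integer",
  nSignature = "integer",
  duplicateProbeFraction = "numeric",
  inconsistentReplicateFraction = "numeric",
  noiseSd = "numeric",
  seed = "integer",
  tissue = "character",
  groupSeverity = "numeric"
))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@groups) < 1L || anyDuplicated(object@groups))
    msg <- c(msg, "groups: need at least one unique group label")
  if (length(object@weeks) < 1L || is.unsorted(object@weeks, strictly = TRUE))
    msg <- c(msg, "weeks: must be strictly increasing")
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates: must be >= 1")
  if (object@nGenes < 0L)
    msg <- c(msg, "nGenes: must be >= 0")
  if (object@nSignature < 0L || object@nSignature > object@nGenes)
    msg <- c(msg, "nSignature: must satisfy 0 <= nSignature <= nGenes")
  for (f in c("duplicateProbeFraction", "inconsistentReplicateFraction")) {
    v <- slot(object, f)
    if (!is.finite(v) || v < 0 || v >= 1)
      msg <- c(msg, paste0(f, ": must lie in [0, 1)"))
  }
  if (!is.finite(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd: must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth behind a synthetic study
#'
#' @slot signatureGenes gene symbols carrying planted signal.
#' @slot coefficients matrix (gene x phenotype) of planted linear effects,
#'   phenotype units per log2 unit; nonzero exactly on signature genes.
#' @slot baseline data.frame of control-diet phenotype values per week.
#' @slot groupEffects named numeric severity per group producing the
#'   control/disease divergence that plateaus at the critical week.
#' @export
setClass("GroundTruth", representation(
  signatureGenes = "character",
  coefficients = "matrix",
  baseline = "data.frame",
  groupEffects = "numeric"
))

#' Per-week master list of noise-filtered genes
#'
#' The non-redundant gene-level table for one tissue/group/week after
#' replicate-consistency filtering and minimum-p probe deduplication.
#'
#' @slot week integer sampling week.
#' @slot entries data.frame with columns gene_symbol, expression (log2
#'   ratio), p_value, class (up/down/insignificant), one row per gene.
#' @export
setClass("MasterList", representation(
  week = "integer",
  entries = "data.frame"
))

setValidity("MasterList", function(object) {
  e <- object@entries
  need <- c("gene_symbol", "expression", "p_value", "class")
  if (!all(need %in% names(e)))
    return(paste("entries: missing columns",
                 paste(setdiff(need, names(e)), collapse = ", ")))
  if (anyDuplicated(e$gene_symbol))
    return("entries: gene symbols must be unique")
  TRUE
})

#' Observation-by-gene design matrix for PLS
#'
#' Rows are (group, input week) observations; columns are gene symbols; the
#' response block carries the phenotype value(s) at the critical output
#' week(s), repeated across a group's rows. Under the union protocol, genes
#' absent from a week's master list are NA.
#'
#' @slot X numeric matrix, observations x genes, NA marking absent genes.
#' @slot Y numeric matrix, observations x responses.
#' @slot rowInfo data.frame with columns group and week per row of X.
#' @slot protocol "intersection" or "union".
#' @export
setClass("PLSDesign", representation(
  X = "matrix",
  Y = "matrix",
  rowInfo = "data.frame",
  protocol = "character"
))

setValidity("PLSDesign", function(object) {
  if (nrow(object@X) != nrow(object@Y) || nrow(object@X) != nrow(object@rowInfo))
    return("X, Y and rowInfo must have the same number of rows")
  if (object@protocol == "intersection" && anyNA(object@X))
    return("intersection designs cannot contain missing values")
  TRUE
})

#' Fitted partial least squares model
#'
#' NIPALS latent-variable model with unit-variance scaling and mean
#' centering. Scores, weights and loadings are stored per component;
#' `coefficients` maps scaled X to scaled Y.
#'
#' @slot ncomp number of latent components A.
#' @slot weights X-weights W (p x A), unit norm per component.
#' @slot loadingsX X-loadings P (p x A).
#' @slot loadingsY Y-loadings Q (r x A).
#' @slot scores X-scores T (n x A), mutually orthogonal.
#' @slot coefficients B (p x r) in the scaled space.
#' @slot xCenter,xScale,yCenter,yScale centering/scaling vectors.
#' @slot ssY per-component explained Y sum of squares (scaled space).
#' @slot fitted fitted responses on the original scale.
#' @export
setClass("PLSModel", representation(
  ncomp = "integer",
  weights = "matrix",
  loadingsX = "matrix",
  loadingsY = "matrix",
  scores = "matrix",
  coefficients = "matrix",
  xCenter = "numeric",
  xScale = "numeric",
  yCenter = "numeric",
  yScale = "numeric",
  ssY = "numeric",
  fitted = "matrix"
))

#' Cross-validated model diagnostics
#'
#' @slot r2x,r2y cumulative fraction of X / Y variance explained per
#'   component count.
#' @slot q2 cumulative cross-validated predictive ability per component
#'   count (1 - PRESS/SS); may be negative.
#' @slot q2Increment marginal Q2 gain of each added component.
#' @slot cvFolds,cvSeed cross-validation configuration.
#' @export
setClass("PLSDiagnostics", representation(
  r2x = "numeric",
  r2y = "numeric",
  q2 = "numeric",
  q2Increment = "numeric",
  cvFolds = "integer",
  cvSeed = "integer"
))

#' Specification of one tissue/parameter model
#'
#' Fixes the physiological parameter, its critical output week(s), the two
#' early input weeks, and the week-combination protocol.
#'
#' @slot tissue tissue label.
#' @slot parameter one of body_weight, blood_glucose, anti_cytokines,
#'   pro_cytokines.
#' @slot inputWeeks two early weeks whose expression enters as rows.
#' @slot outputWeeks critical week(s) supplying the response.
#' @slot protocol "auto", "intersection" or "union".
#' @export
setClass("ModelSpec", representation(
  tissue = "character",
  parameter = "character",
  inputWeeks = "integer",
  outputWeeks = "integer",
  protocol = "character"
))

setValidity("ModelSpec", function(object) {
  ok <- c("body_weight", "blood_glucose", "anti_cytokines", "pro_cytokines")
  if (!object@parameter %in% ok)
    return(paste("parameter: must be one of", paste(ok, collapse = ", ")))
  if (length(object@inputWeeks) != 2L)
    return("inputWeeks: exactly two input weeks are required")
  if (!object@protocol %in% c("auto", "intersection", "union"))
    return("protocol: must be auto, intersection or union")
  TRUE
})

#' Trained gene signature for one tissue/parameter
#'
#' @slot spec the ModelSpec trained against.
#' @slot protocolUsed protocol that produced the final model.
#' @slot genes selected signature gene symbols (VIP above cutoff).
#' @slot model refit PLSModel on the selected genes.
#' @slot diagnostics PLSDiagnostics of the refit model.
#' @slot preDiagnostics PLSDiagnostics of the all-gene model.
#' @slot worked TRUE iff the refit model passes the Q2 > 0.5 gate.
#' @export
setClass("TrainedSignature", representation(
  spec = "ModelSpec",
  protocolUsed = "character",
  genes = "character",
  model = "ANY",
  diagnostics = "ANY",
  preDiagnostics = "ANY",
  worked = "logical"
))

#' Linear cross-experiment conversion
#'
#' The map reference = m * new + c aligning a new experiment's phenotype
#' scale with the reference experiment used to train the models.
#'
#' @slot m slope (dimensionless).
#' @slot c intercept (phenotype units).
#' @export
setClass("LinearConversion", representation(m = "numeric", c = "numeric"))

setValidity("LinearConversion", function(object) {
  if (!is.finite(object@m) || object@m == 0) return("m: must be finite and nonzero")
  if (!is.finite(object@c)) return("c: must be finite")
  TRUE
})

#' Reference-range cutpoints for effectiveness classification
#'
#' The 25% and 50% points of the control-to-disease phenotype gap; values
#' at or below `lower` are normal ("+"), between `lower` and `upper`
#' borderline ("+/-"), above `upper` diseased ("-").
#'
#' @slot lower 25% point (upper bound of the normal range).
#' @slot upper 50% point (disease threshold).
#' @slot nd,hfhsd the control and disease anchors.
#' @export
setClass("Cutpoints", representation(
  lower = "numeric", upper = "numeric", nd = "numeric", hfhsd = "numeric"
))

#' Annotated protein-protein interaction graph
#'
#' Undirected simple graph over signature genes and their first-neighbour
#' interactors; each node is annotated with the set of physiological
#' parameters whose signature contains it (empty for pure interactors).
#'
#' @slot graph an igraph object.
#' @slot annotation named list, node -> character vector of parameters.
#' @export
setClass("InteractionGraph", representation(
  graph = "ANY",
  annotation = "list"
))
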