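# Cross-experiment evaluation of formulations.
#
# Phenotype scales differ between experiments (different cohorts, ages,
# assay batches), so observed values from a new experiment are aligned to
# the reference experiment by the two-point linear map anchored at the
# control-diet and disease-diet values -- the same construction as a
# Celsius/Fahrenheit conversion. Effectiveness is then read off reference
# ranges placed at 25% and 50% of the control-to-disease gap.

#' Fit the two-point linear conversion between experiments
#'
#' Returns the map from the NEW experiment's scale to the REFERENCE scale:
#' m = (ref_HFHSD - ref_ND) / (new_HFHSD - new_ND), c = ref_ND - m * new_ND.
#'
#' @param referenceNd,referenceHfhsd control and disease anchors of the
#'   reference experiment (phenotype units).
#' @param newNd,newHfhsd the same anchors measured in the new experiment.
#' @return a \linkS4class{LinearConversion}.
#' @export
fitConversion <- function(referenceNd, referenceHfhsd, newNd, newHfhsd) {
  for (v in c(referenceNd, referenceHfhsd, newNd, newHfhsd))
    stopIfNotScalarFinite(v, "anchor value")
  if (newHfhsd == newNd)
    stop("new-experiment anchors coincide; the conversion slope is undefined")
  if (referenceHfhsd == referenceNd)
    stop("reference anchors coincide; the conversion is degenerate")
  m <- (referenceHfhsd - referenceNd) / (newHfhsd - newNd)
  new("LinearConversion", m = m, c = referenceNd - m * newNd)
}

#' Apply a linear conversion
#'
#' @param value finite numeric value(s) on the new experiment's scale.
#' @param conversion a \linkS4class{LinearConversion}.
#' @return m * value + c, on the reference scale.
#' @export
convertValue <- function(value, conversion) {
  stopifnot(is(conversion, "LinearConversion"))
  if (any(!is.finite(value))) stop("'value' must be finite")
  conversion@m * value + conversion@c
}

#' Reference ranges separating normal, borderline and diseased states
#'
#' The normal range ends 25% of the way from the control anchor to the
#' disease anchor; the disease range begins at 50%.
#'
#' @param nd,hfhsd control and disease anchors (phenotype units).
#' @return a \linkS4class{Cutpoints}.
#' @export
referenceRanges <- function(nd, hfhsd) {
  stopIfNotScalarFinite(nd, "nd"); stopIfNotScalarFinite(hfhsd, "hfhsd")
  if (hfhsd == nd) stop("anchors coincide; ranges are degenerate")
  gap <- hfhsd - nd
  new("Cutpoints", lower = nd + 0.25 * gap, upper = nd + 0.5 * gap,
      nd = nd, hfhsd = hfhsd)
}

#' Classify a phenotype value against reference ranges
#'
#' "+" for values at or below the 25% point (formulation works), "+/-"
#' between the 25% and 50% points (partially works), "-" above the 50%
#' point (disease state). Boundary values go to the milder class, since the
#' disease class is defined by strictly exceeding the threshold.
#'
#' @param value finite numeric value(s) on the reference scale.
#' @param cutpoints a \linkS4class{Cutpoints}.
#' @return character vector in {"+", "+/-", "-"}.
#' @export
classifyEffectiveness <- function(value, cutpoints) {
  stopifnot(is(cutpoints, "Cutpoints"))
  if (any(!is.finite(value))) stop("'value' must be finite")
  ifelse(value <= cutpoints@lower, "+",
         ifelse(value <= cutpoints@upper, "+/-", "-"))
}

#' Evaluate formulations against observed outcomes
#'
#' Converts each formulation's observed phenotype to the reference scale,
#' classifies both the model prediction and the converted observation
#' against the reference ranges, and reports them side by side with an
#' agreement flag.
#'
#' @param predictions named numeric vector (formulation -> predicted value,
#'   reference scale).
#' @param observations named numeric vector (formulation -> observed value,
#'   new-experiment scale), same names as `predictions`.
#' @param referenceNd,referenceHfhsd reference-experiment anchors defining
#'   both the ranges and the conversion target.
#' @param newNd,newHfhsd new-experiment anchors; alternatively supply
#'   `conversion` directly when the anchors are unavailable or the printed
#'   (m, c) of an experiment are to be used as-is.
#' @param conversion optional \linkS4class{LinearConversion} overriding the
#'   anchor-derived one.
#' @param digits display rounding for the converted column (default 2).
#' @return data.frame: formulation, predicted, predicted_label, observed,
#'   converted, observed_label, agree.
#' @export
evaluateFormulation <- function(predictions, observations,
                                referenceNd, referenceHfhsd,
                                newNd = NULL, newHfhsd = NULL,
                                conversion = NULL, digits = 2) {
  if (is.null(conversion)) {
    if (is.null(newNd) || is.null(newHfhsd))
      stop("supply either the new experiment's anchors or a conversion")
    conversion <- fitConversion(referenceNd, referenceHfhsd, newNd, newHfhsd)
  }
  if (is.null(names(predictions)) || is.null(names(observations)))
    stop("'predictions' and 'observations' must be named by formulation")
  obs <- observations[names(predictions)]
  if (anyNA(obs)) stop("observations missing for: ",
                       paste(names(predictions)[is.na(obs)], collapse = ", "))
  cp <- referenceRanges(referenceNd, referenceHfhsd)
  converted <- convertValue(obs, conversion)
  data.frame(
    formulation = names(predictions),
    predicted = unname(predictions),
    predicted_label = classifyEffectiveness(predictions, cp),
    observed = unname(obs),
    converted = round(unname(converted), digits),
    observed_label = classifyEffectiveness(converted, cp),
    agree = classifyEffectiveness(predictions, cp) ==
      classifyEffectiveness(converted, cp),
    stringsAsFactors = FALSE, row.names = NULL)
}
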