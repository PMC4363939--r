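# Per-tissue, per-parameter signature training and blind prediction.
#
# A model "works" when its cross-validated Q2 exceeds 0.5. Training first
# uses the intersection protocol (genes common to both input weeks across
# the training groups); when that fails the gate, the union protocol is
# retried, with genes absent from a week's master list entered as missing.

#' Construct a model specification
#'
#' Output weeks are fixed by the physiological parameter: week 15 for body
#' weight, week 12 for blood glucose, and weeks 9 and 12 combined for the
#' cytokine panels (the week-9 critical point alone gives too little
#' response variation, so the two weeks enter as parallel response
#' columns).
#'
#' @param parameter one of body_weight, blood_glucose, anti_cytokines,
#'   pro_cytokines.
#' @param tissue tissue label.
#' @param inputWeeks two early input weeks (default 3 and 6).
#' @param protocol "auto" (intersection with union fallback),
#'   "intersection" or "union".
#' @return a \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(parameter, tissue = "skeletal",
                      inputWeeks = c(3L, 6L), protocol = "auto") {
  outputWeeks <- switch(parameter,
                        body_weight = 15L,
                        blood_glucose = 12L,
                        anti_cytokines = c(9L, 12L),
                        pro_cytokines = c(9L, 12L),
                        stop("parameter: must be one of body_weight, ",
                             "blood_glucose, anti_cytokines, pro_cytokines"))
  new("ModelSpec", tissue = tissue, parameter = parameter,
      inputWeeks = as.integer(inputWeeks), outputWeeks = outputWeeks,
      protocol = protocol)
}

.q2Gate <- 0.5

.trainOne <- function(spec, masterLists, phenotypes, protocol, groups,
                      controlGroup, cutoff, folds, seed) {
  design <- assembleDesign(masterLists, phenotypes, spec@parameter,
                           protocol = protocol,
                           inputWeeks = spec@inputWeeks, groups = groups,
                           controlGroup = controlGroup,
                           outputWeeks = spec@outputWeeks)
  n <- nrow(design@X)
  sel <- selectAndRefit(design@X, design@Y, cutoff = cutoff,
                        folds = min(folds, n), seed = seed)
  finalQ2 <- max(sel$diagnostics@q2)
  list(design = design, sel = sel, q2 = finalQ2)
}

#' Train a signature model for one tissue/parameter
#'
#' Builds the design per the spec's protocol, selects genes by VIP and
#' refits, and applies the Q2 > 0.5 worked/not-worked gate. Under protocol
#' "auto", the intersection protocol is tried first and the union protocol
#' is the fallback; if both fail the gate, the better attempt is returned
#' with `worked = FALSE`.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param masterLists nested per-group, per-week master lists (see
#'   [assembleDesign()]).
#' @param phenotypes phenotype data.frame.
#' @param groups training groups (default: control + every group with
#'   master lists; hold blind groups out by listing the rest here).
#' @param controlGroup control diet label contributing all-zero rows; NULL
#'   to train without control rows.
#' @param cutoff VIP selection cutoff.
#' @param folds,seed cross-validation control.
#' @return a \linkS4class{TrainedSignature}.
#' @export
trainSignature <- function(spec, masterLists, phenotypes, groups = NULL,
                           controlGroup = "ND", cutoff = 1, folds = 7L,
                           seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  protocols <- switch(spec@protocol,
                      auto = c("intersection", "union"),
                      spec@protocol)
  attempts <- list()
  for (pr in protocols) {
    att <- tryCatch(
      .trainOne(spec, masterLists, phenotypes, pr, groups, controlGroup,
                cutoff, folds, seed),
      error = function(e) NULL)
    if (!is.null(att)) {
      att$protocol <- pr
      attempts[[pr]] <- att
      if (att$q2 > .q2Gate) break
    }
  }
  if (length(attempts) == 0)
    stop("model training failed under every protocol (",
         paste(protocols, collapse = ", "), ")")
  best <- attempts[[which.max(vapply(attempts, `[[`, numeric(1), "q2"))]]
  new("TrainedSignature", spec = spec, protocolUsed = best$protocol,
      genes = best$sel$selected, model = best$sel$model,
      diagnostics = best$sel$diagnostics,
      preDiagnostics = best$sel$preDiagnostics,
      worked = best$q2 > .q2Gate)
}

#' Predict phenotypes for a blind group
#'
#' Produces one prediction per input week from the blind group's master
#' lists. Signature genes absent from a week's blind list (removed by noise
#' filtration there) enter as missing values; a week with no signature gene
#' present predicts the training response mean.
#'
#' @param trained a worked \linkS4class{TrainedSignature}.
#' @param blindLists per-week master lists for the blind group:
#'   `blindLists[[as.character(week)]]`.
#' @return data.frame with one row per (input week, response).
#' @export
predictBlind <- function(trained, blindLists) {
  stopifnot(is(trained, "TrainedSignature"))
  if (!trained@worked)
    stop("model did not pass the Q2 gate; blind prediction is not meaningful")
  genes <- rownames(trained@model@weights)
  weeks <- trained@spec@inputWeeks
  X <- matrix(NA_real_, nrow = length(weeks), ncol = length(genes),
              dimnames = list(NULL, genes))
  for (i in seq_along(weeks)) {
    ml <- blindLists[[as.character(weeks[i])]]
    if (is.null(ml)) stop("missing blind master list for week ", weeks[i])
    e <- ml@entries
    X[i, ] <- e$expression[match(genes, e$gene_symbol)]
  }
  pred <- predictPLS(trained@model, X)
  out <- data.frame(week = rep(weeks, each = ncol(pred)),
                    response = rep(colnames(pred), length(weeks)),
                    predicted = as.vector(t(pred)),
                    stringsAsFactors = FALSE)
  out
}
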