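test_that("a planted body-weight study trains under the intersection protocol", {
  d <- studyDesign(nGenes = 120L, nSignature = 15L, noiseSd = 0.1, seed = 21L)
  s <- generateStudy(d)
  ml <- buildMasterLists(s$expression, weeks = c(3, 6))
  fit <- trainSignature(modelSpec("body_weight"), ml, s$phenotypes,
                        groups = setdiff(d@groups, "KAL-5"))
  expect_true(worked(fit))
  expect_identical(fit@protocolUsed, "intersection")
  expect_gt(length(signatureGenes(fit)), 0)
  # selected genes are dominated by the planted signature
  expect_gt(mean(signatureGenes(fit) %in% signatureGenes(s$truth)), 0.5)
})

test_that("a pure-noise study fails the Q2 gate under both protocols", {
  d <- studyDesign(nGenes = 80L, nSignature = 0L, noiseSd = 0.3, seed = 22L)
  s <- generateStudy(d)
  ml <- buildMasterLists(s$expression, weeks = c(3, 6))
  fit <- tryCatch(
    trainSignature(modelSpec("body_weight"), ml, s$phenotypes,
                   groups = setdiff(d@groups, "KAL-5")),
    error = function(e) NULL)
  if (!is.null(fit)) expect_false(worked(fit))
  else succeed("training failed outright on pure noise")
})

test_that("union protocol rescues disjoint week lists", {
  # week-6 lists share no genes with week-3 lists, but both carry the
  # severity signal: the intersection is empty, the union model works
  lists <- handLists(sigGenes3 = paste0("A", 1:8),
                     sigGenes6 = paste0("B", 1:8),
                     filler3 = paste0("F", 1:3), filler6 = paste0("H", 1:3))
  ph <- handPhenotypes()
  fit <- trainSignature(modelSpec("body_weight"), lists, ph, seed = 2L)
  expect_identical(fit@protocolUsed, "union")
  expect_true(worked(fit))
})

test_that("cytokine panels train with parallel per-week response columns", {
  lists <- handLists()
  ph <- handPhenotypes()
  fit <- trainSignature(modelSpec("pro_cytokines"), lists, ph, seed = 3L)
  expect_true(worked(fit))
  expect_equal(nrow(fit@model@loadingsY), 16)  # 8 cytokines x 2 output weeks
})

test_that("blind rows identical to a training group's reproduce its fit", {
  lists <- handLists()
  ph <- handPhenotypes()
  fit <- trainSignature(modelSpec("body_weight"), lists, ph, seed = 4L)
  expect_true(worked(fit))
  pb <- predictBlind(fit, lists[["KAL-20"]])
  fitted <- fit@model@fitted
  # design rows are ordered group-major, week-minor; KAL-20 is third of
  # (ND, HFHSD, KAL-20, KAL-75)
  expect_equal(pb$predicted, fitted[c(5, 6), 1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a blind list without any signature gene predicts the training mean", {
  lists <- handLists()
  ph <- handPhenotypes()
  fit <- trainSignature(modelSpec("body_weight"), lists, ph, seed = 5L)
  emptyEntries <- data.frame(gene_symbol = character(),
                             expression = numeric(), p_value = numeric(),
                             class = character(), stringsAsFactors = FALSE)
  blank <- list("3" = new("MasterList", week = 3L, entries = emptyEntries),
                "6" = new("MasterList", week = 6L, entries = emptyEntries))
  pb <- predictBlind(fit, blank)
  yTrain <- ph$body_weight[ph$week == 15 & ph$group %in%
                             c("ND", "HFHSD", "KAL-20", "KAL-75")]
  expect_equal(pb$predicted, rep(mean(rep(yTrain, each = 2)), 2),
               tolerance = 1e-8)
})

test_that("blind holdout prediction lands near the planted truth", {
  d <- studyDesign(nGenes = 120L, nSignature = 15L, noiseSd = 0.1, seed = 26L)
  s <- generateStudy(d)
  ml <- buildMasterLists(s$expression, weeks = c(3, 6))
  fit <- trainSignature(modelSpec("body_weight"), ml, s$phenotypes,
                        groups = setdiff(d@groups, "KAL-5"))
  expect_true(worked(fit))
  pb <- predictBlind(fit, ml[["KAL-5"]])
  truth <- s$phenotypes$body_weight[s$phenotypes$group == "KAL-5" &
                                      s$phenotypes$week == 15]
  # error budget: replicate + cell-level noise propagated through the
  # planted coefficients, with a factor-2 margin for model error
  sig <- signatureGenes(s$truth)
  tol <- 3 * 2 * d@noiseSd *
    sqrt(sum(s$truth@coefficients[sig, "body_weight"]^2))
  expect_true(all(abs(pb$predicted - truth) < tol))
})

test_that("identical noiseless weeks give coinciding per-week predictions", {
  d <- studyDesign(nGenes = 60L, nSignature = 10L, noiseSd = 0,
                   duplicateProbeFraction = 0,
                   inconsistentReplicateFraction = 0, seed = 27L)
  s <- generateStudy(d)
  ml <- buildMasterLists(s$expression, weeks = c(3, 6))
  fit <- trainSignature(modelSpec("body_weight"), ml, s$phenotypes,
                        groups = setdiff(d@groups, "KAL-5"))
  pb <- predictBlind(fit, ml[["KAL-5"]])
  expect_equal(pb$predicted[pb$week == 3], pb$predicted[pb$week == 6],
               tolerance = 1e-8)
})

test_that("stronger planted effects never flip a working gate off", {
  for (s in 1:3) {
    workedAt <- vapply(c(0.5, 1, 2), function(eff) {
      fx <- plantedMatrix(p = 60, nSignal = 10, noiseSd = 0.1, seed = s,
                          effectScale = eff)
      sel <- selectAndRefit(fx$X, fx$y, seed = s)
      max(sel$diagnostics@q2) > 0.5
    }, logical(1))
    expect_true(all(diff(workedAt) >= 0) || all(workedAt))
  }
})

test_that("blind prediction refuses a failed model", {
  spec <- modelSpec("body_weight")
  dead <- new("TrainedSignature", spec = spec, protocolUsed = "intersection",
              genes = character(), model = NULL, diagnostics = NULL,
              preDiagnostics = NULL, worked = FALSE)
  expect_error(predictBlind(dead, list()), "gate")
})
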