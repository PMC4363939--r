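test_that("regulation classes use strict two-fold boundaries", {
  expect_identical(classifyRegulation(1.5), "up")
  expect_identical(classifyRegulation(0.0), "insignificant")
  expect_identical(classifyRegulation(1.0), "insignificant")
  expect_identical(classifyRegulation(-1.0), "insignificant")
  expect_identical(classifyRegulation(-1.5), "down")
  expect_identical(classifyRegulation(c(2, -2, 0.5)),
                   c("up", "down", "insignificant"))
  expect_error(classifyRegulation(NaN), "finite")
  expect_error(classifyRegulation(1.5, threshold = 0), "positive")
})

test_that("replicate-consistency filtering keeps unanimous regulated probes", {
  tab <- data.frame(probe_id = c("a", "b", "c"), gene_symbol = c("A", "B", "C"),
                    rep1 = c(1.2, 1.2, 0.2), rep2 = c(1.5, -1.5, 0.5),
                    rep3 = c(2.0, 2.0, 0.4),
                    geom_mean = c(1.56, 0.57, 0.37),
                    p_value = c(0.01, 0.02, 0.03))
  kept <- filterConsistent(tab)
  expect_identical(kept$gene_symbol, "A")
  expect_identical(filterConsistent(kept), kept)  # idempotent
  withInsig <- filterConsistent(tab, keepInsignificant = TRUE)
  expect_setequal(withInsig$gene_symbol, c("A", "C"))
})

test_that("probe dedup keeps the minimum-p probe per gene", {
  tab <- data.frame(probe_id = c("p2", "p1", "p3"),
                    gene_symbol = c("G1", "G1", "G2"),
                    rep1 = 1.5, rep2 = 1.5, rep3 = 1.5,
                    geom_mean = c(1.2, 1.8, -1.4),
                    p_value = c(0.04, 0.01, 0.02))
  out <- dedupProbes(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$expression[out$gene_symbol == "G1"], 1.8)
  expect_identical(out$class, c("up", "down"))
  expect_false(anyDuplicated(out$gene_symbol) > 0)

  tie <- tab; tie$p_value <- c(0.02, 0.02, 0.01)
  out2 <- dedupProbes(tie)  # exact tie -> lexicographically smallest probe_id
  expect_equal(out2$expression[out2$gene_symbol == "G1"], 1.8)

  single <- tab[3, , drop = FALSE]
  expect_equal(dedupProbes(single)$expression, -1.4)
})

test_that("master lists compose filtering and dedup", {
  ml <- buildMasterList(probeFixture(), week = 3)
  expect_s4_class(ml, "MasterList")
  expect_equal(nrow(entries(ml)), 4)
  expect_setequal(entries(ml)$gene_symbol, c("GA", "GB", "GC", "GD"))
  # GA keeps the p=0.01 probe, GB the p=0.005 probe
  expect_equal(entries(ml)$expression[entries(ml)$gene_symbol == "GA"], 1.5)
  expect_equal(entries(ml)$expression[entries(ml)$gene_symbol == "GB"], -1.37)

  empty <- buildMasterList(probeFixture()[0, ], week = 3)
  expect_equal(nrow(entries(empty)), 0)

  clean <- probeFixture()[1:6, ][c(1, 3, 5, 6), ]  # unique consistent probes
  expect_equal(nrow(entries(buildMasterList(clean, 3))), 4)
})

mkLists <- function(genes3, genes6, group = "HFHSD") {
  mk <- function(genes, week) {
    new("MasterList", week = week,
        entries = data.frame(gene_symbol = genes,
                             expression = seq(1.5, by = 0.5,
                                              length.out = length(genes)),
                             p_value = 0.01, class = "up",
                             stringsAsFactors = FALSE))
  }
  out <- list()
  out[[group]] <- list("3" = mk(genes3, 3L), "6" = mk(genes6, 6L))
  out
}

phen2 <- data.frame(group = rep(c("ND", "HFHSD"), each = 2),
                    week = rep(c(12L, 15L), 2),
                    body_weight = c(27, 27.5, 37, 38),
                    blood_glucose = c(140, 141, 170, 171))

test_that("intersection and union protocols assemble the stated designs", {
  lists <- mkLists(c("A", "B"), c("A", "C"))
  di <- assembleDesign(lists, phen2, "body_weight", "intersection")
  expect_identical(colnames(designMatrix(di)), "A")
  expect_equal(nrow(designMatrix(di)), 4)
  expect_false(anyNA(designMatrix(di)))

  du <- assembleDesign(lists, phen2, "body_weight", "union")
  expect_setequal(colnames(designMatrix(du)), c("A", "B", "C"))
  # genes absent from a week's list are marked missing
  hf <- du@rowInfo$group == "HFHSD"
  expect_true(is.na(designMatrix(du)[du@rowInfo$week == 3 & hf, "C"]))
  expect_true(is.na(designMatrix(du)[du@rowInfo$week == 6 & hf, "B"]))
  expect_true(all(colnames(designMatrix(di)) %in% colnames(designMatrix(du))))

  # control rows are all zero (expression is a ratio against the control)
  nd <- du@rowInfo$group == "ND"
  expect_true(all(designMatrix(du)[nd, ] == 0))
})

test_that("responses repeat the group's critical-week phenotype across rows", {
  lists <- mkLists(c("A", "B"), c("A", "C"))
  d <- assembleDesign(lists, phen2, "body_weight", "intersection")
  expect_identical(colnames(responseMatrix(d)), "body_weight@wk15")
  hf <- d@rowInfo$group == "HFHSD"
  expect_equal(unname(responseMatrix(d)[hf, 1]), c(38, 38))
  expect_equal(unname(responseMatrix(d)[!hf, 1]), c(27.5, 27.5))
})

test_that("an empty intersection is reported as a protocol error", {
  lists <- mkLists(c("A", "B"), c("C", "D"))
  expect_error(assembleDesign(lists, phen2, "body_weight", "intersection"),
               "intersection")
  expect_silent(assembleDesign(lists, phen2, "body_weight", "union"))
})

test_that("row count is groups times the two input weeks", {
  lists <- c(mkLists(c("A", "B"), c("A", "C")),
             mkLists(c("A", "D"), c("A", "E"), group = "KAL-20"))
  ph <- rbind(phen2, data.frame(group = "KAL-20", week = c(12L, 15L),
                                body_weight = c(30, 31),
                                blood_glucose = c(150, 151)))
  d <- assembleDesign(lists, ph, "body_weight", "union")
  expect_equal(nrow(designMatrix(d)), 3 * 2)
})
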