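# End-to-end orchestration: simulate -> preprocess -> train -> predict ->
# evaluate -> network, driven by a validated config (R list or YAML file),
# with a JSON manifest recording every parameter needed to reproduce a run.

.configDefaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = c("simulate", "preprocess", "train", "predict", "evaluate",
               "network"),
    design = list(),
    models = list(list(parameter = "body_weight"),
                  list(parameter = "blood_glucose")),
    blind_group = "KAL-5",
    pls = list(folds = 7L, cutoff = 1, max_comp = 10L),
    network = list(top_fraction = 0.05, min_score = 1,
                   mean_degree = 4),
    evaluation = list())
}

.validateConfig <- function(config) {
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, config)
  # modifyList recurses into nested lists; the model list and stage vector
  # are replacements, not merges
  for (key in c("models", "stages"))
    if (key %in% names(config)) merged[[key]] <- config[[key]]
  designKeys <- names(formals(studyDesign))
  bad <- setdiff(names(merged$design), designKeys)
  if (length(bad))
    stop("unknown design key(s): ", paste(bad, collapse = ", "))
  badStages <- setdiff(merged$stages, defaults$stages)
  if (length(badStages))
    stop("unknown stage(s): ", paste(badStages, collapse = ", "))
  merged
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on a synthetic study: simulate
#' the study, build master lists, train one signature per configured model
#' holding the blind group out, predict the blind group per input week,
#' evaluate body-weight/glucose predictions against the simulated
#' observations, and characterize the signature interaction network. All
#' artifacts are plain text under `outDir`, and `manifest.json` records the
#' configuration; a rerun with the same config reproduces the run.
#'
#' @param config named list or path to a YAML file; unknown keys are
#'   rejected. Keys: seed, out_dir, stages, design (studyDesign overrides),
#'   models (list of modelSpec arguments), blind_group, pls (folds, cutoff,
#'   max_comp), network (top_fraction, min_score, mean_degree), evaluation.
#' @param outDir output directory (overrides `config$out_dir`).
#' @return invisibly, a list with the run artifacts.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .validateConfig(config)
  if (!is.null(outDir)) cfg$out_dir <- outDir
  if (is.null(cfg$out_dir)) stop("an output directory is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  artifacts <- list()
  ranStages <- character()
  study <- NULL
  lists <- NULL
  trained <- list()
  blindPred <- list()

  runStage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    ranStages <<- c(ranStages, stage)
    res
  }

  runStage("simulate", function() {
    design <- do.call(studyDesign, utils::modifyList(list(seed = cfg$seed),
                                                     cfg$design))
    study <<- generateStudy(design)
    writeFixture(study, file.path(cfg$out_dir, "study"))
  })
  if (is.null(study)) stop("the simulate stage is required in this release")

  runStage("preprocess", function() {
    lists <<- buildMasterLists(study$expression, weeks = c(3L, 6L))
    mlDir <- file.path(cfg$out_dir, "master_lists")
    dir.create(mlDir, showWarnings = FALSE)
    for (g in names(lists)) for (w in names(lists[[g]]))
      writeMasterList(lists[[g]][[w]],
                      file.path(mlDir, sprintf("master_%s_week%s.tsv", g, w)))
  })

  trainGroups <- setdiff(study$design@groups, cfg$blind_group)
  runStage("train", function() {
    for (ms in cfg$models) {
      spec <- do.call(modelSpec, ms)
      fit <- trainSignature(spec, lists, study$phenotypes,
                            groups = trainGroups,
                            controlGroup = study$design@groups[1],
                            cutoff = cfg$pls$cutoff, folds = cfg$pls$folds,
                            seed = cfg$seed)
      trained[[spec@parameter]] <<- fit
      writePLSModel(fit@model,
                    file.path(cfg$out_dir,
                              sprintf("model_%s.json", spec@parameter)))
    }
  })

  runStage("predict", function() {
    bl <- lists[[cfg$blind_group]]
    if (is.null(bl)) stop("no master lists for blind group '",
                          cfg$blind_group, "'")
    for (p in names(trained)) {
      if (!trained[[p]]@worked) next
      blindPred[[p]] <<- predictBlind(trained[[p]], bl)
      utils::write.csv(blindPred[[p]],
                       file.path(cfg$out_dir, sprintf("blind_%s.csv", p)),
                       row.names = FALSE)
    }
  })

  evalReport <- runStage("evaluate", function() {
    phen <- study$phenotypes
    anchors <- function(col, wk, grp)
      phen[[col]][phen$group == grp & phen$week == wk]
    rows <- list()
    for (p in intersect(c("body_weight", "blood_glucose"), names(blindPred))) {
      wk <- .criticalWeekFor(p)
      preds <- blindPred[[p]]$predicted
      names(preds) <- paste0(cfg$blind_group, "@wk", blindPred[[p]]$week)
      obs <- setNames(rep(anchors(p, wk, cfg$blind_group), length(preds)),
                      names(preds))
      rep <- evaluateFormulation(
        preds, obs,
        referenceNd = anchors(p, wk, study$design@groups[1]),
        referenceHfhsd = anchors(p, wk, "HFHSD"),
        newNd = anchors(p, wk, study$design@groups[1]),
        newHfhsd = anchors(p, wk, "HFHSD"))
      rep$parameter <- p
      rows[[p]] <- rep
    }
    out <- do.call(rbind, rows)
    if (!is.null(out))
      utils::write.csv(out, file.path(cfg$out_dir, "evaluation.csv"),
                       row.names = FALSE)
    out
  })

  netStats <- runStage("network", function() {
    geneSets <- lapply(trained, function(t) t@genes)
    geneSets <- geneSets[lengths(geneSets) > 0]
    if (length(geneSets) == 0) stop("no trained signatures to network")
    edgePath <- file.path(cfg$out_dir, "interactions.tsv")
    simulateInteractions(unique(unlist(geneSets)), edgePath,
                         seed = cfg$seed,
                         meanDegree = cfg$network$mean_degree)
    edges <- readInteractions(edgePath, minScore = cfg$network$min_score)
    ig <- buildInteractionGraph(geneSets, edges)
    writeGraphML(ig, file.path(cfg$out_dir, "network.graphml"))
    stats <- moduleStats(ig)
    hubs <- identifyHubs(ig, cfg$network$top_fraction)
    utils::write.csv(stats, file.path(cfg$out_dir, "module_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(hubs, file.path(cfg$out_dir, "hubs.csv"),
                     row.names = FALSE)
    list(stats = stats, hubs = hubs)
  })

  manifest <- list(
    package = "plsig",
    version = as.character(utils::packageVersion("plsig")),
    seed = cfg$seed,
    stages = ranStages,
    config = cfg[c("design", "models", "blind_group", "pls", "network")],
    models = lapply(trained, function(t) list(
      parameter = t@spec@parameter, protocol = t@protocolUsed,
      ncomp = t@model@ncomp, q2 = max(t@diagnostics@q2),
      n_genes = length(t@genes), worked = t@worked)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(study = study, masterLists = lists, trained = trained,
                 blind = blindPred, evaluation = evalReport,
                 network = netStats, manifest = manifest,
                 dir = cfg$out_dir))
}

#' Simulate a STRING-style interaction edge list
#'
#' Attaches a seeded number of interactor proteins to each input gene and
#' sprinkles interactor-interactor edges, writing the TSV dialect
#' [readInteractions()] consumes (protein1, protein2, experimental,
#' combined_score). Purely synthetic: a stand-in network for demonstration
#' and testing, with no biological meaning.
#'
#' @param genes character vector of gene symbols to anchor the network.
#' @param path output TSV path.
#' @param seed integer seed.
#' @param meanDegree average interactors per gene.
#' @return invisibly, the path.
#' @export
simulateInteractions <- function(genes, path, seed = 1L, meanDegree = 4) {
  withSeed(seed, {
    nInt <- max(3L, round(length(genes) * meanDegree / 2))
    interactors <- sprintf("INT%04d", seq_len(nInt))
    from <- character(); to <- character()
    for (g in genes) {
      d <- max(1L, rpois(1, meanDegree))
      to_g <- sample(interactors, min(d, nInt))
      from <- c(from, rep(g, length(to_g))); to <- c(to, to_g)
    }
    # preferential extra edges among interactors give a right-skewed degree
    nExtra <- nInt
    a <- sample(interactors, nExtra, replace = TRUE,
                prob = seq_along(interactors)^-1)
    b <- sample(interactors, nExtra, replace = TRUE)
    ok <- a != b
    from <- c(from, a[ok]); to <- c(to, b[ok])
    df <- data.frame(protein1 = from, protein2 = to,
                     experimental = round(runif(length(from), 100, 900)),
                     combined_score = round(runif(length(from), 400, 999)))
    .writeTable(df, path, sep = "\t")
  })
  invisible(path)
}
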