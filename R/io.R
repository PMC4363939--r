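# Plain-text interchange formats.
#
# Expression TSV per (tissue, group, week): probe_id, gene_symbol,
# rep1..repK, geom_mean, p_value (log2 ratios vs the control diet).
# Phenotype CSV: group, week, then one column per phenotype. Master-list
# TSV: gene_symbol, expression, p_value, class. Design TSV uses "NA" as the
# missing marker. Numbers are written with full precision so that a
# write/read cycle is exact.

.writeTable <- function(df, path, sep) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatNum(out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

.fixtureFileName <- function(tissue, group, week) {
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  sprintf("expr_%s_%s_week%s.tsv", safe(tissue), safe(group), week)
}

#' Write a generated study to disk
#'
#' Emits one expression TSV per fed group and week plus a phenotype CSV,
#' in the formats the readers accept (and that mirror real array exports).
#'
#' @param study the list returned by [generateStudy()].
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
writeFixture <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tissue <- study$design@tissue
  paths <- character()
  for (g in names(study$expression)) {
    for (wk in names(study$expression[[g]])) {
      p <- file.path(dir, .fixtureFileName(tissue, g, wk))
      .writeTable(study$expression[[g]][[wk]], p, sep = "\t")
      paths <- c(paths, p)
    }
  }
  pp <- file.path(dir, "phenotypes.csv")
  .writeTable(study$phenotypes, pp, sep = ",")
  invisible(c(paths, pp))
}

#' Read a probe-level expression table
#'
#' @param path TSV with columns probe_id, gene_symbol, rep1..repK,
#'   geom_mean, p_value.
#' @return data.frame in the same layout.
#' @export
readProbeTable <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "gene_symbol", "geom_mean", "p_value")
  if (!all(need %in% names(tab)))
    stop("'", path, "' lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab
}

#' Read a phenotype table
#'
#' @param path CSV with columns group, week, then phenotype columns.
#' @return data.frame, one row per (group, week).
#' @export
readPhenotypeTable <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("group", "week") %in% names(tab)))
    stop("'", path, "' lacks group/week columns")
  tab
}

#' Read a fixture directory back into study form
#'
#' @param dir directory written by [writeFixture()].
#' @param tissue tissue label used in the file names.
#' @return list with `expression` (nested by group then week) and
#'   `phenotypes`.
#' @export
readStudy <- function(dir, tissue = "skeletal") {
  files <- list.files(dir, pattern = "^expr_.*\\.tsv$", full.names = TRUE)
  rx <- "^expr_(.+)_(.+)_week([0-9]+)\\.tsv$"
  expression <- list()
  for (f in files) {
    b <- basename(f)
    grp <- sub(rx, "\\2", b)
    wk <- sub(rx, "\\3", b)
    expression[[grp]][[wk]] <- readProbeTable(f)
  }
  phen <- readPhenotypeTable(file.path(dir, "phenotypes.csv"))
  list(expression = expression, phenotypes = phen)
}

#' Write / read a master list
#'
#' @param x a \linkS4class{MasterList}.
#' @param path TSV path.
#' @return `writeMasterList` the path, invisibly; `readMasterList` a
#'   \linkS4class{MasterList}.
#' @export
writeMasterList <- function(x, path) {
  stopifnot(is(x, "MasterList"))
  .writeTable(x@entries, path, sep = "\t")
}

#' @rdname writeMasterList
#' @param week integer week recorded on the read list.
#' @export
readMasterList <- function(path, week) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("MasterList", week = as.integer(week), entries = tab)
}

#' Serialize / restore a fitted PLS model as JSON
#'
#' @param model a \linkS4class{PLSModel}.
#' @param path JSON file path.
#' @export
writePLSModel <- function(model, path) {
  stopifnot(is(model, "PLSModel"))
  payload <- list(
    ncomp = model@ncomp,
    variables = rownames(model@weights),
    responses = rownames(model@loadingsY),
    weights = model@weights, loadingsX = model@loadingsX,
    loadingsY = model@loadingsY, scores = model@scores,
    coefficients = model@coefficients,
    xCenter = model@xCenter, xScale = model@xScale,
    yCenter = model@yCenter, yScale = model@yScale,
    ssY = model@ssY, fitted = model@fitted)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePLSModel
#' @export
readPLSModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(m, rn = NULL, cn = NULL) {
    m <- as.matrix(m)
    if (!is.null(rn)) rownames(m) <- rn
    m
  }
  vars <- x$variables; resp <- x$responses
  new("PLSModel", ncomp = as.integer(x$ncomp),
      weights = mat(x$weights, vars), loadingsX = mat(x$loadingsX, vars),
      loadingsY = mat(x$loadingsY, resp), scores = mat(x$scores),
      coefficients = mat(x$coefficients, vars),
      xCenter = setNames(as.numeric(x$xCenter), vars),
      xScale = setNames(as.numeric(x$xScale), vars),
      yCenter = setNames(as.numeric(x$yCenter), resp),
      yScale = setNames(as.numeric(x$yScale), resp),
      ssY = as.numeric(x$ssY), fitted = mat(x$fitted))
}
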