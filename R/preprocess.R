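# Noise filtration of probe-level log2-ratio data into per-week master
# lists, and assembly of observation-by-gene design matrices.
#
# A gene is significantly regulated when its log2 ratio exceeds +1
# (up-regulated) or falls below -1 (down-regulated); values in between are
# insignificant. A probe is kept only when all replicates share one
# regulation class; duplicate probes of a gene are resolved to the one with
# the minimum p-value.

#' Classify a log2 ratio into a regulation class
#'
#' @param x finite numeric vector of log2 ratios.
#' @param threshold positive log2 threshold (default 1, i.e. two-fold).
#' @return character vector in {"up", "down", "insignificant"}; the
#'   boundaries are strict ("greater than" / "less than").
#' @export
classifyRegulation <- function(x, threshold = 1) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite log2 ratios")
  stopIfNotScalarFinite(threshold, "threshold")
  if (threshold <= 0) stop("'threshold' must be positive")
  out <- rep("insignificant", length(x))
  out[x > threshold] <- "up"
  out[x < -threshold] <- "down"
  out
}

.replicateCols <- function(table) {
  grep("^rep[0-9]+$", names(table), value = TRUE)
}

#' Keep probes whose replicates agree in regulation class
#'
#' A probe survives when every replicate maps to the same regulation class
#' and (default policy) that class is up or down: the master list is meant
#' to hold only consistently, significantly perturbed genes.
#'
#' @param table probe-level data.frame with rep1..repK columns.
#' @param threshold regulation threshold.
#' @param keepInsignificant also keep probes unanimously insignificant.
#' @return the filtered data.frame.
#' @export
filterConsistent <- function(table, threshold = 1, keepInsignificant = FALSE) {
  repCols <- .replicateCols(table)
  if (length(repCols) == 0) stop("no replicate columns (rep1..repK) found")
  if (nrow(table) == 0) return(table)
  cls <- vapply(repCols, function(cn)
    classifyRegulation(table[[cn]], threshold), character(nrow(table)))
  cls <- matrix(cls, nrow = nrow(table))
  unanimous <- apply(cls, 1, function(r) length(unique(r)) == 1L)
  keep <- unanimous & (keepInsignificant | cls[, 1] != "insignificant")
  table[keep, , drop = FALSE]
}

#' Resolve duplicate probes per gene by minimum p-value
#'
#' Among the probes measuring one gene, exactly the probe with the smallest
#' p-value is retained; its geometric-mean expression becomes the gene's
#' value. Exact p ties go to the lexicographically smallest probe_id.
#'
#' @param table consistency-filtered probe data.frame.
#' @param threshold regulation threshold used to record the gene's class.
#' @return data.frame with columns gene_symbol, expression, p_value, class,
#'   one row per gene, ordered by gene_symbol.
#' @export
dedupProbes <- function(table, threshold = 1) {
  if (nrow(table) == 0)
    return(data.frame(gene_symbol = character(), expression = numeric(),
                      p_value = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  ord <- order(table$gene_symbol, table$p_value, table$probe_id)
  tab <- table[ord, , drop = FALSE]
  first <- !duplicated(tab$gene_symbol)
  kept <- tab[first, , drop = FALSE]
  data.frame(gene_symbol = kept$gene_symbol,
             expression = kept$geom_mean,
             p_value = kept$p_value,
             class = classifyRegulation(kept$geom_mean, threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the master list for one tissue/group/week
#'
#' Composition of [filterConsistent()] then [dedupProbes()]: the
#' non-redundant, noise-free set of significantly regulated genes at one
#' timepoint.
#'
#' @param table probe-level data.frame.
#' @param week integer week the table belongs to.
#' @param threshold regulation threshold.
#' @param keepInsignificant see [filterConsistent()].
#' @return a \linkS4class{MasterList}.
#' @export
buildMasterList <- function(table, week, threshold = 1,
                            keepInsignificant = FALSE) {
  filtered <- filterConsistent(table, threshold, keepInsignificant)
  new("MasterList", week = as.integer(week),
      entries = dedupProbes(filtered, threshold))
}

.responseSpec <- function(parameter, outputWeeks = NULL) {
  defaults <- list(
    body_weight = list(cols = "body_weight", weeks = 15L),
    blood_glucose = list(cols = "blood_glucose", weeks = 12L),
    pro_cytokines = list(cols = PRO_CYTOKINES, weeks = c(9L, 12L)),
    anti_cytokines = list(cols = ANTI_CYTOKINES, weeks = c(9L, 12L)))
  if (!parameter %in% names(defaults))
    stop("unknown parameter '", parameter, "'")
  spec <- defaults[[parameter]]
  if (!is.null(outputWeeks)) spec$weeks <- as.integer(outputWeeks)
  spec
}

#' Assemble a PLS design matrix from master lists and phenotypes
#'
#' Each training group contributes one observation row per input week. The
#' gene columns are the intersection of all contributing master lists
#' (protocol "intersection") or their union with NA where a gene is absent
#' from a week's list (protocol "union"). Control-group rows are all-zero
#' (expression data are log2 ratios against the control diet). Every row of
#' a group carries that group's phenotype value(s) at the critical output
#' week(s) as the response; for cytokine panels the responses are parallel
#' columns, one per cytokine per output week.
#'
#' @param masterLists nested list: `masterLists[[group]][[as.character(week)]]`
#'   is a \linkS4class{MasterList}; required for every non-control training
#'   group at both input weeks.
#' @param phenotypes phenotype data.frame (group, week, phenotype columns).
#' @param parameter one of body_weight, blood_glucose, pro_cytokines,
#'   anti_cytokines.
#' @param protocol "intersection" or "union".
#' @param inputWeeks exactly two early weeks.
#' @param groups training groups; defaults to control + all groups with
#'   master lists.
#' @param controlGroup label of the control diet group (all-zero rows);
#'   NULL to use no control rows.
#' @param outputWeeks override the parameter's default critical week(s).
#' @return a \linkS4class{PLSDesign}.
#' @export
assembleDesign <- function(masterLists, phenotypes, parameter,
                           protocol = c("intersection", "union"),
                           inputWeeks = c(3L, 6L),
                           groups = NULL, controlGroup = "ND",
                           outputWeeks = NULL) {
  protocol <- match.arg(protocol)
  if (length(inputWeeks) != 2L) stop("exactly two input weeks are required")
  inputWeeks <- as.integer(inputWeeks)
  if (is.null(groups))
    groups <- unique(c(controlGroup, names(masterLists)))
  fed <- setdiff(groups, controlGroup)
  wkChr <- as.character(inputWeeks)
  for (g in fed) for (w in wkChr) {
    if (is.null(masterLists[[g]][[w]]))
      stop("missing master list for group '", g, "', week ", w)
  }

  geneSets <- unlist(lapply(fed, function(g) lapply(wkChr, function(w)
    masterLists[[g]][[w]]@entries$gene_symbol)), recursive = FALSE)
  genes <- if (protocol == "intersection") Reduce(intersect, geneSets)
           else sort(unique(unlist(geneSets)))
  if (protocol == "intersection") {
    if (length(genes) == 0)
      stop("no common genes across master lists under the intersection protocol")
    genes <- sort(genes)
  }

  rowInfo <- expand.grid(group = groups, week = inputWeeks,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rowInfo <- rowInfo[order(match(rowInfo$group, groups), rowInfo$week), ,
                     drop = FALSE]
  rownames(rowInfo) <- NULL

  X <- matrix(NA_real_, nrow = nrow(rowInfo), ncol = length(genes),
              dimnames = list(NULL, genes))
  for (i in seq_len(nrow(rowInfo))) {
    g <- rowInfo$group[i]
    if (!is.null(controlGroup) && g == controlGroup) {
      X[i, ] <- 0
    } else {
      e <- masterLists[[g]][[as.character(rowInfo$week[i])]]@entries
      idx <- match(genes, e$gene_symbol)
      X[i, ] <- e$expression[idx]
    }
  }

  spec <- .responseSpec(parameter, outputWeeks)
  respNames <- as.vector(outer(spec$cols, spec$weeks, paste, sep = "@wk"))
  Y <- matrix(NA_real_, nrow = nrow(rowInfo), ncol = length(respNames),
              dimnames = list(NULL, respNames))
  for (i in seq_len(nrow(rowInfo))) {
    g <- rowInfo$group[i]
    for (w in spec$weeks) {
      prow <- phenotypes[phenotypes$group == g & phenotypes$week == w, ,
                         drop = FALSE]
      if (nrow(prow) != 1L)
        stop("need exactly one phenotype row for group '", g, "', week ", w)
      for (cn in spec$cols) {
        Y[i, paste0(cn, "@wk", w)] <- prow[[cn]]
      }
    }
  }

  new("PLSDesign", X = X, Y = Y, rowInfo = rowInfo, protocol = protocol)
}

#' Build master lists for every fed group and input week of a study
#'
#' @param expression nested list of probe tables (as from [generateStudy()]
#'   or [readStudy()]).
#' @param weeks weeks to build lists for (default: all present).
#' @param threshold,keepInsignificant see [buildMasterList()].
#' @return nested list of \linkS4class{MasterList} objects.
#' @export
buildMasterLists <- function(expression, weeks = NULL, threshold = 1,
                             keepInsignificant = FALSE) {
  out <- list()
  for (g in names(expression)) {
    wks <- names(expression[[g]])
    if (!is.null(weeks)) wks <- intersect(wks, as.character(weeks))
    for (w in wks)
      out[[g]][[w]] <- buildMasterList(expression[[g]][[w]], as.integer(w),
                                       threshold, keepInsignificant)
  }
  out
}
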