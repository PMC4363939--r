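# Interaction-network characterization of signature genes.
#
# Edges come from a STRING-export-style TSV restricted to the experimental
# evidence channel. Connectivity statistics follow the NetworkAnalyzer
# conventions: density = 2E/(n(n-1)), average neighbours = 2E/n,
# centralization = [n/(n-2)] * [max_k/(n-1) - density], heterogeneity =
# sqrt(var(k))/mean(k) with the population variance.

#' Read a STRING-style interaction edge list
#'
#' Expects a tab-separated file whose header names at least `protein1`,
#' `protein2` and the requested evidence channel. Edges are undirected:
#' A-B and B-A collapse to one edge (keeping the higher score), self-loops
#' are dropped, and only edges with channel score >= `minScore` survive.
#'
#' @param path edge-list TSV.
#' @param evidenceChannel score column to filter on (default
#'   "experimental": interactions backed by direct experiment).
#' @param minScore minimum channel score to keep an edge (default 1, i.e.
#'   any nonzero evidence on STRING's 0-1000 scale).
#' @return data.frame with columns protein1, protein2, score.
#' @export
readInteractions <- function(path, evidenceChannel = "experimental",
                             minScore = 1) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(lines)))
    return(data.frame(protein1 = character(), protein2 = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("protein1", "protein2", evidenceChannel)
  if (!all(need %in% header))
    stop("edge file lacks columns: ", paste(setdiff(need, header), collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad))
    stop("malformed edge line ", bad[1] + 1L, ": expected ", length(header),
         " fields, got ", lengths(parts)[bad[1]])
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- header
  score <- suppressWarnings(as.numeric(tab[[evidenceChannel]]))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    stop("malformed edge line ", bad + 1L, ": non-numeric '", evidenceChannel,
         "' score")
  }
  keep <- score >= minScore
  a <- tab$protein1[keep]; b <- tab$protein2[keep]; s <- score[keep]
  notLoop <- a != b
  a <- a[notLoop]; b <- b[notLoop]; s <- s[notLoop]
  lo <- pmin(a, b); hi <- pmax(a, b)
  ord <- order(lo, hi, -s)
  key <- paste(lo[ord], hi[ord], sep = "\r")
  first <- !duplicated(key)
  data.frame(protein1 = lo[ord][first], protein2 = hi[ord][first],
             score = s[ord][first], stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the annotated signature interaction graph
#'
#' Nodes are the signature genes of every parameter plus their first
#' neighbours in the edge list; the retained edges are those of the edge
#' list among this node set. Signature genes with no interactions remain as
#' isolated annotated nodes. Each node's annotation is the set of
#' parameters whose signature contains it (genes influencing more than one
#' physiological parameter carry a multi-parameter annotation).
#'
#' @param geneSets named list: parameter -> character vector of signature
#'   genes.
#' @param edges data.frame from [readInteractions()].
#' @return an \linkS4class{InteractionGraph}.
#' @export
buildInteractionGraph <- function(geneSets, edges) {
  if (length(geneSets) == 0 || all(lengths(geneSets) == 0))
    stop("geneSets: need at least one nonempty signature gene set")
  sig <- unique(unlist(geneSets))
  touching <- edges$protein1 %in% sig | edges$protein2 %in% sig
  nbrs <- unique(c(edges$protein1[touching], edges$protein2[touching]))
  nodes <- sort(unique(c(sig, nbrs)))
  keep <- edges$protein1 %in% nodes & edges$protein2 %in% nodes
  g <- igraph::graph_from_data_frame(edges[keep, , drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  ann <- lapply(nodes, function(n)
    names(geneSets)[vapply(geneSets, function(s) n %in% s, logical(1))])
  names(ann) <- nodes
  new("InteractionGraph", graph = g, annotation = ann)
}

.asIgraph <- function(graph) {
  if (is(graph, "InteractionGraph")) graph@graph else graph
}

#' Empirical degree distribution
#'
#' @param graph an \linkS4class{InteractionGraph} or igraph object.
#' @return data.frame with columns k and pk (probabilities summing to 1).
#' @export
degreeDistribution <- function(graph) {
  g <- .asIgraph(graph)
  k <- igraph::degree(g)
  tab <- table(k)
  data.frame(k = as.integer(names(tab)),
             pk = as.vector(tab) / length(k))
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares of log P(k) on log k over positive degrees with
#' nonzero probability, as in the classical log-log check of the scale-free
#' property: P(k) ~ c * k^(-gamma).
#'
#' @param distribution data.frame from [degreeDistribution()], or a graph.
#' @return list with `gamma` (positive for a decaying fit), `c` (intercept
#'   on the natural scale) and `r_squared` of the log-log regression.
#' @export
fitPowerLaw <- function(distribution) {
  if (is(distribution, "InteractionGraph") || is(distribution, "igraph"))
    distribution <- degreeDistribution(distribution)
  d <- distribution[distribution$k >= 1 & distribution$pk > 0, , drop = FALSE]
  if (length(unique(d$k)) < 3)
    stop("cannot fit a power law: fewer than 3 distinct positive degrees")
  fit <- lm(log(pk) ~ log(k), data = d)
  res <- residuals(fit)
  r2 <- 1 - sum(res^2) / sum((log(d$pk) - mean(log(d$pk)))^2)
  list(gamma = -unname(coef(fit)[2]),
       c = exp(unname(coef(fit)[1])),
       r_squared = r2)
}

#' Connectivity statistics of a module
#'
#' @param graph an \linkS4class{InteractionGraph} or igraph object
#'   (typically an induced functional sub-network).
#' @return one-row data.frame: n_nodes, clustering, centralization,
#'   avg_neighbors, density, heterogeneity. Centralization is NA for fewer
#'   than 3 nodes.
#' @export
moduleStats <- function(graph) {
  g <- .asIgraph(graph)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  e <- igraph::ecount(g)
  k <- igraph::degree(g)
  density <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  centralization <- if (n >= 3)
    (n / (n - 2)) * (max(k) / (n - 1) - density) else NA_real_
  heterogeneity <- if (mean(k) > 0)
    sqrt(mean((k - mean(k))^2)) / mean(k) else NA_real_
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  data.frame(n_nodes = n,
             clustering = if (n > 0) mean(cc) else NA_real_,
             centralization = centralization,
             avg_neighbors = 2 * e / n,
             density = density,
             heterogeneity = heterogeneity)
}

#' Extract degree-based hub nodes
#'
#' Takes the max(1, floor(n * topFraction)) highest-degree nodes; ties are
#' broken by degree, then lexicographic node id. A module where every node
#' has the same degree is flagged degenerate via a warning.
#'
#' @param graph an \linkS4class{InteractionGraph} or igraph object.
#' @param topFraction fraction of nodes to take (0 < topFraction < 1).
#' @return data.frame with columns node and degree, ordered by rank.
#' @export
identifyHubs <- function(graph, topFraction = 0.05) {
  stopIfNotScalarFinite(topFraction, "topFraction")
  if (topFraction <= 0 || topFraction >= 1)
    stop("'topFraction' must lie strictly between 0 and 1")
  g <- .asIgraph(graph)
  k <- igraph::degree(g)
  n <- length(k)
  if (n == 0) stop("empty graph")
  nHubs <- max(1L, floor(n * topFraction))
  if (length(unique(k)) == 1L)
    warning("all nodes have equal degree; hub selection is degenerate")
  ord <- order(-k, names(k))
  data.frame(node = names(k)[ord][seq_len(nHubs)],
             degree = unname(k[ord][seq_len(nHubs)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Induced functional sub-network
#'
#' Restricts the interaction graph to the genes carrying a given
#' biological-process label in an annotation table (an offline export of a
#' gene -> process classification).
#'
#' @param graph an \linkS4class{InteractionGraph}.
#' @param annotation data.frame with columns gene_symbol and process_label.
#' @param process process label to select.
#' @return an \linkS4class{InteractionGraph} over the matching nodes.
#' @export
moduleSubgraph <- function(graph, annotation, process) {
  stopifnot(is(graph, "InteractionGraph"))
  genes <- annotation$gene_symbol[annotation$process_label == process]
  nodes <- intersect(igraph::V(graph@graph)$name, genes)
  if (length(nodes) == 0) stop("no graph nodes carry process '", process, "'")
  sg <- igraph::induced_subgraph(graph@graph, nodes)
  new("InteractionGraph", graph = sg,
      annotation = graph@annotation[nodes])
}

#' Write a graph to GraphML
#'
#' @param graph an \linkS4class{InteractionGraph}.
#' @param path output path.
#' @export
writeGraphML <- function(graph, path) {
  g <- .asIgraph(graph)
  if (is(graph, "InteractionGraph")) {
    ann <- vapply(igraph::V(g)$name, function(n)
      paste(graph@annotation[[n]], collapse = ";"), character(1))
    g <- igraph::set_vertex_attr(g, "parameters", value = unname(ann))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
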