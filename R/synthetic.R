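# Synthetic diet-intervention study generator.
#
# Emulates the shape of a five-group, six-timepoint mouse feeding study with
# replicated two-colour arrays reported as log2 ratios against the control
# diet, and a phenotype panel (body weight, blood glucose, 8 pro- and 3
# anti-inflammatory cytokines) with a planted linear gene -> phenotype
# signal, so parameter recovery can be checked against known ground truth.

PRO_CYTOKINES <- c("GM_CSF", "IFNg", "IL_1a", "IL_1b", "IL_6", "MCP1",
                   "TNF_a", "IL_12p70")
ANTI_CYTOKINES <- c("IL_4", "IL_10", "IL_13")
PHENOTYPE_COLS <- c("body_weight", "blood_glucose", PRO_CYTOKINES, ANTI_CYTOKINES)

# Critical weeks: the timepoint where the disease-vs-control difference of a
# phenotype plateaus.
CRITICAL_WEEK <- c(body_weight = 15, blood_glucose = 12, cytokines = 9)

# Control-diet anchor values at the critical week and the control-to-disease
# gap at full severity (phenotype units).
.phenoBaselinePlateau <- c(body_weight = 27.5, blood_glucose = 141,
                           setNames(c(55, 70, 100, 55, 60, 90, 90, 85), PRO_CYTOKINES),
                           setNames(c(40, 60, 65), ANTI_CYTOKINES))
.phenoStart <- c(body_weight = 22, blood_glucose = 135,
                 setNames(c(55, 70, 100, 55, 60, 90, 90, 85), PRO_CYTOKINES),
                 setNames(c(40, 60, 65), ANTI_CYTOKINES))
.phenoGap <- c(body_weight = 10.5, blood_glucose = 29,
               setNames(rep(40, 8), PRO_CYTOKINES),
               setNames(rep(20, 3), ANTI_CYTOKINES))

.defaultSeverity <- c("ND" = 0, "HFHSD" = 1, "KAL-5" = 0.85,
                      "KAL-20" = 0.45, "KAL-75" = 0.15)

.criticalWeekFor <- function(phenotype) {
  if (phenotype %in% c(PRO_CYTOKINES, ANTI_CYTOKINES)) CRITICAL_WEEK[["cytokines"]]
  else CRITICAL_WEEK[[phenotype]]
}

# Saturating approach to the plateau: 0 at week 0, exactly 1 at and beyond
# the critical week.
plateauRamp <- function(week, criticalWeek) {
  s <- (1 - exp(-3 * week / criticalWeek)) / (1 - exp(-3))
  ifelse(week >= criticalWeek, 1, s)
}

#' Construct a study design
#'
#' Defaults describe the emulated study: five diet groups (control, the
#' high-fat/high-sucrose disease group, and three doses of a botanical
#' formulation), weeks 3 to 18 in steps of 3, and three replicate arrays per
#' cell. Severities express how far each group's phenotypes travel toward
#' the full disease state; dose-dependent efficacy makes the high dose the
#' most protective.
#'
#' @param groups group labels; the first is the control diet.
#' @param weeks strictly increasing sampling weeks.
#' @param nReplicates replicate arrays per tissue/group/week.
#' @param nGenes genes per array.
#' @param nSignature planted predictive genes.
#' @param duplicateProbeFraction fraction of genes carried by two probes.
#' @param inconsistentReplicateFraction fraction of probes with mixed
#'   replicate regulation classes.
#' @param noiseSd replicate/biological noise SD in log2 units.
#' @param seed integer seed.
#' @param tissue tissue label.
#' @param groupSeverity named severities in [0,1]; unnamed groups get a
#'   seeded uniform draw, the control group is always 0.
#' @return a validated \linkS4class{StudyDesign}.
#' @export
studyDesign <- function(groups = names(.defaultSeverity),
                        weeks = seq(3L, 18L, by = 3L),
                        nReplicates = 3L,
                        nGenes = 300L,
                        nSignature = 20L,
                        duplicateProbeFraction = 0.1,
                        inconsistentReplicateFraction = 0.1,
                        noiseSd = 0.1,
                        seed = 1L,
                        tissue = "skeletal",
                        groupSeverity = .defaultSeverity) {
  sev <- groupSeverity[intersect(names(groupSeverity), groups)]
  missing <- setdiff(groups, names(sev))
  if (length(missing)) {
    extra <- withSeed(seed + 777L, runif(length(missing)))
    names(extra) <- missing
    sev <- c(sev, extra)
  }
  sev[groups[1L]] <- 0
  sev <- sev[groups]
  new("StudyDesign", groups = groups, weeks = as.integer(weeks),
      nReplicates = as.integer(nReplicates), nGenes = as.integer(nGenes),
      nSignature = as.integer(nSignature),
      duplicateProbeFraction = duplicateProbeFraction,
      inconsistentReplicateFraction = inconsistentReplicateFraction,
      noiseSd = noiseSd, seed = as.integer(seed), tissue = tissue,
      groupSeverity = sev)
}

#' Generate a synthetic study
#'
#' Draws gene-level architecture (planted signature genes with a diet-shared
#' baseline perturbation plus a severity-tracking component; exchangeable
#' perturbations elsewhere), simulates replicated probe tables per fed
#' group and week, and derives phenotypes as the control baseline plus a
#' planted linear function of the realized week-3/6 signature expression,
#' scaled by a ramp that plateaus at each phenotype's critical week.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return list with `expression` (per fed group, per week, a probe-level
#'   data.frame with columns probe_id, gene_symbol, rep1..repK, geom_mean,
#'   p_value), `phenotypes` (one row per group/week), `truth`
#'   (\linkS4class{GroundTruth}) and `design`.
#' @export
generateStudy <- function(design) {
  v <- validObject(design, test = TRUE)
  if (!isTRUE(v)) stop("invalid StudyDesign: ", paste(v, collapse = "; "))
  withSeed(design@seed, .generateStudyImpl(design))
}

.generateStudyImpl <- function(design) {
  groups <- design@groups
  control <- groups[1L]
  fed <- groups[-1L]
  weeks <- design@weeks
  nG <- design@nGenes
  nS <- design@nSignature
  nr <- design@nReplicates
  sdn <- design@noiseSd
  sev <- design@groupSeverity

  genes <- if (nG > 0) sprintf("G%04d", seq_len(nG)) else character()
  sigGenes <- head(genes, nS)

  # per-gene architecture for signature genes
  dirs <- if (nS) sample(c(-1, 1), nS, replace = TRUE) else numeric()
  base <- if (nS) runif(nS, 1.3, 1.8) else numeric()   # diet-shared offset
  amp  <- if (nS) runif(nS, 1.0, 2.0) else numeric()   # severity-tracking

  # planted coefficients: phenotype = baseline + sum_g coef * expression
  coefs <- matrix(0, nrow = nG, ncol = length(PHENOTYPE_COLS),
                  dimnames = list(genes, PHENOTYPE_COLS))
  if (nS) {
    w <- dirs / (nS * (base + amp))
    for (p in PHENOTYPE_COLS) coefs[seq_len(nS), p] <- .phenoGap[[p]] * w
  }

  # true cell means: week-stationary; control is identically zero
  mu <- array(0, dim = c(nG, length(fed), length(weeks)),
              dimnames = list(genes, fed, as.character(weeks)))
  for (gi in seq_along(fed)) {
    s <- sev[[fed[gi]]]
    if (nS) {
      vals <- dirs * (base + amp * s)
      for (wi in seq_along(weeks)) mu[seq_len(nS), gi, wi] <- vals
    }
    if (nG > nS) {
      # exchangeable non-predictive perturbations, independent per cell
      nOther <- nG - nS
      for (wi in seq_along(weeks)) {
        perturbed <- runif(nOther) < 0.3
        vals <- runif(nOther, -0.8, 0.8)
        vals[perturbed] <- sample(c(-1, 1), sum(perturbed), replace = TRUE) *
          runif(sum(perturbed), 1.2, 2.8)
        mu[nS + seq_len(nOther), gi, wi] <- vals
      }
    }
  }
  # biological cell-level noise enters the phenotype linkage
  cellNoise <- array(rnorm(length(mu), sd = sdn), dim = dim(mu),
                     dimnames = dimnames(mu))
  m <- mu + cellNoise

  # probe layout: duplicated genes get a second probe of the same gene
  nDup <- floor(design@duplicateProbeFraction * nG)
  dupGenes <- if (nDup > 0) sample(genes, nDup) else character()
  probeGene <- c(genes, dupGenes)
  probeId <- sprintf("P%05d", seq_along(probeGene))
  nonSigProbes <- which(!(probeGene %in% sigGenes))
  nInc <- floor(design@inconsistentReplicateFraction * length(probeGene))
  nInc <- min(nInc, length(nonSigProbes))
  incProbes <- if (nInc > 0) sample(nonSigProbes, nInc) else integer()

  pvals <- matrix(runif(length(probeGene) * length(fed) * length(weeks),
                        0, 0.05),
                  nrow = length(probeGene))

  expression <- list()
  col <- 0L
  for (g in fed) {
    expression[[g]] <- list()
    for (wk in as.character(weeks)) {
      col <- col + 1L
      if (nG == 0) {
        tab <- data.frame(probe_id = character(), gene_symbol = character())
        for (r in seq_len(nr)) tab[[paste0("rep", r)]] <- numeric()
        tab$geom_mean <- numeric(); tab$p_value <- numeric()
        expression[[g]][[wk]] <- tab
        next
      }
      cellMean <- m[probeGene, g, wk]
      reps <- matrix(rnorm(length(probeGene) * nr, mean = cellMean, sd = sdn),
                     ncol = nr)
      if (length(incProbes)) {
        # unreliable probes: equal-magnitude replicates with one flipped sign
        vm <- pmax(abs(cellMean[incProbes]), 1.5)
        sgn <- ifelse(cellMean[incProbes] >= 0, 1, -1)
        reps[incProbes, ] <- matrix(rnorm(length(incProbes) * nr, sd = sdn),
                                    ncol = nr) + vm * sgn
        reps[incProbes, nr] <- reps[incProbes, nr] - 2 * vm * sgn
      }
      tab <- data.frame(probe_id = probeId, gene_symbol = probeGene,
                        stringsAsFactors = FALSE)
      for (r in seq_len(nr)) tab[[paste0("rep", r)]] <- reps[, r]
      tab$geom_mean <- rowMeans(reps)   # log2 of the geometric-mean ratio
      tab$p_value <- pvals[, col]
      expression[[g]][[wk]] <- tab
    }
  }

  # phenotypes: baseline trajectory + ramp * planted linear disease level
  baseTraj <- sapply(PHENOTYPE_COLS, function(p) {
    wc <- .criticalWeekFor(p)
    .phenoStart[[p]] +
      (.phenoBaselinePlateau[[p]] - .phenoStart[[p]]) * plateauRamp(weeks, wc)
  })
  baseTraj <- matrix(baseTraj, nrow = length(weeks),
                     dimnames = list(as.character(weeks), PHENOTYPE_COLS))

  inWeeks <- as.character(intersect(c(3L, 6L), weeks))
  if (length(inWeeks) == 0) inWeeks <- as.character(weeks[1L])
  level <- matrix(0, nrow = length(groups), ncol = length(PHENOTYPE_COLS),
                  dimnames = list(groups, PHENOTYPE_COLS))
  if (nS > 0) {
    for (g in fed) {
      sub <- m[seq_len(nS), g, inWeeks, drop = FALSE]
      omega <- apply(sub, 1, mean)
      level[g, ] <- colSums(coefs[seq_len(nS), , drop = FALSE] * omega)
    }
  }
  phen <- expand.grid(group = groups, week = weeks, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  for (p in PHENOTYPE_COLS) {
    wc <- .criticalWeekFor(p)
    phen[[p]] <- baseTraj[as.character(phen$week), p] +
      level[phen$group, p] * plateauRamp(phen$week, wc)
  }

  truth <- new("GroundTruth", signatureGenes = sigGenes, coefficients = coefs,
               baseline = data.frame(week = weeks, baseTraj,
                                     check.names = FALSE),
               groupEffects = sev)
  list(expression = expression, phenotypes = phen, truth = truth,
       design = design)
}
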