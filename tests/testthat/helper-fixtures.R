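# Fixtures built in code: planted regression matrices, hand-sized probe
# tables, and STRING-style edge files.

# Planted design-like matrix: 8 rows patterned as 4 severity conditions x 2
# weeks; `nSignal` columns carry a diet-baseline-plus-severity signal, the
# rest are exchangeable noise; y is an exact linear function of the signal
# columns plus the stated noise.
plantedMatrix <- function(n = 8, p = 300, nSignal = 20, noiseSd = 0.1,
                          seed = 1, effectScale = 1) {
  set.seed(seed)
  delta <- rep(c(0, 1, 0.45, 0.15), length.out = n / 2)
  delta <- rep(delta, each = 2)
  d <- sample(c(-1, 1), nSignal, TRUE)
  b <- runif(nSignal, 1.3, 1.8)
  a <- runif(nSignal, 1.0, 2.0)
  Xs <- sapply(seq_len(nSignal), function(j)
    ifelse(delta > 0, d[j] * (b[j] + a[j] * delta) * effectScale, 0) +
      rnorm(n, sd = noiseSd))
  X <- cbind(Xs, matrix(rnorm(n * (p - nSignal)), n))
  colnames(X) <- paste0("g", seq_len(p))
  cf <- d / (nSignal * (b + a))
  y <- 27.5 + 10.5 * as.vector(Xs %*% cf) / effectScale
  list(X = X, y = y, signal = paste0("g", seq_len(nSignal)),
       coef = cf, delta = delta)
}

# Exact one-latent-variable data: X is rank 1, y a noiseless function of
# the latent score, so a one-component PLS model predicts perfectly.
rank1Fixture <- function(n = 8, p = 20, seed = 3) {
  set.seed(seed)
  t0 <- rnorm(n)
  w0 <- rnorm(p)
  X <- outer(t0, w0)
  colnames(X) <- paste0("g", seq_len(p))
  list(X = X, y = 5 + 2 * t0, t0 = t0, w0 = w0)
}

# Ten probes: 4 with mixed replicate classes, and among the 6 consistent
# ones two genes measured by duplicate probe pairs -> 4 master-list genes.
probeFixture <- function() {
  data.frame(
    probe_id = sprintf("P%02d", 1:10),
    gene_symbol = c("GA", "GA", "GB", "GB", "GC", "GD",
                    "GE", "GF", "GG", "GH"),
    rep1 = c(1.5, 1.8, -1.4, -1.2, 2.0, -1.6, 1.4, -1.2, 1.9, 0.3),
    rep2 = c(1.6, 1.7, -1.5, -1.4, 2.1, -1.5, -1.4, 1.2, 0.2, 1.8),
    rep3 = c(1.4, 1.9, -1.3, -1.5, 1.8, -1.7, 1.5, -1.3, 1.7, -1.5),
    geom_mean = c(1.5, 1.8, -1.4, -1.37, 1.97, -1.6, 0.5, -0.43, 1.27, 0.2),
    p_value = c(0.01, 0.04, 0.03, 0.005, 0.02, 0.01, 0.02, 0.03, 0.01, 0.04),
    stringsAsFactors = FALSE)
}

# STRING-export-style edge file.
edgeFixture <- function(path, lines = NULL) {
  if (is.null(lines))
    lines <- c("protein1\tprotein2\texperimental\tcombined_score",
               "A\tB\t500\t900",
               "B\tA\t500\t900",
               "A\tC\t0\t700",
               "C\tD\t300\t800",
               "D\tE\t0\t600")
  writeLines(lines, path)
  path
}

# Hand-built master lists with exact severity-proportional signal genes and
# a few uninformative filler genes; expression has no noise so training
# behaviour is deterministic.
handLists <- function(groups = c("HFHSD", "KAL-20", "KAL-75"),
                      severity = c(HFHSD = 1, `KAL-20` = 0.45,
                                   `KAL-75` = 0.15),
                      sigGenes3 = paste0("A", 1:8),
                      sigGenes6 = paste0("A", 1:8),
                      filler3 = paste0("F", 1:4),
                      filler6 = paste0("F", 1:4),
                      seed = 11) {
  set.seed(seed)
  dirs <- function(gs) setNames(rep_len(c(1, -1), length(gs)), gs)
  amp <- function(gs) setNames(seq(1.0, 2.0, length.out = length(gs)), gs)
  base <- 1.5
  mkList <- function(genes, fillers, sev, week, groupIdx) {
    dg <- dirs(genes); ag <- amp(genes)
    expr <- dg * (base + ag * sev)
    # fillers alternate sign across groups, so they carry no severity signal
    fi <- seq_along(fillers)
    fill <- setNames((-1)^(fi + groupIdx) * (1.3 + 0.2 * fi), fillers)
    e <- data.frame(gene_symbol = c(genes, fillers),
                    expression = c(unname(expr), unname(fill)),
                    p_value = runif(length(genes) + length(fillers), 0, 0.05),
                    stringsAsFactors = FALSE)
    e$class <- ifelse(e$expression > 1, "up", "down")
    new("MasterList", week = as.integer(week), entries = e)
  }
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    out[[g]][["3"]] <- mkList(sigGenes3, filler3, severity[[g]], 3, gi)
    out[[g]][["6"]] <- mkList(sigGenes6, filler6, severity[[g]], 6, gi)
  }
  out
}

# Phenotypes consistent with handLists(): critical-week value linear in
# severity, earlier weeks on the plateau ramp used by the generator.
handPhenotypes <- function(groups = c("ND", "HFHSD", "KAL-20", "KAL-75"),
                           severity = c(ND = 0, HFHSD = 1, `KAL-20` = 0.45,
                                        `KAL-75` = 0.15)) {
  grid <- expand.grid(group = groups, week = c(3L, 6L, 9L, 12L, 15L, 18L),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ramp <- function(w, wc) ifelse(w >= wc, 1,
                                 (1 - exp(-3 * w / wc)) / (1 - exp(-3)))
  sev <- severity[grid$group]
  grid$body_weight <- 27.5 + 10.5 * sev * ramp(grid$week, 15)
  grid$blood_glucose <- 141 + 29 * sev * ramp(grid$week, 12)
  for (cc in c(plsig:::PRO_CYTOKINES))
    grid[[cc]] <- 80 + 40 * sev * ramp(grid$week, 9)
  for (cc in c(plsig:::ANTI_CYTOKINES))
    grid[[cc]] <- 50 + 20 * sev * ramp(grid$week, 9)
  grid
}
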