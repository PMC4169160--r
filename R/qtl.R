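#' Single-marker case/control association scan
#'
#' For every marker, alleles of called genotypes are counted in cases versus
#' controls (two per genotype) and tested for independence with a Pearson
#' chi-squared statistic on the 2x2 table (one degree of freedom, no
#' continuity correction). Family-wise error is controlled by Bonferroni:
#' the per-test threshold is `alpha` divided by the number of testable
#' markers. Markers monomorphic among called, phenotyped samples get an
#' undefined p-value and are never significant.
#'
#' @param gm a [GBSGenotypes-class].
#' @param pheno named binary (0/1) phenotype vector; samples missing from it
#'   (or `NA`) are excluded.
#' @param alpha family-wise significance level.
#' @return `DataFrame` with one row per marker: allele counts
#'   (`caseRef`, `caseAlt`, `ctrlRef`, `ctrlAlt`), `chi2`, `pval`,
#'   `significant`; the per-test threshold is in
#'   `metadata()$bonferroniAlpha` together with `metadata()$nTests`.
#' @export
singleMarkerScan <- function(gm, pheno, alpha = 0.05) {
  use <- intersect(colnames(gm), names(pheno)[!is.na(pheno)])
  if (!length(use)) stop("no phenotyped samples in the genotype matrix")
  ph <- pheno[use]
  if (!all(ph %in% 0:1)) stop("phenotype must be coded 0/1")
  call <- genotypeCalls(gm)[, use, drop = FALSE]
  cs <- call[, ph == 1L, drop = FALSE]
  ct <- call[, ph == 0L, drop = FALSE]
  caseAlt <- rowSums(cs, na.rm = TRUE)
  caseRef <- 2 * rowSums(!is.na(cs)) - caseAlt
  ctrlAlt <- rowSums(ct, na.rm = TRUE)
  ctrlRef <- 2 * rowSums(!is.na(ct)) - ctrlAlt
  n <- caseAlt + caseRef + ctrlAlt + ctrlRef
  rowCase <- caseAlt + caseRef
  rowCtrl <- ctrlAlt + ctrlRef
  colRef <- caseRef + ctrlRef
  colAlt <- caseAlt + ctrlAlt
  denom <- rowCase * rowCtrl * colRef * colAlt
  chi2 <- ifelse(denom > 0,
                 n * (caseRef * ctrlAlt - caseAlt * ctrlRef)^2 / denom,
                 NA_real_)
  pval <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  nTests <- sum(!is.na(pval))
  bonf <- alpha / max(nTests, 1L)
  out <- DataFrame(marker = rownames(call),
                   chrom = as.character(seqnames(rowRanges(gm))),
                   pos = start(rowRanges(gm)),
                   caseRef = unname(caseRef), caseAlt = unname(caseAlt),
                   ctrlRef = unname(ctrlRef), ctrlAlt = unname(ctrlAlt),
                   chi2 = unname(chi2), pval = unname(pval),
                   significant = unname(!is.na(pval) & pval < bonf))
  metadata(out)$bonferroniAlpha <- bonf
  metadata(out)$nTests <- nTests
  out
}

#' Reconstruct parental-transmission probabilities along the map
#'
#' Models the homolog transmitted by one parent as a two-state Markov chain
#' along each linkage group (transition probability between adjacent loci =
#' recombination fraction from the inverse Kosambi of the cM gap) and runs
#' the forward-backward algorithm per offspring, conditioning on the
#' phase-aligned transmissions observed at that parent's informative
#' markers: its backcross-type markers reveal the transmitted homolog
#' directly; homozygous calls at intercross-type markers reveal it too,
#' heterozygous calls are uninformative and are marginalized, as are missing
#' calls. A small emission error `eps` absorbs residual genotyping error.
#'
#' @param map a [GeneticMap-class].
#' @param gm the [GBSGenotypes-class] the map was built from.
#' @param parent which parent's meioses to reconstruct (1 or 2).
#' @param step grid spacing in cM.
#' @param eps per-marker emission error probability.
#' @return list with `parent`, `offspring`, and `groups`: per linkage group
#'   a list (`group`, `posCM` grid, `probs` offspring x positions matrix of
#'   P(homolog 1 transmitted)).
#' @export
genotypeProbs <- function(map, gm, parent = 2L, step = 1, eps = 0.01) {
  tb <- mapTable(map)
  off <- offspringIds(gm)
  hetCfg <- if (parent == 1L) c("ABxAA", "ABxAB") else c("AAxAB", "ABxAB")
  phaseCol <- if (parent == 1L) "phase1" else "phase2"
  groups <- list()
  for (g in sort(unique(tb$group))) {
    sub <- tb[tb$group == g & tb$representative &
              tb$config %in% hetCfg & !is.na(tb[[phaseCol]]), , drop = FALSE]
    span <- max(tb$posCM[tb$group == g])
    grid <- seq(0, span, by = step)
    if (!nrow(sub)) next
    sub <- sub[order(sub$posCM, sub$marker), , drop = FALSE]
    ## observed transmitted homolog per offspring x marker (0/1/NA)
    obs <- transmissionObs(gm, sub$marker,
                           setNames(as.character(sub$config), sub$marker),
                           setNames(sub[[phaseCol]], sub$marker), parent)
    probs <- transmissionFB(obs, sub$posCM, grid, eps)
    rownames(probs) <- off
    groups[[length(groups) + 1L]] <- list(group = g, posCM = grid,
                                          probs = probs)
  }
  list(parent = as.integer(parent), offspring = off, groups = groups)
}

## forward-backward for the two-state transmission chain, vectorized over
## offspring. obs: offspring x markers (0/1/NA); returns offspring x
## length(grid) posterior P(state = 1).
transmissionFB <- function(obs, markerPos, grid, eps) {
  n <- nrow(obs)
  ev <- rbind(data.frame(pos = markerPos, marker = seq_along(markerPos)),
              data.frame(pos = grid, marker = NA_integer_))
  ev <- ev[order(ev$pos, is.na(ev$marker)), ]
  E <- nrow(ev)
  emis1 <- matrix(1, n, E)   # P(obs | state 0) columns interleaved below
  emis0 <- matrix(1, n, E)
  for (e in seq_len(E)) {
    k <- ev$marker[e]
    if (is.na(k)) next
    o <- obs[, k]
    emis0[, e] <- ifelse(is.na(o), 1, ifelse(o == 0L, 1 - eps, eps))
    emis1[, e] <- ifelse(is.na(o), 1, ifelse(o == 1L, 1 - eps, eps))
  }
  r <- kosambiInverse(diff(ev$pos))
  ## forward
  f0 <- matrix(0, n, E); f1 <- matrix(0, n, E)
  f0[, 1L] <- 0.5 * emis0[, 1L]
  f1[, 1L] <- 0.5 * emis1[, 1L]
  if (E > 1L) for (e in 2:E) {
    a0 <- f0[, e - 1L] * (1 - r[e - 1L]) + f1[, e - 1L] * r[e - 1L]
    a1 <- f0[, e - 1L] * r[e - 1L] + f1[, e - 1L] * (1 - r[e - 1L])
    f0[, e] <- a0 * emis0[, e]
    f1[, e] <- a1 * emis1[, e]
    norm <- f0[, e] + f1[, e]
    f0[, e] <- f0[, e] / norm
    f1[, e] <- f1[, e] / norm
  }
  ## backward
  b0 <- matrix(0, n, E); b1 <- matrix(0, n, E)
  b0[, E] <- 1; b1[, E] <- 1
  if (E > 1L) for (e in (E - 1L):1L) {
    t0 <- emis0[, e + 1L] * b0[, e + 1L]
    t1 <- emis1[, e + 1L] * b1[, e + 1L]
    b0[, e] <- (1 - r[e]) * t0 + r[e] * t1
    b1[, e] <- r[e] * t0 + (1 - r[e]) * t1
    norm <- b0[, e] + b1[, e]
    b0[, e] <- b0[, e] / norm
    b1[, e] <- b1[, e] / norm
  }
  post1 <- f1 * b1 / (f0 * b0 + f1 * b1)
  post1[, is.na(ev$marker), drop = FALSE][, order(ev$pos[is.na(ev$marker)]),
                                          drop = FALSE]
}

#' Binary-trait interval mapping with a permutation threshold
#'
#' At every grid position the phenotype is modeled as a two-penetrance
#' Bernoulli mixture over the transmitted parental homolog, weighted by the
#' forward-backward transmission probabilities; penetrances are fitted by
#' EM and the LOD is the log10 likelihood ratio against a single-penetrance
#' null. The genome-wide significance threshold is the (1 - alpha) quantile
#' of the maximum LOD over `nPerm` random permutations of the phenotype. A
#' 2-LOD support interval is reported around the peak.
#'
#' @param probs output of [genotypeProbs()].
#' @param pheno named binary phenotype vector (offspring).
#' @param nPerm number of phenotype permutations (0 skips the threshold).
#' @param seed RNG seed for the permutations.
#' @param alpha genome-wide error rate of the threshold.
#' @param dropLOD support-interval depth below the peak (default 2).
#' @return A [QTLScan-class].
#' @export
intervalScan <- function(probs, pheno, nPerm = 1000L, seed = 1L,
                         alpha = 0.05, dropLOD = 2) {
  off <- intersect(probs$offspring, names(pheno)[!is.na(pheno)])
  y <- as.numeric(pheno[off])
  if (all(y == 0) || all(y == 1)) {
    stop("phenotype is constant; interval mapping needs both classes")
  }
  n <- length(y)
  K <- nPerm + 1L
  Y <- matrix(0, n, K)
  Y[, 1L] <- y
  if (nPerm > 0L) {
    withSeed(seed, {
      for (k in seq_len(nPerm)) Y[, k + 1L] <- y[sample.int(n)]
    })
  }
  groupIds <- vapply(probs$groups, `[[`, numeric(1), "group")
  lodCols <- list()
  posTab <- list()
  for (gi in seq_along(probs$groups)) {
    gr <- probs$groups[[gi]]
    P <- gr$probs[off, , drop = FALSE]
    lodCols[[gi]] <- scanLODBlock(P, Y)       # K x positions
    posTab[[gi]] <- DataFrame(group = gr$group, posCM = gr$posCM)
  }
  lodAll <- do.call(cbind, lodCols)           # K x totalPositions
  pos <- do.call(rbind, posTab)
  realLod <- lodAll[1L, ]
  permMax <- if (nPerm > 0L) apply(lodAll[-1L, , drop = FALSE], 1L, max)
             else numeric()
  threshold <- if (nPerm > 0L)
    unname(stats::quantile(permMax, 1 - alpha)) else numeric()
  peakIdx <- which.max(realLod)
  peak <- DataFrame(group = pos$group[peakIdx], posCM = pos$posCM[peakIdx],
                    lod = realLod[peakIdx])
  inGroup <- which(pos$group == peak$group)
  above <- realLod[inGroup] >= peak$lod - dropLOD
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peakLocal <- match(peakIdx, inGroup)
  runIdx <- which(starts <= peakLocal & ends >= peakLocal & runs$values)
  interval <- DataFrame(group = peak$group,
                        lo = pos$posCM[inGroup[starts[runIdx]]],
                        hi = pos$posCM[inGroup[ends[runIdx]]])
  new("QTLScan",
      scan = DataFrame(group = pos$group, posCM = pos$posCM, lod = realLod),
      threshold = as.numeric(threshold), nPerm = as.integer(nPerm),
      alpha = alpha, parent = probs$parent, peak = peak,
      interval = interval, permMax = as.numeric(permMax))
}

## EM penetrance fit and LOD at each column of P (positions), vectorized
## over the columns of Y (real + permuted phenotypes). Returns K x positions.
scanLODBlock <- function(P, Y, maxit = 30L, tol = 1e-8) {
  n <- nrow(Y); K <- ncol(Y)
  npos <- ncol(P)
  out <- matrix(0, K, npos)
  ybar <- colMeans(Y)
  ll0 <- n * (ybar * log10(pmax(ybar, 1e-300)) +
              (1 - ybar) * log10(pmax(1 - ybar, 1e-300)))
  for (j in seq_len(npos)) {
    p <- P[, j]
    sp <- sum(p); sq <- n - sp
    pi1 <- pmin(pmax(crossprod(Y, p)[, 1L] / max(sp, 1e-12), 1e-6), 1 - 1e-6)
    pi0 <- pmin(pmax(crossprod(Y, 1 - p)[, 1L] / max(sq, 1e-12), 1e-6),
                1 - 1e-6)
    for (it in seq_len(maxit)) {
      B1 <- Y * rep(pi1, each = n) + (1 - Y) * rep(1 - pi1, each = n)
      B0 <- Y * rep(pi0, each = n) + (1 - Y) * rep(1 - pi0, each = n)
      num <- p * B1
      den <- num + (1 - p) * B0
      G <- num / den
      sg <- colSums(G)
      pi1New <- pmin(pmax(colSums(G * Y) / pmax(sg, 1e-12), 1e-6), 1 - 1e-6)
      pi0New <- pmin(pmax(colSums((1 - G) * Y) / pmax(n - sg, 1e-12), 1e-6),
                     1 - 1e-6)
      delta <- max(abs(pi1New - pi1), abs(pi0New - pi0))
      pi1 <- pi1New; pi0 <- pi0New
      if (delta < tol) break
    }
    B1 <- Y * rep(pi1, each = n) + (1 - Y) * rep(1 - pi1, each = n)
    B0 <- Y * rep(pi0, each = n) + (1 - Y) * rep(1 - pi0, each = n)
    ll1 <- colSums(log10(pmax(p * B1 + (1 - p) * B0, 1e-300)))
    out[, j] <- pmax(ll1 - ll0, 0)
  }
  out
}

#' Write scan results as CSV
#'
#' @param scan a [QTLScan-class].
#' @param path output CSV of (group, posCM, lod); threshold, peak and
#'   support interval are included as comment lines.
#' @return `path`, invisibly.
#' @export
writeScan <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(scan@threshold)) {
    writeLines(sprintf("# threshold %.4f (alpha %.2f, %d permutations)",
                       scan@threshold, scan@alpha, scan@nPerm), con)
  }
  if (nrow(scan@peak)) {
    writeLines(sprintf("# peak group %s pos %.2f lod %.4f",
                       scan@peak$group, scan@peak$posCM, scan@peak$lod), con)
  }
  if (nrow(scan@interval)) {
    writeLines(sprintf("# interval %.2f %.2f",
                       scan@interval$lo, scan@interval$hi), con)
  }
  utils::write.csv(as.data.frame(scan@scan), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write association results as CSV
#'
#' @param assoc result of [singleMarkerScan()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeAssociation <- function(assoc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bonferroni_alpha %.6g over %d tests",
                     metadata(assoc)$bonferroniAlpha,
                     metadata(assoc)$nTests), con)
  utils::write.csv(as.data.frame(assoc), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
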