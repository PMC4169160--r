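test_that("duplicated marker rows fall into a common bin", {
  off <- rep(c(0L, 1L), 15)
  call <- rbind(mA = c(1L, 0L, off), mB = c(1L, 0L, off),
                mC = c(1L, 0L, rev(off)))
  gm <- toyGm(call)
  cfg <- configsOf(gm)
  bins <- binCosegregating(gm, cfg, minOverlap = 10L)
  expect_equal(bins$bin[1], bins$bin[2])
  expect_false(bins$bin[3] == bins$bin[1])
  expect_equal(sum(bins$representative), 2)
})

test_that("distinct vectors give singleton bins", {
  set.seed(3)
  call <- cbind(1L, 0L, matrix(sample(0:1, 5 * 40, replace = TRUE), 5))
  rownames(call) <- paste0("m", 1:5)
  gm <- toyGm(call)
  bins <- binCosegregating(gm, configsOf(gm), minOverlap = 10L)
  expect_equal(length(unique(bins$bin)), 5)
  expect_true(all(bins$representative))
})

test_that("binning matches a brute-force greedy partition on a toy set", {
  set.seed(21)
  nOff <- 30
  base <- sample(0:1, nOff, replace = TRUE)
  v2 <- base; v2[is.na(v2)] <- 0L
  v3 <- base; v3[4] <- NA                 # compatible with base
  v4 <- 1L - base                         # incompatible
  v5 <- base; v5[1:15] <- NA              # too little overlap (15 < 20)
  v6 <- sample(0:1, nOff, replace = TRUE)
  call <- rbind(m1 = c(1L, 0L, base), m2 = c(1L, 0L, v2),
                m3 = c(1L, 0L, v3), m4 = c(1L, 0L, v4),
                m5 = c(1L, 0L, v5), m6 = c(1L, 0L, v6))
  gm <- toyGm(call)
  cfg <- configsOf(gm)
  bins <- binCosegregating(gm, cfg, minOverlap = 20L)
  ## oracle: sequential greedy complete-linkage with the same rule
  oc <- call[, -(1:2)]
  compat <- function(a, b) {
    both <- !is.na(oc[a, ]) & !is.na(oc[b, ])
    sum(both) >= 20 && all(oc[a, both] == oc[b, both])
  }
  oracle <- integer(6); oracle[1] <- 1L; nb <- 1L
  members <- list(1L)
  for (i in 2:6) {
    placed <- FALSE
    for (b in seq_len(nb)) {
      if (all(vapply(members[[b]], function(m) compat(i, m), logical(1)))) {
        oracle[i] <- b; members[[b]] <- c(members[[b]], i); placed <- TRUE
        break
      }
    }
    if (!placed) {
      nb <- nb + 1L; oracle[i] <- nb; members[[nb]] <- i
    }
  }
  expect_equal(bins$bin, oracle)
})

test_that("grouping is a transitive closure over passing edges", {
  mk <- c("a", "b", "c", "d")
  r <- matrix(0.5, 4, 4, dimnames = list(mk, mk))
  lod <- matrix(0, 4, 4, dimnames = list(mk, mk))
  r["a", "b"] <- r["b", "a"] <- 0.1; lod["a", "b"] <- lod["b", "a"] <- 10
  r["b", "c"] <- r["c", "b"] <- 0.1; lod["b", "c"] <- lod["c", "b"] <- 8
  ## a-c fails on its own, d fails everywhere
  tp <- list(markers = mk, r = r, lod = lod)
  grp <- groupMarkers(tp, lodMin = 6, rMax = 0.35)
  expect_equal(sort(grp$groups[[1]]), c("a", "b", "c"))
  expect_equal(grp$unlinked, "d")
  ## no passing edge at all
  grp0 <- groupMarkers(tp, lodMin = 99, rMax = 0.35)
  expect_length(grp0$groups, 0)
  expect_setequal(grp0$unlinked, mk)
})

test_that("simulated chromosomes group into themselves", {
  sc <- quickScenario(nOffspring = 200, nChromosomes = 5,
                      markersPerChrom = 30, seed = 71)
  seg <- segregationAnalysis(filterMarkers(maskByDepth(sc$gm, 6), 0.2, 0.2))
  keep <- seg$table$marker[seg$table$decision == "KEEP" &
                           seg$table$config %in%
                             c("ABxAA", "AAxAB", "ABxAB")]
  cfg <- setNames(as.character(seg$table$config), seg$table$marker)
  bins <- binCosegregating(seg$genotypes, cfg[keep], markers = keep)
  reps <- bins$marker[bins$representative]
  tp <- twoPointTable(seg$genotypes, cfg[reps], markers = reps)
  grp <- groupMarkers(tp)
  expect_equal(length(grp$groups), 5)
  for (g in grp$groups) {
    expect_equal(length(unique(sub("_.*", "", g))), 1)
  }
})

test_that("small groups attain the exhaustive SARF minimum", {
  ## single-parent backcross markers: every pair shares the full 87
  ## meioses, so an 8-marker order is statistically resolvable
  p <- simParams(nOffspring = 87, nChromosomes = 1, chromLengthCM = 60,
                 markersPerChrom = 8, qtlChrom = 1,
                 configProbs = c(ABxAA = 1, AAxAB = 0, ABxAB = 0,
                                 UNINFORMATIVE = 0),
                 depthMean = 30, depthSize = 10, parentScale = 4,
                 scaleSdlog = 0.3, seed = 73)
  truth <- simulatePopulation(p)
  gm <- simulateGenotypes(truth)
  seg <- segregationAnalysis(filterMarkers(maskByDepth(gm, 6), 0.2, 0.2))
  keep <- seg$table$marker[seg$table$decision == "KEEP" &
                           seg$table$config %in%
                             c("ABxAA", "AAxAB", "ABxAB")]
  cfg <- setNames(as.character(seg$table$config), seg$table$marker)
  tp <- twoPointTable(seg$genotypes, cfg, markers = keep)
  ord <- orderGroup(tp, keep)
  ## oracle: enumerate every permutation independently
  d <- gbsCrossMap:::completedDistances(tp, keep)
  n <- length(keep)
  allPerms <- gbsCrossMap:::permutations(n)
  best <- Inf
  for (i in seq_len(nrow(allPerms))) {
    o <- keep[allPerms[i, ]]
    best <- min(best, sum(d[cbind(o[-n], o[-1])]))
  }
  expect_equal(ord$sarf, best, tolerance = 1e-9)
  ## and the order matches the simulated chromosome up to reversal and
  ## swaps of markers too close to resolve (< 2 cM)
  tpos <- truth@map$posCM[match(ord$markers, truth@map$marker)]
  if (sum(diff(tpos) > 0) < length(tpos) / 2) tpos <- rev(tpos)
  bad <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (tpos[i] > tpos[j] && tpos[i] - tpos[j] >= 2) bad <- bad + 1
  }
  expect_equal(bad, 0)
})

test_that("adjacent recombination converts to Kosambi steps", {
  n <- 200
  off1 <- rep(c(0L, 1L), n / 2)
  off2 <- off1; off2[seq_len(40)] <- 1L - off2[seq_len(40)]  # r = 0.2
  call <- rbind(mA = c(1L, 0L, off1), mB = c(1L, 0L, off1),
                mC = c(1L, 0L, off2))
  gm <- toyGm(call)
  cfg <- configsOf(gm)
  tp <- twoPointTable(gm, cfg)
  ord <- orderGroup(tp, c("mA", "mB", "mC"))
  expect_equal(max(ord$posCM) - min(ord$posCM), kosambi(0.2),
               tolerance = 1e-6)
  expect_equal(sort(diff(sort(ord$posCM))), c(0, kosambi(0.2)),
               tolerance = 1e-6)
})

test_that("misfit dropping is the identity when nothing inflates", {
  ## genuinely clean data: no miscalls, saturating depth
  sc <- quickScenario(nOffspring = 100, nChromosomes = 1,
                      markersPerChrom = 25, seed = 79,
                      errorRate = 0, depthMean = 50, depthSize = 50,
                      scaleSdlog = 0.2)
  seg <- segregationAnalysis(filterMarkers(maskByDepth(sc$gm, 6), 0.2, 0.2))
  keep <- seg$table$marker[seg$table$decision == "KEEP" &
                           seg$table$config %in%
                             c("ABxAA", "AAxAB", "ABxAB")]
  cfg <- setNames(as.character(seg$table$config), seg$table$marker)
  tp <- twoPointTable(seg$genotypes, cfg, markers = keep)
  ord <- orderGroup(tp, keep)
  kept <- dropMisfits(ord, tp, inflationLimit = 10)
  expect_length(kept$dropped, 0)
  expect_identical(dropMisfits(ord, tp, Inf)$markers, ord$markers)
})

test_that("an error-riddled marker is dropped first", {
  set.seed(83)
  n <- 100
  base <- cumsum(c(0L, rbinom(5, 1, 0.05))) %% 2L  # nearby haplotypes
  offs <- t(replicate(n, {
    s <- rbinom(1, 1, 0.5)
    flips <- cumsum(rbinom(6, 1, 0.03))
    (s + flips) %% 2L
  }))
  bad <- offs[, 3]
  err <- sample(n, 20)
  bad[err] <- 1L - bad[err]            # 20% genotyping error
  call <- rbind(c(1L, 0L, offs[, 1]), c(1L, 0L, offs[, 2]),
                c(1L, 0L, bad), c(1L, 0L, offs[, 4]),
                c(1L, 0L, offs[, 5]), c(1L, 0L, offs[, 6]))
  rownames(call) <- paste0("m", 1:6)
  gm <- toyGm(call)
  cfg <- configsOf(gm)
  tp <- twoPointTable(gm, cfg)
  ord <- orderGroup(tp, rownames(call))
  res <- dropMisfits(ord, tp, inflationLimit = 15)
  expect_true("m3" %in% res$dropped)
  expect_equal(res$dropped[1], "m3")
})

test_that("genetic map construction places bin members at their representative", {
  sc <- quickScenario(nOffspring = 90, nChromosomes = 2,
                      markersPerChrom = 15, seed = 89)
  seg <- segregationAnalysis(filterMarkers(maskByDepth(sc$gm, 6), 0.2, 0.2))
  map <- buildGeneticMap(seg$genotypes, seg)
  tb <- mapTable(map)
  expect_s4_class(map, "GeneticMap")
  for (b in unique(tb$bin)) {
    sub <- tb[tb$bin == b, ]
    expect_equal(length(unique(sub$posCM)), 1)
    expect_equal(sum(sub$representative), 1)
  }
  ## every kept informative marker is mapped, unlinked, or dropped
  keep <- seg$table$marker[seg$table$decision == "KEEP" &
                           seg$table$config %in%
                             c("ABxAA", "AAxAB", "ABxAB")]
  expect_setequal(keep, c(tb$marker, unlinkedMarkers(map), map@dropped))
})
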