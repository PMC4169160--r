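test_that("perfectly cosegregating backcross markers give the closed-form LOD", {
  gm <- bcPairGm(nRec = 0, nTot = 86)
  cfg <- configsOf(gm)
  res <- twoPoint(gm, cfg, "mA", "mB")
  expect_equal(res$class, "BCp1xBCp1")
  expect_lt(res$r, 1e-6)
  expect_equal(res$lod, 86 * log10(2), tolerance = 1e-6)
})

test_that("a known recombinant count recovers r and the Pearson-style LOD", {
  n <- 200; k <- 30
  gm <- bcPairGm(nRec = k, nTot = n)
  cfg <- configsOf(gm)
  res <- twoPoint(gm, cfg, "mA", "mB")
  r <- k / n
  expect_equal(res$r, r, tolerance = 1e-6)
  lodExp <- (n - k) * log10(2 * (1 - r)) + k * log10(2 * r)
  expect_equal(res$lod, lodExp, tolerance = 1e-6)
})

test_that("backcross markers from different parents are uninformative", {
  call <- rbind(mA = c(1L, 0L, rep(c(0L, 1L), 20)),
                mB = c(0L, 1L, rep(c(0L, 0L, 1L, 1L), 10)))
  gm <- toyGm(call)
  cfg <- configsOf(gm)
  res <- twoPoint(gm, cfg, "mA", "mB")
  expect_equal(res$class, "BCp1xBCp2")
  expect_equal(res$lod, 0)
})

test_that("EM estimates agree with a fine grid search across pair types", {
  sc <- quickScenario(nOffspring = 120, nChromosomes = 1,
                      markersPerChrom = 14, seed = 51)
  seg <- segregationAnalysis(filterMarkers(maskByDepth(sc$gm, 6), 0.2, 0.2))
  keep <- seg$table$marker[seg$table$decision == "KEEP"]
  cfg <- setNames(as.character(seg$table$config), seg$table$marker)
  classes <- character()
  for (a in seq_len(min(6, length(keep) - 1))) {
    for (b in (a + 1):min(a + 3, length(keep))) {
      em <- twoPoint(seg$genotypes, cfg, keep[a], keep[b])
      if (em$class %in% c("UNINFORMATIVE", "BCp1xBCp2") || is.na(em$r)) next
      gr <- twoPointGrid(seg$genotypes, cfg, keep[a], keep[b])
      expect_lt(abs(em$r - gr$r), 1e-4 + 5e-5)
      expect_lt(abs(em$lod - gr$lod), 1e-3)
      classes <- c(classes, em$class)
    }
  }
  expect_gt(length(classes), 3)
})

test_that("linked simulated markers recover the Haldane r at 20 cM", {
  p <- simParams(nOffspring = 2000, nChromosomes = 1, chromLengthCM = 20,
                 markersPerChrom = 2, qtlChrom = 1,
                 configProbs = c(ABxAA = 1, AAxAB = 0, ABxAB = 0,
                                 UNINFORMATIVE = 0),
                 errorRate = 0, depthMean = 40, depthSize = 30,
                 scaleSdlog = 0, seed = 53)
  truth <- simulatePopulation(p)
  gm <- simulateGenotypes(truth)
  cfg <- configsOf(gm)
  mk <- rownames(gm)
  res <- twoPoint(gm, cfg, mk[1], mk[2])
  rTrue <- haldaneInverse(abs(diff(truth@map$posCM)))
  se <- sqrt(rTrue * (1 - rTrue) / 2000)
  expect_lt(abs(res$r - rTrue), 3 * se)
})

test_that("markers on different chromosomes look unlinked", {
  p <- simParams(nOffspring = 300, nChromosomes = 2, markersPerChrom = 1,
                 qtlChrom = 1, configProbs = c(ABxAA = 1, AAxAB = 0,
                                               ABxAB = 0, UNINFORMATIVE = 0),
                 errorRate = 0, depthMean = 40, depthSize = 30,
                 scaleSdlog = 0, seed = 59)
  gm <- simulateGenotypes(simulatePopulation(p))
  cfg <- configsOf(gm)
  mk <- rownames(gm)
  res <- twoPoint(gm, cfg, mk[1], mk[2])
  expect_gt(res$r, 0.4)
  expect_lt(res$lod, 2)
})

test_that("phase switching is an involution that flips apparent linkage", {
  n <- 100
  off1 <- rep(c(0L, 1L), n / 2)
  off2 <- 1L - off1                 # opposite phase: raw r would be ~1
  off2[1:5] <- off1[1:5]
  call <- rbind(mA = c(1L, 0L, off1), mB = c(1L, 0L, off2))
  gm <- toyGm(call)
  cfg <- configsOf(gm)
  before <- twoPoint(gm, cfg, "mA", "mB")
  expect_equal(before$phase1, 1)    # repulsion detected
  expect_equal(before$r, 0.05, tolerance = 1e-6)
  sw <- switchPhase(gm, "mB")
  after <- twoPoint(sw, cfg, "mA", "mB")
  expect_equal(after$phase1, 0)
  expect_equal(after$r, before$r, tolerance = 1e-9)
  expect_equal(after$lod, before$lod, tolerance = 1e-9)
  ## involution
  expect_identical(genotypeCalls(switchPhase(sw, "mB")), genotypeCalls(gm))
  icRow <- toyGm(rbind(mC = c(1L, 1L, sample(c(0:2), 20, TRUE))))
  expect_identical(
    genotypeCalls(switchPhase(switchPhase(icRow, "mC"), "mC")),
    genotypeCalls(icRow))
})

test_that("the pair table matches single-pair estimates", {
  sc <- quickScenario(nOffspring = 80, nChromosomes = 1,
                      markersPerChrom = 10, seed = 61)
  seg <- segregationAnalysis(filterMarkers(maskByDepth(sc$gm, 6), 0.2, 0.2))
  keep <- seg$table$marker[seg$table$decision == "KEEP"]
  cfg <- setNames(as.character(seg$table$config), seg$table$marker)
  tp <- twoPointTable(seg$genotypes, cfg, markers = keep)
  for (a in 1:3) for (b in (a + 1):4) {
    single <- twoPoint(seg$genotypes, cfg, keep[a], keep[b])
    if (single$class %in% c("UNINFORMATIVE", "BCp1xBCp2")) {
      expect_true(is.na(tp$r[keep[a], keep[b]]))
    } else {
      expect_equal(tp$r[keep[a], keep[b]], single$r, tolerance = 1e-6)
      expect_equal(tp$lod[keep[a], keep[b]], single$lod, tolerance = 1e-5)
    }
  }
  ## symmetry and bounds
  expect_true(all(tp$r == t(tp$r), na.rm = TRUE))
  expect_true(all(tp$r >= 0 & tp$r <= 0.5, na.rm = TRUE))
  expect_true(all(tp$lod >= 0))
})

test_that("too few jointly called offspring yields an undefined estimate", {
  call <- rbind(mA = c(1L, 0L, 1L, NA, NA, NA),
                mB = c(1L, 0L, NA, 0L, 1L, NA))
  gm <- toyGm(call)
  cfg <- configsOf(gm)
  res <- twoPoint(gm, cfg, "mA", "mB")
  expect_equal(res$lod, 0)
  expect_true(is.na(res$r))
})
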