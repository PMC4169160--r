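test_that("allele association matches hand-computed Pearson chi-squared", {
  ## 40 samples: 20 cases all hom-alt, 20 controls half/half
  call <- matrix(c(rep(2L, 20), rep(0L, 10), rep(2L, 10)), nrow = 1)
  rownames(call) <- "m1"
  gm <- toyGm(call, roles = rep("offspring", 40))
  pheno <- setNames(c(rep(1L, 20), rep(0L, 20)), colnames(gm))
  res <- singleMarkerScan(gm, pheno, alpha = 0.05)
  ## 2x2 table: cases (ref 0, alt 40), controls (ref 20, alt 20)
  o <- matrix(c(0, 40, 20, 20), 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi2 <- sum((o - e)^2 / e)
  expect_equal(res$chi2[1], chi2, tolerance = 1e-12)
  expect_equal(res$pval[1], pchisq(chi2, 1, lower.tail = FALSE))
})

test_that("balanced allele tables give chi-squared zero", {
  call <- matrix(rep(1L, 40), nrow = 1)   # all het: 50/50 in both groups
  gm <- toyGm(call, roles = rep("offspring", 40))
  pheno <- setNames(rep(c(0L, 1L), 20), colnames(gm))
  res <- singleMarkerScan(gm, pheno)
  expect_equal(res$chi2[1], 0)
  expect_equal(res$pval[1], 1)
  expect_false(res$significant[1])
})

test_that("monomorphic markers are untestable and never significant", {
  call <- rbind(m1 = rep(0L, 30), m2 = c(rep(0L, 15), rep(1L, 15)))
  gm <- toyGm(call, roles = rep("offspring", 30))
  pheno <- setNames(rep(c(0L, 1L), 15), colnames(gm))
  res <- singleMarkerScan(gm, pheno)
  expect_true(is.na(res$pval[1]))
  expect_false(res$significant[1])
  expect_equal(metadata(res)$nTests, 1)   # only the polymorphic marker
})

test_that("the Bonferroni threshold divides alpha by the test count", {
  set.seed(14)
  nm <- 500
  call <- matrix(sample(0:2, nm * 40, replace = TRUE), nm, 40)
  gm <- toyGm(call, roles = rep("offspring", 40))
  pheno <- setNames(rep(c(0L, 1L), 20), colnames(gm))
  res <- singleMarkerScan(gm, pheno, alpha = 0.05)
  expect_equal(metadata(res)$bonferroniAlpha,
               0.05 / metadata(res)$nTests)
  expect_identical(as.vector(res$significant),
                   as.vector(!is.na(res$pval) &
                             res$pval < metadata(res)$bonferroniAlpha))
})

## a hand-built two-group map over one parent's backcross markers
handMap <- function(nOff, markerStates, posCM, group = 1L) {
  m <- nrow(markerStates)
  call <- rbind(matrix(0L, 0, nOff + 2))
  rows <- lapply(seq_len(m), function(k) c(0L, 1L, markerStates[k, ]))
  call <- do.call(rbind, rows)
  rownames(call) <- sprintf("g%d_m%d", group, seq_len(m))
  gm <- toyGm(call)
  tb <- DataFrame(marker = rownames(call), group = group,
                  bin = seq_len(m) + 1000L * group, representative = TRUE,
                  posCM = posCM, phase1 = NA_integer_, phase2 = 0L,
                  config = "AAxAB")
  list(gm = gm, tb = tb)
}

test_that("transmission probabilities are exact at informative markers", {
  set.seed(15)
  nOff <- 30
  states <- matrix(rbinom(3 * nOff, 1, 0.5), 3, byrow = FALSE)
  hm <- handMap(nOff, states, posCM = c(0, 10, 20))
  map <- new("GeneticMap", table = hm$tb, unlinked = character(),
             dropped = character())
  pr <- genotypeProbs(map, hm$gm, parent = 2L, step = 10, eps = 0)
  P <- pr$groups[[1]]$probs
  ## grid points 0, 10, 20 coincide with the markers
  expect_equal(unname(P[, 1]), as.numeric(states[1, ]), tolerance = 1e-9)
  expect_equal(unname(P[, 2]), as.numeric(states[2, ]), tolerance = 1e-9)
  expect_equal(unname(P[, 3]), as.numeric(states[3, ]), tolerance = 1e-9)
})

test_that("conflicting flanks give symmetric midpoint probabilities", {
  nOff <- 4
  states <- rbind(c(0L, 0L, 1L, 1L), c(1L, 0L, 0L, 1L))
  hm <- handMap(nOff, states, posCM = c(0, 20))
  map <- new("GeneticMap", table = hm$tb, unlinked = character(),
             dropped = character())
  pr <- genotypeProbs(map, hm$gm, parent = 2L, step = 10, eps = 0)
  P <- pr$groups[[1]]$probs
  mid <- P[, 2]
  expect_equal(unname(mid[1]), 0.5)   # flanks 0 then 1
  expect_equal(unname(mid[3]), 0.5)   # flanks 1 then 0
  expect_lt(mid[2], 0.1)              # flanks agree on 0
  expect_gt(mid[4], 0.9)              # flanks agree on 1
})

test_that("forward-backward equals exhaustive path enumeration", {
  nOff <- 6
  set.seed(16)
  states <- matrix(rbinom(4 * nOff, 1, 0.5), 4)
  states[2, 3] <- NA                      # one missing observation
  hm <- handMap(nOff, states, posCM = c(0, 7, 13, 26))
  map <- new("GeneticMap", table = hm$tb, unlinked = character(),
             dropped = character())
  hm$gm <- local({                        # force the missing cell
    call <- genotypeCalls(hm$gm)
    call["g1_m2", 2 + 3] <- NA
    SummarizedExperiment::assay(hm$gm, "call") <- call
    hm$gm
  })
  eps <- 0.02
  queryPos <- 10
  pr <- genotypeProbs(map, hm$gm, parent = 2L, step = queryPos, eps = eps)
  P <- pr$groups[[1]]$probs
  ## oracle: enumerate hidden states at every chain node the model uses
  ## (markers plus the whole query grid)
  mpos <- c(0, 7, 13, 26)
  allPos <- sort(unique(c(mpos, seq(0, max(mpos), by = queryPos))))
  qIdx <- match(queryPos, allPos)
  obsAt <- function(i, k) {
    x <- genotypeCalls(hm$gm)[sprintf("g1_m%d", k), 2 + i]
    if (is.na(x)) NA_integer_ else as.integer(x == 2L) * 0L + x  # 0/1 already
  }
  for (i in seq_len(nOff)) {
    tot <- 0; tot1 <- 0
    grid <- expand.grid(rep(list(0:1), length(allPos)))
    for (row in seq_len(nrow(grid))) {
      s <- as.integer(grid[row, ])
      p <- 0.5
      for (k in 2:length(allPos)) {
        r <- kosambiInverse(allPos[k] - allPos[k - 1])
        p <- p * ifelse(s[k] == s[k - 1], 1 - r, r)
      }
      for (k in seq_along(mpos)) {
        o <- obsAt(i, k)
        if (is.na(o)) next
        sk <- s[match(mpos[k], allPos)]
        p <- p * ifelse(o == sk, 1 - eps, eps)
      }
      tot <- tot + p
      if (s[qIdx] == 1L) tot1 <- tot1 + p
    }
    expect_equal(unname(P[i, 2]), tot1 / tot, tolerance = 1e-9)
  }
})

test_that("a deterministic marker phenotype gives the closed-form LOD", {
  nOff <- 80
  states <- matrix(rep(c(0L, 1L), each = nOff / 2), 1)
  hm <- handMap(nOff, states, posCM = 0)
  map <- new("GeneticMap", table = hm$tb, unlinked = character(),
             dropped = character())
  pr <- genotypeProbs(map, hm$gm, parent = 2L, step = 1, eps = 0)
  pheno <- setNames(c(0L, 1L, as.integer(states[1, ])),
                    colnames(hm$gm))
  sc <- intervalScan(pr, pheno, nPerm = 0)
  expect_equal(qtlPeak(sc)$lod, nOff * log10(2), tolerance = 1e-4)
  expect_true(all(scanTable(sc)$lod >= 0))
})

test_that("constant phenotypes abort the scan", {
  nOff <- 20
  states <- matrix(rbinom(nOff, 1, 0.5), 1)
  hm <- handMap(nOff, states, posCM = 0)
  map <- new("GeneticMap", table = hm$tb, unlinked = character(),
             dropped = character())
  pr <- genotypeProbs(map, hm$gm, parent = 2L)
  pheno <- setNames(rep(1L, nOff + 2), colnames(hm$gm))
  expect_error(intervalScan(pr, pheno), "constant")
})

test_that("the permutation threshold is invariant to label swapping", {
  set.seed(18)
  nOff <- 40
  states <- matrix(rbinom(3 * nOff, 1, 0.5), 3)
  hm <- handMap(nOff, states, posCM = c(0, 12, 30))
  map <- new("GeneticMap", table = hm$tb, unlinked = character(),
             dropped = character())
  pr <- genotypeProbs(map, hm$gm, parent = 2L, step = 5)
  pheno <- setNames(c(0L, 1L, rbinom(nOff, 1, 0.5)), colnames(hm$gm))
  s1 <- intervalScan(pr, pheno, nPerm = 50, seed = 7)
  s2 <- intervalScan(pr, setNames(1L - pheno, names(pheno)),
                     nPerm = 50, seed = 7)
  expect_equal(s1@permMax, s2@permMax, tolerance = 1e-9)
  expect_equal(lodThreshold(s1), lodThreshold(s2), tolerance = 1e-9)
  ## support interval contains the peak
  expect_gte(qtlPeak(s1)$posCM, supportInterval(s1)$lo)
  expect_lte(qtlPeak(s1)$posCM, supportInterval(s1)$hi)
})
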