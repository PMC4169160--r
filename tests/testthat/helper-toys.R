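## Construct a GBSGenotypes object from a bare call matrix (markers x
## samples). Depth defaults to 10 where called, 0 where missing, so no
## depth filter interferes unless a test sets depths explicitly.
toyGm <- function(call, depth = NULL, roles = NULL, chrom = NULL,
                  pos = NULL) {
  call <- as.matrix(call)
  m <- nrow(call)
  ns <- ncol(call)
  if (is.null(rownames(call))) rownames(call) <- sprintf("m%02d", seq_len(m))
  if (is.null(colnames(call))) {
    colnames(call) <- c("P1", "P2", sprintf("O%02d", seq_len(ns - 2L)))
  }
  if (is.null(depth)) {
    depth <- matrix(10L, m, ns)
    depth[is.na(call)] <- 0L
  }
  if (is.null(roles)) roles <- c("parent1", "parent2",
                                 rep("offspring", ns - 2L))
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  GBSGenotypes(call, depth, chrom = chrom, pos = pos,
               ref = rep("A", m), alt = rep("G", m), roles = roles)
}

## A BC-type (het x hom-ref) marker pair with an exact number of
## recombinant offspring, plus both parents in front.
bcPairGm <- function(nRec, nTot) {
  off1 <- c(rep(1L, nTot / 2), rep(0L, nTot / 2))
  off2 <- off1
  flip <- seq_len(nRec)
  off2[flip] <- 1L - off2[flip]
  call <- rbind(mA = c(1L, 0L, off1), mB = c(1L, 0L, off2))
  toyGm(call)
}

## Small simulated scenario with well-covered genotypes, for pipeline-level
## tests; returns list(truth, gm).
quickScenario <- function(nOffspring = 87, nChromosomes = 2,
                          markersPerChrom = 20, seed = 1, ...) {
  args <- utils::modifyList(
    list(nOffspring = nOffspring, nChromosomes = nChromosomes,
         markersPerChrom = markersPerChrom, qtlChrom = 1L,
         depthMean = 25, depthSize = 5, parentScale = 5,
         scaleSdlog = 0.5, seed = seed),
    list(...))
  p <- do.call(simParams, args)
  truth <- simulatePopulation(p)
  list(truth = truth, gm = simulateGenotypes(truth))
}

## configs named by marker for a GBSGenotypes object
configsOf <- function(gm) {
  cls <- classifyMarkers(gm)
  setNames(as.character(cls$config), cls$marker)
}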