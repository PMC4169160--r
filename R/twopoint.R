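## Two-point recombination-fraction estimation for a double pseudo-testcross.
##
## Machinery: offspring genotypes at every informative marker are first put
## on a canonical scale where the homozygous parent (of a backcross-type
## marker) carries the reference allele, so a marker's observable classes are
## alt-dosages {0,1} (backcross type) or {0,1,2} (intercross type). For a
## marker pair, the joint class distribution given r and the linkage phase(s)
## is obtained by enumerating each parent's hidden meiosis (homolog choice at
## the first locus, recombination indicator between loci); collecting terms
## gives P(c | r) = sum_K w[c,K] r^K (1-r)^(Kmax-K) with Kmax the number of
## heterozygous parents. EM treats the recombination indicators as the
## hidden data; meioses uninformative for r are enumerated too, which leaves
## the observed likelihood untouched and the EM fixed point at the MLE.

## transmitted-allele enumeration for one parent:
## het1/het2 say whether the parent is heterozygous at each locus, phase
## flips its homolog labels at the second locus. Returns rows
## (a, b, k, w): transmitted alt dosages, recombination exponent, weight.
parentPaths <- function(het1, het2, phase = 0L) {
  hap1 <- if (het1) c(0L, 1L) else c(0L, 0L)
  hap2 <- if (het2) {
    if (phase == 0L) c(0L, 1L) else c(1L, 0L)
  } else c(0L, 0L)
  if (!het1 && !het2) {
    return(data.frame(a = 0L, b = 0L, k = NA_integer_, w = 1))
  }
  grid <- expand.grid(h = 0:1, k = 0:1)
  data.frame(a = hap1[grid$h + 1L],
             b = hap2[bitwXor(grid$h, grid$k) + 1L],
             k = grid$k, w = 0.5)
}

## 9 x (Kmax+1) weight matrix W for P(class | r); rows index the joint
## canonical classes (g1, g2) in column-major order g1 fastest, columns the
## total recombination exponent K.
pairTensor <- function(het1p1, het2p1, het1p2, het2p2,
                       phase1 = 0L, phase2 = 0L) {
  p1 <- parentPaths(het1p1, het2p1, phase1)
  p2 <- parentPaths(het1p2, het2p2, phase2)
  kmax <- sum(het1p1 || het2p1, het1p2 || het2p2)
  W <- matrix(0, 9L, kmax + 1L)
  for (i in seq_len(nrow(p1))) {
    for (j in seq_len(nrow(p2))) {
      g1 <- p1$a[i] + p2$a[j]
      g2 <- p1$b[i] + p2$b[j]
      k <- sum(p1$k[i], p2$k[j], na.rm = TRUE)
      cls <- g1 + 3L * g2 + 1L
      W[cls, k + 1L] <- W[cls, k + 1L] + p1$w[i] * p2$w[j]
    }
  }
  W
}

## whether a pair key (het flags) carries any information about r:
## at least one parent heterozygous at both loci.
pairInformative <- function(het1p1, het2p1, het1p2, het2p2) {
  (het1p1 && het2p1) || (het1p2 && het2p2)
}

## vectorized EM over pairs sharing one tensor. N: P x 9 counts; returns
## r (MLE in [0, 0.5]) and log10-likelihood at r and at 0.5.
emBatch <- function(N, W, maxit = 200L, tol = 1e-10) {
  kmax <- ncol(W) - 1L
  K <- 0:kmax
  P <- nrow(N)
  tot <- rowSums(N)
  r <- rep(0.25, P)
  ll <- function(r) {
    RK <- outer(r, K, function(r, k) r^k * (1 - r)^(kmax - k))
    Pc <- RK %*% t(W)
    rowSums(N * log10(pmax(Pc, 1e-300)) * (N > 0))
  }
  for (it in seq_len(maxit)) {
    RK <- outer(r, K, function(r, k) r^k * (1 - r)^(kmax - k))
    Pc <- RK %*% t(W)                       # P x 9
    EKnum <- (RK %*% (K * t(W)))            # P x 9, E[K]*P numerator
    EK <- ifelse(Pc > 0, EKnum / Pc, 0)
    rNew <- rowSums(N * EK) / (kmax * pmax(tot, 1))
    rNew <- pmin(pmax(rNew, 1e-9), 0.5)
    delta <- max(abs(rNew - r))
    r <- rNew
    if (delta < tol) break
  }
  list(r = r, ll = ll(r), ll0 = ll(rep(0.5, P)))
}

## canonical calls: offspring calls recoded so the homozygous parent of a
## backcross marker carries dosage 0. Returns offspring x markers matrix.
canonicalCalls <- function(gm, config) {
  call <- genotypeCalls(gm)
  off <- offspringIds(gm)
  p1 <- parentId(gm, 1); p2 <- parentId(gm, 2)
  flip <- (config == "ABxAA" & !is.na(call[, p2]) & call[, p2] == 2L) |
          (config == "AAxAB" & !is.na(call[, p1]) & call[, p1] == 2L)
  oc <- t(call[, off, drop = FALSE])
  oc[, flip] <- 2L - oc[, flip, drop = FALSE]
  oc
}

#' Two-point linkage over all informative marker pairs
#'
#' Estimates the recombination fraction, LOD score (likelihood ratio against
#' r = 0.5) and linkage phase for every pair of informative markers, by
#' maximum likelihood under the pseudo-testcross pair-class model:
#' backcross-type pairs within one parent have closed-form estimates; pairs
#' involving intercross-type markers are fitted by EM over the hidden
#' parental transmissions; backcross-type pairs from different parents share
#' no meiosis and are flagged uninformative (LOD 0). For each pair all
#' admissible phase combinations are evaluated and the best-likelihood phase
#' is retained, folding r into \[0, 0.5\].
#'
#' @param gm a [GBSGenotypes-class] (offspring calls are used).
#' @param config named factor/character of parental configurations per marker
#'   (from [classifyMarkers()] or [segregationAnalysis()]); only markers with
#'   an informative configuration enter the table.
#' @param markers optional character vector restricting the marker set.
#' @param minShared pairs with fewer jointly called offspring get LOD 0 and
#'   r = NA.
#' @return list with marker ids and square matrices `r`, `lod`, `phase1`,
#'   `phase2`, `nShared`; `phase1`/`phase2` give each parent's relative
#'   phase (0 = coupling, 1 = repulsion, NA = parent not heterozygous at
#'   both).
#' @export
twoPointTable <- function(gm, config, markers = NULL, minShared = 2L) {
  cfg <- as.character(config)
  names(cfg) <- if (!is.null(names(config))) names(config) else rownames(gm)
  use <- names(cfg)[cfg %in% c("ABxAA", "AAxAB", "ABxAB")]
  if (!is.null(markers)) use <- intersect(markers, use)
  m <- length(use)
  if (m < 2L) stop("need at least two informative markers")
  sub <- gm[use, ]
  oc <- canonicalCalls(sub, cfg[use])        # offspring x m
  het1 <- cfg[use] %in% c("ABxAA", "ABxAB")
  het2 <- cfg[use] %in% c("AAxAB", "ABxAB")

  I <- lapply(0:2, function(g) {
    x <- oc == g
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "double"
    x
  })
  N <- vector("list", 9L)
  for (b in 0:2) for (a in 0:2) {
    N[[a + 3L * b + 1L]] <- crossprod(I[[a + 1L]], I[[b + 1L]])
  }
  called <- I[[1L]] + I[[2L]] + I[[3L]]
  nShared <- crossprod(called)

  rM <- matrix(NA_real_, m, m, dimnames = list(use, use))
  lodM <- matrix(0, m, m, dimnames = list(use, use))
  ph1 <- matrix(NA_real_, m, m, dimnames = list(use, use))
  ph2 <- matrix(NA_real_, m, m, dimnames = list(use, use))

  ut <- which(upper.tri(matrix(0, m, m)))
  ii <- ((ut - 1L) %% m) + 1L
  jj <- ((ut - 1L) %/% m) + 1L
  key <- paste(het1[ii], het2[ii], het1[jj], het2[jj])
  ok <- nShared[ut] >= minShared

  Ncols <- vapply(N, function(x) x[ut], numeric(length(ut)))

  for (k in unique(key)) {
    sel <- which(key == k & ok)
    if (!length(sel)) next
    f <- as.logical(strsplit(k, " ")[[1]])
    ## het flags in pair orientation: parent1 at (i, j), parent2 at (i, j)
    h <- list(p1 = c(f[1L], f[3L]), p2 = c(f[2L], f[4L]))
    if (!pairInformative(h$p1[1L], h$p1[2L], h$p2[1L], h$p2[2L])) next
    phases1 <- if (h$p1[1L] && h$p1[2L]) 0:1 else 0L
    phases2 <- if (h$p2[1L] && h$p2[2L]) 0:1 else 0L
    best <- NULL
    for (a1 in phases1) for (a2 in phases2) {
      W <- pairTensor(h$p1[1L], h$p1[2L], h$p2[1L], h$p2[2L], a1, a2)
      fit <- emBatch(Ncols[sel, , drop = FALSE], W)
      if (is.null(best)) {
        best <- list(r = fit$r, ll = fit$ll, ll0 = fit$ll0,
                     a1 = rep(a1, length(sel)), a2 = rep(a2, length(sel)))
      } else {
        upd <- fit$ll > best$ll + 1e-12
        best$r[upd] <- fit$r[upd]
        best$ll[upd] <- fit$ll[upd]
        best$a1[upd] <- a1
        best$a2[upd] <- a2
      }
    }
    idx <- ut[sel]
    rM[idx] <- pmin(best$r, 0.5)
    lodM[idx] <- pmax(best$ll - best$ll0, 0)
    if (length(phases1) > 1L) ph1[idx] <- best$a1
    if (length(phases2) > 1L) ph2[idx] <- best$a2
  }
  ## mirror to the lower triangle
  low <- lower.tri(rM)
  rM[low] <- t(rM)[low]
  lodM[low] <- t(lodM)[low]
  ph1[low] <- t(ph1)[low]
  ph2[low] <- t(ph2)[low]
  diag(rM) <- 0
  diag(lodM) <- 0
  list(markers = use, r = rM, lod = lodM, phase1 = ph1, phase2 = ph2,
       nShared = nShared, het1 = setNames(het1, use),
       het2 = setNames(het2, use))
}

#' Two-point estimate for a single marker pair
#'
#' Same model as [twoPointTable()] for one pair, reporting the pair class
#' and the chosen phase. The EM estimate can be validated against
#' [twoPointGrid()], a brute-force likelihood grid.
#'
#' @inheritParams twoPointTable
#' @param i,j marker ids (or row indices).
#' @return list: `markers`, `class` (e.g. `"BCp1xBCp1"`, `"BCxIC"`,
#'   `"ICxIC"`, `"BCp1xBCp2"`), `n` (jointly called offspring), `r`, `lod`,
#'   `phase1`, `phase2`.
#' @export
twoPoint <- function(gm, config, i, j, minShared = 2L) {
  ids <- rownames(gm)
  if (is.numeric(i)) i <- ids[i]
  if (is.numeric(j)) j <- ids[j]
  cfg <- as.character(config)
  names(cfg) <- if (!is.null(names(config))) names(config) else ids
  cls <- pairClassLabel(cfg[i], cfg[j])
  sub <- gm[c(i, j), ]
  oc <- canonicalCalls(sub, cfg[c(i, j)])
  cc <- stats::complete.cases(oc)
  n <- sum(cc)
  het1 <- cfg[c(i, j)] %in% c("ABxAA", "ABxAB")
  het2 <- cfg[c(i, j)] %in% c("AAxAB", "ABxAB")
  out <- list(markers = c(i, j), class = cls, n = n, r = NA_real_, lod = 0,
              phase1 = NA_real_, phase2 = NA_real_)
  if (n < minShared ||
      !pairInformative(het1[1L], het1[2L], het2[1L], het2[2L])) {
    return(out)
  }
  Nv <- as.vector(table(factor(oc[cc, 1L], 0:2), factor(oc[cc, 2L], 0:2)))
  N <- matrix(Nv, 1L)
  phases1 <- if (het1[1L] && het1[2L]) 0:1 else 0L
  phases2 <- if (het2[1L] && het2[2L]) 0:1 else 0L
  best <- NULL
  for (a1 in phases1) for (a2 in phases2) {
    W <- pairTensor(het1[1L], het1[2L], het2[1L], het2[2L], a1, a2)
    fit <- emBatch(N, W)
    cand <- list(r = fit$r, ll = fit$ll, ll0 = fit$ll0, a1 = a1, a2 = a2)
    if (is.null(best) || cand$ll > best$ll + 1e-12) best <- cand
  }
  out$r <- min(best$r, 0.5)
  out$lod <- max(best$ll - best$ll0, 0)
  if (length(phases1) > 1L) out$phase1 <- best$a1
  if (length(phases2) > 1L) out$phase2 <- best$a2
  out
}

pairClassLabel <- function(c1, c2) {
  lab <- function(x) switch(x, ABxAA = "BCp1", AAxAB = "BCp2", ABxAB = "IC",
                            "NI")
  a <- lab(c1); b <- lab(c2)
  if (a == "NI" || b == "NI") return("UNINFORMATIVE")
  if (a != "IC" && b != "IC") {
    if (a == b) paste0(a, "x", a) else "BCp1xBCp2"
  } else if (a == "IC" && b == "IC") {
    "ICxIC"
  } else {
    "BCxIC"
  }
}

#' Brute-force grid likelihood for a marker pair
#'
#' Maximizes the same pair-class likelihood as [twoPoint()] on an r grid —
#' an independent check of the EM estimator.
#'
#' @inheritParams twoPoint
#' @param step grid spacing on \[0, 0.5\].
#' @return list: `r` (grid argmax over phases), `lod`.
#' @export
twoPointGrid <- function(gm, config, i, j, step = 1e-4) {
  ids <- rownames(gm)
  if (is.numeric(i)) i <- ids[i]
  if (is.numeric(j)) j <- ids[j]
  cfg <- as.character(config)
  names(cfg) <- if (!is.null(names(config))) names(config) else ids
  sub <- gm[c(i, j), ]
  oc <- canonicalCalls(sub, cfg[c(i, j)])
  cc <- stats::complete.cases(oc)
  het1 <- cfg[c(i, j)] %in% c("ABxAA", "ABxAB")
  het2 <- cfg[c(i, j)] %in% c("AAxAB", "ABxAB")
  Nv <- as.vector(table(factor(oc[cc, 1L], 0:2), factor(oc[cc, 2L], 0:2)))
  rGrid <- seq(0, 0.5, by = step)
  phases1 <- if (het1[1L] && het1[2L]) 0:1 else 0L
  phases2 <- if (het2[1L] && het2[2L]) 0:1 else 0L
  bestR <- NA_real_; bestLL <- -Inf; ll0 <- NA_real_
  for (a1 in phases1) for (a2 in phases2) {
    W <- pairTensor(het1[1L], het1[2L], het2[1L], het2[2L], a1, a2)
    kmax <- ncol(W) - 1L
    RK <- outer(rGrid, 0:kmax, function(r, k) r^k * (1 - r)^(kmax - k))
    Pc <- RK %*% t(W)
    ll <- as.vector(log10(pmax(Pc, 1e-300)) %*% Nv)
    if (max(ll) > bestLL) {
      bestLL <- max(ll)
      bestR <- rGrid[which.max(ll)]
      ll0 <- ll[length(ll)]
    }
  }
  list(r = bestR, lod = max(bestLL - ll0, 0))
}

#' Switch the linkage-phase coding of a marker
#'
#' Relabels which parental homolog carries which allele at one marker by
#' swapping the offspring genotype classes that encode the heterozygous
#' parent's transmission: for a backcross-type marker the heterozygote and
#' the homozygote matching the homozygous parent swap; for an
#' intercross-type marker the two homozygote classes swap. A pure relabeling
#' (applying it twice is the identity) that flips an apparent recombination
#' fraction r to 1 - r without changing the LOD.
#'
#' @param gm a [GBSGenotypes-class].
#' @param marker marker id (or row index).
#' @param config the marker's parental configuration (from
#'   [classifyMarkers()]); if missing it is derived from the parental calls.
#' @return The relabeled [GBSGenotypes-class].
#' @export
switchPhase <- function(gm, marker, config = NULL) {
  ids <- rownames(gm)
  if (is.numeric(marker)) marker <- ids[marker]
  call <- genotypeCalls(gm)
  if (is.null(config)) {
    config <- as.character(classifyMarker(call[marker, parentId(gm, 1)],
                                          call[marker, parentId(gm, 2)]))
  }
  off <- offspringIds(gm)
  x <- call[marker, off]
  if (config == "ABxAB") {
    x <- ifelse(is.na(x), NA_integer_, c(2L, 1L, 0L)[x + 1L])
  } else if (config %in% c("ABxAA", "AAxAB")) {
    homParent <- if (config == "ABxAA") parentId(gm, 2) else parentId(gm, 1)
    homCall <- call[marker, homParent]
    swap <- if (!is.na(homCall) && homCall == 2L) c(0L, 2L, 1L) else
      c(1L, 0L, 2L)
    x <- ifelse(is.na(x), NA_integer_, swap[x + 1L])
  } else {
    stop("phase switching applies to informative markers only")
  }
  call[marker, off] <- x
  SummarizedExperiment::assay(gm, "call") <- call
  gm
}
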