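#' Bin markers with identical segregation
#'
#' Markers whose offspring genotype vectors are identical wherever both are
#' called (with at least `minOverlap` jointly called offspring) carry no
#' mutual recombination information and are collapsed into bins; a single
#' representative per bin enters two-point analysis and ordering. Binning is
#' restricted to markers with the same parental configuration and parental
#' genotypes. A marker joins the first existing bin (in creation order) with
#' which it is compatible against every member; the representative is the
#' member with the least missing data, ties to the earliest marker.
#'
#' @param gm a [GBSGenotypes-class].
#' @param config parental configuration per marker (named, from
#'   [classifyMarkers()]).
#' @param markers optional restriction of the marker set.
#' @param minOverlap minimum jointly called offspring for identity.
#' @return `DataFrame`: marker, bin (integer id), representative (logical).
#' @export
binCosegregating <- function(gm, config, markers = NULL, minOverlap = 20L) {
  cfg <- as.character(config)
  names(cfg) <- if (!is.null(names(config))) names(config) else rownames(gm)
  use <- if (is.null(markers)) names(cfg) else markers
  call <- genotypeCalls(gm)
  off <- offspringIds(gm)
  p1 <- parentId(gm, 1); p2 <- parentId(gm, 2)
  stratum <- paste(cfg[use], call[use, p1], call[use, p2])
  oc <- call[use, off, drop = FALSE]

  bin <- integer(length(use))
  names(bin) <- use
  nextBin <- 0L
  members <- list()
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    localBins <- integer()   # bin ids created in this stratum
    for (i in idx) {
      placed <- FALSE
      for (b in localBins) {
        compat <- TRUE
        for (mIdx in members[[b]]) {
          both <- !is.na(oc[i, ]) & !is.na(oc[mIdx, ])
          if (sum(both) < minOverlap ||
              any(oc[i, both] != oc[mIdx, both])) {
            compat <- FALSE
            break
          }
        }
        if (compat) {
          bin[i] <- b
          members[[b]] <- c(members[[b]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        nextBin <- nextBin + 1L
        bin[i] <- nextBin
        members[[nextBin]] <- i
        localBins <- c(localBins, nextBin)
      }
    }
  }
  nMiss <- rowSums(is.na(oc))
  rep_ <- logical(length(use))
  for (b in seq_len(nextBin)) {
    mem <- members[[b]]
    rep_[mem[order(nMiss[mem], mem)][1L]] <- TRUE
  }
  DataFrame(marker = use, bin = as.integer(bin), representative = rep_)
}

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure over the two-point graph: markers are
#' connected when their pairwise LOD is at least `lodMin` and the estimated
#' recombination fraction at most `rMax`. Connected components of two or
#' more markers become linkage groups; isolated markers are unlinked.
#'
#' @param tp result of [twoPointTable()].
#' @param lodMin minimum pairwise LOD for a grouping edge.
#' @param rMax maximum recombination fraction for a grouping edge.
#' @return list: `groups` (list of character vectors, largest first),
#'   `unlinked` (character).
#' @export
groupMarkers <- function(tp, lodMin = 6, rMax = 0.35) {
  adj <- !is.na(tp$r) & tp$r <= rMax & tp$lod >= lodMin
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  mem <- split(tp$markers, comp$membership)
  sizes <- lengths(mem)
  groups <- mem[sizes >= 2L]
  groups <- groups[order(-lengths(groups),
                         vapply(groups, min, character(1)))]
  names(groups) <- NULL
  list(groups = groups, unlinked = unlist(mem[sizes == 1L], use.names = FALSE))
}

## completed pairwise distance matrix (cM) for one group: Kosambi transform
## of informative r-hat entries, missing entries filled by shortest paths
## over the informative-edge graph.
completedDistances <- function(tp, group) {
  idx <- match(group, tp$markers)
  r <- tp$r[idx, idx, drop = FALSE]
  inf <- !is.na(r)
  d <- matrix(NA_real_, length(idx), length(idx),
              dimnames = list(group, group))
  d[inf] <- kosambi(pmin(r[inf], 0.49))
  diag(d) <- 0
  if (any(is.na(d))) {
    w <- d
    w[is.na(w)] <- 0
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    sp <- igraph::distances(g)
    ## igraph treats absent edges as Inf; zero-weight edges stay connected
    miss <- is.na(d)
    d[miss] <- sp[miss]
    d[is.infinite(d)] <- max(d[is.finite(d)]) + 50
  }
  d
}

## SARF of an order under a distance matrix.
sarf <- function(order, d) {
  if (length(order) < 2L) return(0)
  sum(d[cbind(order[-length(order)], order[-1L])])
}

## pairwise Kosambi distances (D) and LOD weights (W) of the informative
## pairs within a marker set, in the given marker order; uninformative or
## unreliable pairs get weight 0 and D = NA.
pairwiseDW <- function(tp, markers, rCap = 0.49, lodMinPair = 0.5) {
  idx <- match(markers, tp$markers)
  r <- tp$r[idx, idx, drop = FALSE]
  lod <- tp$lod[idx, idx, drop = FALSE]
  inf <- !is.na(r) & r <= rCap & lod >= lodMinPair
  D <- matrix(NA_real_, length(idx), length(idx))
  D[inf] <- kosambi(pmin(r[inf], 0.49))
  W <- matrix(0, length(idx), length(idx))
  W[inf] <- lod[inf]
  diag(W) <- 0
  list(D = D, W = W)
}

## weighted non-negative least-squares step sizes for a fixed order
## ("regression mapping"): every informative pair (i, j) constrains the sum
## of the steps it spans to its Kosambi distance, weighted by LOD. The
## normal equations A'WA s = A'Wd have the closed form
## M[a,b] = sum of weights of pairs spanning both steps a and b
##        = sum_{i <= a, j >= b+1} W[i,j]  (a <= b),
## built by two-dimensional cumulative sums; negative steps are clamped to
## zero by an active-set loop. Returns NA for steps spanned by no pair.
## `window` keeps only pairs separated by at most that many positions in
## the current order: long-range pairs are both noisier and biased by the
## map-function mismatch, so local pairs carry the distance scale.
nnlsSteps <- function(D, W, window = Inf) {
  n <- nrow(W)
  nSteps <- n - 1L
  Wu <- W
  Wu[lower.tri(Wu, diag = TRUE)] <- 0
  Wu[is.na(D)] <- 0
  if (is.finite(window)) {
    Wu[abs(outer(seq_len(n), seq_len(n), "-")) > window] <- 0
  }
  Qu <- Wu * ifelse(is.na(D), 0, D)
  ## C[a, b] = sum_{i <= a, j >= b} of the matrix
  revColCumsum <- function(M) {
    t(apply(apply(M, 2L, cumsum), 1L, function(x) rev(cumsum(rev(x)))))
  }
  Cw <- revColCumsum(Wu)
  Cq <- revColCumsum(Qu)
  ab <- which(upper.tri(matrix(0, nSteps, nSteps), diag = TRUE),
              arr.ind = TRUE)
  M <- matrix(0, nSteps, nSteps)
  M[ab] <- Cw[cbind(ab[, 1L], ab[, 2L] + 1L)]
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  b <- Cq[cbind(seq_len(nSteps), seq_len(nSteps) + 1L)]
  s <- rep(NA_real_, nSteps)
  free <- diag(M) > 0
  while (any(free)) {
    Mf <- M[free, free, drop = FALSE] + diag(1e-9, sum(free))
    sf <- solve(Mf, b[free])
    if (all(sf >= -1e-9)) {
      s[free] <- pmax(sf, 0)
      break
    }
    neg <- which(free)[sf < -1e-9]
    free[neg] <- FALSE
    s[neg] <- 0
  }
  s
}

## cumulative map positions for markers in a fixed order; steps with no
## spanning informative pair fall back to the completed distances of their
## flanking markers.
regressionPositions <- function(tp, markers, window = 6L) {
  n <- length(markers)
  if (n < 2L) return(0)
  dw <- pairwiseDW(tp, markers)
  s <- nnlsSteps(dw$D, dw$W, window = window)
  if (any(is.na(s))) {
    d <- completedDistances(tp, markers)
    na <- which(is.na(s))
    s[na] <- d[cbind(markers[na], markers[na + 1L])]
  }
  c(0, cumsum(s))
}

## weighted stress of an order: squared residuals between fitted inter-
## marker distances (from the NNLS positions) and the pairwise two-point
## distances, LOD-weighted. D/W are in the original marker indexing.
orderStress <- function(ordIdx, D, W, window = 6L) {
  Dp <- D[ordIdx, ordIdx]
  Wp <- W[ordIdx, ordIdx]
  ## positions are fitted from local pairs (window), but the residuals are
  ## taken over every informative pair: a marker moved away from its
  ## linkage partners is penalized no matter how far it moves
  s <- nnlsSteps(Dp, Wp, window = window)
  s[is.na(s)] <- 0
  x <- c(0, cumsum(s))
  pred <- abs(outer(x, x, "-"))
  use <- !is.na(Dp) & upper.tri(Dp)
  sum(Wp[use] * (pred[use] - Dp[use])^2)
}

## one-dimensional weighted metric scaling (SMACOF-style majorization) of
## the informative distances, initialized from classical scaling of the
## completed distance matrix. Returns a coordinate per marker.
smacof1d <- function(dCompleted, D, W, maxit = 300L, tol = 1e-7) {
  n <- nrow(D)
  x <- stats::cmdscale(stats::as.dist(dCompleted), k = 1L)[, 1L]
  D0 <- ifelse(is.na(D), 0, D)
  rw <- pmax(rowSums(W), 1e-9)
  for (it in seq_len(maxit)) {
    sgn <- sign(outer(x, x, "-"))
    sgn[sgn == 0] <- 1
    xn <- rowSums(W * (matrix(x, n, n, byrow = TRUE) + D0 * sgn)) / rw
    if (max(abs(xn - x)) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  x
}

## phase-corrected transmission observations for one parent over a marker
## set: offspring x markers matrix with entries 0/1 (reference/other group
## homolog transmitted) or NA (missing, ambiguous het at an intercross
## marker, or marker uninformative for this parent).
transmissionObs <- function(gm, markers, config, phase, parent) {
  call <- genotypeCalls(gm)
  off <- offspringIds(gm)
  other <- parentId(gm, if (parent == 1L) 2L else 1L)
  hetCfg <- if (parent == 1L) c("ABxAA", "ABxAB") else c("AAxAB", "ABxAB")
  out <- matrix(NA_integer_, length(off), length(markers),
                dimnames = list(off, markers))
  for (k in seq_along(markers)) {
    mk <- markers[k]
    cf <- config[[mk]]
    if (!(cf %in% hetCfg) || is.na(phase[[mk]])) next
    x <- call[mk, off]
    t <- if (cf == "ABxAB") {
      ifelse(is.na(x) | x == 1L, NA_integer_, as.integer(x == 2L))
    } else {
      hc <- call[mk, other]
      if (!is.na(hc) && hc == 2L) {
        ifelse(is.na(x) | x == 0L, NA_integer_, 2L - x)
      } else {
        ifelse(is.na(x) | x == 2L, NA_integer_, x)
      }
    }
    out[, k] <- bitwXor(t, phase[[mk]])
  }
  out
}

## multipoint chain fit for one parent: Baum-Welch re-estimation of the
## adjacent recombination fractions (a few iterations from the two-point
## initial values) followed by the forward log-likelihood. Vectorized over
## offspring.
mpChainFit <- function(obs, rInit, eps = 0.01, iters = 2L) {
  m <- ncol(obs)
  nf <- nrow(obs)
  if (m < 2L) return(list(ll = 0, r = numeric()))
  E0 <- ifelse(is.na(obs), 1, ifelse(obs == 0L, 1 - eps, eps))
  E1 <- ifelse(is.na(obs), 1, ifelse(obs == 1L, 1 - eps, eps))
  r <- rInit
  f0 <- matrix(0, nf, m); f1 <- matrix(0, nf, m); sc <- matrix(0, nf, m)
  for (it in seq_len(iters + 1L)) {
    f0[, 1L] <- 0.5 * E0[, 1L]
    f1[, 1L] <- 0.5 * E1[, 1L]
    s <- f0[, 1L] + f1[, 1L]
    sc[, 1L] <- s; f0[, 1L] <- f0[, 1L] / s; f1[, 1L] <- f1[, 1L] / s
    for (k in 2:m) {
      a0 <- f0[, k - 1L] * (1 - r[k - 1L]) + f1[, k - 1L] * r[k - 1L]
      a1 <- f0[, k - 1L] * r[k - 1L] + f1[, k - 1L] * (1 - r[k - 1L])
      f0[, k] <- a0 * E0[, k]
      f1[, k] <- a1 * E1[, k]
      s <- f0[, k] + f1[, k]
      sc[, k] <- s; f0[, k] <- f0[, k] / s; f1[, k] <- f1[, k] / s
    }
    if (it == iters + 1L) return(list(ll = sum(log(sc)), r = r))
    b0 <- matrix(1, nf, m); b1 <- matrix(1, nf, m)
    for (k in (m - 1L):1L) {
      t0 <- E0[, k + 1L] * b0[, k + 1L]
      t1 <- E1[, k + 1L] * b1[, k + 1L]
      b0[, k] <- (1 - r[k]) * t0 + r[k] * t1
      b1[, k] <- r[k] * t0 + (1 - r[k]) * t1
      s <- b0[, k] + b1[, k]
      b0[, k] <- b0[, k] / s; b1[, k] <- b1[, k] / s
    }
    for (k in seq_len(m - 1L)) {
      x00 <- f0[, k] * (1 - r[k]) * E0[, k + 1L] * b0[, k + 1L]
      x01 <- f0[, k] * r[k] * E1[, k + 1L] * b1[, k + 1L]
      x10 <- f1[, k] * r[k] * E0[, k + 1L] * b0[, k + 1L]
      x11 <- f1[, k] * (1 - r[k]) * E1[, k + 1L] * b1[, k + 1L]
      tot <- x00 + x01 + x10 + x11
      r[k] <- min(max(sum((x01 + x10) / tot) / nf, 1e-4), 0.49)
    }
  }
}

## multipoint log-likelihood of a candidate order: both parents' chains,
## adjacent recombination fractions initialized from the two-point table.
mpOrderLL <- function(ordIdx, rM, obs1, obs2) {
  total <- 0
  for (obs in list(obs1, obs2)) {
    sub <- ordIdx[colSums(!is.na(obs[, ordIdx, drop = FALSE])) > 0]
    if (length(sub) < 2L) next
    rInit <- rM[cbind(sub[-length(sub)], sub[-1L])]
    rInit[is.na(rInit)] <- 0.3
    rInit <- pmin(pmax(rInit, 1e-4), 0.49)
    total <- total + mpChainFit(obs[, sub, drop = FALSE], rInit)$ll
  }
  total
}

## final multipoint polish: single-marker relocations (attempted for the
## markers with the worst pairwise-stress residuals, where misplacements
## live) and windowed segment reversals, accepted when they raise the
## multipoint likelihood. Catches block misplacements the pairwise stress
## cannot resolve: a misplaced marker forces spurious double crossovers,
## which the chain likelihood punishes.
mpPolish <- function(ord, rM, obs1, obs2, D, W, window = 8L,
                     maxSweeps = 4L, maxReloc = 15L) {
  n <- length(ord)
  cur <- mpOrderLL(ord, rM, obs1, obs2)
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    ## stress residual per marker under the current order
    Dp <- D[ord, ord]
    Wp <- W[ord, ord]
    s0 <- nnlsSteps(Dp, Wp, window = 6L)
    s0[is.na(s0)] <- 0
    x <- c(0, cumsum(s0))
    resid <- Wp * (abs(outer(x, x, "-")) - ifelse(is.na(Dp), 0, Dp))^2
    resid[is.na(Dp)] <- 0
    perMarker <- rowSums(resid)
    cand <- order(-perMarker)[seq_len(min(maxReloc, n))]
    for (i in sort(cand)) {
      mk <- ord[i]
      rest <- ord[-i]
      for (pos in 0:length(rest)) {
        if (pos == i - 1L) next
        candOrd <- append(rest, mk, after = pos)
        s <- mpOrderLL(candOrd, rM, obs1, obs2)
        if (s > cur + 1e-6) {
          ord <- candOrd
          cur <- s
          improved <- TRUE
          break
        }
      }
    }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):min(n, i + window)) {
        candOrd <- ord
        candOrd[i:j] <- rev(candOrd[i:j])
        s <- mpOrderLL(candOrd, rM, obs1, obs2)
        if (s > cur + 1e-6) {
          ord <- candOrd
          cur <- s
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

## local search over orders: windowed 2-opt segment reversals minimizing
## the regression stress (global relocations are handled afterwards by the
## multipoint polish).
refineOrder <- function(ord, D, W, window = 12L, maxSweeps = 20L) {
  n <- length(ord)
  cur <- orderStress(ord, D, W)
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):min(n, i + window)) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        s <- orderStress(cand, D, W)
        if (s < cur - 1e-9) {
          ord <- cand
          cur <- s
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

#' Order the markers of one linkage group
#'
#' Seriation of the two-point distances. Groups of up to `exhaustiveMax`
#' markers are ordered by exhaustive enumeration of permutations,
#' guaranteeing the minimum sum of adjacent recombination fractions (SARF)
#' on the completed distance matrix. Larger groups are seeded by
#' one-dimensional weighted metric scaling of the informative (LOD-weighted)
#' Kosambi distances and refined by window-limited 2-opt segment reversals
#' plus short-segment relocations, minimizing the weighted regression
#' stress (squared mismatch between fitted map distances and two-point
#' distances). Positions come from non-negative least-squares regression
#' mapping over all informative pairs. Deterministic: ties break on marker
#' id and the output is oriented so the first marker id precedes the last.
#'
#' @param tp result of [twoPointTable()].
#' @param group character vector of (representative) marker ids.
#' @param exhaustiveMax exhaustive-enumeration size limit.
#' @param window 2-opt reversal window (markers).
#' @param obs optional list of the two parents' phase-corrected transmission
#'   matrices over `group` (as built inside [buildGeneticMap()]); when
#'   present, large groups get a final multipoint-likelihood polish.
#' @return list: `markers` (ordered ids), `posCM` (cumulative positions),
#'   `sarf`.
#' @export
orderGroup <- function(tp, group, exhaustiveMax = 8L, window = 12L,
                       obs = NULL) {
  n <- length(group)
  if (n == 1L) {
    return(list(markers = group, posCM = 0, sarf = 0))
  }
  d <- completedDistances(tp, group)
  if (n <= exhaustiveMax) {
    ord <- exhaustiveOrder(d)
  } else {
    dw <- pairwiseDW(tp, group)
    x <- smacof1d(d, dw$D, dw$W)
    ord <- order(x, group)
    ord <- refineOrder(ord, dw$D, dw$W, window = window)
    if (!is.null(obs)) {
      idx <- match(group, tp$markers)
      rM <- tp$r[idx, idx, drop = FALSE]
      ord <- mpPolish(ord, rM, obs[[1L]], obs[[2L]], dw$D, dw$W)
    }
  }
  markers <- group[ord]
  if (markers[1L] > markers[n]) markers <- rev(markers)
  list(markers = markers, posCM = regressionPositions(tp, markers),
       sarf = sarf(markers, d))
}

## exact seriation by enumeration (first element fixed smaller than last to
## halve the search); returns an index order into rownames(d).
exhaustiveOrder <- function(d) {
  n <- nrow(d)
  if (n == 2L) return(1:2)
  perms <- permutations(n)
  keep <- perms[, 1L] < perms[, n]
  perms <- perms[keep, , drop = FALSE]
  vals <- numeric(nrow(perms))
  for (p in seq_len(nrow(perms))) {
    ord <- perms[p, ]
    vals[p] <- sum(d[cbind(ord[-n], ord[-1L])])
  }
  best <- which(vals <= min(vals) + 1e-12)
  ## deterministic among ties: lexicographically smallest permutation
  perms[best[order(apply(perms[best, , drop = FALSE], 1L, paste,
                         collapse = ","))[1L]], ]
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[row:(row + nrow(sub) - 1L), ] <- cbind(i, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Drop markers that inflate a linkage group
#'
#' Iteratively removes the marker that most inflates the group length. For
#' each marker the nearest preceding and following markers with an
#' informative two-point distance to it are found in the current order; the
#' marker's inflation is its triangle excess over those anchors,
#' \eqn{d(l,m) + d(m,r) - d(l,r)} — near zero for a well-fitting marker
#' however long its flanking gaps are, large when accumulated genotyping
#' errors inflate both of its flanking distances. For a terminal marker
#' (one-sided anchors only) the inflation is its distance to the nearest
#' informative anchor, since an error-ridden marker is typically pushed to
#' the group end as a long terminal gap. Markers are removed while the
#' largest inflation exceeds `inflationLimit` cM, then positions are
#' recomputed.
#'
#' @param ordered result of [orderGroup()].
#' @param tp result of [twoPointTable()].
#' @param inflationLimit smallest inflation (cM) that justifies dropping a
#'   marker; `Inf` disables. The default tolerates ordinary terminal gaps
#'   of a dense map and the modest excess created by unresolvable local
#'   order noise, while still catching error-ridden markers.
#' @param anchorDepth how far (in order positions) to search for
#'   informative anchors on each side.
#' @return list: `markers`, `posCM`, `dropped`.
#' @export
dropMisfits <- function(ordered, tp, inflationLimit = 15,
                        anchorDepth = 6L) {
  markers <- ordered$markers
  dropped <- character()
  if (is.infinite(inflationLimit)) {
    return(list(markers = markers, posCM = ordered$posCM, dropped = dropped))
  }
  repeat {
    n <- length(markers)
    if (n < 3L) break
    D <- pairwiseDW(tp, markers)$D
    excess <- numeric(n)
    for (k in seq_len(n)) {
      lcand <- rev(seq_len(k - 1L))
      lcand <- lcand[seq_len(min(length(lcand), anchorDepth))]
      rcand <- seq_len(n)[-seq_len(k)]
      rcand <- rcand[seq_len(min(length(rcand), anchorDepth))]
      l <- lcand[which(!is.na(D[lcand, k]))[1L]]
      r <- rcand[which(!is.na(D[rcand, k]))[1L]]
      if (!is.na(l) && !is.na(r) && !is.na(D[l, r])) {
        excess[k] <- D[l, k] + D[k, r] - D[l, r]
      } else if (is.na(l) && !is.na(r) && k == 1L) {
        excess[k] <- D[k, r]
      } else if (is.na(r) && !is.na(l) && k == n) {
        excess[k] <- D[l, k]
      }
    }
    worst <- which.max(excess)
    if (excess[worst] <= inflationLimit) break
    dropped <- c(dropped, markers[worst])
    markers <- markers[-worst]
  }
  list(markers = markers, posCM = regressionPositions(tp, markers),
       dropped = dropped)
}

## per-parent phase assignment within an ordered group: breadth-first
## propagation of relative two-point phases from the first marker that is
## heterozygous in the parent, using edges in decreasing LOD order.
assignPhases <- function(tp, markers, parent, lodMin = 3) {
  het <- if (parent == 1L) tp$het1 else tp$het2
  phM <- if (parent == 1L) tp$phase1 else tp$phase2
  hetMk <- markers[het[markers]]
  phase <- setNames(rep(NA_integer_, length(markers)), markers)
  conflicts <- setNames(integer(length(markers)), markers)
  if (!length(hetMk)) return(list(phase = phase, conflicts = conflicts))
  idx <- match(hetMk, tp$markers)
  sub <- phM[idx, idx, drop = FALSE]
  lod <- tp$lod[idx, idx, drop = FALSE]
  usable <- !is.na(sub) & lod >= lodMin
  phase[hetMk[1L]] <- 0L
  frontier <- hetMk[1L]
  while (length(frontier)) {
    nxt <- character()
    for (mk in frontier) {
      i <- match(mk, hetMk)
      nb <- which(usable[i, ])
      for (k in nb) {
        other <- hetMk[k]
        prop <- as.integer(bitwXor(phase[mk], as.integer(sub[i, k])))
        if (is.na(phase[other])) {
          phase[other] <- prop
          nxt <- c(nxt, other)
        } else if (phase[other] != prop) {
          conflicts[other] <- conflicts[other] + 1L
        }
      }
    }
    frontier <- nxt
  }
  list(phase = phase, conflicts = conflicts)
}

#' Build the composite pseudo-testcross genetic map
#'
#' The full mapping stage: co-segregating markers are binned; two-point
#' recombination fractions, LODs and phases are estimated between bin
#' representatives; representatives are grouped at `lodMin`/`rMax`,
#' ordered by seriation, positioned by cumulative Kosambi distances, pruned
#' of map-inflating misfits, and phased per parent. Bin members inherit the
#' position and phases of their representative.
#'
#' @param gm a [GBSGenotypes-class] (after filtering and Mendelian masking).
#' @param seg result of [segregationAnalysis()]; only markers with decision
#'   `KEEP` and an informative configuration are mapped.
#' @param lodMin,rMax grouping thresholds.
#' @param minOverlap joint-call threshold for bin identity.
#' @param inflationLimit misfit-drop threshold in cM (see [dropMisfits()]).
#' @param minShared minimum jointly called offspring per informative pair.
#' @return A [GeneticMap-class].
#' @export
buildGeneticMap <- function(gm, seg, lodMin = 6, rMax = 0.35,
                            minOverlap = 20L, inflationLimit = 10,
                            minShared = 2L) {
  tab <- seg$table
  keep <- tab$marker[tab$decision == "KEEP" &
                     tab$config %in% c("ABxAA", "AAxAB", "ABxAB")]
  if (length(keep) < 2L) stop("fewer than two mappable markers")
  cfg <- setNames(as.character(tab$config), tab$marker)
  gmK <- seg$genotypes
  bins <- binCosegregating(gmK, cfg[keep], markers = keep,
                           minOverlap = minOverlap)
  reps <- bins$marker[bins$representative]
  tp <- twoPointTable(gmK, cfg[reps], markers = reps, minShared = minShared)
  grp <- groupMarkers(tp, lodMin = lodMin, rMax = rMax)

  if (!length(grp$groups)) {
    return(new("GeneticMap",
               table = DataFrame(marker = character(), group = integer(),
                                 bin = integer(), representative = logical(),
                                 posCM = numeric(), phase1 = integer(),
                                 phase2 = integer(), config = character()),
               unlinked = keep, dropped = character()))
  }
  rows <- list()
  droppedAll <- character()
  gno <- 0L
  for (g in grp$groups) {
    gno <- gno + 1L
    ph1 <- assignPhases(tp, g, 1L)
    ph2 <- assignPhases(tp, g, 2L)
    obs <- list(transmissionObs(gmK, g, cfg, ph1$phase, 1L),
                transmissionObs(gmK, g, cfg, ph2$phase, 2L))
    ord <- orderGroup(tp, g, obs = obs)
    ord <- dropMisfits(ord, tp, inflationLimit = inflationLimit)
    droppedAll <- c(droppedAll, ord$dropped)
    rows[[gno]] <- DataFrame(marker = ord$markers, group = gno,
                             posCM = ord$posCM,
                             phase1 = unname(ph1$phase[ord$markers]),
                             phase2 = unname(ph2$phase[ord$markers]))
  }
  repTab <- do.call(rbind, rows)
  ## expand bins: members take their representative's place
  binOf <- setNames(bins$bin, bins$marker)
  repOfBin <- setNames(bins$marker[bins$representative],
                       bins$bin[bins$representative])
  allRows <- list()
  for (i in seq_len(nrow(bins))) {
    mk <- bins$marker[i]
    repMk <- repOfBin[[as.character(binOf[[mk]])]]
    j <- match(repMk, repTab$marker)
    if (is.na(j)) next   # representative unlinked or dropped
    allRows[[length(allRows) + 1L]] <- DataFrame(
      marker = mk, group = repTab$group[j], bin = binOf[[mk]],
      representative = mk == repMk, posCM = repTab$posCM[j],
      phase1 = repTab$phase1[j], phase2 = repTab$phase2[j],
      config = cfg[[mk]])
  }
  table <- do.call(rbind, allRows)
  table <- table[order(table$group, table$posCM, table$marker), ]
  mapped <- table$marker
  unlinked <- setdiff(bins$marker[bins$marker %in% keep],
                      c(mapped, droppedAll))
  new("GeneticMap", table = table, unlinked = unlinked,
      dropped = droppedAll)
}

#' Write a genetic map as tab-separated text
#'
#' @param map a [GeneticMap-class].
#' @param path output TSV (marker, group, posCM, bin, representative,
#'   phase1, phase2, config).
#' @return `path`, invisibly.
#' @export
writeGeneticMap <- function(map, path) {
  utils::write.table(as.data.frame(mapTable(map)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
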