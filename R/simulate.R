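#' Simulate an F1 double pseudo-testcross population
#'
#' Draws a synthetic outcrossed F1 population: marker positions per
#' chromosome, a parental configuration for each marker (heterozygous in
#' parent 1 only, in parent 2 only, in both, or uninformative), random
#' linkage phases in each heterozygous parent, and one meiosis per parent per
#' offspring with crossovers placed under a no-interference (Haldane)
#' process. A single binary QTL, heterozygous in one parent, determines each
#' offspring's phenotype through a two-penetrance Bernoulli model on the
#' transmitted QTL allele.
#'
#' @param params a [SimParams] object.
#' @return A [TruthSet].
#' @examples
#' truth <- simulatePopulation(simParams(nOffspring = 20, nChromosomes = 2,
#'                                       markersPerChrom = 10, qtlChrom = 1))
#' truth
#' @export
simulatePopulation <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  withSeed(childSeed(params@seed, 1L), {
    n <- params@nOffspring
    nm <- params@markersPerChrom
    samples <- c("P1", "P2", sprintf("F1_%03d", seq_len(n)))

    maps <- list()
    tr1 <- tr2 <- list()
    qtlAllele <- NULL
    for (chrom in seq_len(params@nChromosomes)) {
      L <- params@chromLengthCM[chrom]
      pos <- sort(stats::runif(nm, 0, L))
      hasQtl <- chrom == params@qtlChrom
      simPos <- if (hasQtl) sort(c(pos, params@qtlPosCM)) else pos
      qtlIdx <- if (hasQtl) match(params@qtlPosCM, simPos) else NA_integer_
      m1 <- simMeioses(simPos, n, L)
      m2 <- simMeioses(simPos, n, L)
      if (hasQtl) {
        qtlTrans <- if (params@qtlParent == 1L) m1[, qtlIdx] else m2[, qtlIdx]
        ## homolog 1 of the segregating parent carries the alternate allele
        qtlAllele <- as.integer(qtlTrans)
        m1 <- m1[, -qtlIdx, drop = FALSE]
        m2 <- m2[, -qtlIdx, drop = FALSE]
      }
      cfg <- sample(names(params@configProbs), nm, replace = TRUE,
                    prob = params@configProbs)
      ## phased parental haplotypes (alt dosage per homolog)
      hetPhase1 <- stats::rbinom(nm, 1L, 0.5)   # which homolog carries alt
      hetPhase2 <- stats::rbinom(nm, 1L, 0.5)
      homAll1 <- stats::rbinom(nm, 1L, 0.5)     # hom parent: 0/0 or 1/1
      homAll2 <- stats::rbinom(nm, 1L, 0.5)
      p1het <- cfg %in% c("ABxAA", "ABxAB")
      p2het <- cfg %in% c("AAxAB", "ABxAB")
      p1h1 <- ifelse(p1het, hetPhase1, homAll1)
      p1h2 <- ifelse(p1het, 1L - hetPhase1, homAll1)
      p2h1 <- ifelse(p2het, hetPhase2, homAll2)
      p2h2 <- ifelse(p2het, 1L - hetPhase2, homAll2)
      refalt <- replicate(nm, sample(c("A", "C", "G", "T"), 2L))
      posBp <- as.integer(round(pos * 250000) + seq_len(nm))
      maps[[chrom]] <- DataFrame(
        marker = sprintf("%d_%d", chrom, posBp),
        chrom = paste0("chr", chrom), posCM = pos, posBp = posBp,
        config = cfg,
        p1h1 = as.integer(p1h1), p1h2 = as.integer(p1h2),
        p2h1 = as.integer(p2h1), p2h2 = as.integer(p2h2),
        ref = refalt[1L, ], alt = refalt[2L, ]
      )
      tr1[[chrom]] <- m1
      tr2[[chrom]] <- m2
    }
    map <- do.call(rbind, maps)
    trans1 <- do.call(cbind, tr1)
    trans2 <- do.call(cbind, tr2)
    colnames(trans1) <- colnames(trans2) <- map$marker
    rownames(trans1) <- rownames(trans2) <- samples[-(1:2)]

    pen <- ifelse(qtlAllele == 1L, params@penetranceAlt, params@penetranceRef)
    phenoOff <- stats::rbinom(n, 1L, pen)
    ## parent phenotypes follow their own QTL genotype deterministically:
    ## parent carrying the alternate allele expresses iff it raises penetrance
    domPheno <- as.integer(params@penetranceAlt > params@penetranceRef)
    pheno <- c(if (params@qtlParent == 1L) c(domPheno, 1L - domPheno)
               else c(1L - domPheno, domPheno),
               phenoOff)
    names(pheno) <- samples

    scale <- stats::rlnorm(n + 2L, meanlog = -params@scaleSdlog^2 / 2,
                           sdlog = params@scaleSdlog)
    scale[1:2] <- scale[1:2] * params@parentScale
    names(scale) <- samples

    new("TruthSet", params = params, samples = samples, map = map,
        trans1 = trans1, trans2 = trans2,
        qtlAllele = as.integer(qtlAllele),
        phenotype = setNames(as.integer(pheno), samples),
        sampleScale = scale)
  })
}

## One parent's meioses: n gametes over loci at `pos` (cM) on a chromosome of
## length L. Crossover count ~ Poisson(L/100), breakpoints uniform; the
## transmitted homolog flips at each breakpoint (no interference).
simMeioses <- function(pos, n, L) {
  m <- length(pos)
  out <- matrix(0L, n, m)
  start <- stats::rbinom(n, 1L, 0.5)
  nxo <- stats::rpois(n, L / 100)
  for (i in seq_len(n)) {
    if (nxo[i] == 0L || m == 0L) {
      out[i, ] <- start[i]
    } else {
      bp <- stats::runif(nxo[i], 0, L)
      flips <- vapply(pos, function(p) sum(bp < p) %% 2L, integer(1))
      out[i, ] <- as.integer(xor(start[i], flips))
    }
  }
  out
}

#' Degrade a simulated population into observed GBS genotypes
#'
#' Applies the GBS observation model to the true genotypes: per-cell read
#' depth is negative-binomial with mean `depthMean` scaled by the sample's
#' log-normal factor; given depth *d*, the alternate-allele read count is
#' binomial with allele-sampling error `errorRate`; the observed call is the
#' maximum-likelihood genotype, and cells with zero depth are missing. The
#' resulting sparse matrix (and optional VCF) is what the filtering stage of
#' the pipeline consumes; the noiseless truth stays available via
#' `metadata()$trueCall` and `metadata()$truth`.
#'
#' @param truth a [TruthSet].
#' @param vcf optional path; if given, the observed matrix is also written as
#'   a multi-sample VCF with GT and DP fields.
#' @return A [GBSGenotypes-class] object (markers x samples, parents first).
#' @export
simulateGenotypes <- function(truth, vcf = NULL) {
  stopifnot(is(truth, "TruthSet"))
  params <- truth@params
  withSeed(childSeed(params@seed, 2L), {
    g <- trueGenotypes(truth)                    # markers x samples
    m <- nrow(g); ns <- ncol(g)
    mu <- outer(rep(1, m), truth@sampleScale) * params@depthMean
    depth <- matrix(stats::rnbinom(m * ns, size = params@depthSize,
                                   mu = mu), m, ns)
    e <- params@errorRate
    pAlt <- c(e, 0.5, 1 - e)[g + 1L]
    k <- stats::rbinom(m * ns, size = depth, prob = pAlt)
    call <- mlGenotype(k, as.vector(depth), e)
    call[depth == 0L] <- NA_integer_
    call <- matrix(call, m, ns, dimnames = dimnames(g))
    dimnames(depth) <- dimnames(g)
    gm <- GBSGenotypes(call, depth,
                       chrom = truth@map$chrom, pos = truth@map$posBp,
                       ref = truth@map$ref, alt = truth@map$alt,
                       roles = c("parent1", "parent2",
                                 rep("offspring", ns - 2L)))
    metadata(gm)$truth <- truth
    metadata(gm)$trueCall <- g
    if (!is.null(vcf)) writeGenotypesVcf(gm, vcf)
    gm
  })
}

## Maximum-likelihood hard call from alt-read count k at depth d with
## allele-sampling error e. Ties resolve toward the lower dosage.
mlGenotype <- function(k, d, e) {
  e <- max(e, 1e-12)
  l0 <- stats::dbinom(k, d, e, log = TRUE)
  l1 <- stats::dbinom(k, d, 0.5, log = TRUE)
  l2 <- stats::dbinom(k, d, 1 - e, log = TRUE)
  as.integer(max.col(cbind(l0, l1, l2), ties.method = "first") - 1L)
}

#' Write a GBSGenotypes matrix as a multi-sample VCF
#'
#' Emits VCF 4.2 with `GT` and `DP` per cell (missing calls as `./.`).
#'
#' @param gm a [GBSGenotypes-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(gm, path) {
  gr <- rowRanges(gm)
  call <- genotypeCalls(gm)
  depth <- readDepth(gm)
  gt <- matrix(c("0/0", "0/1", "1/1")[call + 1L], nrow(call), ncol(call))
  gt[is.na(call)] <- "./."
  cells <- matrix(paste0(gt, ":", depth), nrow(call), ncol(call))
  chroms <- unique(as.character(seqnames(gr)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gbsCrossMap-simulator",
           paste0("##contig=<ID=", chroms, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(call)), collapse = "\t"))
  body <- paste(as.character(seqnames(gr)), start(gr), rownames(call),
                rowData(gm)$ref, rowData(gm)$alt, ".", "PASS", ".", "GT:DP",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the phenotype table of a simulated population
#'
#' @param truth a [TruthSet].
#' @param path output TSV (columns `sample`, `phenotype`).
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(truth, path) {
  utils::write.table(
    data.frame(sample = names(truth@phenotype),
               phenotype = truth@phenotype),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a raw GBS FASTQ for a simulated population
#'
#' Builds single-end reads with the two-enzyme GBS layout: sample barcode,
#' barcode-side restriction remnant, then genomic insert. Inserts are free of
#' internal full restriction sites (as real digested fragments are), except
#' that a fraction `chimeraRate` of reads carries one internal `AAGCTT` or
#' `CCGG` junction, and a fraction `adapterRate` comes from fragments shorter
#' than the read so the common-side remnant plus adapter appears downstream.
#' Fractions `barcodeFailRate`/`remnantFailRate` of reads have a corrupted
#' barcode (unassignable) or remnant (discardable). Per-sample read totals
#' follow the population's log-normal scale factors and so span more than an
#' order of magnitude. The per-read truth needed to audit demultiplexing is
#' returned as a per-sample count table.
#'
#' @param truth a [TruthSet].
#' @param fastq output FASTQ path.
#' @param key output barcode-key TSV path (`sample`, `barcode`).
#' @return A `data.frame` with one row per sample: reads emitted, reads
#'   assignable (clean barcode + remnant), chimera and adapter events among
#'   the assignable reads.
#' @export
simulateReads <- function(truth, fastq, key) {
  params <- truth@params
  samples <- truth@samples
  if (length(params@barcodes) < length(samples)) {
    stop("barcode_set smaller than the number of samples")
  }
  withSeed(childSeed(params@seed, 3L), {
    barcodes <- params@barcodes[seq_along(samples)]
    names(barcodes) <- samples
    counts <- as.vector(stats::rmultinom(1L, params@totalReads,
                                         truth@sampleScale))
    sampleOf <- rep(samples, counts)
    nr <- length(sampleOf)
    rl <- params@readLength
    brem <- params@barcodeRemnant
    crem <- params@commonRemnant
    ## independent event layers: barcode corruption, then remnant corruption,
    ## then chimera/adapter structure among clean reads
    event <- rep("ok", nr)
    event[stats::runif(nr) < params@barcodeFailRate] <- "bcfail"
    sel <- event == "ok"
    event[sel][stats::runif(sum(sel)) < params@remnantFailRate] <- "remfail"
    clean <- which(event == "ok")
    u <- stats::runif(length(clean))
    event[clean[u < params@chimeraRate]] <- "chimera"
    event[clean[u >= params@chimeraRate &
                u < params@chimeraRate + params@adapterRate]] <- "adapter"

    bc <- barcodes[sampleOf]
    bcl <- nchar(bc)
    insLen <- rl - bcl - nchar(brem)
    seqs <- character(nr)
    ok <- event %in% c("ok", "remfail", "bcfail")
    seqs[ok] <- paste0(bc[ok], brem,
                       cleanInserts(randomBases(insLen[ok])))
    isChim <- event == "chimera"
    if (any(isChim)) {
      site <- sample(c("AAGCTT", "CCGG"), sum(isChim), replace = TRUE)
      ## first-segment length chosen so the trimmed read stays >= minLen
      lo <- params@minLen - nchar(brem)
      hi <- rl - bcl[isChim] - nchar(brem) - nchar(site) - 1L
      l1 <- floor(stats::runif(sum(isChim), lo, hi + 1L))
      l2 <- rl - bcl[isChim] - nchar(brem) - l1 - nchar(site)
      seqs[isChim] <- paste0(bc[isChim], brem,
                             cleanInserts(randomBases(l1)), site,
                             cleanInserts(randomBases(l2)))
    }
    isAd <- event == "adapter"
    if (any(isAd)) {
      ## insert short enough that remnant + >= 4 adapter bases fit the read
      lo <- params@minLen - nchar(brem) - nchar(crem)
      hi <- rl - bcl[isAd] - nchar(brem) - nchar(crem) - 4L
      li <- floor(stats::runif(sum(isAd), lo, hi + 1L))
      full <- paste0(bc[isAd], brem, cleanInserts(randomBases(li)), crem,
                     paste0(params@adapter,
                            randomBases(rep(rl, sum(isAd)))))
      seqs[isAd] <- substr(full, 1L, rl)
    }
    ## corruptions: one N in the barcode, or a remnant base flipped/N'd
    isBc <- event == "bcfail"
    if (any(isBc)) {
      p <- floor(stats::runif(sum(isBc), 1L, bcl[isBc] + 1L))
      substr(seqs[isBc], p, p) <- "N"
    }
    isRem <- event == "remfail"
    if (any(isRem)) {
      idx <- which(isRem)
      p <- bcl[idx] + floor(stats::runif(length(idx), 1L, nchar(brem) + 1L))
      old <- substring(seqs[idx], p, p)
      repl <- ifelse(stats::runif(length(idx)) < 0.5, "N",
                     chartr("ACGT", "CATG", old))
      s <- seqs[idx]
      for (j in seq_along(idx)) substr(s[j], p[j], p[j]) <- repl[j]
      seqs[idx] <- s
    }
    ids <- sprintf("sim_%07d %s %s", seq_len(nr), sampleOf, event)
    ## one flat quality per read, Phred 30-38
    qchar <- substring(rawToChar(as.raw(63L + sample(0:8, nr, replace = TRUE))),
                       seq_len(nr), seq_len(nr))
    quals <- strrep(qchar, nchar(seqs))
    fq <- character(4L * nr)
    fq[seq(1L, by = 4L, length.out = nr)] <- paste0("@", ids)
    fq[seq(2L, by = 4L, length.out = nr)] <- seqs
    fq[seq(3L, by = 4L, length.out = nr)] <- "+"
    fq[seq(4L, by = 4L, length.out = nr)] <- quals
    writeLines(fq, fastq)
    utils::write.table(data.frame(sample = samples, barcode = barcodes),
                       key, sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- data.frame(sample = samples,
                      total = counts,
                      assignable = as.vector(table(factor(
                        sampleOf[!(event %in% c("bcfail", "remfail"))],
                        levels = samples))),
                      chimera = as.vector(table(factor(
                        sampleOf[event == "chimera"], levels = samples))),
                      adapter = as.vector(table(factor(
                        sampleOf[event == "adapter"], levels = samples))),
                      bcfail = as.vector(table(factor(
                        sampleOf[event == "bcfail"], levels = samples))),
                      remfail = as.vector(table(factor(
                        sampleOf[event == "remfail"], levels = samples))))
    tab
  })
}

## Random DNA of the given lengths (vectorized).
randomBases <- function(lens) {
  total <- sum(lens)
  if (total == 0L) return(rep("", length(lens)))
  all <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  groups <- rep.int(seq_along(lens), lens)
  out <- rep("", length(lens))
  out[lens > 0] <- vapply(split(all, groups), paste0, character(1),
                          collapse = "")
  out
}

## Remove chance internal restriction sites from inserts: digested fragments
## cannot contain an intact AAGCTT or CCGG. Each occurrence has one base
## rotated until none remain.
cleanInserts <- function(x) {
  repeat {
    hit <- regexpr("AAGCTT|CCGG", x)
    bad <- which(hit > 0)
    if (!length(bad)) return(x)
    p <- hit[bad] + 1L
    old <- substring(x[bad], p, p)
    new <- chartr("ACGT", "GTAC", old)
    for (j in seq_along(bad)) {
      substr(x[bad[j]], p[j], p[j]) <- new[j]
    }
  }
}

#' Export the simulator's ground-truth genetic map
#'
#' Builds a [GeneticMap-class] directly from a [TruthSet]: true marker
#' order and positions per chromosome, and the true linkage phase of every
#' heterozygous parent. Phases are expressed in the same observed-call
#' coding the mapping stages use (the homozygous parent of a
#' backcross-type marker is recoded to the reference allele based on its
#' *observed* genotype), so the result can be handed to [genotypeProbs()]
#' exactly like an estimated map. This isolates downstream stages — QTL
#' scans in particular — from map-estimation error.
#'
#' @param truth a [TruthSet].
#' @param gm the observed [GBSGenotypes-class] derived from `truth` (its
#'   parental calls define the allele coding).
#' @param markers which markers to place; defaults to every marker with an
#'   informative configuration under the observed parental calls.
#' @return A [GeneticMap-class] with one group per chromosome.
#' @export
truthMap <- function(truth, gm, markers = NULL) {
  stopifnot(is(truth, "TruthSet"))
  call <- genotypeCalls(gm)
  p1 <- parentId(gm, 1); p2 <- parentId(gm, 2)
  cfg <- as.character(classifyMarker(call[, p1], call[, p2]))
  names(cfg) <- rownames(call)
  if (is.null(markers)) {
    markers <- names(cfg)[cfg %in% c("ABxAA", "AAxAB", "ABxAB")]
  }
  tm <- truth@map[match(markers, truth@map$marker), ]
  ## canonical coding: flip when the homozygous parent is observed hom-alt
  flip1 <- !is.na(call[markers, p2]) & call[markers, p2] == 2L
  flip2 <- !is.na(call[markers, p1]) & call[markers, p1] == 2L
  canh1p1 <- ifelse(flip1, 1L - tm$p1h1, tm$p1h1)
  canh1p2 <- ifelse(flip2, 1L - tm$p2h1, tm$p2h1)
  grp <- as.integer(factor(tm$chrom, levels = unique(truth@map$chrom)))
  tb <- DataFrame(marker = tm$marker, group = grp,
                  bin = seq_along(markers), representative = TRUE,
                  posCM = tm$posCM,
                  phase1 = ifelse(cfg[markers] %in% c("ABxAA", "ABxAB"),
                                  canh1p1, NA_integer_),
                  phase2 = ifelse(cfg[markers] %in% c("AAxAB", "ABxAB"),
                                  canh1p2, NA_integer_),
                  config = cfg[markers])
  tb <- tb[order(tb$group, tb$posCM, tb$marker), ]
  new("GeneticMap", table = tb, unlinked = character(),
      dropped = character())
}

#' Plant Mendelian-impossible offspring calls for masking tests
#'
#' Overwrites `k` called offspring cells at informative markers with a
#' genotype impossible under the parental cross (for example a hom-alt
#' offspring under an AB x AA cross), leaving depth intact, so the Mendelian
#' masking stage can be audited cell-for-cell.
#'
#' @param gm a [GBSGenotypes-class] with both parents called at some markers.
#' @param k number of cells to corrupt.
#' @param seed RNG seed.
#' @return list with elements `genotypes` (modified object) and `cells`
#'   (data.frame of marker, sample and injected call).
#' @export
injectViolations <- function(gm, k, seed = 1L) {
  call <- genotypeCalls(gm)
  p1 <- parentId(gm, 1); p2 <- parentId(gm, 2)
  off <- offspringIds(gm)
  g1 <- call[, p1]; g2 <- call[, p2]
  impossible <- impossibleCalls(g1, g2)   # markers x 3 logical
  withSeed(seed, {
    elig <- which(!is.na(call[, off, drop = FALSE]) &
                  rowSums(impossible, na.rm = TRUE)[row(call[, off])] > 0)
    stopifnot(length(elig) >= k)
    pick <- sample(elig, k)
    mk <- ((pick - 1L) %% nrow(call)) + 1L
    sm <- off[((pick - 1L) %/% nrow(call)) + 1L]
    newCall <- integer(k)
    for (j in seq_len(k)) {
      opts <- which(impossible[mk[j], ]) - 1L
      opts <- setdiff(opts, call[mk[j], sm[j]])
      if (!length(opts)) opts <- which(impossible[mk[j], ]) - 1L
      newCall[j] <- opts[1L]
      call[mk[j], sm[j]] <- opts[1L]
    }
    se <- gm
    SummarizedExperiment::assay(se, "call") <- call
    list(genotypes = se,
         cells = data.frame(marker = rownames(call)[mk], sample = sm,
                            call = newCall))
  })
}

## markers x 3 logical matrix: which offspring dosages are impossible given
## called parental genotypes (NA parents -> nothing impossible).
impossibleCalls <- function(g1, g2) {
  poss <- function(g) {
    ## set of alleles a parent can transmit
    switch(as.character(g), "0" = 0L, "1" = c(0L, 1L), "2" = 1L, NULL)
  }
  out <- matrix(FALSE, length(g1), 3L)
  for (i in seq_along(g1)) {
    if (is.na(g1[i]) || is.na(g2[i])) next
    doses <- unique(outer(poss(g1[i]), poss(g2[i]), "+"))
    out[i, ] <- !(0:2 %in% doses)
  }
  out
}
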