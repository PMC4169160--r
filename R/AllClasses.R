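#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData rowData
NULL

## ---------------------------------------------------------------------------
## SimParams
## ---------------------------------------------------------------------------

#' Simulation parameters for a synthetic F1 GBS experiment
#'
#' `SimParams` bundles every knob of the built-in simulator: the cross design
#' (offspring count, chromosome number and map lengths, marker density,
#' parental-configuration mix), the planted binary QTL (chromosome, position,
#' segregating parent, penetrances), the read-depth model (negative-binomial
#' per cell with a log-normal per-sample scale), and the read-level layout of
#' a two-enzyme GBS library (barcodes, restriction-site remnants, adapter,
#' chimera/adapter read-through rates). Defaults mirror the design of a
#' 96-plex apple F1 skin-colour experiment: 87 offspring plus 2 parents,
#' 17 chromosomes, a fully penetrant QTL segregating from parent 2, and read
#' artefact rates of ~1.0% chimeras, ~1.2% adapter read-through, 1.8%
#' unassignable barcodes and 1% invalid remnants.
#'
#' @slot nOffspring integer, F1 progeny count.
#' @slot nChromosomes integer.
#' @slot chromLengthCM numeric, per-chromosome map length in cM (recycled).
#' @slot markersPerChrom integer, candidate SNP markers per chromosome.
#' @slot configProbs named numeric over `ABxAA`, `AAxAB`, `ABxAB`,
#'   `UNINFORMATIVE`; sums to 1.
#' @slot qtlChrom,qtlPosCM,qtlParent planted QTL location and the parent
#'   (1 or 2) in which it is heterozygous.
#' @slot penetranceRef,penetranceAlt probability of phenotype 1 given the
#'   offspring inherited the reference (resp. alternate) QTL allele from the
#'   segregating parent.
#' @slot depthMean,depthSize negative-binomial mean and size (dispersion) of
#'   per-cell read depth before per-sample scaling.
#' @slot scaleSdlog sdlog of the log-normal per-sample depth/read scale.
#' @slot parentScale extra depth/read multiplier for the two parents
#'   (emulates sequencing the parents at higher depth; 1 = same as
#'   offspring).
#' @slot errorRate per-base miscall probability applied to allele sampling.
#' @slot barcodes character, barcode set (prefix-free); at least one per
#'   sample.
#' @slot barcodeRemnant,commonRemnant barcode-side (HindIII, `AGCTT`) and
#'   common-side (MspI, `CCGG`) restriction-site remnants.
#' @slot adapter common-adapter sequence seen on read-through.
#' @slot chimeraRate,adapterRate per-read probabilities of an internal
#'   restriction site and of adapter read-through.
#' @slot barcodeFailRate,remnantFailRate per-read probabilities that the
#'   barcode (resp. remnant) region is corrupted and the read unassignable.
#' @slot readLength,totalReads,minLen FASTQ read length, total reads emitted,
#'   and the minimum post-trim length the demultiplexer keeps.
#' @slot seed integer master seed.
#' @seealso [simParams()], [simulatePopulation()]
#' @export
setClass("SimParams", representation(
  nOffspring = "integer", nChromosomes = "integer",
  chromLengthCM = "numeric", markersPerChrom = "integer",
  configProbs = "numeric",
  qtlChrom = "integer", qtlPosCM = "numeric", qtlParent = "integer",
  penetranceRef = "numeric", penetranceAlt = "numeric",
  depthMean = "numeric", depthSize = "numeric", scaleSdlog = "numeric",
  parentScale = "numeric", errorRate = "numeric",
  barcodes = "character", barcodeRemnant = "character",
  commonRemnant = "character", adapter = "character",
  chimeraRate = "numeric", adapterRate = "numeric",
  barcodeFailRate = "numeric", remnantFailRate = "numeric",
  readLength = "integer", totalReads = "numeric", minLen = "integer",
  seed = "numeric"
))

setValidity("SimParams", function(object) {
  msg <- character()
  probs <- c(object@configProbs, object@chimeraRate, object@adapterRate,
             object@barcodeFailRate, object@remnantFailRate,
             object@penetranceRef, object@penetranceAlt, object@errorRate)
  if (any(probs < 0 | probs > 1)) {
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  }
  if (abs(sum(object@configProbs) - 1) > 1e-8) {
    msg <- c(msg, "configProbs must sum to 1")
  }
  if (!identical(sort(names(object@configProbs)),
                 sort(c("ABxAA", "AAxAB", "ABxAB", "UNINFORMATIVE")))) {
    msg <- c(msg, "configProbs must be named ABxAA, AAxAB, ABxAB, UNINFORMATIVE")
  }
  if (any(object@chromLengthCM < 0)) {
    msg <- c(msg, "chromLengthCM must be non-negative")
  }
  if (object@nOffspring < 1) msg <- c(msg, "nOffspring must be >= 1")
  if (object@penetranceRef == object@penetranceAlt) {
    msg <- c(msg, "penetranceRef must differ from penetranceAlt")
  }
  if (!(object@qtlParent %in% 1:2)) msg <- c(msg, "qtlParent must be 1 or 2")
  if (object@qtlChrom < 1 || object@qtlChrom > object@nChromosomes) {
    msg <- c(msg, "qtlChrom outside the simulated genome")
  }
  if (any(nchar(object@barcodes) < 1) || anyDuplicated(object@barcodes)) {
    msg <- c(msg, "barcodes must be non-empty and unique")
  }
  if (any(nchar(object@barcodes) >= object@readLength)) {
    msg <- c(msg, "barcodes must be shorter than readLength")
  }
  ## prefix-freeness so longest-match assignment is unambiguous
  bc <- object@barcodes
  if (length(bc) > 1) {
    ord <- order(nchar(bc))
    for (i in seq_along(ord)[-length(ord)]) {
      short <- bc[ord[i]]
      longer <- bc[ord[-seq_len(i)]]
      if (any(startsWith(longer, short))) {
        msg <- c(msg, "barcodes must be mutually prefix-free")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SimParams Constructor with study-design defaults.
#' @param nOffspring,nChromosomes,chromLengthCM,markersPerChrom,configProbs
#'   cross design; see slots.
#' @param qtlChrom,qtlPosCM,qtlParent,penetranceRef,penetranceAlt planted QTL.
#' @param depthMean,depthSize,scaleSdlog,parentScale,errorRate genotyping
#'   depth model.
#' @param barcodes,barcodeRemnant,commonRemnant,adapter read layout.
#' @param chimeraRate,adapterRate,barcodeFailRate,remnantFailRate read
#'   artefact rates.
#' @param readLength,totalReads,minLen FASTQ geometry.
#' @param seed integer master seed.
#' @return A validated `SimParams` object.
#' @export
simParams <- function(nOffspring = 87L, nChromosomes = 17L,
                      chromLengthCM = 75, markersPerChrom = 120L,
                      configProbs = c(ABxAA = 0.33, AAxAB = 0.39,
                                      ABxAB = 0.19, UNINFORMATIVE = 0.09),
                      qtlChrom = 9L, qtlPosCM = 55, qtlParent = 2L,
                      penetranceRef = 0, penetranceAlt = 1,
                      depthMean = 3, depthSize = 0.3, scaleSdlog = 0.8,
                      parentScale = 1, errorRate = 0.002,
                      barcodes = defaultBarcodes(96L),
                      barcodeRemnant = "AGCTT", commonRemnant = "CCGG",
                      adapter = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
                      chimeraRate = 0.010, adapterRate = 0.012,
                      barcodeFailRate = 0.018, remnantFailRate = 0.010,
                      readLength = 100L, totalReads = 1e5, minLen = 30L,
                      seed = 1L) {
  new("SimParams",
      nOffspring = as.integer(nOffspring),
      nChromosomes = as.integer(nChromosomes),
      chromLengthCM = rep_len(as.numeric(chromLengthCM),
                              as.integer(nChromosomes)),
      markersPerChrom = as.integer(markersPerChrom),
      configProbs = configProbs[c("ABxAA", "AAxAB", "ABxAB", "UNINFORMATIVE")],
      qtlChrom = as.integer(qtlChrom), qtlPosCM = as.numeric(qtlPosCM),
      qtlParent = as.integer(qtlParent),
      penetranceRef = penetranceRef, penetranceAlt = penetranceAlt,
      depthMean = depthMean, depthSize = depthSize, scaleSdlog = scaleSdlog,
      parentScale = parentScale, errorRate = errorRate, barcodes = barcodes,
      barcodeRemnant = barcodeRemnant, commonRemnant = commonRemnant,
      adapter = adapter, chimeraRate = chimeraRate, adapterRate = adapterRate,
      barcodeFailRate = barcodeFailRate, remnantFailRate = remnantFailRate,
      readLength = as.integer(readLength), totalReads = as.numeric(totalReads),
      minLen = as.integer(minLen), seed = as.numeric(seed))
}

#' Default prefix-free barcode set
#'
#' Deterministically generates `n` distinct 6-mer barcodes (equal length, so
#' trivially prefix-free) with no homopolymer runs longer than 3.
#'
#' @param n number of barcodes.
#' @return Character vector of length `n`.
#' @export
defaultBarcodes <- function(n = 96L) {
  bases <- c("A", "C", "G", "T")
  idx <- expand.grid(rep(list(seq_len(4L)), 6L))
  codes <- apply(idx, 1L, function(i) paste0(bases[i], collapse = ""))
  codes <- codes[!grepl("A{4}|C{4}|G{4}|T{4}", codes)]
  ## fixed stride walk through the code space: spread out, reproducible
  stopifnot(n <= length(codes))
  codes[(seq_len(n) * 7L) %% length(codes) + 1L]
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nOffspring, "offspring + 2 parents,",
      object@nChromosomes, "chromosomes,",
      object@markersPerChrom, "markers/chrom\n")
  cat("  QTL: chrom", object@qtlChrom, "at", object@qtlPosCM,
      "cM, heterozygous in parent", object@qtlParent,
      sprintf("(penetrance %.2f/%.2f)\n",
              object@penetranceRef, object@penetranceAlt))
  cat(sprintf("  depth: NB(mean=%.2g, size=%.2g), sample scale sdlog=%.2g\n",
              object@depthMean, object@depthSize, object@scaleSdlog))
  cat(sprintf("  reads: %g x %d bp, chimera %.1f%%, adapter %.1f%%\n",
              object@totalReads, object@readLength,
              100 * object@chimeraRate, 100 * object@adapterRate))
})

## ---------------------------------------------------------------------------
## TruthSet
## ---------------------------------------------------------------------------

#' Ground truth of a simulated F1 population
#'
#' Holds everything the simulator knows and the pipeline must recover:
#' phased parental haplotypes per marker, each offspring's transmitted
#' homolog at every marker (hence all crossovers), the true marker order and
#' genetic positions, the QTL allele transmitted by the segregating parent,
#' and the binary phenotype of every sample.
#'
#' @slot params the generating [SimParams].
#' @slot samples character, sample ids; first two are the parents.
#' @slot map `DataFrame` with one row per marker: id, chromosome, genetic
#'   position (cM), physical position (bp), configuration, phased parental
#'   haplotype alleles (`p1h1`, `p1h2`, `p2h1`, `p2h2`; alt-allele dosage of
#'   each homolog), and REF/ALT bases.
#' @slot trans1,trans2 integer matrices (offspring x markers) of the homolog
#'   (0/1) transmitted by parent 1 (resp. 2) at each marker.
#' @slot qtlAllele integer, alt-dosage (0/1) of the QTL allele each offspring
#'   inherited from the segregating parent.
#' @slot phenotype named integer 0/1 per sample (parents included).
#' @slot sampleScale numeric, per-sample DNA-quantity scale (log-normal,
#'   mean 1) shared by the read-count and depth models.
#' @export
setClass("TruthSet", representation(
  params = "SimParams", samples = "character", map = "DataFrame",
  trans1 = "matrix", trans2 = "matrix",
  qtlAllele = "integer", phenotype = "integer", sampleScale = "numeric"
))

setValidity("TruthSet", function(object) {
  n <- object@params@nOffspring
  m <- nrow(object@map)
  msg <- character()
  if (!all(dim(object@trans1) == c(n, m)) ||
      !all(dim(object@trans2) == c(n, m))) {
    msg <- c(msg, "transmission matrices must be offspring x markers")
  }
  if (!all(object@phenotype %in% 0:1)) {
    msg <- c(msg, "phenotypes must be 0/1")
  }
  if (length(object@samples) != n + 2L) {
    msg <- c(msg, "samples must be 2 parents + offspring")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", length(object@samples), "samples (2 parents),",
      nrow(object@map), "markers on",
      object@params@nChromosomes, "chromosomes\n")
  cat("  phenotype prevalence among offspring:",
      sprintf("%.2f\n", mean(object@phenotype[-(1:2)])))
})

#' True genotype dosage matrix of a simulated population
#'
#' @param truth a [TruthSet].
#' @return Integer matrix (markers x samples) of alt-allele dosages 0/1/2;
#'   columns are parent1, parent2, then offspring.
#' @export
trueGenotypes <- function(truth) {
  stopifnot(is(truth, "TruthSet"))
  map <- truth@map
  n <- truth@params@nOffspring
  p1 <- map$p1h1 + map$p1h2
  p2 <- map$p2h1 + map$p2h2
  h1 <- cbind(map$p1h1, map$p1h2)   # markers x 2 homolog alleles
  h2 <- cbind(map$p2h1, map$p2h2)
  m <- nrow(map)
  off <- matrix(0L, nrow = m, ncol = n)
  for (i in seq_len(n)) {
    a1 <- h1[cbind(seq_len(m), truth@trans1[i, ] + 1L)]
    a2 <- h2[cbind(seq_len(m), truth@trans2[i, ] + 1L)]
    off[, i] <- as.integer(a1 + a2)
  }
  out <- cbind(p1, p2, off)
  dimnames(out) <- list(map$marker, truth@samples)
  out
}

## ---------------------------------------------------------------------------
## GBSGenotypes
## ---------------------------------------------------------------------------

#' Sparse GBS genotype matrix
#'
#' `GBSGenotypes` extends `RangedSummarizedExperiment` with two assays over
#' markers (rows) and samples (columns): `call` (alt-allele dosage 0 =
#' hom-ref, 1 = het, 2 = hom-alt, `NA` = missing) and `depth` (supporting
#' read count). Marker coordinates and REF/ALT alleles live in `rowRanges`;
#' each sample's role (`parent1`, `parent2`, `offspring`) in `colData$role`.
#'
#' @export
setClass("GBSGenotypes", contains = "RangedSummarizedExperiment")

setValidity("GBSGenotypes", function(object) {
  msg <- character()
  if (!all(c("call", "depth") %in% names(assays(object)))) {
    return("assays 'call' and 'depth' are required")
  }
  cl <- assay(object, "call")
  dp <- assay(object, "depth")
  if (!all(cl %in% c(0L, 1L, 2L, NA))) {
    msg <- c(msg, "calls must be 0/1/2/NA")
  }
  if (any(dp < 0, na.rm = TRUE)) msg <- c(msg, "depths must be non-negative")
  if (is.null(colData(object)$role) ||
      !all(colData(object)$role %in% c("parent1", "parent2", "offspring"))) {
    msg <- c(msg, "colData$role must be parent1/parent2/offspring")
  } else {
    if (sum(colData(object)$role == "parent1") > 1 ||
        sum(colData(object)$role == "parent2") > 1) {
      msg <- c(msg, "at most one sample per parental role")
    }
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "marker ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GBSGenotypes object
#'
#' @param call integer matrix (markers x samples), values 0/1/2/NA.
#' @param depth non-negative integer matrix, same shape.
#' @param chrom,pos marker chromosome and 1-based physical position.
#' @param ref,alt marker alleles (single bases).
#' @param roles character per sample: `parent1`, `parent2` or `offspring`.
#' @return A [GBSGenotypes-class] object.
#' @export
GBSGenotypes <- function(call, depth, chrom, pos, ref, alt, roles) {
  stopifnot(all(dim(call) == dim(depth)),
            length(chrom) == nrow(call), length(roles) == ncol(call))
  if (is.null(rownames(call)) && nrow(call) > 0L) {
    rownames(call) <- paste0(chrom, "_", pos)
  }
  gr <- GRanges(chrom, IRanges(pos, width = 1L), ref = ref, alt = alt)
  names(gr) <- rownames(call)
  mode(call) <- "integer"
  mode(depth) <- "integer"
  rownames(depth) <- rownames(call)
  se <- SummarizedExperiment(
    assays = SimpleList(call = call, depth = depth),
    rowRanges = gr,
    colData = DataFrame(role = roles, row.names = colnames(call))
  )
  new("GBSGenotypes", se)
}

#' @describeIn GBSGenotypes-class the call matrix (markers x samples).
#' @param x a `GBSGenotypes` object.
#' @export
genotypeCalls <- function(x) assay(x, "call")

#' @describeIn GBSGenotypes-class the depth matrix.
#' @export
readDepth <- function(x) assay(x, "depth")

#' @describeIn GBSGenotypes-class named role vector.
#' @export
sampleRoles <- function(x) setNames(colData(x)$role, colnames(x))

#' @describeIn GBSGenotypes-class ids of the offspring samples.
#' @export
offspringIds <- function(x) colnames(x)[colData(x)$role == "offspring"]

#' @describeIn GBSGenotypes-class id of a parent sample (or NA if absent).
#' @param which 1 or 2.
#' @export
parentId <- function(x, which = 1) {
  id <- colnames(x)[colData(x)$role == paste0("parent", which)]
  if (length(id)) id else NA_character_
}

setMethod("show", "GBSGenotypes", function(object) {
  cl <- genotypeCalls(object)
  cat("GBSGenotypes:", nrow(object), "markers x", ncol(object), "samples (",
      sum(colData(object)$role == "offspring"), "offspring )\n")
  cat(sprintf("  missing calls: %.1f%%; median depth of called cells: %s\n",
              100 * mean(is.na(cl)),
              stats::median(readDepth(object)[!is.na(cl)])))
})

## ---------------------------------------------------------------------------
## GeneticMap
## ---------------------------------------------------------------------------

#' A composite pseudo-testcross genetic map
#'
#' One row per mapped marker: linkage group, co-segregation bin, whether the
#' marker is the bin representative, position in Kosambi cM, and the inferred
#' linkage phase of each parent (0/1 relative to the group's reference
#' homolog; `NA` where the parent is homozygous). Markers assigned to no
#' group are listed in `unlinked`.
#'
#' @slot table `DataFrame`: marker, group, bin, representative, posCM,
#'   phase1, phase2, config.
#' @slot unlinked character, unlinked marker ids.
#' @slot dropped character, markers removed as misfits during ordering.
#' @export
setClass("GeneticMap", representation(
  table = "DataFrame", unlinked = "character", dropped = "character"
))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  need <- c("marker", "group", "bin", "representative", "posCM",
            "phase1", "phase2", "config")
  if (!all(need %in% colnames(tb))) {
    return(paste("map table needs columns:", paste(need, collapse = ", ")))
  }
  msg <- character()
  for (g in unique(tb$group)) {
    p <- tb$posCM[tb$group == g]
    if (is.unsorted(sort(p))) msg <- c(msg, "positions must be orderable")
  }
  if (any(tb$posCM < 0)) msg <- c(msg, "cM positions must be >= 0")
  if (anyDuplicated(tb$marker)) msg <- c(msg, "duplicate marker in map")
  if (length(intersect(tb$marker, object@unlinked))) {
    msg <- c(msg, "a marker cannot be both mapped and unlinked")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneticMap-class per-marker map table as a `DataFrame`.
#' @param x a `GeneticMap`.
#' @export
mapTable <- function(x) x@table

#' @describeIn GeneticMap-class number of linkage groups.
#' @export
nLinkageGroups <- function(x) length(unique(x@table$group))

#' @describeIn GeneticMap-class total map length (sum of group spans, cM).
#' @export
mapLength <- function(x) {
  sum(vapply(split(x@table$posCM, x@table$group),
             function(p) max(p) - min(p), numeric(1)))
}

#' @describeIn GeneticMap-class ids of unlinked markers.
#' @export
unlinkedMarkers <- function(x) x@unlinked

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  spans <- vapply(split(tb$posCM, tb$group), max, numeric(1))
  cat("GeneticMap:", nrow(tb), "markers in", length(spans),
      "linkage groups,", sprintf("%.0f cM total\n", mapLength(object)))
  cat("  group spans:", paste(sprintf("%.0f", sort(spans)), collapse = " "),
      "\n  unlinked:", length(object@unlinked),
      " dropped:", length(object@dropped), "\n")
})

## ---------------------------------------------------------------------------
## QTLScan
## ---------------------------------------------------------------------------

#' Result of a binary-trait interval-mapping scan
#'
#' @slot scan `DataFrame`: group, posCM, lod at each grid position.
#' @slot threshold genome-wide LOD significance threshold from permutations.
#' @slot nPerm number of phenotype permutations used.
#' @slot alpha genome-wide error rate of the threshold.
#' @slot parent which parent's meioses were scanned (1 or 2).
#' @slot peak `DataFrame` row: group, posCM, lod of the maximum.
#' @slot interval `DataFrame`: group, lo, hi of the 2-LOD support interval.
#' @slot permMax numeric, the permutation null distribution of max LOD.
#' @export
setClass("QTLScan", representation(
  scan = "DataFrame", threshold = "numeric", nPerm = "integer",
  alpha = "numeric", parent = "integer", peak = "DataFrame",
  interval = "DataFrame", permMax = "numeric"
))

setValidity("QTLScan", function(object) {
  msg <- character()
  if (any(object@scan$lod < -1e-8, na.rm = TRUE)) {
    msg <- c(msg, "LOD scores must be non-negative")
  }
  if (nrow(object@peak) == 1 && nrow(object@interval) == 1) {
    if (object@peak$group == object@interval$group &&
        (object@peak$posCM < object@interval$lo - 1e-8 ||
         object@peak$posCM > object@interval$hi + 1e-8)) {
      msg <- c(msg, "support interval must contain the peak")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn QTLScan-class the per-position LOD table.
#' @param x a `QTLScan`.
#' @export
scanTable <- function(x) x@scan

#' @describeIn QTLScan-class the permutation LOD threshold.
#' @export
lodThreshold <- function(x) x@threshold

#' @describeIn QTLScan-class the peak (group, posCM, lod).
#' @export
qtlPeak <- function(x) x@peak

#' @describeIn QTLScan-class the 2-LOD support interval.
#' @export
supportInterval <- function(x) x@interval

setMethod("show", "QTLScan", function(object) {
  cat("QTLScan (parent", object@parent, "meioses):",
      nrow(object@scan), "positions\n")
  if (nrow(object@peak)) {
    cat(sprintf("  peak: group %s at %.1f cM, LOD %.2f\n",
                object@peak$group, object@peak$posCM, object@peak$lod))
  }
  if (length(object@threshold)) {
    cat(sprintf("  genome-wide threshold (alpha %.2f, %d permutations): %.2f\n",
                object@alpha, object@nPerm, object@threshold))
  }
  if (nrow(object@interval)) {
    cat(sprintf("  2-LOD support interval: %.1f-%.1f cM\n",
                object@interval$lo, object@interval$hi))
  }
})

## ---------------------------------------------------------------------------
## DemuxReport
## ---------------------------------------------------------------------------

#' Demultiplexing quality-control report
#'
#' @slot perSample `DataFrame`: sample, emitted read count.
#' @slot counts named numeric of global dispositions: total, matched,
#'   unmatched, ambiguousDiscard, remnantInvalid, chimeraTrimmed,
#'   adapterTrimmed, lengthDiscarded, emitted. `matched` counts reads whose
#'   barcode resolved; `chimeraTrimmed`/`adapterTrimmed` are trimming event
#'   tallies among emitted + length-discarded reads.
#' @export
setClass("DemuxReport", representation(
  perSample = "DataFrame", counts = "numeric"
))

setValidity("DemuxReport", function(object) {
  cts <- object@counts
  need <- c("total", "matched", "unmatched", "ambiguousDiscard",
            "remnantInvalid", "chimeraTrimmed", "adapterTrimmed",
            "lengthDiscarded", "emitted")
  if (!all(need %in% names(cts))) {
    return(paste("counts needs:", paste(need, collapse = ", ")))
  }
  msg <- character()
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  ## disposition partition of the input
  if (cts[["unmatched"]] + cts[["ambiguousDiscard"]] + cts[["remnantInvalid"]] +
      cts[["lengthDiscarded"]] + cts[["emitted"]] != cts[["total"]]) {
    msg <- c(msg, "dispositions must partition the input reads")
  }
  if (sum(object@perSample$reads) != cts[["emitted"]]) {
    msg <- c(msg, "per-sample reads must sum to emitted")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DemuxReport", function(object) {
  cts <- object@counts
  cat("DemuxReport:", cts[["total"]], "reads;",
      sprintf("%.1f%% barcode-matched, %.1f%% of matched remnant-valid\n",
              100 * cts[["matched"]] / max(cts[["total"]], 1),
              100 * (cts[["matched"]] - cts[["ambiguousDiscard"]] -
                     cts[["remnantInvalid"]]) / max(cts[["matched"]], 1)))
  cat(sprintf("  trimmed: %.2f%% chimeric, %.2f%% adapter; emitted %d reads to %d samples\n",
              100 * cts[["chimeraTrimmed"]] / max(cts[["total"]], 1),
              100 * cts[["adapterTrimmed"]] / max(cts[["total"]], 1),
              as.integer(cts[["emitted"]]), nrow(object@perSample)))
})
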