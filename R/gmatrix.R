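#' Load a multi-sample VCF into a GBSGenotypes matrix
#'
#' Reads a VCF (via `VariantAnnotation`), keeps biallelic SNP records only,
#' and populates the call/depth assays. Depth is taken from the `DP` genotype
#' field, falling back to summed allelic depths (`AD`) when `DP` is absent.
#'
#' @param vcf path to a VCF 4.x file (plain or bgzipped).
#' @param roles named character mapping every VCF sample to
#'   `parent1`/`parent2`/`offspring`.
#' @return A [GBSGenotypes-class]; the number of excluded non-biallelic/
#'   non-SNP records is recorded in `metadata()$excluded`.
#' @export
loadVCF <- function(vcf, roles) {
  v <- VariantAnnotation::readVcf(vcf)
  vcfSamples <- colnames(v)
  if (!all(vcfSamples %in% names(roles))) {
    stop("no role assigned for VCF sample(s): ",
         paste(setdiff(vcfSamples, names(roles)), collapse = ", "))
  }
  rr <- SummarizedExperiment::rowRanges(v)
  refA <- as.character(rr$REF)
  altL <- rr$ALT
  biallelic <- S4Vectors::elementNROWS(altL) == 1L
  altA <- rep(NA_character_, length(altL))
  altA[biallelic] <- as.character(unlist(altL[biallelic]))
  snp <- biallelic & nchar(refA) == 1L & !is.na(altA) & nchar(altA) == 1L &
    refA %in% c("A", "C", "G", "T") & altA %in% c("A", "C", "G", "T")
  excluded <- sum(!snp)
  v <- v[snp]
  refA <- refA[snp]; altA <- altA[snp]

  g <- VariantAnnotation::geno(v)
  if (!("GT" %in% names(g))) stop("VCF has no GT field")
  gt <- g$GT
  call <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  call[gt %in% c("0/0", "0|0")] <- 0L
  call[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  call[gt %in% c("1/1", "1|1")] <- 2L
  if ("DP" %in% names(g)) {
    depth <- g$DP
    depth[is.na(depth)] <- 0L
  } else if ("AD" %in% names(g)) {
    ad <- g$AD
    depth <- matrix(vapply(ad, function(x) sum(x, na.rm = TRUE), integer(1)),
                    nrow(gt), ncol(gt), dimnames = dimnames(gt))
  } else {
    stop("VCF has neither DP nor AD; supply a depth source")
  }
  call[depth == 0L] <- NA_integer_
  gr <- SummarizedExperiment::rowRanges(v)
  gm <- GBSGenotypes(call, depth,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     pos = GenomicRanges::start(gr),
                     ref = refA, alt = altA,
                     roles = unname(roles[colnames(call)]))
  metadata(gm)$excluded <- excluded
  gm
}

#' Mask genotype calls below a depth threshold
#'
#' Any call supported by fewer than `minDP` reads is set to missing; nothing
#' else changes. `minDP = 0` is the identity.
#'
#' @param gm a [GBSGenotypes-class].
#' @param minDP minimum supporting read count for a call to survive.
#' @return The masked [GBSGenotypes-class].
#' @export
maskByDepth <- function(gm, minDP = 6L) {
  stopifnot(minDP >= 0)
  call <- genotypeCalls(gm)
  call[readDepth(gm) < minDP] <- NA_integer_
  SummarizedExperiment::assay(gm, "call") <- call
  gm
}

#' Filter markers by minor allele frequency and missingness
#'
#' The minor allele frequency is computed over called genotypes only (each
#' homozygote contributes two copies of its allele, each heterozygote one of
#' each); the missing fraction is over all samples. A marker is kept iff
#' `MAF >= mafMin` and `missing fraction <= missMax`. Marker order is
#' preserved and the filter is idempotent.
#'
#' @param gm a [GBSGenotypes-class].
#' @param mafMin minimum minor allele frequency (0 disables).
#' @param missMax maximum tolerated missing-call fraction (1 disables).
#' @return The filtered [GBSGenotypes-class].
#' @export
filterMarkers <- function(gm, mafMin = 0.2, missMax = 0.2) {
  stopifnot(mafMin >= 0, mafMin <= 1, missMax >= 0, missMax <= 1)
  call <- genotypeCalls(gm)
  nCalled <- rowSums(!is.na(call))
  altCount <- rowSums(call, na.rm = TRUE)
  p <- ifelse(nCalled > 0, altCount / (2 * nCalled), NA_real_)
  maf <- pmin(p, 1 - p)
  missFrac <- 1 - nCalled / ncol(call)
  keep <- !is.na(maf) & maf >= mafMin & missFrac <= missMax
  gm[keep, ]
}

#' Sparsity profile of a genotype matrix
#'
#' Three monotone summaries of how marker and genotype counts respond to
#' missing-data and depth thresholds:
#' \describe{
#'   \item{missingness}{SNP count whose missing fraction is at most each
#'     threshold (cumulative across thresholds).}
#'   \item{depth}{among markers passing `missMax`, the number of called
#'     genotypes supported by at least each depth.}
#'   \item{minDepth}{SNP count surviving depth masking at each minimum depth
#'     followed by re-filtering at `missMax` missingness.}
#' }
#'
#' @param gm a [GBSGenotypes-class].
#' @param missThresholds missing-fraction grid for the first table.
#' @param depthThresholds depth grid for the second and third tables.
#' @param missMax missingness ceiling applied in the depth-dependent tables.
#' @return list of three `data.frame`s: `missingness` (threshold, nSNP),
#'   `depth` (minDepth, nGenotypes), `minDepth` (minDepth, nSNP).
#' @export
sparsityProfile <- function(gm, missThresholds = seq(0, 1, 0.1),
                            depthThresholds = 1:20, missMax = 0.2) {
  call <- genotypeCalls(gm)
  depth <- readDepth(gm)
  missFrac <- rowMeans(is.na(call))
  missTab <- data.frame(
    threshold = missThresholds,
    nSNP = vapply(missThresholds, function(t) sum(missFrac <= t), numeric(1)))
  pass <- missFrac <= missMax
  dSub <- depth[pass, , drop = FALSE]
  cSub <- call[pass, , drop = FALSE]
  dCalled <- dSub[!is.na(cSub)]
  depthTab <- data.frame(
    minDepth = depthThresholds,
    nGenotypes = vapply(depthThresholds, function(d) sum(dCalled >= d),
                        numeric(1)))
  minDepthTab <- data.frame(
    minDepth = depthThresholds,
    nSNP = vapply(depthThresholds, function(d) {
      masked <- call
      masked[depth < d] <- NA_integer_
      sum(rowMeans(is.na(masked)) <= missMax)
    }, numeric(1)))
  list(missingness = missTab, depth = depthTab, minDepth = minDepthTab)
}

#' Export a genotype matrix as PLINK-style transposed text
#'
#' Writes a TPED-like file (chrom, marker, cM, bp, then two allele columns
#' per sample) and a matching TFAM-like sample file with the binary
#' phenotype.
#'
#' @param gm a [GBSGenotypes-class].
#' @param prefix output path prefix; writes `<prefix>.tped` and
#'   `<prefix>.tfam`.
#' @param phenotype optional named 0/1 vector per sample.
#' @return The two paths, invisibly.
#' @export
writePlink <- function(gm, prefix, phenotype = NULL) {
  call <- genotypeCalls(gm)
  gr <- rowRanges(gm)
  ref <- rowData(gm)$ref
  alt <- rowData(gm)$alt
  m <- nrow(call)
  a1 <- matrix("0", m, ncol(call))
  a2 <- matrix("0", m, ncol(call))
  refm <- matrix(ref, m, ncol(call))
  altm <- matrix(alt, m, ncol(call))
  a1[!is.na(call) & call <= 1] <- refm[!is.na(call) & call <= 1]
  a1[!is.na(call) & call == 2] <- altm[!is.na(call) & call == 2]
  a2[!is.na(call) & call == 0] <- refm[!is.na(call) & call == 0]
  a2[!is.na(call) & call >= 1] <- altm[!is.na(call) & call >= 1]
  inter <- matrix("", m, 2L * ncol(call))
  inter[, seq(1L, by = 2L, length.out = ncol(call))] <- a1
  inter[, seq(2L, by = 2L, length.out = ncol(call))] <- a2
  tped <- cbind(as.character(seqnames(gr)), rownames(call), "0",
                as.character(start(gr)), inter)
  utils::write.table(tped, paste0(prefix, ".tped"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ph <- if (is.null(phenotype)) rep(-9, ncol(call)) else
    phenotype[colnames(call)] + 1L
  tfam <- data.frame(fam = colnames(call), id = colnames(call),
                     pat = 0, mat = 0, sex = 0, pheno = ph)
  utils::write.table(tfam, paste0(prefix, ".tfam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".tped"), paste0(prefix, ".tfam")))
}
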