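#' Pipeline configuration
#'
#' Collects every stage threshold of the GBS mapping pipeline with defaults
#' at the values the method was designed around: depth mask 6 reads, MAF
#' 0.2, missingness 20%, segregation alpha 0.01, grouping LOD 6 and rmax
#' 0.35, 1-cM scan step, 1000 permutations, association alpha 0.05.
#'
#' @param fastq,barcodeKey,vcf,phenotypes,outDir file paths (any may be
#'   `NA`; stages without inputs are skipped).
#' @param minDP,maf,maxMissing genotype-matrix filter thresholds.
#' @param segAlpha segregation-distortion significance level.
#' @param lodMin,rMax linkage-grouping thresholds.
#' @param scanStep scan grid spacing (cM).
#' @param nPerm permutation count for the LOD threshold.
#' @param assocAlpha family-wise alpha of the association scan.
#' @param scanParent parent whose meioses are scanned (`NA` = both, best
#'   peak reported).
#' @param seed integer seed.
#' @return A named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(fastq = NA, barcodeKey = NA, vcf = NA,
                           phenotypes = NA, outDir = "gbs_out",
                           minDP = 6L, maf = 0.2, maxMissing = 0.2,
                           segAlpha = 0.01, lodMin = 6, rMax = 0.35,
                           scanStep = 1, nPerm = 1000L, assocAlpha = 0.05,
                           scanParent = NA, seed = 1L) {
  cfg <- list(fastq = fastq, barcodeKey = barcodeKey, vcf = vcf,
              phenotypes = phenotypes, outDir = outDir,
              minDP = as.integer(minDP), maf = maf, maxMissing = maxMissing,
              segAlpha = segAlpha, lodMin = lodMin, rMax = rMax,
              scanStep = scanStep, nPerm = as.integer(nPerm),
              assocAlpha = assocAlpha, scanParent = scanParent,
              seed = as.integer(seed))
  stopifnot(cfg$minDP >= 0, cfg$maf >= 0, cfg$maf <= 1,
            cfg$maxMissing >= 0, cfg$maxMissing <= 1,
            cfg$segAlpha > 0, cfg$segAlpha < 1, cfg$lodMin > 0,
            cfg$rMax > 0, cfg$rMax <= 0.5, cfg$scanStep > 0,
            cfg$nPerm >= 0, cfg$assocAlpha > 0, cfg$assocAlpha < 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' Flat `key = value` text; round-trips through [readPipelineConfig()].
#'
#' @param config a `PipelineConfig`.
#' @param path output file.
#' @return `path` invisibly, or the restored `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  vals <- vapply(config, function(v) as.character(v)[1L], character(1))
  writeLines(paste0(names(config), " = ", vals), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  numeric_keys <- c("minDP", "maf", "maxMissing", "segAlpha", "lodMin",
                    "rMax", "scanStep", "nPerm", "assocAlpha", "seed")
  args <- as.list(vals)
  for (k in intersect(numeric_keys, names(args))) {
    args[[k]] <- as.numeric(args[[k]])
  }
  for (k in names(args)) if (identical(args[[k]], "NA")) args[[k]] <- NA
  do.call(pipelineConfig, args)
}

#' Run the GBS mapping pipeline end to end
#'
#' Executes the enabled stages in order: demultiplex/trim (when a FASTQ and
#' barcode key are given), genotype-matrix construction from VCF, depth/MAF/
#' missingness filtering, segregation analysis, linkage-map construction,
#' and (when phenotypes are given) the single-marker association scan plus
#' binary interval mapping with a permutation threshold. Alignment and
#' variant calling sit between demultiplexing and the VCF and are an
#' explicit external hand-off: the pipeline consumes whatever multi-sample
#' VCF the caller produced (the simulator emits one directly). Every stage
#' logs marker/read counts in, counts out; outputs and a provenance log
#' (tagged with the MD5 of the serialized configuration) land in
#' `config$outDir`.
#'
#' @param config a [pipelineConfig()].
#' @param roles named role vector for the VCF samples; defaults to reading
#'   sample names as `P1`, `P2`, rest offspring.
#' @return list with the stage objects: `demux`, `genotypes`, `filtered`,
#'   `segregation`, `map`, `association`, `scans` (per parent), `log`.
#' @export
runPipeline <- function(config, roles = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(config$outDir, "config.txt")
  writePipelineConfig(config, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  logLines <- c(paste("config_md5", cfgHash))
  say <- function(...) {
    line <- paste(...)
    message(line)
    logLines <<- c(logLines, line)
  }
  out <- list()

  if (!is.na(config$fastq)) {
    key <- readBarcodeKey(config$barcodeKey)
    rep <- splitReads(config$fastq, key,
                      outDir = file.path(config$outDir, "demux"))
    writeDemuxReport(rep, file.path(config$outDir, "demux_report.tsv"))
    say("demux:", rep@counts[["total"]], "reads in,",
        rep@counts[["emitted"]], "emitted")
    out$demux <- rep
  }

  if (!is.na(config$vcf)) {
    if (is.null(roles)) {
      hdr <- grep("^#CHROM", readLines(config$vcf, n = 2000L), value = TRUE)
      samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
      roles <- setNames(c("parent1", "parent2",
                          rep("offspring", length(samples) - 2L)), samples)
    }
    gm <- loadVCF(config$vcf, roles)
    say("load_vcf:", nrow(gm), "biallelic SNPs,",
        metadata(gm)$excluded, "records excluded")
    out$genotypes <- gm

    gmD <- maskByDepth(gm, config$minDP)
    gmF <- filterMarkers(gmD, config$maf, config$maxMissing)
    say("filter:", nrow(gm), "->", nrow(gmF),
        sprintf("markers (minDP=%d, maf>=%.2f, missing<=%.2f)",
                config$minDP, config$maf, config$maxMissing))
    out$filtered <- gmF

    seg <- segregationAnalysis(gmF, alpha = config$segAlpha)
    nKeep <- sum(seg$table$decision == "KEEP")
    say("segregation:", nrow(gmF), "->", nKeep, "markers kept,",
        sum(seg$violations), "offspring cells masked")
    writeSegregationReport(seg, file.path(config$outDir, "segregation.tsv"))
    out$segregation <- seg

    map <- buildGeneticMap(seg$genotypes, seg,
                           lodMin = config$lodMin, rMax = config$rMax)
    say("map:", nrow(mapTable(map)), "markers in", nLinkageGroups(map),
        sprintf("groups, %.0f cM; %d unlinked, %d dropped",
                mapLength(map), length(unlinkedMarkers(map)),
                length(map@dropped)))
    writeGeneticMap(map, file.path(config$outDir, "genetic_map.tsv"))
    out$map <- map

    if (!is.na(config$phenotypes)) {
      ph <- utils::read.table(config$phenotypes, header = TRUE, sep = "\t")
      pheno <- setNames(ph$phenotype, ph$sample)
      assoc <- singleMarkerScan(gmF, pheno, alpha = config$assocAlpha)
      say("assoc:", metadata(assoc)$nTests, "tests, bonferroni",
          signif(metadata(assoc)$bonferroniAlpha, 3), ";",
          sum(assoc$significant), "significant")
      writeAssociation(assoc, file.path(config$outDir, "association.csv"))
      out$association <- assoc

      parents <- if (is.na(config$scanParent)) 1:2 else config$scanParent
      scans <- list()
      for (p in parents) {
        probs <- genotypeProbs(map, seg$genotypes, parent = p,
                               step = config$scanStep)
        if (!length(probs$groups)) next
        sc <- intervalScan(probs, pheno, nPerm = config$nPerm,
                           seed = childSeed(config$seed, 10L + p))
        say(sprintf("scan parent %d: peak LOD %.2f at group %s, %.1f cM (threshold %.2f)",
                    p, sc@peak$lod, sc@peak$group, sc@peak$posCM,
                    ifelse(length(sc@threshold), sc@threshold, NA)))
        writeScan(sc, file.path(config$outDir,
                                sprintf("scan_parent%d.csv", p)))
        scans[[paste0("parent", p)]] <- sc
      }
      out$scans <- scans
    }
  }
  writeLines(logLines, file.path(config$outDir, "pipeline_log.txt"))
  out$log <- logLines
  out
}
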