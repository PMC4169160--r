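#' Read a barcode key table
#'
#' @param path TSV with columns `sample` and `barcode` (header required).
#' @return Named character vector, `sample -> barcode`.
#' @export
readBarcodeKey <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("sample", "barcode") %in% colnames(tab))) {
    stop("barcode key needs 'sample' and 'barcode' columns")
  }
  key <- setNames(tab$barcode, tab$sample)
  checkBarcodeKey(key)
  key
}

checkBarcodeKey <- function(key) {
  if (!length(key)) stop("empty barcode key")
  if (any(!grepl("^[ACGT]+$", key))) stop("barcodes must be ACGT only")
  if (anyDuplicated(key)) stop("duplicate barcodes in key")
  invisible(key)
}

#' Demultiplex a raw GBS FASTQ by sample barcode
#'
#' Splits reads by their 5' barcode (longest exact match), validates the
#' restriction-site remnant expected immediately after the barcode, trims
#' chimeric and adapter-containing reads, and writes one FASTQ per sample.
#' Disposition of every read is tallied:
#' \itemize{
#'   \item no barcode matches exactly: \emph{unmatched};
#'   \item any non-ACGT base inside the barcode + remnant region:
#'     \emph{ambiguous discard};
#'   \item post-barcode bases not equal to `remnant`: \emph{remnant-invalid};
#'   \item an internal full restriction site (any of `sitePatterns`):
#'     truncated immediately before the site (\emph{chimera-trimmed});
#'   \item `commonRemnant` followed by the start of `adapter`: truncated at
#'     the end of the common remnant (\emph{adapter-trimmed}); an internal
#'     site that is itself the start of such a remnant+adapter match is
#'     treated as adapter read-through, not as a chimera;
#'   \item reads shorter than `minLen` after trimming: \emph{length
#'     discarded}.
#' }
#' The barcode is removed from emitted reads; the barcode-side remnant is
#' genomic sequence at the cut site and is retained. Qualities are trimmed in
#' lockstep with bases.
#'
#' @param fastq input FASTQ path.
#' @param key named character, `sample -> barcode` (see [readBarcodeKey()]).
#' @param remnant barcode-side remnant expected after the barcode
#'   (HindIII leaves `"AGCTT"`).
#' @param sitePatterns full restriction sites whose internal occurrence marks
#'   a chimeric junction.
#' @param commonRemnant common-side remnant preceding adapter read-through
#'   (MspI leaves `"CCGG"`).
#' @param adapter common-adapter sequence; at least `adapterMin` of its
#'   leading bases (or all bases to the read end) must match.
#' @param minLen minimum post-trim read length kept.
#' @param adapterMin minimum matching adapter prefix length.
#' @param outDir directory for per-sample FASTQ files (`<sample>.fastq`);
#'   `NULL` suppresses writing.
#' @return A [DemuxReport-class]; when `outDir` is `NULL` the per-sample
#'   reads are attached as attribute `"reads"` (list of named character
#'   vectors).
#' @export
splitReads <- function(fastq, key, remnant = "AGCTT",
                       sitePatterns = c("AAGCTT", "CCGG"),
                       commonRemnant = "CCGG",
                       adapter = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
                       minLen = 30L, adapterMin = 4L, outDir = NULL) {
  checkBarcodeKey(key)
  fq <- readFastq(fastq)
  seqs <- fq$seq
  quals <- fq$qual
  n <- length(seqs)

  ## longest-match barcode assignment
  bcIdx <- rep(NA_integer_, n)
  for (len in sort(unique(nchar(key)), decreasing = TRUE)) {
    bcs <- key[nchar(key) == len]
    idx <- is.na(bcIdx)
    hit <- match(substr(seqs[idx], 1L, len), bcs)
    bcIdx[idx][!is.na(hit)] <- match(names(bcs)[hit[!is.na(hit)]],
                                     names(key))
  }
  matched <- !is.na(bcIdx)
  bcl <- ifelse(matched, nchar(key)[bcIdx], 0L)
  region <- substr(seqs, 1L, bcl + nchar(remnant))
  ambiguous <- matched & grepl("[^ACGT]", region)
  remOk <- matched & !ambiguous &
    substr(seqs, bcl + 1L, bcl + nchar(remnant)) == remnant

  keep <- which(remOk)
  trimmedSeq <- substring(seqs[keep], bcl[keep] + 1L)
  trimmedQual <- substring(quals[keep], bcl[keep] + 1L)
  tr <- trimReads(trimmedSeq, trimmedQual, sitePatterns, commonRemnant,
                  adapter, minLen, adapterMin, protect = nchar(remnant))

  emit <- tr$length >= minLen
  counts <- c(total = n,
              matched = sum(matched),
              unmatched = sum(!matched),
              ambiguousDiscard = sum(ambiguous),
              remnantInvalid = sum(matched & !ambiguous & !remOk),
              chimeraTrimmed = sum(tr$chimera),
              adapterTrimmed = sum(tr$adapter),
              lengthDiscarded = sum(!emit),
              emitted = sum(emit))
  sampleOf <- names(key)[bcIdx[keep]]
  perSample <- DataFrame(
    sample = names(key),
    reads = as.vector(table(factor(sampleOf[emit], levels = names(key)))))
  report <- new("DemuxReport", perSample = perSample, counts = counts)

  outSeq <- tr$seq[emit]
  outQual <- tr$qual[emit]
  outId <- fq$id[keep][emit]
  groups <- split(seq_along(outSeq), sampleOf[emit])
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(key)) {
      i <- groups[[s]]
      path <- file.path(outDir, paste0(s, ".fastq"))
      if (is.null(i)) {
        file.create(path)
      } else {
        writeFastq(outId[i], outSeq[i], outQual[i], path)
      }
    }
  } else {
    attr(report, "reads") <- lapply(groups, function(i) {
      setNames(outSeq[i], outId[i])
    })
  }
  report
}

#' Trim chimeric junctions and adapter read-through from barcode-stripped
#' reads
#'
#' Pure function applying the trimming rules of [splitReads()] to parallel
#' base/quality vectors. The first `protect` bases (the barcode-side remnant)
#' are never scanned, so a site pattern that overlaps the remnant itself does
#' not truncate the read away.
#'
#' @param seqs,quals character vectors of equal lengths.
#' @inheritParams splitReads
#' @param protect number of leading bases excluded from scanning.
#' @return list with `seq`, `qual`, `length`, and logical event flags
#'   `chimera`, `adapter`.
#' @export
trimReads <- function(seqs, quals, sitePatterns = c("AAGCTT", "CCGG"),
                      commonRemnant = "CCGG",
                      adapter = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
                      minLen = 30L, adapterMin = 4L, protect = 0L) {
  stopifnot(length(seqs) == length(quals),
            all(nchar(seqs) == nchar(quals)))
  n <- length(seqs)
  tails <- substring(seqs, protect + 1L)

  ## adapter read-through: commonRemnant followed by an adapter prefix of at
  ## least adapterMin bases (fewer only if the read ends first)
  adPos <- rep(NA_integer_, n)
  hits <- gregexpr(commonRemnant, tails, fixed = TRUE)
  for (i in seq_len(n)) {
    hp <- hits[[i]]
    if (hp[1L] == -1L) next
    for (p in hp) {
      after <- substring(tails[i], p + nchar(commonRemnant))
      want <- substr(adapter, 1L, min(nchar(after), nchar(adapter)))
      if (nchar(after) >= adapterMin && identical(substr(after, 1L,
                                                         nchar(want)), want)) {
        adPos[i] <- p
        break
      }
    }
  }
  ## chimeric junction: first internal full site, unless that occurrence is
  ## the adapter read-through match itself
  sitePos <- rep(NA_integer_, n)
  for (pat in sitePatterns) {
    p <- regexpr(pat, tails, fixed = TRUE)
    upd <- p > 0 & (is.na(sitePos) | p < sitePos)
    sitePos[upd] <- p[upd]
  }
  isAdapter <- !is.na(adPos) & (is.na(sitePos) | sitePos >= adPos)
  isChimera <- !is.na(sitePos) & !isAdapter & (is.na(adPos) | sitePos < adPos)

  cut <- nchar(seqs)
  cut[isChimera] <- protect + sitePos[isChimera] - 1L
  cut[isAdapter] <- protect + adPos[isAdapter] + nchar(commonRemnant) - 1L
  list(seq = substr(seqs, 1L, cut),
       qual = substr(quals, 1L, cut),
       length = cut,
       chimera = isChimera,
       adapter = isAdapter)
}

## Minimal 4-line FASTQ reader/writer used by the demultiplexer; keeps
## ids/bases/qualities as parallel character vectors for string-level
## trimming. Biostrings-backed import is available via readFastqBiostrings().
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " (", length(lines),
         " lines, not a multiple of 4)")
  }
  n <- length(lines) %/% 4L
  id <- sub("^@", "", lines[seq(1L, by = 4L, length.out = n)])
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], ": sequence/quality mismatch")
  }
  list(id = id, seq = seqs, qual = quals)
}

writeFastq <- function(ids, seqs, quals, path) {
  n <- length(ids)
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
  out[seq(2L, by = 4L, length.out = n)] <- seqs
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Import a FASTQ file as a QualityScaledDNAStringSet
#'
#' Convenience wrapper around [Biostrings::readQualityScaledDNAStringSet()]
#' for downstream sequence work on demultiplexed reads.
#'
#' @param path FASTQ file.
#' @return A `QualityScaledDNAStringSet`.
#' @export
readFastqBiostrings <- function(path) {
  Biostrings::readQualityScaledDNAStringSet(path)
}

#' Write a demultiplexing report as TSV
#'
#' @param report a [DemuxReport-class].
#' @param path output file; global counts are written as comment lines
#'   followed by the per-sample table.
#' @return `path`, invisibly.
#' @export
writeDemuxReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cts <- report@counts
  writeLines(sprintf("# %s\t%d", names(cts), as.integer(cts)), con)
  utils::write.table(as.data.frame(report@perSample), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
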