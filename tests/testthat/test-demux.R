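writeTinyFastq <- function(seqs, path, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                             quals)), path)
  path
}

test_that("reads are assigned by exact barcode and keep the remnant", {
  fq <- writeTinyFastq(c(
    paste0("AACT", "AGCTT", strrep("G", 40)),   # S1, clean
    paste0("AACT", "NGCTT", strrep("G", 40)),   # ambiguous base in remnant
    paste0("AACT", "TGCTT", strrep("G", 40)),   # remnant mismatch
    paste0("TTTT", "AGCTT", strrep("G", 40))    # no barcode
  ), tempfile(fileext = ".fastq"))
  rep <- splitReads(fq, c(S1 = "AACT"), remnant = "AGCTT", outDir = NULL)
  cts <- rep@counts
  expect_equal(unname(cts[c("total", "matched", "unmatched",
                            "ambiguousDiscard", "remnantInvalid",
                            "emitted")]),
               c(4, 3, 1, 1, 1, 1))
  reads <- attr(rep, "reads")$S1
  expect_length(reads, 1)
  expect_true(startsWith(unname(reads), "AGCTTGGGG"))
})

test_that("longest barcode match wins for nested-prefix-free keys", {
  ## equal-length keys differing in one base plus a longer one
  key <- c(A = "ACGTAC", B = "ACGTTGAA")
  fq <- writeTinyFastq(c(
    paste0("ACGTAC", "AGCTT", strrep("C", 40)),
    paste0("ACGTTGAA", "AGCTT", strrep("C", 40))
  ), tempfile(fileext = ".fastq"))
  rep <- splitReads(fq, key, outDir = NULL)
  expect_equal(as.vector(rep@perSample$reads), c(1, 1))
})

test_that("duplicate or malformed keys are rejected", {
  expect_error(splitReads("x.fastq", c(A = "ACGT", B = "ACGT")), "duplicate")
  expect_error(splitReads("x.fastq", character()), "empty")
  expect_error(splitReads("x.fastq", c(A = "ACNT")), "ACGT")
})

test_that("internal restriction sites truncate the read before the site", {
  s <- paste0("AGCTT", strrep("C", 35), "AAGCTT", strrep("A", 30))
  tr <- trimReads(s, strrep("I", nchar(s)), protect = 5L)
  expect_equal(tr$length, 40)
  expect_equal(nchar(tr$qual), 40)
  expect_true(tr$chimera)
  expect_false(tr$adapter)
})

test_that("adapter read-through trims after the common remnant", {
  adapter <- "AGATCGGAAGAGC"
  s <- paste0(strrep("T", 60), "CCGG", substr(adapter, 1, 20))
  tr <- trimReads(s, strrep("I", nchar(s)), adapter = adapter)
  expect_equal(tr$length, 64)
  expect_true(tr$adapter)
  expect_false(tr$chimera)   # the CCGG is the remnant, not a chimera site
})

test_that("trimming only shortens and keeps qualities in lockstep", {
  set.seed(4)
  seqs <- vapply(1:50, function(i) {
    paste0(sample(c("A", "C", "G", "T", "AAGCTT", "CCGG"),
                  30, replace = TRUE), collapse = "")
  }, character(1))
  quals <- vapply(nchar(seqs), function(n)
    paste0(sample(c("I", "J", "F"), n, replace = TRUE), collapse = ""),
    character(1))
  tr <- trimReads(seqs, quals)
  expect_true(all(tr$length <= nchar(seqs)))
  expect_true(all(nchar(tr$seq) == nchar(tr$qual)))
  expect_true(all(substr(seqs, 1, tr$length) == tr$seq))
  expect_true(all(substr(quals, 1, tr$length) == tr$qual))
})

test_that("demultiplexing a simulated lane reconciles exactly with truth", {
  p <- simParams(nOffspring = 30, totalReads = 2e4, seed = 31)
  truth <- simulatePopulation(p)
  fq <- tempfile(fileext = ".fastq")
  keyf <- tempfile(fileext = ".tsv")
  tab <- simulateReads(truth, fq, keyf)
  rep <- splitReads(fq, readBarcodeKey(keyf), outDir = NULL)
  cts <- rep@counts
  ## per-sample emitted reads equal the simulator's assignable reads
  expect_equal(as.vector(rep@perSample$reads),
               tab$assignable[match(rep@perSample$sample, tab$sample)])
  expect_equal(unname(cts[["chimeraTrimmed"]]), sum(tab$chimera))
  expect_equal(unname(cts[["adapterTrimmed"]]), sum(tab$adapter))
  expect_equal(unname(cts[["unmatched"]]), sum(tab$bcfail))
  expect_equal(unname(cts[["ambiguousDiscard"]] + cts[["remnantInvalid"]]),
               sum(tab$remfail))
  ## disposition partition
  expect_equal(unname(cts[["unmatched"]] + cts[["ambiguousDiscard"]] +
                      cts[["remnantInvalid"]] + cts[["lengthDiscarded"]] +
                      cts[["emitted"]]),
               unname(cts[["total"]]))
})

test_that("with no artefacts demux returns reads bit-identical minus barcode", {
  p <- simParams(nOffspring = 10, totalReads = 2000, chimeraRate = 0,
                 adapterRate = 0, barcodeFailRate = 0, remnantFailRate = 0,
                 seed = 37)
  truth <- simulatePopulation(p)
  fq <- tempfile(fileext = ".fastq")
  keyf <- tempfile(fileext = ".tsv")
  simulateReads(truth, fq, keyf)
  key <- readBarcodeKey(keyf)
  outDir <- tempfile()
  rep <- splitReads(fq, key, outDir = outDir)
  expect_equal(unname(rep@counts[["emitted"]]), 2000)
  raw <- readFastq(fq)
  rawSample <- sub("^\\S+ (\\S+) .*$", "\\1", raw$id)
  for (s in unique(rawSample)[1:3]) {
    got <- readFastq(file.path(outDir, paste0(s, ".fastq")))
    want <- substring(raw$seq[rawSample == s], nchar(key[[s]]) + 1L)
    expect_identical(got$seq, want)
  }
})

test_that("malformed FASTQ files are reported with a parse error", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)
  expect_error(splitReads(bad, c(A = "ACGT")), "malformed FASTQ")
})
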