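#' Classify the parental configuration of markers
#'
#' In a double pseudo-testcross only three parental genotype combinations
#' are informative: heterozygous x homozygous (`ABxAA`, segregates 1:1 in
#' the first parent's meioses), homozygous x heterozygous (`AAxAB`), and
#' heterozygous x heterozygous (`ABxAB`, segregates 1:2:1). Both parents
#' homozygous is uninformative, and a missing parental call makes the marker
#' unusable for mapping.
#'
#' @param p1,p2 parental calls (0/1/2/NA), vectorized.
#' @return factor with levels `ABxAA`, `AAxAB`, `ABxAB`, `UNINFORMATIVE`,
#'   `PARENT_MISSING`.
#' @examples
#' classifyMarker(1, 0)   # ABxAA
#' classifyMarker(0, 2)   # UNINFORMATIVE
#' @export
classifyMarker <- function(p1, p2) {
  out <- rep("PARENT_MISSING", length(p1))
  known <- !is.na(p1) & !is.na(p2)
  out[known & p1 == 1L & p2 != 1L] <- "ABxAA"
  out[known & p1 != 1L & p2 == 1L] <- "AAxAB"
  out[known & p1 == 1L & p2 == 1L] <- "ABxAB"
  out[known & p1 != 1L & p2 != 1L] <- "UNINFORMATIVE"
  factor(out, levels = CONFIG_LEVELS)
}

#' @describeIn classifyMarker classify every marker of a genotype matrix.
#' @param gm a [GBSGenotypes-class] with both parental roles present.
#' @return For `classifyMarkers`: a `DataFrame` with columns `marker` and
#'   `config`.
#' @export
classifyMarkers <- function(gm) {
  p1 <- parentId(gm, 1); p2 <- parentId(gm, 2)
  if (is.na(p1) || is.na(p2)) stop("both parental roles must be present")
  call <- genotypeCalls(gm)
  DataFrame(marker = rownames(call),
            config = classifyMarker(call[, p1], call[, p2]))
}

#' Mask offspring genotypes inconsistent with Mendelian inheritance
#'
#' Offspring calls that are impossible given the called parental genotypes
#' (for example hom-alt offspring under `ABxAA` with a hom-ref parent, or
#' either homozygote under an `AAxBB` cross) are set to missing. Parental
#' calls are never altered and missing calls never become called.
#'
#' @param gm a [GBSGenotypes-class] with both parental roles.
#' @return list: `genotypes` (masked matrix) and `violations` (named integer,
#'   masked-cell count per marker).
#' @export
mendelianMask <- function(gm) {
  p1 <- parentId(gm, 1); p2 <- parentId(gm, 2)
  if (is.na(p1) || is.na(p2)) stop("both parental roles must be present")
  call <- genotypeCalls(gm)
  off <- offspringIds(gm)
  imp <- impossibleCalls(call[, p1], call[, p2])
  bad <- matrix(FALSE, nrow(call), length(off))
  oc <- call[, off, drop = FALSE]
  for (g in 0:2) {
    bad <- bad | (!is.na(oc) & oc == g & imp[, g + 1L])
  }
  oc[bad] <- NA_integer_
  call[, off] <- oc
  SummarizedExperiment::assay(gm, "call") <- call
  list(genotypes = gm,
       violations = setNames(rowSums(bad), rownames(call)))
}

#' Chi-squared segregation test for one marker
#'
#' Pearson goodness-of-fit of observed offspring genotype-class counts
#' against the expected pseudo-testcross ratio, without continuity
#' correction; degrees of freedom are `classes - 1`.
#'
#' @param counts observed counts per genotype class (length 2 for a 1:1
#'   backcross-type marker, length 3 for a 1:2:1 intercross-type marker).
#' @param ratio expected ratio, `"1:1"` or `"1:2:1"`.
#' @param alpha distortion significance level; markers with `p < alpha` are
#'   dropped.
#' @return list: `chi2`, `pval`, `decision` (`KEEP`, `DROP_DISTORTED`, or
#'   `DROP_UNINFORMATIVE` when no offspring are called, with `pval = NA`).
#' @examples
#' segregationTest(c(44, 43), "1:1")          # chi2 = 1/87, keep
#' segregationTest(c(10, 40, 30), "1:2:1")    # chi2 = 10, dropped at 0.01
#' @export
segregationTest <- function(counts, ratio = c("1:1", "1:2:1"), alpha = 0.01) {
  ratio <- match.arg(ratio)
  expectedProp <- if (ratio == "1:1") c(1, 1) / 2 else c(1, 2, 1) / 4
  stopifnot(length(counts) == length(expectedProp))
  n <- sum(counts)
  if (n == 0) {
    return(list(chi2 = NA_real_, pval = NA_real_,
                decision = "DROP_UNINFORMATIVE"))
  }
  expected <- n * expectedProp
  chi2 <- sum((counts - expected)^2 / expected)
  pval <- stats::pchisq(chi2, df = length(counts) - 1L, lower.tail = FALSE)
  list(chi2 = chi2, pval = pval,
       decision = if (pval < alpha) "DROP_DISTORTED" else "KEEP")
}

#' Full segregation analysis of a genotype matrix
#'
#' Classifies every marker's parental configuration, masks
#' Mendelian-inconsistent offspring calls (configurable order: masking
#' precedes the ratio test by default since masked cells change the test
#' counts), tallies offspring genotype classes, and applies the chi-squared
#' distortion test at `alpha`. Markers with an uninformative configuration or
#' a missing parental call are marked for dropping.
#'
#' @param gm a [GBSGenotypes-class] with both parental roles.
#' @param alpha significance level of the distortion test.
#' @param maskFirst logical; mask Mendelian inconsistencies before counting.
#' @return list: `genotypes` (the masked matrix), `table` (`DataFrame`:
#'   marker, config, class counts `n0`,`n1`,`n2`, `chi2`, `pval`,
#'   `decision`), and `violations` (per-marker masked-cell counts).
#' @export
segregationAnalysis <- function(gm, alpha = 0.01, maskFirst = TRUE) {
  cls <- classifyMarkers(gm)
  masked <- if (maskFirst) mendelianMask(gm) else
    list(genotypes = gm, violations = setNames(integer(nrow(gm)),
                                               rownames(gm)))
  call <- genotypeCalls(masked$genotypes)
  off <- offspringIds(gm)
  oc <- call[, off, drop = FALSE]
  n0 <- rowSums(oc == 0L, na.rm = TRUE)
  n1 <- rowSums(oc == 1L, na.rm = TRUE)
  n2 <- rowSums(oc == 2L, na.rm = TRUE)
  p1 <- parentId(gm, 1); p2 <- parentId(gm, 2)
  homParent <- ifelse(cls$config == "ABxAA", call[, p2],
                      ifelse(cls$config == "AAxAB", call[, p1], NA))
  m <- nrow(call)
  chi2 <- pval <- rep(NA_real_, m)
  decision <- rep("DROP_UNINFORMATIVE", m)
  for (i in seq_len(m)) {
    cfg <- as.character(cls$config[i])
    if (cfg %in% c("UNINFORMATIVE", "PARENT_MISSING")) next
    counts <- if (cfg == "ABxAB") {
      c(n0[i], n1[i], n2[i])
    } else if (!is.na(homParent[i]) && homParent[i] == 0L) {
      c(n0[i], n1[i])     # backcross against a hom-ref parent
    } else {
      c(n2[i], n1[i])     # backcross against a hom-alt parent
    }
    ratio <- if (cfg == "ABxAB") "1:2:1" else "1:1"
    res <- segregationTest(counts, ratio, alpha)
    chi2[i] <- res$chi2
    pval[i] <- res$pval
    decision[i] <- res$decision
  }
  tab <- DataFrame(marker = rownames(call), config = cls$config,
                   n0 = n0, n1 = n1, n2 = n2,
                   chi2 = chi2, pval = pval, decision = decision)
  list(genotypes = masked$genotypes, table = tab,
       violations = masked$violations)
}

#' Write a segregation report as TSV
#'
#' @param seg result of [segregationAnalysis()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSegregationReport <- function(seg, path) {
  utils::write.table(as.data.frame(seg$table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
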