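## Hardy-Weinberg screening with the FIS*sqrt(N) statistic. FIS is Wright's
## within-population fixation index, estimated per site as
## 1 - Hobs/Hexp; multiplied by sqrt(n_called) it is approximately standard
## normal under HWE, so |FISN| > 1.96 rejects at the 5% level. Heterozygote
## excess (the paralog-collapse signature the filter targets) drives FISN
## negative; heterozygote deficit drives it positive.

#' Per-site Hardy-Weinberg statistics
#'
#' Computes, for every site, the number of called diploids, observed
#' heterozygote count, alt-allele frequency, the FIS estimate and
#' FISN = FIS * sqrt(n_called). With the default \code{hexp = "unbiased"},
#' expected heterozygosity carries Nei's small-sample factor
#' \code{2n/(2n - 1)}, which centres the FISN null on zero;
#' \code{hexp = "plain"} uses the raw \code{2*p*(1-p)}. Monomorphic or
#' otherwise degenerate sites (Hexp = 0, or fewer than 2 called diploids)
#' get NA statistics and are never flagged for removal: the filter looks
#' for deviating heterozygosity, of which such sites carry no evidence.
#'
#' @param x a \linkS4class{GenotypeMatrix} of biallelic sites.
#' @param thresholdZ positive cutoff; sites with |FISN| > thresholdZ are
#'   flagged in the \code{removed} column.
#' @param hexp expected-heterozygosity estimator, "unbiased" or "plain".
#' @return data.frame with columns scaffold, pos, n_called, het_obs, p_hat,
#'   fis, fisn, removed.
#' @examples
#' gm <- simulateHweGenotypes(nInd = 50, nSites = 100, seed = 1)
#' head(siteHwe(gm))
#' @export
siteHwe <- function(x, thresholdZ = 1.96, hexp = c("unbiased", "plain")) {
  hexp <- match.arg(hexp)
  if (thresholdZ <= 0) stop("thresholdZ must be positive")
  gt <- assay(x, "GT")
  nCalled <- rowSums(!is.na(gt))
  hetObs <- rowSums(gt == 1L, na.rm = TRUE)
  nAllele <- 2 * nCalled
  pHat <- ifelse(nAllele > 0, rowSums(gt, na.rm = TRUE) / nAllele,
                 NA_real_)
  hObs <- ifelse(nCalled > 0, hetObs / nCalled, NA_real_)
  hExp <- 2 * pHat * (1 - pHat)
  if (hexp == "unbiased")
    hExp <- hExp * ifelse(nAllele > 1, nAllele / (nAllele - 1), NA_real_)
  ok <- !is.na(hExp) & hExp > 0 & nCalled >= 2
  fis <- ifelse(ok, 1 - hObs / hExp, NA_real_)
  fisn <- fis * sqrt(nCalled)
  data.frame(scaffold = scaffolds(x), pos = positions(x),
             n_called = nCalled, het_obs = hetObs, p_hat = pHat,
             fis = fis, fisn = fisn,
             removed = !is.na(fisn) & abs(fisn) > thresholdZ)
}

#' Remove sites deviating from Hardy-Weinberg equilibrium
#'
#' Drops sites with |FISN| above \code{thresholdZ} (fixed per-site cutoff,
#' no multiple-testing correction) and returns both the filtered matrix and
#' the full per-site report; \code{reportPath} optionally writes the report
#' as TSV.
#'
#' @inheritParams siteHwe
#' @param reportPath optional TSV path for the per-site report.
#' @return list with elements \code{genotypes} (filtered
#'   \linkS4class{GenotypeMatrix}) and \code{report} (the [siteHwe()]
#'   data.frame).
#' @export
filterHwe <- function(x, thresholdZ = 1.96, hexp = c("unbiased", "plain"),
                      reportPath = NULL) {
  report <- siteHwe(x, thresholdZ = thresholdZ, hexp = hexp)
  keep <- !report$removed
  .logStep(sprintf("filterHwe (|FISN| <= %g)", thresholdZ),
           nrow(x), sum(keep))
  if (!is.null(reportPath))
    write.table(report, reportPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(genotypes = x[keep, ], report = report)
}
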