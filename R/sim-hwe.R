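## Single-site genotype simulator: draws per-site allele frequencies and
## genotypes from the inbreeding-adjusted Hardy-Weinberg law
## P(hom-ref, het, hom-alt) = (q^2 + f p q, 2 p q (1 - f), p^2 + f p q),
## so f = 0 is exact HWE and f = 1 fully inbred. Used to calibrate the
## FISN null and as a generic matrix fixture factory.

#' Simulate genotypes under (possibly inbred) Hardy-Weinberg draws
#'
#' @param nInd number of diploid individuals.
#' @param nSites number of biallelic sites.
#' @param pRange alt-allele frequency range; per site p ~ Uniform(pRange).
#' @param f inbreeding coefficient in [-1, 1]; negative f (heterozygote
#'   excess) must satisfy f >= -p/q and f >= -q/p at every drawn p, else
#'   genotype probabilities go negative and an error explains the limit.
#' @param seed optional integer seed.
#' @param scaffold scaffold id for the simulated sites.
#' @param posStep spacing between consecutive site positions in bp.
#' @return A \linkS4class{GenotypeMatrix} (no DP/GQ assays).
#' @examples
#' gm <- simulateHweGenotypes(nInd = 20, nSites = 50, f = 0, seed = 7)
#' table(calls(gm))
#' @export
simulateHweGenotypes <- function(nInd, nSites, pRange = c(0.1, 0.9),
                                 f = 0, seed = NULL, scaffold = "sim1",
                                 posStep = 100) {
  stopifnot(nInd >= 1, nSites >= 1, f >= -1, f <= 1,
            pRange[1] > 0, pRange[2] < 1, pRange[1] <= pRange[2])
  if (!is.null(seed)) set.seed(seed)
  p <- runif(nSites, pRange[1], pRange[2])
  q <- 1 - p
  pHomRef <- q^2 + f * p * q
  pHet <- 2 * p * q * (1 - f)
  pHomAlt <- p^2 + f * p * q
  if (any(pHomRef < 0) || any(pHomAlt < 0))
    stop("negative genotype probability: f = ", f,
         " is below -min(p/q, q/p) for a drawn frequency; ",
         "raise f or narrow pRange")
  u <- matrix(runif(nSites * nInd), nSites, nInd)
  gt <- (u > pHomRef) + (u > pHomRef + pHet)
  storage.mode(gt) <- "integer"
  GenotypeMatrix(scaffold = rep(scaffold, nSites),
                 pos = seq(1, by = posStep, length.out = nSites),
                 calls = gt, ref = rep("A", nSites),
                 alt = rep("C", nSites), qual = rep(60, nSites),
                 individuals = sprintf("ind%02d", seq_len(nInd)))
}
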