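# Fixture builders. VCF text is written by hand here (independently of the
# package's writer) so that load tests do not trust the code under test.

toyVcfLines <- function(records, samples = c("ind1", "ind2"),
                        contigs = NULL, format = "GT:DP:GQ") {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>",
                     names(contigs), contigs),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  c(hdr, records)
}

writeToyVcf <- function(records, path = tempfile(fileext = ".vcf"), ...) {
  writeLines(toyVcfLines(records, ...), path)
  path
}

rec <- function(chrom, pos, ref, alt, qual, ..., format = "GT:DP:GQ") {
  paste(c(chrom, pos, ".", ref, alt, qual, ".", ".", format, ...),
        collapse = "\t")
}

# small matrix straight from components (bypasses VCF)
gmFromCalls <- function(calls, pos = NULL, scaffold = "s1", ...) {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 100
  GenotypeMatrix(scaffold = rep(scaffold, nrow(calls)), pos = pos,
                 calls = calls, ...)
}

# genotype matrix drawn from a neutral constant-size folded-SFS model:
# unfolded derived-allele count k has probability proportional to 1/k,
# alleles assigned to haploid slots at random, no missing data.
neutralSfsMatrix <- function(nSites, nInd) {
  nHap <- 2L * nInd
  kProb <- (1 / seq_len(nHap - 1))
  k <- sample(seq_len(nHap - 1), nSites, replace = TRUE,
              prob = kProb / sum(kProb))
  gt <- matrix(0L, nSites, nInd)
  for (i in seq_len(nSites)) {
    hap <- sample.int(nHap, k[i])
    ind <- (hap + 1L) %/% 2L
    for (j in ind) gt[i, j] <- gt[i, j] + 1L
  }
  gmFromCalls(gt, individuals = sprintf("i%02d", seq_len(nInd)))
}

expectedFoldedProbs <- function(nHap) {
  half <- nHap %/% 2L
  p <- vapply(seq_len(half), function(i) {
    if (nHap - i == i) 1 / i else 1 / i + 1 / (nHap - i)
  }, numeric(1))
  p / sum(p)
}
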