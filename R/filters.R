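## The SNP filtering cascade: per-genotype masking, site-level filters,
## MAF filtering and scaffold/interval subsetting. Every op is monotone
## (output sites are a subset of input sites) and logs before/after counts.

.log <- function(fmt, ...) message(sprintf(paste0("[rohdiv] ", fmt), ...))

.logStep <- function(step, before, after)
  .log("%s: %d -> %d sites", step, before, after)

#' Mask low-confidence genotype calls
#'
#' Sets individual calls with read depth below \code{genoMinDepth} or
#' genotype quality below \code{genoMinGq} to missing. Calls with an absent
#' or NA DP/GQ value are left untouched; a matrix without DP and GQ assays
#' is returned unchanged with a warning.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param config a \linkS4class{FilterConfig}.
#' @return The masked \linkS4class{GenotypeMatrix}.
#' @export
maskGenotypes <- function(x, config = filterConfig()) {
  dp <- readDepth(x); gq <- genoQual(x)
  if (is.null(dp) && is.null(gq)) {
    warning("no DP or GQ assay; genotype masking is a no-op")
    return(x)
  }
  gt <- assay(x, "GT")
  nBefore <- sum(!is.na(gt))
  mask <- matrix(FALSE, nrow(gt), ncol(gt))
  if (!is.null(dp)) mask <- mask | (!is.na(dp) & dp < config@genoMinDepth)
  if (!is.null(gq)) mask <- mask | (!is.na(gq) & gq < config@genoMinGq)
  gt[mask] <- NA_integer_
  assay(x, "GT") <- gt
  .log("maskGenotypes: %d of %d calls set to missing",
       nBefore - sum(!is.na(gt)), nBefore)
  x
}

#' Resolve data-derived site depth bounds
#'
#' When the config's summed-depth bounds are NA they are derived from the
#' per-site summed depth distribution as \code{[mean/3, 2*mean]}, a
#' conventional guard against collapsed repeats and dropout. Returns the
#' config with bounds filled in (and logged), so that downstream filtering
#' is reproducible and idempotent.
#'
#' @param x a \linkS4class{GenotypeMatrix} with a DP assay.
#' @param config a \linkS4class{FilterConfig}.
#' @return A \linkS4class{FilterConfig} with numeric depth bounds.
#' @export
resolveDepthBounds <- function(x, config = filterConfig()) {
  if (!is.na(config@siteDepthLow) && !is.na(config@siteDepthHigh))
    return(config)
  dp <- readDepth(x)
  if (is.null(dp)) {
    .log("resolveDepthBounds: no DP assay; depth filter disabled")
    config@siteDepthLow <- 0
    config@siteDepthHigh <- Inf
    return(config)
  }
  m <- mean(rowSums(dp, na.rm = TRUE))
  if (is.na(config@siteDepthLow)) config@siteDepthLow <- m / 3
  if (is.na(config@siteDepthHigh)) config@siteDepthHigh <- 2 * m
  .log("resolveDepthBounds: summed-depth bounds [%.1f, %.1f] (mean %.1f)",
       config@siteDepthLow, config@siteDepthHigh, m)
  config
}

#' Site-level quality filtering
#'
#' Removes, in order: indel and multi-allelic records; sites whose summed
#' depth falls outside \code{[siteDepthLow, siteDepthHigh]} (bounds derived
#' from the data when NA, see [resolveDepthBounds()]; skipped without DP);
#' sites with QUAL below \code{minQual} (NA QUAL passes, as monomorphic
#' records carry none); sites with a missing-genotype fraction of
#' \code{maxMissingFrac} or more (strict: exactly 10\% missing fails the
#' default); and, unless \code{keepMonomorphic}, monomorphic records.
#'
#' @param x a \linkS4class{GenotypeMatrix} (genotypes already masked).
#' @param config a \linkS4class{FilterConfig}.
#' @param keepMonomorphic keep ALT="." records (all-sites mode).
#' @return The filtered \linkS4class{GenotypeMatrix}.
#' @export
filterSites <- function(x, config = filterConfig(),
                        keepMonomorphic = FALSE) {
  validObject(config)
  isIndel <- nchar(refAllele(x)) > 1L |
    vapply(strsplit(altAllele(x), ",", fixed = TRUE),
           function(a) any(nchar(a) > 1L & a != "."), logical(1))
  keep <- !isIndel & !isMultiallelic(x)
  .logStep("filterSites/indel+multiallelic", nrow(x), sum(keep))
  x <- x[keep, ]

  dp <- readDepth(x)
  if (!is.null(dp)) {
    config <- resolveDepthBounds(x, config)
    sd <- rowSums(dp, na.rm = TRUE)
    keep <- sd >= config@siteDepthLow & sd <= config@siteDepthHigh
    .logStep("filterSites/site-depth", nrow(x), sum(keep))
    x <- x[keep, ]
  }

  q <- siteQual(x)
  keep <- is.na(q) | q >= config@minQual
  .logStep("filterSites/QUAL", nrow(x), sum(keep))
  x <- x[keep, ]

  gt <- assay(x, "GT")
  missFrac <- rowMeans(is.na(gt))
  keep <- missFrac < config@maxMissingFrac
  .logStep("filterSites/missingness", nrow(x), sum(keep))
  x <- x[keep, ]

  if (!keepMonomorphic) {
    keep <- !isMonomorphic(x)
    .logStep("filterSites/monomorphic", nrow(x), sum(keep))
    x <- x[keep, ]
  }
  x
}

#' Minor allele frequency filter
#'
#' Keeps biallelic sites whose minor allele frequency, computed over
#' non-missing alleles, is at least \code{mafMin}. Sites with no called
#' alleles are removed unless \code{mafMin} is zero.
#'
#' @param x a \linkS4class{GenotypeMatrix} of biallelic sites.
#' @param mafMin MAF cutoff in [0, 0.5].
#' @return The filtered \linkS4class{GenotypeMatrix}.
#' @export
mafFilter <- function(x, mafMin = 0.05) {
  stopifnot(mafMin >= 0, mafMin <= 0.5)
  gt <- assay(x, "GT")
  nAllele <- 2 * rowSums(!is.na(gt))
  altc <- rowSums(gt, na.rm = TRUE)
  p <- ifelse(nAllele > 0, altc / nAllele, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- (!is.na(maf) & maf >= mafMin) | (is.na(maf) & mafMin == 0)
  .logStep(sprintf("mafFilter (MAF >= %g)", mafMin), nrow(x), sum(keep))
  x[keep, ]
}

#' Subset sites by scaffold and exclusion intervals
#'
#' Retains sites on an explicit scaffold set or on the \code{longestN}
#' scaffolds of a length table, then drops sites falling inside exclusion
#' intervals (e.g. sex-linked scaffolds or low-mappability regions supplied
#' as BED; see [readBedMask()] for the coordinate convention).
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param include character vector of scaffolds to keep; unknown scaffolds
#'   are an error.
#' @param longestN keep the N longest scaffolds of \code{scaffoldLengths}
#'   (ties broken by name for determinism).
#' @param scaffoldLengths named lengths vector (or TSV path); required with
#'   \code{longestN}.
#' @param excludeBed GRanges of excluded intervals, or a BED path.
#' @return The subset \linkS4class{GenotypeMatrix}.
#' @export
subsetScaffolds <- function(x, include = NULL, longestN = NULL,
                            scaffoldLengths = NULL, excludeBed = NULL) {
  if (is.character(scaffoldLengths) && length(scaffoldLengths) == 1L)
    scaffoldLengths <- readScaffoldLengths(scaffoldLengths)
  if (!is.null(longestN)) {
    if (is.null(scaffoldLengths))
      stop("longestN requires a scaffold length table")
    ord <- order(-scaffoldLengths, names(scaffoldLengths))
    include <- unique(c(include,
                        names(scaffoldLengths)[head(ord, longestN)]))
  }
  if (!is.null(include)) {
    known <- unique(scaffolds(x))
    if (!is.null(scaffoldLengths))
      known <- union(known, names(scaffoldLengths))
    bad <- setdiff(include, known)
    if (length(bad))
      stop("unknown scaffold(s) in include list: ",
           paste(bad, collapse = ", "))
    keep <- scaffolds(x) %in% include
    .logStep("subsetScaffolds/include", nrow(x), sum(keep))
    x <- x[keep, ]
  }
  if (!is.null(excludeBed)) {
    if (is.character(excludeBed)) excludeBed <- readBedMask(excludeBed)
    if (length(excludeBed)) {
      hit <- suppressWarnings(overlapsAny(granges(rowRanges(x)), excludeBed,
                                          ignore.strand = TRUE))
      .logStep("subsetScaffolds/excludeBed", nrow(x), sum(!hit))
      x <- x[!hit, ]
    }
  }
  x
}
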