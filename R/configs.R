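#' Create a FilterConfig
#'
#' @param siteDepthLow,siteDepthHigh bounds on per-site summed depth; NA
#'   (default) derives \code{[mean/3, 2*mean]} from the data at filter time.
#' @param genoMinDepth,genoMinGq per-genotype masking thresholds (calls with
#'   DP < genoMinDepth or GQ < genoMinGq become missing).
#' @param minQual minimum site QUAL.
#' @param maxMissingFrac sites with missing-call fraction >= this are removed.
#' @param mafMin minor allele frequency cutoff (kept when MAF >= mafMin).
#' @param hweAlphaZ cutoff on |FIS*sqrt(N)|.
#' @return A \linkS4class{FilterConfig}.
#' @examples
#' filterConfig(genoMinDepth = 8)
#' @export
filterConfig <- function(siteDepthLow = NA_real_, siteDepthHigh = NA_real_,
                         genoMinDepth = 10, genoMinGq = 15, minQual = 30,
                         maxMissingFrac = 0.10, mafMin = 0.05,
                         hweAlphaZ = 1.96) {
  new("FilterConfig", siteDepthLow = as.numeric(siteDepthLow),
      siteDepthHigh = as.numeric(siteDepthHigh),
      genoMinDepth = as.numeric(genoMinDepth),
      genoMinGq = as.numeric(genoMinGq), minQual = as.numeric(minQual),
      maxMissingFrac = as.numeric(maxMissingFrac),
      mafMin = as.numeric(mafMin), hweAlphaZ = as.numeric(hweAlphaZ))
}

#' Create an ROHConfig
#'
#' @param windowSnps scanning window size in SNPs (slides by one SNP).
#' @param minSnpsPerRun minimum SNPs for a reported run.
#' @param minDensityBpPerSnp maximum bp per SNP (density requirement).
#' @param maxGapBp maximum bp between consecutive SNPs of one run.
#' @param maxHetFracWindow,maxMissFracWindow per-window allowances for
#'   heterozygous and missing calls.
#' @param supportThreshold minimum fraction of homozygous covering windows
#'   for a SNP to be included in a run.
#' @param minLengthBp minimum run length in bp.
#' @param classEdgesBp increasing length-class edges in bp.
#' @param cmPerMb centimorgans per megabase, for ROH-age mapping.
#' @return An \linkS4class{ROHConfig}.
#' @examples
#' rohConfig(minLengthBp = 1e6)
#' @export
rohConfig <- function(windowSnps = 100, minSnpsPerRun = 100,
                      minDensityBpPerSnp = 1e4, maxGapBp = 1e5,
                      maxHetFracWindow = 0.08, maxMissFracWindow = 0.15,
                      supportThreshold = 0.05, minLengthBp = 5e5,
                      classEdgesBp = c(5e5, 1e6, 2e6, 4e6), cmPerMb = 1) {
  new("ROHConfig", windowSnps = as.integer(windowSnps),
      minSnpsPerRun = as.integer(minSnpsPerRun),
      minDensityBpPerSnp = as.numeric(minDensityBpPerSnp),
      maxGapBp = as.numeric(maxGapBp),
      maxHetFracWindow = as.numeric(maxHetFracWindow),
      maxMissFracWindow = as.numeric(maxMissFracWindow),
      supportThreshold = as.numeric(supportThreshold),
      minLengthBp = as.numeric(minLengthBp),
      classEdgesBp = as.numeric(classEdgesBp),
      cmPerMb = as.numeric(cmPerMb))
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:\n")
  cat(sprintf("  site depth bounds: [%s, %s] (NA = derived from data)\n",
              format(object@siteDepthLow), format(object@siteDepthHigh)))
  cat(sprintf("  genotype mask: DP < %g or GQ < %g -> missing\n",
              object@genoMinDepth, object@genoMinGq))
  cat(sprintf("  site: QUAL >= %g, missing < %g, MAF >= %g, |FISN| <= %g\n",
              object@minQual, object@maxMissingFrac, object@mafMin,
              object@hweAlphaZ))
})

setMethod("show", "ROHConfig", function(object) {
  cat("ROHConfig:\n")
  cat(sprintf("  window %d SNPs; het <= %g, missing <= %g per window\n",
              object@windowSnps, object@maxHetFracWindow,
              object@maxMissFracWindow))
  cat(sprintf("  SNP support >= %g; run: >= %d SNPs, >= %g bp, <= %g bp/SNP, gap <= %g bp\n",
              object@supportThreshold, object@minSnpsPerRun,
              object@minLengthBp, object@minDensityBpPerSnp,
              object@maxGapBp))
  cat(sprintf("  classes (bp): %s; %g cM/Mb\n",
              paste(object@classEdgesBp, collapse = "/"), object@cmPerMb))
})
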