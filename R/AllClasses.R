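## Central S4 classes. GenotypeMatrix rides on RangedSummarizedExperiment so
## that range-based subsetting, seqinfo and assay handling come from the
## Bioconductor stack; the GT assay uses the conventional diploid dosage
## coding 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing.

#' GenotypeMatrix: sites x individuals diploid genotype calls
#'
#' A \linkS4class{RangedSummarizedExperiment} subclass holding biallelic (or
#' flagged multi-allelic/monomorphic) sites as rows and diploid individuals
#' as columns. Assays: \code{GT} (integer dosage of the first ALT allele:
#' 0 hom-ref, 1 het, 2 hom-alt, NA missing), and optionally \code{DP}
#' (per-call read depth) and \code{GQ} (per-call phred genotype quality).
#' Row metadata: \code{ref}, \code{alt} (comma-collapsed), \code{qual}
#' (site QUAL), \code{monomorphic}, \code{multiallelic}.
#'
#' @seealso [GenotypeMatrix()] for construction, [loadVcf()] to read from
#'   VCF, [writeVcf()] to write.
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"GT" %in% assayNames(object))
    msg <- c(msg, "assay 'GT' is required")
  else {
    gt <- assay(object, "GT")
    bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
    if (any(bad))
      msg <- c(msg, "GT values must be 0, 1, 2 or NA")
  }
  need <- c("ref", "alt", "qual", "monomorphic", "multiallelic")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing rowData column(s): ",
                         paste(miss, collapse = ", ")))
  sc <- as.character(seqnames(rowRanges(object)))
  pos <- start(rowRanges(object))
  if (nrow(object) > 1L) {
    same <- sc[-1L] == sc[-length(sc)]
    if (any(same & diff(pos) <= 0))
      msg <- c(msg, "positions must be strictly increasing within a scaffold")
  }
  for (a in intersect(c("DP", "GQ"), assayNames(object))) {
    v <- assay(object, a)
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, paste0(a, " must be nonnegative"))
  }
  if (length(msg)) msg else TRUE
})

#' FilterConfig: thresholds of the SNP filtering cascade
#'
#' Holds every threshold of the site/genotype quality-filtering cascade as an
#' explicit parameter. Defaults follow common practice for ~20x short-read
#' resequencing panels: genotypes with depth < 10 or GQ < 15 are masked;
#' sites need QUAL >= 30 and < 10\% missing genotypes; MAF filtering at 0.05;
#' the Hardy-Weinberg z cutoff is |1.96|. Site summed-depth bounds default to
#' NA, meaning they are derived from the data as
#' \code{[mean/3, 2*mean]} of per-site summed depth at filter time.
#'
#' @slot siteDepthLow,siteDepthHigh numeric, bounds on per-site summed depth
#'   (NA = derive from the depth distribution).
#' @slot genoMinDepth,genoMinGq numeric, per-genotype masking thresholds.
#' @slot minQual numeric, minimum site QUAL.
#' @slot maxMissingFrac numeric, sites with missing fraction >= this are
#'   removed (strict: exactly 10\% missing fails the default).
#' @slot mafMin numeric, minor allele frequency cutoff.
#' @slot hweAlphaZ numeric, |FIS*sqrt(N)| cutoff.
#' @export
setClass("FilterConfig", representation(
  siteDepthLow = "numeric", siteDepthHigh = "numeric",
  genoMinDepth = "numeric", genoMinGq = "numeric",
  minQual = "numeric", maxMissingFrac = "numeric",
  mafMin = "numeric", hweAlphaZ = "numeric"),
  prototype(siteDepthLow = NA_real_, siteDepthHigh = NA_real_,
            genoMinDepth = 10, genoMinGq = 15, minQual = 30,
            maxMissingFrac = 0.10, mafMin = 0.05, hweAlphaZ = 1.96))

setValidity("FilterConfig", function(object) {
  msg <- character()
  num <- c(genoMinDepth = object@genoMinDepth, genoMinGq = object@genoMinGq,
           minQual = object@minQual, mafMin = object@mafMin,
           hweAlphaZ = object@hweAlphaZ)
  if (any(num < 0, na.rm = TRUE))
    msg <- c(msg, "all thresholds must be nonnegative")
  if (object@maxMissingFrac < 0 || object@maxMissingFrac > 1)
    msg <- c(msg, "maxMissingFrac must be in [0, 1]")
  if (!is.na(object@siteDepthLow) && !is.na(object@siteDepthHigh) &&
      object@siteDepthLow >= object@siteDepthHigh)
    msg <- c(msg, "siteDepthLow must be < siteDepthHigh")
  if (length(msg)) msg else TRUE
})

#' ROHConfig: parameters of the sliding-window ROH scan
#'
#' All knobs of the runs-of-homozygosity detector. Defaults reproduce a
#' conservative scan for >= 0.5 Mb runs: scanning windows of 100 SNPs
#' sliding by one SNP, up to 8\% heterozygous and 15\% missing calls per
#' window, SNPs kept when >= 5\% of covering windows are homozygous
#' (which trims four SNPs off each flank of a long homozygous block),
#' runs of >= 100 SNPs, >= 0.5 Mb, with at least 1 SNP per 10 kb and no
#' gap over 100 kb. Length classes 0.5-1, 1-2 and 2-4 Mb map to
#' inbreeding 100-50, 50-25 and 25-12.5 generations back under the
#' default 1 cM/Mb.
#'
#' @slot windowSnps integer, scanning window size in SNPs.
#' @slot minSnpsPerRun integer, minimum SNPs in a reported run.
#' @slot minDensityBpPerSnp numeric, maximum bp per SNP within a run.
#' @slot maxGapBp numeric, maximum gap between consecutive run SNPs.
#' @slot maxHetFracWindow,maxMissFracWindow numeric, window allowances.
#' @slot supportThreshold numeric, minimum fraction of homozygous covering
#'   windows for a SNP to enter a run.
#' @slot minLengthBp numeric, minimum run length.
#' @slot classEdgesBp numeric, increasing length-class edges.
#' @slot cmPerMb numeric, genetic-map calibration.
#' @export
setClass("ROHConfig", representation(
  windowSnps = "integer", minSnpsPerRun = "integer",
  minDensityBpPerSnp = "numeric", maxGapBp = "numeric",
  maxHetFracWindow = "numeric", maxMissFracWindow = "numeric",
  supportThreshold = "numeric", minLengthBp = "numeric",
  classEdgesBp = "numeric", cmPerMb = "numeric"),
  prototype(windowSnps = 100L, minSnpsPerRun = 100L,
            minDensityBpPerSnp = 1e4, maxGapBp = 1e5,
            maxHetFracWindow = 0.08, maxMissFracWindow = 0.15,
            supportThreshold = 0.05, minLengthBp = 5e5,
            classEdgesBp = c(5e5, 1e6, 2e6, 4e6), cmPerMb = 1))

setValidity("ROHConfig", function(object) {
  msg <- character()
  pos <- c(object@windowSnps, object@minSnpsPerRun,
           object@minDensityBpPerSnp, object@maxGapBp, object@minLengthBp,
           object@cmPerMb)
  if (any(pos <= 0)) msg <- c(msg, "all parameters must be positive")
  if (object@supportThreshold <= 0 || object@supportThreshold > 1)
    msg <- c(msg, "supportThreshold must be in (0, 1]")
  if (object@maxHetFracWindow < 0 || object@maxHetFracWindow > 1 ||
      object@maxMissFracWindow < 0 || object@maxMissFracWindow > 1)
    msg <- c(msg, "window allowances must be fractions in [0, 1]")
  if (is.unsorted(object@classEdgesBp, strictly = TRUE))
    msg <- c(msg, "classEdgesBp must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' FoldedSFS: folded site frequency spectrum
#'
#' Counts of sites per minor-allele-count bin 1..floor(n/2) for a (possibly
#' projected) haploid sample size n, together with L, the total number of
#' observed nucleic sites (monomorphic included) used to scale the spectrum
#' in downstream demographic inference.
#'
#' @slot bins numeric vector of length floor(nHaploid/2); bins[i] is the
#'   (possibly fractional, under expected projection) number of sites with
#'   minor-allele count i.
#' @slot nHaploid integer haploid sample size after projection.
#' @slot L numeric, total observed nucleic sites (NA when not supplied).
#' @export
setClass("FoldedSFS", representation(
  bins = "numeric", nHaploid = "integer", L = "numeric"),
  prototype(bins = numeric(), nHaploid = 0L, L = NA_real_))

setValidity("FoldedSFS", function(object) {
  msg <- character()
  if (length(object@bins) != object@nHaploid %/% 2L)
    msg <- c(msg, "bins must have length floor(nHaploid/2)")
  if (any(object@bins < 0)) msg <- c(msg, "bin counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' PedigreeSpec: mating design for the gene-dropping simulator
#'
#' Describes founders, matings and the simulated genome. Founders are named
#' \code{F1..Fk}; each mating row produces one named non-founder child.
#' Defaults emulate an outbred sea-duck-like founder pool: heterozygosity
#' 0.003 per bp and a 1 cM/Mb recombination map.
#'
#' @slot founders integer, number of founders.
#' @slot matings data.frame with character columns parentA, parentB, child;
#'   parents must be declared (founders or earlier children) before use.
#' @slot genome named numeric vector of scaffold lengths in bp.
#' @slot founderHetPerBp numeric, target founder heterozygosity per bp
#'   (0 simulates IBD tracts only, with no sites).
#' @slot recombCmPerMb numeric, recombination rate.
#' @slot seed integer or NA; when set, [simulatePedigree()] seeds from it.
#' @export
setClass("PedigreeSpec", representation(
  founders = "integer", matings = "data.frame", genome = "numeric",
  founderHetPerBp = "numeric", recombCmPerMb = "numeric", seed = "integer"),
  prototype(founders = 2L, matings = data.frame(), genome = c(scaf1 = 1e7),
            founderHetPerBp = 0.003, recombCmPerMb = 1, seed = NA_integer_))

setValidity("PedigreeSpec", function(object) {
  msg <- character()
  if (object@founders < 1L) msg <- c(msg, "need at least one founder")
  if (is.null(names(object@genome)) || any(object@genome <= 0))
    msg <- c(msg, "genome must be a named vector of positive lengths")
  if (object@founderHetPerBp < 0 || object@recombCmPerMb < 0)
    msg <- c(msg, "rates must be nonnegative")
  m <- object@matings
  if (nrow(m)) {
    if (!all(c("parentA", "parentB", "child") %in% colnames(m)))
      msg <- c(msg, "matings needs columns parentA, parentB, child")
    else {
      known <- paste0("F", seq_len(object@founders))
      for (i in seq_len(nrow(m))) {
        if (!all(c(m$parentA[i], m$parentB[i]) %in% known)) {
          msg <- c(msg, sprintf(
            "mating %d: parents must precede children (unknown parent)", i))
          break
        }
        if (m$child[i] %in% known) {
          msg <- c(msg, sprintf("mating %d: duplicate individual '%s'",
                                i, m$child[i]))
          break
        }
        known <- c(known, m$child[i])
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' PedigreeGenomes: simulated genomes with ground truth
#'
#' Result of [simulatePedigree()]: per-individual haplotype mosaics over
#' founder haplotype labels, the founder mutation map, and ground-truth
#' autozygous (IBD) tracts. Use [pedGenotypes()] to extract a
#' \linkS4class{GenotypeMatrix} and [truthTracts()] for the tract GRanges.
#'
#' @slot spec the generating \linkS4class{PedigreeSpec}.
#' @slot sites list per scaffold: data.frame(pos, owner) of mutation
#'   positions and the founder-haplotype label carrying the derived allele.
#' @slot haplotypes nested list: individual -> scaffold -> list(h1, h2),
#'   each a list(breaks, labels) run-length mosaic (breaks are 1-based
#'   segment start positions, first always 1).
#' @slot tracts GRanges of autozygous tracts with mcols individual.
#' @export
setClass("PedigreeGenomes", representation(
  spec = "PedigreeSpec", sites = "list", haplotypes = "list",
  tracts = "GRanges"))
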