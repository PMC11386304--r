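## Sliding-window runs-of-homozygosity detection. Windows are SNP-index
## based: consecutive windows of windowSnps SNPs sliding by one SNP, fully
## contained in the scaffold. A window is homozygous-eligible when its
## heterozygous and missing call counts stay within the allowances; a SNP
## enters a run when at least supportThreshold of the windows covering it
## are eligible (the denominator is the actual covering count, so scaffold
## edges are handled gracefully). With 100-SNP windows and 5% support this
## trims exactly four SNPs off each flank of a maximal eligible block.
## Candidate runs are maximal stretches of consecutively included SNPs,
## split at gaps over maxGapBp, then screened for SNP count, length and
## density.

#' Per-window homozygosity verdicts for one individual on one scaffold
#'
#' @param calls integer vector of dosage calls (0/1/2/NA), position-sorted.
#' @param config an \linkS4class{ROHConfig}.
#' @return Logical vector of length \code{length(calls) - windowSnps + 1}
#'   (empty when the scaffold has fewer SNPs than one window): TRUE where
#'   the window's het count <= floor(maxHetFracWindow * windowSnps) and
#'   missing count <= floor(maxMissFracWindow * windowSnps).
#' @export
windowVerdicts <- function(calls, config = rohConfig()) {
  w <- config@windowSnps
  n <- length(calls)
  if (n < w) return(logical(0))
  het <- as.numeric(!is.na(calls) & calls == 1L)
  mis <- as.numeric(is.na(calls))
  ch <- c(0, cumsum(het)); cm <- c(0, cumsum(mis))
  i <- seq_len(n - w + 1L)
  hetCount <- ch[i + w] - ch[i]
  misCount <- cm[i + w] - cm[i]
  hetCount <= floor(config@maxHetFracWindow * w) &
    misCount <= floor(config@maxMissFracWindow * w)
}

#' SNP support from overlapping window verdicts
#'
#' @param verdicts logical vector from [windowVerdicts()].
#' @param nSnps number of SNPs on the scaffold.
#' @param config an \linkS4class{ROHConfig}.
#' @return list with \code{support} (fraction of covering windows that are
#'   eligible; NA when the scaffold yields no window), \code{nCovering},
#'   and \code{included} (support >= supportThreshold).
#' @export
snpSupport <- function(verdicts, nSnps, config = rohConfig()) {
  w <- config@windowSnps
  nw <- length(verdicts)
  if (nw == 0L)
    return(list(support = rep(NA_real_, nSnps),
                nCovering = integer(nSnps),
                included = logical(nSnps)))
  stopifnot(nw == nSnps - w + 1L)
  i <- seq_len(nSnps)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  cv <- c(0, cumsum(verdicts))
  elig <- cv[hi + 1L] - cv[lo]
  nCover <- hi - lo + 1L
  support <- elig / nCover
  list(support = support, nCovering = nCover,
       included = support >= config@supportThreshold)
}

#' Assemble included SNPs into runs of homozygosity
#'
#' @param pos positions (bp, sorted) of the scaffold's SNPs.
#' @param included logical inclusion flags from [snpSupport()].
#' @param config an \linkS4class{ROHConfig}.
#' @return data.frame with one row per retained run: start, end (positions
#'   of the first/last included SNP), n_snps, length_bp (end - start + 1).
#' @export
assembleRuns <- function(pos, included, config = rohConfig()) {
  stopifnot(length(pos) == length(included))
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be sorted")
  idx <- which(included)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0))
  if (!length(idx)) return(empty)
  newRun <- c(TRUE, diff(idx) != 1L | diff(pos[idx]) > config@maxGapBp)
  first <- which(newRun)
  last <- c(first[-1L] - 1L, length(idx))
  start <- pos[idx[first]]
  end <- pos[idx[last]]
  nSnps <- last - first + 1L
  len <- end - start + 1
  keep <- nSnps >= config@minSnpsPerRun & len >= config@minLengthBp &
    len / nSnps <= config@minDensityBpPerSnp
  data.frame(start = as.numeric(start[keep]), end = as.numeric(end[keep]),
             n_snps = as.integer(nSnps[keep]),
             length_bp = as.numeric(len[keep]), row.names = NULL)
}

#' ROH scan for one individual on one scaffold
#'
#' Chains [windowVerdicts()], [snpSupport()] and [assembleRuns()]. Exposed
#' for streaming use on data too large to hold as one matrix.
#'
#' @inheritParams assembleRuns
#' @param calls integer dosage vector parallel to \code{pos}.
#' @return The [assembleRuns()] data.frame.
#' @export
rohScaffold <- function(calls, pos, config = rohConfig()) {
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be sorted")
  v <- windowVerdicts(calls, config)
  s <- snpSupport(v, length(calls), config)
  assembleRuns(pos, s$included, config)
}

.classLabels <- function(edges) {
  mb <- function(b) sub("\\.?0+$", "", sprintf("%.2f", b / 1e6))
  k <- length(edges)
  c(paste0(mb(edges[-k]), "-", mb(edges[-1]), "Mb"),
    paste0(">", mb(edges[k]), "Mb"))
}

.classify <- function(lengthBp, edges) {
  lab <- .classLabels(edges)
  idx <- findInterval(lengthBp, edges)
  idx[idx == 0] <- NA_integer_  # below the first edge (non-default configs)
  factor(lab[idx], levels = lab)
}

#' Detect runs of homozygosity in a genotype matrix
#'
#' Runs the sliding-window scan for every individual on every scaffold.
#' Scaffolds shorter than \code{minLengthBp} (by seqlength, when known) are
#' skipped with a logged warning; scaffolds with fewer SNPs than one window
#' yield nothing.
#'
#' @param x a \linkS4class{GenotypeMatrix} (typically MAF-filtered,
#'   mappability-masked, on the longest scaffolds).
#' @param config an \linkS4class{ROHConfig}.
#' @return A GRanges of ROH segments (start/end = first/last included SNP,
#'   1-based inclusive) with mcols: individual, n_snps, length_bp,
#'   size_class, gen_min, gen_max (the inbreeding-age range of the class,
#'   in generations; see [ageFromLength()]).
#' @export
detectRoh <- function(x, config = rohConfig()) {
  sc <- scaffolds(x)
  pos <- positions(x)
  gt <- assay(x, "GT")
  ids <- sampleIds(x)
  sl <- seqlengths(rowRanges(x))
  byScaf <- split(seq_along(sc), factor(sc, levels = unique(sc)))
  short <- names(byScaf)[!is.na(sl[names(byScaf)]) &
                           sl[names(byScaf)] < config@minLengthBp]
  if (length(short)) {
    .log("detectRoh: skipping %d scaffold(s) shorter than %g bp",
         length(short), config@minLengthBp)
    byScaf <- byScaf[setdiff(names(byScaf), short)]
  }
  res <- list()
  for (s in names(byScaf)) {
    i <- byScaf[[s]]
    p <- pos[i]
    for (j in seq_along(ids)) {
      runs <- rohScaffold(gt[i, j], p, config)
      if (nrow(runs)) {
        runs$scaffold <- s
        runs$individual <- ids[j]
        res[[length(res) + 1L]] <- runs
      }
    }
  }
  if (!length(res)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(individual = character(0),
                           n_snps = integer(0), length_bp = numeric(0),
                           size_class = factor(character(0),
                             levels = .classLabels(config@classEdgesBp)),
                           gen_min = numeric(0), gen_max = numeric(0))
    return(gr)
  }
  df <- do.call(rbind, res)
  gr <- GRanges(seqnames = df$scaffold,
                ranges = IRanges(df$start, df$end))
  cls <- .classify(df$length_bp, config@classEdgesBp)
  edges <- config@classEdgesBp
  gmax <- ageFromLength(edges, config@cmPerMb)       # age at lower edge
  gmin <- c(ageFromLength(edges[-1], config@cmPerMb), 0)
  ci <- as.integer(cls)
  mcols(gr) <- DataFrame(individual = df$individual,
                         n_snps = df$n_snps, length_bp = df$length_bp,
                         size_class = cls,
                         gen_min = gmin[ci], gen_max = gmax[ci])
  gr[order(mcols(gr)$individual, as.character(seqnames(gr)), start(gr))]
}

#' F_ROH and length-class decomposition per individual
#'
#' F_ROH = total ROH length / length of the analysed autosome
#' (\code{lAutoBp}, e.g. the summed length of the scaffolds scanned).
#' Segments at or above the top class edge are counted in the open top
#' class and reported; none are expected under the default scan.
#'
#' @param segments GRanges from [detectRoh()].
#' @param lAutoBp analysed autosome length in bp.
#' @param individuals individuals to report (zero rows included); defaults
#'   to those present in \code{segments}.
#' @param scaffoldLengths optional named lengths; when given, a segment
#'   extending beyond its scaffold is an error.
#' @param config the \linkS4class{ROHConfig} used (for class edges).
#' @return data.frame with columns individual, n_roh, l_roh_bp, f_roh and
#'   one l_<class>_bp plus f_<class> pair per length class.
#' @export
classifyFroh <- function(segments, lAutoBp, individuals = NULL,
                         scaffoldLengths = NULL, config = rohConfig()) {
  stopifnot(lAutoBp > 0)
  if (!is.null(scaffoldLengths)) {
    sn <- as.character(seqnames(segments))
    bad <- is.na(scaffoldLengths[sn]) | end(segments) > scaffoldLengths[sn]
    if (any(bad))
      stop("segment(s) outside the analysed scaffolds: ",
           paste(head(sn[bad]), collapse = ", "))
  }
  if (is.null(individuals))
    individuals <- sort(unique(mcols(segments)$individual))
  lab <- levels(mcols(segments)$size_class)
  rows <- lapply(individuals, function(id) {
    seg <- segments[mcols(segments)$individual == id]
    len <- mcols(seg)$length_bp
    byClass <- vapply(lab, function(cl)
      sum(len[mcols(seg)$size_class == cl]), numeric(1))
    out <- data.frame(individual = id, n_roh = length(seg),
                      l_roh_bp = sum(len), f_roh = sum(len) / lAutoBp)
    for (cl in lab) {
      out[[paste0("l_", gsub("[->]", "", cl), "_bp")]] <- byClass[[cl]]
      out[[paste0("f_", gsub("[->]", "", cl))]] <- byClass[[cl]] / lAutoBp
    }
    out
  })
  do.call(rbind, rows)
}

#' Expected age of an ROH from its length
#'
#' An autozygous segment inherited from a common ancestor g generations
#' back has expected length 100/(2g) cM; inverting, g = 100/(2 L_cM) with
#' L_cM = length_bp * cmPerMb / 1e6. Under 1 cM/Mb the class edges 0.5, 1,
#' 2 and 4 Mb map to 100, 50, 25 and 12.5 generations.
#'
#' @param lengthBp segment length(s) in bp, positive.
#' @param cmPerMb genetic-map calibration (default 1).
#' @return Expected number of generations to the common ancestor.
#' @examples
#' ageFromLength(c(5e5, 1e6, 2e6, 4e6))  # 100, 50, 25, 12.5
#' @export
ageFromLength <- function(lengthBp, cmPerMb = 1) {
  if (any(lengthBp <= 0)) stop("lengthBp must be positive")
  if (cmPerMb <= 0) stop("cmPerMb must be positive")
  lengthCm <- lengthBp * cmPerMb / 1e6
  100 / (2 * lengthCm)
}
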