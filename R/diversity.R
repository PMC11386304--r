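## Diversity from the "all sites" matrix: per-individual heterozygosity and
## windowed nucleotide diversity with a missing-data-aware denominator
## (monomorphic genotyped sites contribute comparisons with zero
## differences, so pi is a per-base-pair quantity, not a per-SNP one).

#' Per-individual observed heterozygosity
#'
#' Heterozygous calls divided by non-missing calls, per individual, over an
#' all-sites matrix (polymorphic plus monomorphic). The per-individual
#' genotyped-site counts are returned too; their mean is the conventional
#' choice for the L parameter scaling a site frequency spectrum.
#'
#' @param x a \linkS4class{GenotypeMatrix} including monomorphic sites.
#' @return data.frame with columns individual, n_genotyped, n_het,
#'   heterozygosity (NA, with a warning, for individuals with no genotyped
#'   site).
#' @export
individualHeterozygosity <- function(x) {
  gt <- assay(x, "GT")
  nGeno <- colSums(!is.na(gt))
  nHet <- colSums(gt == 1L, na.rm = TRUE)
  het <- ifelse(nGeno > 0, nHet / nGeno, NA_real_)
  if (any(nGeno == 0))
    warning("individual(s) with zero genotyped sites: ",
            paste(sampleIds(x)[nGeno == 0], collapse = ", "))
  data.frame(individual = sampleIds(x), n_genotyped = nGeno,
             n_het = nHet, heterozygosity = het, row.names = NULL)
}

#' Average genotyped sites per individual (the SFS "L")
#'
#' @param x a \linkS4class{GenotypeMatrix} including monomorphic sites.
#' @return Mean over individuals of the non-missing call count.
#' @export
observedL <- function(x) mean(colSums(!is.na(assay(x, "GT"))))

#' Windowed nucleotide diversity
#'
#' For each genotyped site with k alt alleles among n called alleles the
#' number of pairwise allele differences is k(n-k) and the number of
#' pairwise comparisons n(n-1)/2; windows of \code{windowBp} tiling each
#' scaffold from position 1 sum both. Ungenotyped positions (and positions
#' absent from the matrix) contribute nothing to either count; multi-allelic
#' records are excluded. The final partial window of a scaffold is retained
#' and flagged.
#'
#' @param x a \linkS4class{GenotypeMatrix} all-sites matrix.
#' @param windowBp window width in bp (default 10 kb).
#' @param scaffoldLengths optional named lengths; defaults to the matrix's
#'   seqlengths, falling back to the last observed position per scaffold.
#' @return data.frame with columns scaffold, start, end, n_sites, n_diffs,
#'   n_comps, pi (NA where n_comps = 0), partial.
#' @export
windowedPi <- function(x, windowBp = 1e4, scaffoldLengths = NULL) {
  if (windowBp <= 0) stop("windowBp must be positive")
  x <- x[!isMultiallelic(x), ]
  gt <- assay(x, "GT")
  n <- 2 * rowSums(!is.na(gt))
  k <- rowSums(gt, na.rm = TRUE)
  diffs <- k * (n - k)
  comps <- n * (n - 1) / 2
  sc <- scaffolds(x)
  pos <- positions(x)
  sl <- seqlengths(rowRanges(x))
  lv <- seqlevels(rowRanges(x))
  if (is.null(scaffoldLengths)) scaffoldLengths <- sl
  lens <- vapply(lv, function(s) {
    L <- scaffoldLengths[s]
    if (is.null(L) || is.na(L)) max(pos[sc == s], 0) else as.numeric(L)
  }, numeric(1))
  out <- lapply(lv, function(s) {
    i <- sc == s
    L <- lens[[s]]
    nWin <- max(1L, ceiling(L / windowBp))
    win <- (pos[i] - 1) %/% windowBp + 1
    d <- numeric(nWin); cmp <- numeric(nWin); ns <- numeric(nWin)
    td <- rowsum(diffs[i], win); tc <- rowsum(comps[i], win)
    tn <- rowsum(rep(1, sum(i)), win)
    wIdx <- as.integer(rownames(td))
    d[wIdx] <- td[, 1]; cmp[wIdx] <- tc[, 1]; ns[wIdx] <- tn[, 1]
    start <- (seq_len(nWin) - 1) * windowBp + 1
    end <- pmin(start + windowBp - 1, L)
    data.frame(scaffold = s, start = start, end = end, n_sites = ns,
               n_diffs = d, n_comps = cmp,
               pi = ifelse(cmp > 0, d / cmp, NA_real_),
               partial = end - start + 1 < windowBp)
  })
  do.call(rbind, out)
}

#' Genome-wide nucleotide diversity from windows
#'
#' Pools raw difference and comparison counts across windows
#' (\code{sum(n_diffs)/sum(n_comps)}), the weighting that keeps the
#' estimate unbiased under uneven callable fractions; the unweighted mean
#' of per-window ratios is reported alongside for comparison.
#'
#' @param windows output of [windowedPi()].
#' @return list with \code{pi} (pooled-count estimate), \code{meanWindowPi},
#'   \code{n_diffs}, \code{n_comps}. \code{pi} is NA, with a warning, when
#'   no window has comparisons.
#' @export
genomewidePi <- function(windows) {
  d <- sum(windows$n_diffs); cmp <- sum(windows$n_comps)
  if (cmp == 0) {
    warning("no window with genotyped comparisons; pi undefined")
    return(list(pi = NA_real_, meanWindowPi = NA_real_,
                n_diffs = d, n_comps = cmp))
  }
  list(pi = d / cmp,
       meanWindowPi = mean(windows$pi, na.rm = TRUE),
       n_diffs = d, n_comps = cmp)
}
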