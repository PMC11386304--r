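## Folded site-frequency spectrum with expected hypergeometric projection.
## Folding bins sites by minor-allele count (ancestral state unknown);
## projection spreads a site with k alt alleles among n called ones over
## the spectrum of a smaller haploid sample m by the hypergeometric
## sampling distribution, which keeps sites with missing genotypes usable.

#' Folded site frequency spectrum from a genotype matrix
#'
#' With \code{mode = "project"} (default), every biallelic site with at
#' least \code{projectTo} called alleles contributes its expected
#' hypergeometric allocation over minor-allele counts 1..floor(projectTo/2)
#' (mass that projects to monomorphic is dropped; singletons are kept).
#' \code{projectTo} defaults to 90\% of the full haploid size, a standard
#' compromise keeping most sites at little spectrum shrinkage. With
#' \code{mode = "complete"}, only sites with no missing call contribute,
#' at the full haploid size.
#'
#' @param x a \linkS4class{GenotypeMatrix} of biallelic SNPs.
#' @param projectTo projected haploid sample size (>= 2); ignored in
#'   complete mode.
#' @param mode "project" or "complete".
#' @param L total observed nucleic sites to record (see [observedL()]);
#'   NA when not supplied.
#' @return A \linkS4class{FoldedSFS}.
#' @export
foldedSfs <- function(x, projectTo = NULL,
                      mode = c("project", "complete"), L = NA_real_) {
  mode <- match.arg(mode)
  x <- x[!isMultiallelic(x), ]
  gt <- assay(x, "GT")
  full <- 2L * ncol(gt)
  nCalled <- 2L * rowSums(!is.na(gt))
  k <- rowSums(gt, na.rm = TRUE)
  if (mode == "complete") {
    m <- full
    use <- nCalled == full
    kk <- k[use]
    minor <- pmin(kk, m - kk)
    minor <- minor[minor > 0]
    bins <- tabulate(minor, nbins = m %/% 2L)
  } else {
    if (is.null(projectTo)) projectTo <- floor(0.9 * full)
    m <- as.integer(projectTo)
    if (m < 2) stop("projectTo must be at least 2")
    if (m > full) stop("projectTo cannot exceed the full haploid size")
    use <- nCalled >= m
    grp <- table(paste(nCalled[use], k[use]))
    unfolded <- numeric(m + 1L)
    for (g in names(grp)) {
      nk <- as.integer(strsplit(g, " ", fixed = TRUE)[[1]])
      j <- 0:m
      unfolded <- unfolded +
        grp[[g]] * dhyper(j, nk[2], nk[1] - nk[2], m)
    }
    half <- m %/% 2L
    bins <- numeric(half)
    for (i in seq_len(half)) {
      bins[i] <- unfolded[i + 1L] +
        if (m - i != i) unfolded[m - i + 1L] else 0
    }
  }
  new("FoldedSFS", bins = as.numeric(bins), nHaploid = as.integer(m),
      L = as.numeric(L))
}

#' @rdname FoldedSFS-accessors
#' @param x a \linkS4class{FoldedSFS}.
#' @export
setMethod("sfsBins", "FoldedSFS", function(x) x@bins)
#' @rdname FoldedSFS-accessors
#' @export
setMethod("sfsHaploidSize", "FoldedSFS", function(x) x@nHaploid)
#' @rdname FoldedSFS-accessors
#' @export
setMethod("sfsL", "FoldedSFS", function(x) x@L)

#' Accessors for FoldedSFS
#' @name FoldedSFS-accessors
#' @return \code{sfsBins}: numeric vector of per-bin site counts;
#'   \code{sfsHaploidSize}: integer; \code{sfsL}: numeric.
NULL

setMethod("show", "FoldedSFS", function(object) {
  cat("FoldedSFS: n_haploid =", object@nHaploid,
      "| segregating mass =", round(sum(object@bins), 2),
      "| L =", object@L, "\n")
})

#' Write / read a folded SFS as plain text
#'
#' A whitespace-separated bin vector (minor-allele counts ascending)
#' preceded by commented header lines recording the haploid sample size
#' and L.
#'
#' @param sfs a \linkS4class{FoldedSFS}.
#' @param path text file path.
#' @return \code{writeSfs}: \code{path} invisibly; \code{readSfs}: a
#'   \linkS4class{FoldedSFS}.
#' @export
writeSfs <- function(sfs, path) {
  writeLines(c(sprintf("# n_haploid: %d", sfs@nHaploid),
               sprintf("# L: %s", format(sfs@L, digits = 15)),
               paste(format(sfs@bins, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     collapse = " ")), path)
  invisible(path)
}

#' @rdname writeSfs
#' @export
readSfs <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  nh <- as.integer(sub(".*n_haploid:\\s*", "", grep("n_haploid", hdr,
                                                    value = TRUE)[1]))
  Ls <- sub(".*L:\\s*", "", grep("L:", hdr, value = TRUE)[1])
  L <- if (is.na(Ls) || Ls == "NA") NA_real_ else as.numeric(Ls)
  vec <- grep("^[^#]", lines, value = TRUE)
  bins <- as.numeric(strsplit(trimws(vec[1]), "\\s+")[[1]])
  new("FoldedSFS", bins = bins, nHaploid = nh, L = L)
}
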