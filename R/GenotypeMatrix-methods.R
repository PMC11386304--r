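#' Construct a GenotypeMatrix
#'
#' Builds a \linkS4class{GenotypeMatrix} from parallel per-site vectors and a
#' sites x individuals call matrix. Sites are sorted by scaffold (order of
#' first appearance) and position; duplicated (scaffold, position) pairs are
#' an error.
#'
#' @param scaffold character vector of scaffold ids, one per site.
#' @param pos 1-based positions, one per site.
#' @param calls integer matrix, sites x individuals, values 0 (hom-ref),
#'   1 (het), 2 (hom-alt) or NA (missing).
#' @param ref,alt per-site alleles; \code{alt} uses "." for monomorphic
#'   records and comma-separated alleles for multi-allelic ones.
#' @param qual per-site phred-scaled QUAL (NA allowed).
#' @param depth,genoQual optional per-call matrices (same dim as calls).
#' @param individuals individual ids; default taken from colnames(calls).
#' @param scaffoldLengths optional named vector of scaffold lengths, stored
#'   as seqlengths.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' gm <- GenotypeMatrix(scaffold = c("s1", "s1"), pos = c(100, 200),
#'                      calls = rbind(c(0L, 1L), c(2L, NA)),
#'                      ref = c("A", "C"), alt = c("G", "T"),
#'                      individuals = c("i1", "i2"))
#' calls(gm)
#' @export
GenotypeMatrix <- function(scaffold, pos, calls,
                           ref = rep("N", length(pos)),
                           alt = rep("N", length(pos)),
                           qual = rep(NA_real_, length(pos)),
                           depth = NULL, genoQual = NULL,
                           individuals = colnames(calls),
                           scaffoldLengths = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n <- length(pos)
  stopifnot(length(scaffold) == n, nrow(calls) == n)
  if (is.null(individuals))
    individuals <- paste0("ind", seq_len(ncol(calls)))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  qual <- rep_len(qual, n)
  ord <- order(match(scaffold, unique(scaffold)), pos)
  scaffold <- scaffold[ord]; pos <- pos[ord]
  if (n > 1L && any(scaffold[-1L] == scaffold[-n] & diff(pos) == 0))
    stop("duplicated (scaffold, position) pair")
  calls <- calls[ord, , drop = FALSE]
  ref <- ref[ord]; alt <- alt[ord]; qual <- qual[ord]
  alt[is.na(alt)] <- "."
  mono <- alt %in% c(".", "")
  multi <- grepl(",", alt, fixed = TRUE)
  rr <- GRanges(seqnames = factor(scaffold, levels = unique(scaffold)),
                ranges = IRanges(start = pos, width = 1L))
  mcols(rr) <- DataFrame(ref = ref, alt = alt, qual = as.numeric(qual),
                         monomorphic = mono, multiallelic = multi)
  if (!is.null(scaffoldLengths)) {
    sl <- scaffoldLengths[seqlevels(rr)]
    names(sl) <- seqlevels(rr)
    suppressWarnings(seqlengths(rr) <- sl)
  }
  assays <- list(GT = unname(calls))
  if (!is.null(depth)) {
    depth <- as.matrix(depth)[ord, , drop = FALSE]
    storage.mode(depth) <- "integer"
    assays$DP <- unname(depth)
  }
  if (!is.null(genoQual)) {
    genoQual <- as.matrix(genoQual)[ord, , drop = FALSE]
    storage.mode(genoQual) <- "integer"
    assays$GQ <- unname(genoQual)
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = rr,
                             colData = DataFrame(row.names = individuals))
  new("GenotypeMatrix", se)
}

#' Accessors for GenotypeMatrix
#'
#' Small accessors in place of slot/assay access: \code{calls} returns the
#' integer GT matrix, \code{readDepth}/\code{genoQual} the DP/GQ matrices
#' (NULL when absent), the rest per-site metadata vectors.
#'
#' @param x a \linkS4class{GenotypeMatrix} (or \linkS4class{FoldedSFS} for
#'   the sfs* accessors).
#' @return Matrix, vector or scalar as named.
#' @name GenotypeMatrix-accessors
NULL

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("calls", "GenotypeMatrix", function(x) {
  m <- assay(x, "GT")
  dimnames(m) <- list(NULL, rownames(colData(x)))
  m
})
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("readDepth", "GenotypeMatrix", function(x)
  if ("DP" %in% assayNames(x)) assay(x, "DP") else NULL)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("genoQual", "GenotypeMatrix", function(x)
  if ("GQ" %in% assayNames(x)) assay(x, "GQ") else NULL)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("scaffolds", "GenotypeMatrix", function(x)
  as.character(seqnames(rowRanges(x))))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("positions", "GenotypeMatrix", function(x) start(rowRanges(x)))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("refAllele", "GenotypeMatrix", function(x) rowData(x)$ref)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("altAllele", "GenotypeMatrix", function(x) rowData(x)$alt)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("siteQual", "GenotypeMatrix", function(x) rowData(x)$qual)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("isMonomorphic", "GenotypeMatrix", function(x)
  rowData(x)$monomorphic)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("isMultiallelic", "GenotypeMatrix", function(x)
  rowData(x)$multiallelic)
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x)
  rownames(colData(x)))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) nrow(x))
#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) ncol(x))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object),
      "individuals\n")
  cat("  scaffolds:", length(unique(scaffolds(object))),
      "| monomorphic:", sum(isMonomorphic(object)),
      "| multiallelic:", sum(isMultiallelic(object)), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  gt <- assay(object, "GT")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(gt))))
})
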