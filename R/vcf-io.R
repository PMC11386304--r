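## VCF, BED and scaffold-table I/O. Parsing leans on VariantAnnotation /
## rtracklayer; writing uses a small v4.2 text emitter so that monomorphic
## ALT="." records round-trip exactly.

# GT string -> dosage code; haploid and half-calls (./1) and any genotype
# touching an allele index >= 2 are treated as missing.
.gtToCode <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    a <- strsplit(s, "[/|]", perl = FALSE)[[1]]
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai > 1L)) return(NA_integer_)
    sum(ai)
  }, integer(1))
  m <- matrix(code[match(as.vector(gt), u)], nrow = nrow(gt),
              ncol = ncol(gt))
  colnames(m) <- colnames(gt)
  m
}

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' Parses a VCF (v4.2, GT required; DP/GQ used when present) via
#' \pkg{VariantAnnotation}. Multi-allelic records are retained but flagged
#' (their genotypes touching allele indices >= 2 become missing); records
#' with ALT="." are flagged monomorphic and kept only when
#' \code{keepMonomorphic}. Duplicated (scaffold, position) records are an
#' error. Contig lengths from the header are stored as seqlengths.
#'
#' @param path VCF file (plain or bgzipped).
#' @param keepMonomorphic logical; keep ALT="." records (the "all sites"
#'   representation needed for missing-data-aware diversity).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
loadVcf <- function(path, keepMonomorphic = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  g <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(g)) stop("VCF '", path, "' has no GT FORMAT field")
  rr <- rowRanges(vcf)
  scaffold <- as.character(seqnames(rr))
  pos <- start(rr)
  if (anyDuplicated(paste(scaffold, pos)))
    stop("duplicated (scaffold, position) record in '", path, "'")
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  altC <- as(altL, "CharacterList")
  alt <- unstrsplit(altC, sep = ",")
  alt[alt == ""] <- "."
  qual <- VariantAnnotation::qual(vcf)
  callsM <- .gtToCode(g$GT)
  dp <- if ("DP" %in% names(g)) {
    d <- g$DP; storage.mode(d) <- "integer"; d
  } else NULL
  gq <- if ("GQ" %in% names(g)) {
    q <- g$GQ; storage.mode(q) <- "integer"; q
  } else NULL
  sl <- seqlengths(vcf)
  gm <- GenotypeMatrix(scaffold = scaffold, pos = pos, calls = callsM,
                       ref = ref, alt = alt, qual = qual,
                       depth = dp, genoQual = gq,
                       individuals = colnames(g$GT),
                       scaffoldLengths = if (all(is.na(sl))) NULL else sl)
  if (!keepMonomorphic) gm <- gm[!isMonomorphic(gm), ]
  gm
}

.codeToGt <- function(code) {
  out <- c("0/0", "0/1", "1/1")[code + 1L]
  out[is.na(code)] <- "./."
  out
}

#' Write a GenotypeMatrix as VCF v4.2
#'
#' Emits GT plus DP/GQ when present; monomorphic sites are written with
#' ALT=".". Method on the \pkg{VariantAnnotation} generic.
#'
#' @param obj a \linkS4class{GenotypeMatrix}.
#' @param filename output path.
#' @param ... unused.
#' @return \code{filename}, invisibly.
#' @export
setMethod("writeVcf", "GenotypeMatrix", function(obj, filename, ...) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rohdiv")
  sl <- seqlengths(rowRanges(obj))
  lv <- seqlevels(rowRanges(obj))
  hdr <- c(hdr, ifelse(is.na(sl[lv]),
                       sprintf("##contig=<ID=%s>", lv),
                       sprintf("##contig=<ID=%s,length=%d>", lv, sl[lv])))
  hdr <- c(hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  hasDp <- !is.null(readDepth(obj))
  hasGq <- !is.null(genoQual(obj))
  if (hasDp) hdr <- c(hdr,
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (hasGq) hdr <- c(hdr,
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sampleIds(obj)),
                      collapse = "\t"))
  gt <- calls(obj)
  fields <- matrix(.codeToGt(gt), nrow = nrow(gt))
  fmt <- "GT"
  if (hasDp) {
    d <- readDepth(obj)
    ds <- matrix(as.character(d), nrow = nrow(d)); ds[is.na(d)] <- "."
    fields <- matrix(paste(fields, ds, sep = ":"), nrow = nrow(d))
    fmt <- paste0(fmt, ":DP")
  }
  if (hasGq) {
    q <- genoQual(obj)
    qs <- matrix(as.character(q), nrow = nrow(q)); qs[is.na(q)] <- "."
    fields <- matrix(paste(fields, qs, sep = ":"), nrow = nrow(q))
    fmt <- paste0(fmt, ":GQ")
  }
  qual <- siteQual(obj)
  qualS <- ifelse(is.na(qual), ".", sub("\\.?0+$", "",
                                        sprintf("%.4f", qual)))
  body <- paste(scaffolds(obj), positions(obj), ".", refAllele(obj),
                altAllele(obj), qualS, ".", ".", fmt, sep = "\t")
  if (ncol(fields)) {
    smp <- do.call(paste, c(lapply(seq_len(ncol(fields)),
                                   function(j) fields[, j]),
                            list(sep = "\t")))
    body <- paste(body, smp, sep = "\t")
  }
  writeLines(c(hdr, body), filename)
  invisible(filename)
})

#' Read a two-column scaffold length table
#'
#' Tab-separated \code{scaffold<TAB>length}; a header line is detected and
#' skipped.
#'
#' @param path TSV path.
#' @return Named numeric vector of lengths.
#' @export
readScaffoldLengths <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("scaffold length table needs two columns")
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, ]
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a BED exclusion mask as GRanges
#'
#' Centralises the 0-based half-open (BED) to 1-based inclusive (VCF)
#' conversion, which \pkg{rtracklayer} performs on import. An empty file
#' yields an empty GRanges.
#'
#' @param path BED path.
#' @return A GRanges of excluded intervals (1-based inclusive).
#' @export
readBedMask <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  lines <- readLines(path)
  if (!length(trimws(lines)) || all(trimws(lines) == ""))
    return(GRanges())
  rtracklayer::import(path, format = "BED")
}
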