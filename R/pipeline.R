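## Orchestration of the two data-set flows:
##   base VCF  -> mask -> site filters -> HWE -> MAF -> scaffold subset -> ROH
##   all-sites -> mask -> site filters(keep mono) -> heterozygosity + pi
##   base      -> folded SFS (with L from the all-sites flow)
## Each stage logs before/after counts; the effective configuration is
## echoed to the output directory for provenance.

.writeTsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

.echoConfig <- function(cfg, outDir, name) {
  yaml::write_yaml(cfg, file.path(outDir, name))
}

.cfgList <- function(x) {
  sl <- slotNames(class(x))
  setNames(lapply(sl, function(s) slot(x, s)), sl)
}

#' Run the inbreeding (ROH) flow
#'
#' Base VCF through genotype masking, site filters, the Hardy-Weinberg
#' FISN filter, MAF filtering, scaffold subsetting (longest N, minus
#' exclusion intervals), the sliding-window ROH scan and the F_ROH
#' summary. Outputs (in \code{outDir}): \code{hwe_report.tsv},
#' \code{roh_segments.tsv}, \code{froh_summary.tsv},
#' \code{roh_class_table.tsv}, \code{inbreeding_config.yaml}.
#'
#' @param vcf path to the base VCF (biallelic SNPs).
#' @param outDir output directory (created if needed).
#' @param scaffoldLengths named lengths vector or two-column TSV path.
#' @param filter a \linkS4class{FilterConfig}.
#' @param roh an \linkS4class{ROHConfig}.
#' @param longestN restrict the scan to the N longest scaffolds (NULL =
#'   all); L_AUTO is the summed length of the scanned scaffolds.
#' @param excludeBed optional BED of excluded intervals (sex-linked or
#'   low-mappability regions).
#' @param applyMaf apply the MAF filter before scanning.
#' @return list with \code{segments} (GRanges), \code{froh} (data.frame),
#'   \code{lAutoBp}, \code{hweReport}, invisibly.
#' @export
runInbreeding <- function(vcf, outDir, scaffoldLengths,
                          filter = filterConfig(), roh = rohConfig(),
                          longestN = 100, excludeBed = NULL,
                          applyMaf = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(scaffoldLengths))
    scaffoldLengths <- readScaffoldLengths(scaffoldLengths)
  m <- loadVcf(vcf, keepMonomorphic = FALSE)
  if (nrow(m) == 0) stop("stage load: no polymorphic site in ", vcf)
  .log("runInbreeding: loaded %d sites x %d individuals", nrow(m), ncol(m))
  m <- tryCatch(maskGenotypes(m, filter), warning = function(w) {
    .log("maskGenotypes: %s", conditionMessage(w)); suppressWarnings(
      maskGenotypes(m, filter))
  })
  filter <- resolveDepthBounds(m, filter)
  m <- filterSites(m, filter, keepMonomorphic = FALSE)
  hw <- filterHwe(m, thresholdZ = filter@hweAlphaZ,
                  reportPath = file.path(outDir, "hwe_report.tsv"))
  m <- hw$genotypes
  if (applyMaf) m <- mafFilter(m, filter@mafMin)
  m <- subsetScaffolds(m, longestN = longestN,
                       scaffoldLengths = scaffoldLengths,
                       excludeBed = excludeBed)
  scanned <- if (is.null(longestN)) names(scaffoldLengths) else {
    ord <- order(-scaffoldLengths, names(scaffoldLengths))
    names(scaffoldLengths)[head(ord, longestN)]
  }
  lAuto <- sum(scaffoldLengths[scanned])
  segs <- detectRoh(m, roh)
  froh <- classifyFroh(segs, lAutoBp = lAuto, individuals = sampleIds(m),
                       scaffoldLengths = scaffoldLengths, config = roh)
  segDf <- data.frame(individual = mcols(segs)$individual,
                      scaffold = as.character(seqnames(segs)),
                      start = start(segs), end = end(segs),
                      n_snps = mcols(segs)$n_snps,
                      length_bp = mcols(segs)$length_bp,
                      size_class = as.character(mcols(segs)$size_class),
                      gen_min = mcols(segs)$gen_min,
                      gen_max = mcols(segs)$gen_max)
  .writeTsv(segDf, file.path(outDir, "roh_segments.tsv"))
  .writeTsv(froh, file.path(outDir, "froh_summary.tsv"))
  classTab <- as.data.frame(table(
    size_class = mcols(segs)$size_class,
    individual = mcols(segs)$individual))
  .writeTsv(classTab, file.path(outDir, "roh_class_table.tsv"))
  .echoConfig(list(vcf = vcf, longestN = longestN, lAutoBp = lAuto,
                   filter = .cfgList(filter), roh = .cfgList(roh)),
              outDir, "inbreeding_config.yaml")
  invisible(list(segments = segs, froh = froh, lAutoBp = lAuto,
                 hweReport = hw$report))
}

#' Run the diversity flow
#'
#' All-sites VCF (polymorphic plus monomorphic) through genotype masking
#' and site filters (monomorphic kept), then per-individual heterozygosity,
#' windowed nucleotide diversity and the genome-wide pooled estimate.
#' Outputs: \code{heterozygosity.tsv}, \code{pi_windows.tsv},
#' \code{diversity_summary.yaml}, \code{diversity_config.yaml}.
#'
#' @param allSitesVcf path to the all-sites VCF.
#' @param outDir output directory.
#' @param filter a \linkS4class{FilterConfig}.
#' @param windowBp pi window width (default 10 kb).
#' @param applyHweFilter also drop FISN-deviant polymorphic sites before
#'   computing diversity (off by default; both orders are defensible and
#'   the choice is logged).
#' @param scaffoldLengths optional named lengths or TSV path, for window
#'   tiling.
#' @return list with \code{het}, \code{windows}, \code{pi} (the
#'   [genomewidePi()] list) and \code{L}, invisibly.
#' @export
runDiversity <- function(allSitesVcf, outDir, filter = filterConfig(),
                         windowBp = 1e4, applyHweFilter = FALSE,
                         scaffoldLengths = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(scaffoldLengths))
    scaffoldLengths <- readScaffoldLengths(scaffoldLengths)
  m <- loadVcf(allSitesVcf, keepMonomorphic = TRUE)
  if (nrow(m) == 0) stop("stage load: no site in ", allSitesVcf)
  .log("runDiversity: loaded %d sites x %d individuals", nrow(m), ncol(m))
  m <- suppressWarnings(maskGenotypes(m, filter))
  m <- filterSites(m, filter, keepMonomorphic = TRUE)
  if (applyHweFilter) {
    poly <- !isMonomorphic(m)
    rep0 <- siteHwe(m[poly, ], thresholdZ = filter@hweAlphaZ)
    drop <- paste(rep0$scaffold, rep0$pos)[rep0$removed]
    .logStep("diversity/HWE", nrow(m),
             nrow(m) - length(drop))
    m <- m[!(paste(scaffolds(m), positions(m)) %in% drop), ]
  }
  het <- individualHeterozygosity(m)
  L <- observedL(m)
  win <- windowedPi(m, windowBp = windowBp,
                    scaffoldLengths = scaffoldLengths)
  gw <- genomewidePi(win)
  .writeTsv(het, file.path(outDir, "heterozygosity.tsv"))
  .writeTsv(win, file.path(outDir, "pi_windows.tsv"))
  yaml::write_yaml(list(pi = gw$pi, mean_window_pi = gw$meanWindowPi,
                        n_diffs = gw$n_diffs, n_comps = gw$n_comps,
                        L = L),
                   file.path(outDir, "diversity_summary.yaml"))
  .echoConfig(list(vcf = allSitesVcf, window_bp = windowBp,
                   apply_hwe = applyHweFilter,
                   filter = .cfgList(filter)),
              outDir, "diversity_config.yaml")
  invisible(list(het = het, windows = win, pi = gw, L = L))
}

#' Run the folded-SFS flow
#'
#' Base VCF through masking, site filters and the HWE filter, then folded
#' SFS construction in both projection and complete-case modes. Outputs:
#' \code{sfs_projected.txt}, \code{sfs_complete.txt}, \code{sfs_bins.tsv},
#' \code{sfs_config.yaml}.
#'
#' @param vcf path to the base VCF.
#' @param outDir output directory.
#' @param filter a \linkS4class{FilterConfig}.
#' @param projectTo projected haploid size (default 90\% of full).
#' @param L total observed nucleic sites (e.g. [observedL()] of the
#'   all-sites matrix, or the \code{L} element of [runDiversity()]).
#' @return list with \code{projected} and \code{complete}
#'   \linkS4class{FoldedSFS} objects, invisibly.
#' @export
runSfs <- function(vcf, outDir, filter = filterConfig(),
                   projectTo = NULL, L = NA_real_) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  m <- loadVcf(vcf, keepMonomorphic = FALSE)
  if (nrow(m) == 0) stop("stage load: no polymorphic site in ", vcf)
  m <- suppressWarnings(maskGenotypes(m, filter))
  m <- filterSites(m, filter, keepMonomorphic = FALSE)
  m <- filterHwe(m, thresholdZ = filter@hweAlphaZ)$genotypes
  proj <- foldedSfs(m, projectTo = projectTo, mode = "project", L = L)
  comp <- foldedSfs(m, mode = "complete", L = L)
  writeSfs(proj, file.path(outDir, "sfs_projected.txt"))
  writeSfs(comp, file.path(outDir, "sfs_complete.txt"))
  .writeTsv(data.frame(minor_allele_count = seq_along(sfsBins(proj)),
                       projected = sfsBins(proj)),
            file.path(outDir, "sfs_bins.tsv"))
  .echoConfig(list(vcf = vcf, project_to = sfsHaploidSize(proj), L = L,
                   filter = .cfgList(filter)),
              outDir, "sfs_config.yaml")
  invisible(list(projected = proj, complete = comp))
}

#' Read a pipeline configuration file
#'
#' YAML with keys: \code{vcf}, \code{all_sites_vcf},
#' \code{scaffold_lengths}, \code{exclude_bed}, \code{out_dir},
#' \code{longest_n}, \code{window_bp}, \code{project_to}, \code{seed},
#' plus optional \code{filter:} and \code{roh:} blocks overriding any
#' \linkS4class{FilterConfig} / \linkS4class{ROHConfig} default by slot
#' name.
#'
#' @param path YAML path.
#' @return list with parsed paths/options and built \code{filter} and
#'   \code{roh} config objects.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  fc <- do.call(filterConfig, cfg$filter %||% list())
  rc <- do.call(rohConfig, cfg$roh %||% list())
  for (p in c("vcf", "all_sites_vcf", "scaffold_lengths", "exclude_bed"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured file does not exist: ", p, " = ", cfg[[p]])
  list(vcf = cfg$vcf, all_sites_vcf = cfg$all_sites_vcf,
       scaffold_lengths = cfg$scaffold_lengths,
       exclude_bed = cfg$exclude_bed,
       out_dir = cfg$out_dir %||% "rohdiv_out",
       longest_n = cfg$longest_n, window_bp = cfg$window_bp %||% 1e4,
       project_to = cfg$project_to, seed = cfg$seed,
       filter = fc, roh = rc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run all configured stages
#'
#' @param config list from [readPipelineConfig()] (or an equivalent list).
#' @param stages subset of c("roh", "diversity", "sfs").
#' @return list of stage results, invisibly.
#' @export
runPipeline <- function(config, stages = c("roh", "diversity", "sfs")) {
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- list()
  if ("roh" %in% stages && !is.null(config$vcf)) {
    out$roh <- tryCatch(
      runInbreeding(config$vcf, file.path(config$out_dir, "roh"),
                    scaffoldLengths = config$scaffold_lengths,
                    filter = config$filter, roh = config$roh,
                    longestN = config$longest_n,
                    excludeBed = config$exclude_bed),
      error = function(e) stop("stage roh failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  L <- NA_real_
  if ("diversity" %in% stages && !is.null(config$all_sites_vcf)) {
    out$diversity <- tryCatch(
      runDiversity(config$all_sites_vcf,
                   file.path(config$out_dir, "diversity"),
                   filter = config$filter,
                   windowBp = config$window_bp,
                   scaffoldLengths = config$scaffold_lengths),
      error = function(e) stop("stage diversity failed: ",
                               conditionMessage(e), call. = FALSE))
    L <- out$diversity$L
  }
  if ("sfs" %in% stages && !is.null(config$vcf)) {
    out$sfs <- tryCatch(
      runSfs(config$vcf, file.path(config$out_dir, "sfs"),
             filter = config$filter, projectTo = config$project_to,
             L = L),
      error = function(e) stop("stage sfs failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  invisible(out)
}
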