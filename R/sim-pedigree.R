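## Pedigree gene-dropping genome simulator. Founder haplotypes carry unique
## integer labels; meioses place crossovers as a Poisson process (Haldane,
## no interference — consistent with a flat cM/Mb map), so every
## descendant haplotype is a label mosaic. Autozygosity is exact: a region
## is IBD iff the two labels coincide. Mutations are sprinkled uniquely per
## founder haplotype (infinite sites), making IBD equivalent to
## homozygosity-by-state at every simulated site.

#' Create a PedigreeSpec
#'
#' @param founders number of founders (named F1..Fk).
#' @param matings data.frame with character columns parentA, parentB,
#'   child; parents must be founders or previously defined children.
#' @param genome named vector of scaffold lengths (bp).
#' @param founderHetPerBp target founder heterozygosity per bp; 0 simulates
#'   tracts only (no sites).
#' @param recombCmPerMb recombination rate (1 cM/Mb default).
#' @param seed optional seed applied by [simulatePedigree()].
#' @return A \linkS4class{PedigreeSpec}.
#' @export
pedigreeSpec <- function(founders, matings,
                         genome = setNames(rep(5e7, 10),
                                           paste0("scaf", 1:10)),
                         founderHetPerBp = 0.003, recombCmPerMb = 1,
                         seed = NA) {
  if (is.list(matings) && !is.data.frame(matings))
    matings <- do.call(rbind, lapply(matings, function(m)
      data.frame(parentA = m[1], parentB = m[2], child = m[3])))
  new("PedigreeSpec", founders = as.integer(founders), matings = matings,
      genome = genome, founderHetPerBp = founderHetPerBp,
      recombCmPerMb = recombCmPerMb, seed = as.integer(seed))
}

#' Stock consanguineous pedigrees
#'
#' Convenience mating designs: offspring of a full-sib mating (expected
#' inbreeding F = 0.25), of a half-sib mating (F = 0.125) and of a
#' first-cousin mating (F = 0.0625). Offspring are named O1..On.
#'
#' @param nOffspring number of offspring of the final mating.
#' @param ... passed to [pedigreeSpec()] (genome, rates, seed).
#' @return A \linkS4class{PedigreeSpec}.
#' @export
fullSibPedigree <- function(nOffspring = 1, ...) {
  m <- rbind(data.frame(parentA = "F1", parentB = "F2",
                        child = c("S1", "S2")),
             data.frame(parentA = "S1", parentB = "S2",
                        child = paste0("O", seq_len(nOffspring))))
  pedigreeSpec(founders = 2, matings = m, ...)
}

#' @rdname fullSibPedigree
#' @export
halfSibPedigree <- function(nOffspring = 1, ...) {
  m <- rbind(data.frame(parentA = c("F1", "F1"), parentB = c("F2", "F3"),
                        child = c("S1", "S2")),
             data.frame(parentA = "S1", parentB = "S2",
                        child = paste0("O", seq_len(nOffspring))))
  pedigreeSpec(founders = 3, matings = m, ...)
}

#' @rdname fullSibPedigree
#' @export
firstCousinPedigree <- function(nOffspring = 1, ...) {
  m <- rbind(data.frame(parentA = c("F1", "F1"), parentB = c("F2", "F2"),
                        child = c("P1", "P2")),
             data.frame(parentA = c("P1", "P2"), parentB = c("F3", "F4"),
                        child = c("C1", "C2")),
             data.frame(parentA = "C1", parentB = "C2",
                        child = paste0("O", seq_len(nOffspring))))
  pedigreeSpec(founders = 4, matings = m, ...)
}

.pedIndividuals <- function(spec)
  c(paste0("F", seq_len(spec@founders)),
    if (nrow(spec@matings)) spec@matings$child else character(0))

#' Expected inbreeding coefficients from the pedigree
#'
#' Tabular kinship recursion: F(child) equals the kinship of its parents.
#'
#' @param spec a \linkS4class{PedigreeSpec}.
#' @return Named numeric vector of expected F, one entry per individual.
#' @examples
#' pedigreeInbreeding(fullSibPedigree())["O1"]  # 0.25
#' @export
pedigreeInbreeding <- function(spec) {
  validObject(spec)
  ids <- .pedIndividuals(spec)
  n <- length(ids)
  par <- matrix(0L, n, 2)
  if (nrow(spec@matings)) {
    off <- spec@founders + seq_len(nrow(spec@matings))
    par[off, 1] <- match(spec@matings$parentA, ids)
    par[off, 2] <- match(spec@matings$parentB, ids)
  }
  K <- matrix(0, n, n)
  Fcoef <- numeric(n)
  for (i in seq_len(n)) {
    if (par[i, 1] == 0L) {
      K[i, i] <- 0.5
    } else {
      Fcoef[i] <- K[par[i, 1], par[i, 2]]
      K[i, i] <- 0.5 * (1 + Fcoef[i])
      for (j in seq_len(i - 1L))
        K[i, j] <- K[j, i] <- 0.5 * (K[par[i, 1], j] + K[par[i, 2], j])
    }
  }
  setNames(Fcoef, ids)
}

# one meiosis: recombine a parent's two label mosaics
.meiosis <- function(h1, h2, len, coRatePerBp) {
  nco <- rpois(1, len * coRatePerBp)
  co <- if (nco > 0) sort(sample.int(len - 1L, min(nco, len - 1L)))
        else integer(0)
  segStart <- c(1, co + 1)
  segEnd <- c(co, len)
  src <- rep_len(if (runif(1) < 0.5) c(1L, 2L) else c(2L, 1L),
                 length(segStart))
  breaks <- integer(0); labels <- integer(0)
  for (k in seq_along(segStart)) {
    h <- if (src[k] == 1L) h1 else h2
    i0 <- findInterval(segStart[k], h$breaks)
    i1 <- findInterval(segEnd[k], h$breaks)
    bs <- h$breaks[i0:i1]
    bs[1] <- segStart[k]
    breaks <- c(breaks, bs)
    labels <- c(labels, h$labels[i0:i1])
  }
  keep <- c(TRUE, labels[-1L] != labels[-length(labels)])
  list(breaks = breaks[keep], labels = labels[keep])
}

.autoTracts <- function(h1, h2, len) {
  b <- sort(unique(c(h1$breaks, h2$breaks)))
  auto <- h1$labels[findInterval(b, h1$breaks)] ==
    h2$labels[findInterval(b, h2$breaks)]
  ends <- c(b[-1] - 1, len)
  grp <- cumsum(c(TRUE, diff(auto) != 0))
  keep <- tapply(auto, grp, function(a) a[1])
  start <- tapply(b, grp, min)[keep]
  end <- tapply(ends, grp, max)[keep]
  if (!length(start)) return(NULL)
  data.frame(start = as.numeric(start), end = as.numeric(end))
}

#' Gene-drop a pedigree through a simulated genome
#'
#' Simulates founder haplotypes (unique labels, infinite-sites mutations at
#' the density implied by \code{founderHetPerBp}), drops them through the
#' matings with Poisson crossovers at \code{recombCmPerMb}, and records
#' ground-truth autozygous tracts wherever an individual's two labels share
#' a founder haplotype.
#'
#' @param spec a \linkS4class{PedigreeSpec}.
#' @return A \linkS4class{PedigreeGenomes}; use [pedGenotypes()] and
#'   [truthTracts()].
#' @examples
#' sim <- simulatePedigree(fullSibPedigree(
#'   genome = c(s1 = 2e6), founderHetPerBp = 1e-4, seed = 11))
#' truthTracts(sim, "O1")
#' @export
simulatePedigree <- function(spec) {
  validObject(spec)
  if (!is.na(spec@seed)) set.seed(spec@seed)
  genome <- spec@genome
  ids <- .pedIndividuals(spec)
  nHap <- 2L * spec@founders
  mu <- spec@founderHetPerBp / 2   # mutations per bp per haplotype
  coRate <- spec@recombCmPerMb / 1e8  # crossovers per bp per meiosis

  sites <- list()
  for (s in names(genome)) {
    len <- genome[[s]]
    counts <- rpois(nHap, len * mu)
    tot <- sum(counts)
    if (tot == 0) {
      sites[[s]] <- data.frame(pos = numeric(0), owner = integer(0))
      next
    }
    pos <- sample.int(len, tot)          # random order, no duplicates
    owner <- rep(seq_len(nHap), counts)
    ord <- order(pos)
    sites[[s]] <- data.frame(pos = pos[ord], owner = owner[ord])
  }

  haps <- list()
  for (i in seq_len(spec@founders)) {
    id <- ids[i]
    haps[[id]] <- lapply(setNames(names(genome), names(genome)),
      function(s) list(
        h1 = list(breaks = 1L, labels = 2L * i - 1L),
        h2 = list(breaks = 1L, labels = 2L * i)))
  }
  if (nrow(spec@matings)) {
    for (r in seq_len(nrow(spec@matings))) {
      a <- spec@matings$parentA[r]; b <- spec@matings$parentB[r]
      child <- spec@matings$child[r]
      haps[[child]] <- lapply(setNames(names(genome), names(genome)),
        function(s) {
          len <- genome[[s]]
          list(h1 = .meiosis(haps[[a]][[s]]$h1, haps[[a]][[s]]$h2,
                             len, coRate),
               h2 = .meiosis(haps[[b]][[s]]$h1, haps[[b]][[s]]$h2,
                             len, coRate))
        })
    }
  }

  tr <- list()
  for (id in ids) for (s in names(genome)) {
    tt <- .autoTracts(haps[[id]][[s]]$h1, haps[[id]][[s]]$h2, genome[[s]])
    if (!is.null(tt)) {
      tt$scaffold <- s; tt$individual <- id
      tr[[length(tr) + 1L]] <- tt
    }
  }
  tracts <- if (length(tr)) {
    df <- do.call(rbind, tr)
    gr <- GRanges(df$scaffold, IRanges(df$start, df$end))
    mcols(gr)$individual <- df$individual
    suppressWarnings(seqlengths(gr) <- genome[seqlevels(gr)])
    gr
  } else GRanges()
  new("PedigreeGenomes", spec = spec, sites = sites, haplotypes = haps,
      tracts = tracts)
}

#' Extract genotypes from a simulated pedigree
#'
#' Emits the diploid genotype matrix at every segregating founder mutation
#' (sites monomorphic within the selected individuals are retained: they
#' are polymorphic in the founder pool, mirroring an all-cohort VCF).
#'
#' @param sim a \linkS4class{PedigreeGenomes}.
#' @param individuals individuals to emit (default: all, pedigree order).
#' @param scaffolds scaffolds to emit (default: all).
#' @return A \linkS4class{GenotypeMatrix} (VCF-writable via [writeVcf()]).
#' @export
pedGenotypes <- function(sim, individuals = NULL, scaffolds = NULL) {
  spec <- sim@spec
  if (is.null(individuals)) individuals <- .pedIndividuals(spec)
  if (is.null(scaffolds)) scaffolds <- names(spec@genome)
  unknown <- setdiff(individuals, .pedIndividuals(spec))
  if (length(unknown))
    stop("unknown individual(s): ", paste(unknown, collapse = ", "))
  parts <- lapply(scaffolds, function(s) {
    st <- sim@sites[[s]]
    gt <- matrix(0L, nrow(st), length(individuals))
    for (j in seq_along(individuals)) {
      h <- sim@haplotypes[[individuals[j]]][[s]]
      l1 <- h$h1$labels[findInterval(st$pos, h$h1$breaks)]
      l2 <- h$h2$labels[findInterval(st$pos, h$h2$breaks)]
      gt[, j] <- (l1 == st$owner) + (l2 == st$owner)
    }
    list(scaffold = rep(s, nrow(st)), pos = st$pos, gt = gt)
  })
  GenotypeMatrix(
    scaffold = unlist(lapply(parts, `[[`, "scaffold")),
    pos = unlist(lapply(parts, `[[`, "pos")),
    calls = do.call(rbind, lapply(parts, `[[`, "gt")),
    ref = "A", alt = "T", qual = NA_real_,
    individuals = individuals,
    scaffoldLengths = spec@genome)
}

#' Streaming genotype access for one individual on one scaffold
#'
#' Lightweight companion to [pedGenotypes()] that skips container
#' construction: returns the site positions and the individual's dosage
#' calls as plain vectors. Intended for scans over many large simulated
#' genomes where holding a full matrix would be wasteful.
#'
#' @param sim a \linkS4class{PedigreeGenomes}.
#' @param individual one individual id.
#' @param scaffold one scaffold name.
#' @return list with \code{pos} (bp) and \code{calls} (integer 0/1/2).
#' @export
pedCalls <- function(sim, individual, scaffold) {
  st <- sim@sites[[scaffold]]
  h <- sim@haplotypes[[individual]][[scaffold]]
  if (is.null(st) || is.null(h))
    stop("unknown individual or scaffold")
  l1 <- h$h1$labels[findInterval(st$pos, h$h1$breaks)]
  l2 <- h$h2$labels[findInterval(st$pos, h$h2$breaks)]
  list(pos = st$pos, calls = (l1 == st$owner) + (l2 == st$owner))
}

#' @rdname simulatePedigree
#' @param x a \linkS4class{PedigreeGenomes}.
#' @param individuals optional filter on individuals.
#' @param ... unused.
#' @export
setMethod("truthTracts", "PedigreeGenomes",
          function(x, individuals = NULL, ...) {
  tr <- x@tracts
  if (!is.null(individuals))
    tr <- tr[mcols(tr)$individual %in% individuals]
  tr
})

#' Compare called ROH segments with ground-truth autozygous tracts
#'
#' Per truth tract: base-pair sensitivity and, for the best-overlapping
#' called segment, absolute start/end boundary errors. Per individual:
#' called, truth, overlapping and false-positive bp. The summary aggregates
#' bp-weighted sensitivity, mean boundary error over matched tracts, the
#' false-positive fraction of called bp, and (when \code{lAutoBp} is given)
#' mean called F_ROH versus mean truth autozygous fraction.
#'
#' @param segments GRanges of called ROH (mcols individual, as from
#'   [detectRoh()]).
#' @param truth GRanges of autozygous tracts (mcols individual, as from
#'   [truthTracts()]).
#' @param individuals individuals to assess; default: union of both sets.
#' @param lAutoBp analysed genome length for the F comparison (optional).
#' @return list with \code{tracts} and \code{perIndividual} data.frames and
#'   a \code{summary} list.
#' @export
truthCompare <- function(segments, truth, individuals = NULL,
                         lAutoBp = NULL) {
  if (is.null(individuals))
    individuals <- sort(union(unique(mcols(segments)$individual),
                              unique(mcols(truth)$individual)))
  tractRows <- list(); indRows <- list()
  for (id in individuals) {
    seg <- segments[mcols(segments)$individual == id]
    tru <- truth[mcols(truth)$individual == id]
    ovBp <- if (length(seg) && length(tru))
      sum(width(suppressWarnings(
        GenomicRanges::intersect(granges(seg), granges(tru))))) else 0
    indRows[[id]] <- data.frame(
      individual = id,
      called_bp = sum(width(seg)), truth_bp = sum(width(tru)),
      overlap_bp = ovBp,
      false_positive_bp = sum(width(seg)) - ovBp)
    if (length(tru)) {
      hits <- suppressWarnings(findOverlaps(tru, seg))
      for (t in seq_along(tru)) {
        hs <- subjectHits(hits)[queryHits(hits) == t]
        ovw <- if (length(hs)) suppressWarnings(
          width(pintersect(rep(granges(tru[t]), length(hs)),
                           granges(seg[hs])))) else numeric(0)
        ov <- sum(ovw)
        best <- if (length(hs)) hs[which.max(ovw)] else NA_integer_
        tractRows[[length(tractRows) + 1L]] <- data.frame(
          individual = id, scaffold = as.character(seqnames(tru[t])),
          start = start(tru[t]), end = end(tru[t]),
          length_bp = width(tru[t]), overlap_bp = ov,
          sensitivity = ov / width(tru[t]),
          start_error = if (is.na(best)) NA_real_ else
            abs(start(seg[best]) - start(tru[t])),
          end_error = if (is.na(best)) NA_real_ else
            abs(end(seg[best]) - end(tru[t])))
      }
    }
  }
  tracts <- if (length(tractRows)) do.call(rbind, tractRows) else
    data.frame()
  perInd <- do.call(rbind, indRows)
  matched <- if (nrow(tracts)) !is.na(tracts$start_error) else logical(0)
  summary <- list(
    sensitivity_bp = if (sum(perInd$truth_bp) > 0)
      sum(perInd$overlap_bp) / sum(perInd$truth_bp) else NA_real_,
    mean_boundary_error_bp = if (any(matched))
      mean(c(tracts$start_error[matched], tracts$end_error[matched]))
      else NA_real_,
    false_positive_frac = if (sum(perInd$called_bp) > 0)
      sum(perInd$false_positive_bp) / sum(perInd$called_bp) else 0)
  if (!is.null(lAutoBp)) {
    summary$mean_froh_called <- mean(perInd$called_bp / lAutoBp)
    summary$mean_froh_truth <- mean(perInd$truth_bp / lAutoBp)
  }
  list(tracts = tracts, perIndividual = perInd, summary = summary)
}
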