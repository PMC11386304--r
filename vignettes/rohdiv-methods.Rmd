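---
title: "Methods and design of rohdiv: filtering, Hardy-Weinberg screening, diversity, ROH and the folded SFS"
author: "rohdiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of rohdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohdiv)
```

# Scope

`rohdiv` analyses small multi-individual whole-genome resequencing
panels — typically 10–20 diploids at ~20× on a fragmented draft
assembly — for genetic diversity and recent inbreeding. It covers the
stretch of the analysis between a called multi-sample VCF and the
population-genetic summaries: quality filtering, a Hardy–Weinberg site
screen, heterozygosity and windowed nucleotide diversity, sliding-window
runs-of-homozygosity (ROH) detection with \(F_{ROH}\), and folded
site-frequency-spectrum (SFS) construction. Upstream steps (mapping,
SNP calling, mappability estimation, sex-scaffold identification) and
downstream demographic inference engines are out of scope; their
products enter as inputs (VCF, BED masks, scaffold tables) or leave as
outputs (the SFS text file and its \(L\)).

# Data model

A `GenotypeMatrix` is a `RangedSummarizedExperiment`: rows are sites
(scaffold, 1-based position, REF/ALT, QUAL, monomorphic and
multi-allelic flags), columns are individuals, and assays hold the
diploid dosage calls (`GT`: 0 hom-ref, 1 het, 2 hom-alt, NA missing)
plus optional per-call depth (`DP`) and genotype quality (`GQ`).
Two matrices matter:

* the **base** matrix of polymorphic biallelic SNPs, and
* the **all-sites** matrix that retains monomorphic (ALT = ".")
  records. Monomorphic genotyped sites carry the information about how
  much sequence was actually callable, which is what makes
  per-base-pair diversity and the SFS \(L\) well defined under missing
  data.

Half-calls (`./1`), haploid calls and genotypes touching allele
indices ≥ 2 are conservatively treated as missing; multi-allelic
records are retained but flagged, and the site filter removes them.

# Filtering cascade

`maskGenotypes()` sets calls with DP < 10 or GQ < 15 to missing —
below these values single-call genotypes at ~20× panels are dominated
by sampling and mapping error. `filterSites()` then removes indels and
multi-allelic records, sites with summed depth outside
\([\bar d/3,\, 2\bar d]\) (collapsed repeats inflate depth, dropout
deflates it; the bounds are derived once from the per-site summed-depth
distribution by `resolveDepthBounds()`, logged, and overridable — the
data-derived default mirrors the common practice of reading the bounds
off the depth histogram), sites with QUAL < 30, and sites with ≥ 10 %
missing genotypes. The missingness comparison is deliberately strict
(a site at exactly 10 % is removed). With 15 individuals the 10 % rule
means at most one missing genotype per site. `mafFilter()` (MAF ≥ 0.05
over called alleles, boundary kept) feeds analyses that are sensitive
to rare-allele noise, such as the ROH scan. All filters are monotone
(site subsets), log before/after counts, and are idempotent once the
depth bounds are resolved to numbers.

Whether the depth bounds should apply to per-site summed depth or to
mean per-individual depth is underdetermined in common usage; `rohdiv`
uses summed depth (the quantity bcftools reports per record) and
documents the choice here.

# The Hardy–Weinberg screen

Per site, with \(n\) called diploids, observed heterozygosity
\(H_{obs}\) and alt-allele frequency \(\hat p\):

\[
F_{IS} = 1 - \frac{H_{obs}}{H_{exp}}, \qquad
FISN = F_{IS}\sqrt{n},
\]

and sites with \(|FISN| > 1.96\) are removed (fixed per-site cutoff, no
multiple-testing correction — the screen is an artefact filter, not an
inference). Heterozygote excess, the signature of collapsed paralogs,
gives negative values; deficit positive ones.

The estimator of \(H_{exp}\) is a genuine design choice. The plain
moment estimator \(2\hat p(1-\hat p)\) makes \(FISN\) biased by about
\(-1/(2\sqrt n)\) under the null (with \(n=100\): −0.05, a visible
shift of the whole null distribution). Since the screen's justification
is that \(FISN\) is standard normal under HWE, the default uses Nei's
small-sample expected heterozygosity
\(2\hat p(1-\hat p)\cdot 2n/(2n-1)\), which centres the null
(simulated mean ≈ 0.004 at \(n=100\)); the plain variant remains
available as `hexp = "plain"`, and the hand-checkable identities
(all-heterozygote site: \(F_{IS}=-1\), \(FISN=-\sqrt n\)) hold exactly
under it. Monomorphic or degenerate sites (\(H_{exp}=0\), \(n<2\)) get
NA statistics and always pass: they carry no evidence of deviating
heterozygosity, and failing them would silently thin the all-sites set.

# Diversity

Per-individual heterozygosity is heterozygous calls over non-missing
calls on the all-sites matrix; the mean per-individual genotyped-site
count is exported as `observedL()` for SFS scaling.

Nucleotide diversity uses the missing-data-aware counts: a genotyped
site with \(k\) alt among \(n\) called alleles contributes
\(k(n-k)\) pairwise differences and \(\binom{n}{2}\) comparisons;
windows of 10 kb (a compromise between local resolution and per-window
variance at ~0.003/bp diversity) tile each scaffold from position 1,
the final partial window retained and flagged. The genome-wide estimate
pools raw counts, \(\sum\text{diffs}/\sum\text{comps}\), rather than
averaging per-window ratios: ratio averaging over-weights windows with
little callable sequence. Both numbers are reported; the pooled one is
the headline. Whether the Hardy–Weinberg screen should run before
diversity is left to the caller (`applyHweFilter`), since removing
heterozygote-excess artefacts deflates π slightly while leaving them
inflates it; the default (off) matches treating the all-sites matrix as
primary data, and the choice is logged.

# ROH detection

The scan is SNP-index based: windows of 100 consecutive SNPs sliding by
one SNP, fully contained in the scaffold. A window is
homozygous-eligible when it has at most \(\lfloor 0.08\cdot 100\rfloor
= 8\) heterozygous and \(\lfloor 0.15\cdot 100\rfloor = 15\) missing
calls — allowances for genotyping error and missingness that would
otherwise shatter long runs. A SNP is included when at least 5 % of the
windows covering it are eligible; the denominator is the *actual*
covering count, so scaffold-edge SNPs (covered by fewer than 100
windows) are handled without special cases, and the comparison is
\(\ge\) (a stated minimum is attainable). At the flank of a maximal
block of eligible windows this trims exactly
\(\lceil 0.05 \cdot 100\rceil - 1 = 4\) SNPs per side — the
worked example in the test suite checks that identity, and it guards
run boundaries against stray heterozygotes.

Included SNPs are assembled into maximal consecutive stretches, split
where adjacent SNPs are > 100 kb apart, and kept when they have
≥ 100 SNPs, span ≥ 0.5 Mb, and average ≤ 10 kb per SNP. Run length is
measured first-to-last included SNP + 1 bp: the data carry no
information beyond the genotyped markers, so extrapolating into the
flanking gaps would manufacture length. The density and gap checks
apply to the final (post-trimming) segments; applying them before
trimming would let four flank SNPs rescue or doom a borderline run, and
the configurable order is noted in the code. Scaffolds shorter than the
minimum run length are skipped with a logged warning — short scaffolds
bias ROH length downward, which is why scans are usually restricted to
the longest scaffolds (e.g. the longest 100, with
\(L_{AUTO}\) their summed length).

\(F_{ROH} = L_{ROH}/L_{AUTO}\) per individual, decomposed into length
classes 0.5–1, 1–2 and 2–4 Mb. Under the 1 Mb = 1 cM calibration an
autozygous segment from a common ancestor \(g\) generations back has
expected length \(100/(2g)\) cM, so the class edges 0.5/1/2/4 Mb map to
100/50/25/12.5 generations; segments above the top edge land in an open
`>4Mb` class.

Missing calls inside a run neither break it nor count toward its SNP
tally; they only consume the window missing allowance. Determinism is
exact: the scan has no random component.

# Folded SFS

Sites are binned by minor-allele count (ancestral states are unknown in
non-model species). Missing data are handled by expected hypergeometric
projection: a site with \(k\) alt among \(n'\) called alleles
contributes \(P(j) = \mathrm{Hyper}(j;\,k,\,n'-k,\,m)\) to each
projected count \(j\) of a haploid sample of size \(m\), mass at
\(j=0\) and \(j=m\) (monomorphic after projection) is dropped, and
singletons are kept. The default \(m\) is 90 % of the full haploid
size — large enough to keep most of the spectrum, small enough that
sites with one missing genotype still contribute; sites with fewer than
\(m\) called alleles are dropped. A complete-case mode (only fully
called sites, full haploid size) is emitted alongside, because which of
the two a given downstream tool expects varies; comparing them is a
useful sanity check. \(L\) is not computed from the base matrix — it
is the average number of genotyped sites per individual in the
all-sites matrix, passed in from the diversity flow.

# The synthetic-data generators

`simulateHweGenotypes()` draws per-site allele frequencies uniformly
and genotypes from the inbreeding-adjusted law
\((q^2+fpq,\; 2pq(1-f),\; p^2+fpq)\); \(f=0\) is exact HWE. It
calibrates the FISN null (mean 0, sd 1, 5 % rejection at |1.96|) and
provides generic fixtures.

`simulatePedigree()` gene-drops founder haplotypes through an explicit
mating design. Founder haplotypes carry unique labels; meioses place
crossovers as a Poisson process at 1 cM/Mb (Haldane, no interference —
the same interference-free map the ROH age calibration assumes), so
descendants are label mosaics and a region is autozygous exactly where
the two labels coincide: the ground-truth tracts are read off the
labels, not inferred. Mutations are sprinkled uniquely per founder
haplotype (infinite sites) at density `founderHetPerBp/2` per
haplotype, making IBD equivalent to homozygosity-by-state at every
simulated site. Defaults emulate the target study systems: founder
heterozygosity 0.003/bp (sea-duck-like; the plausible range for such
panels is ~0.003–0.006), 1 cM/Mb, and a 10 × 50 Mb recovery genome —
large enough that full-sib \(F_{ROH}\) variance permits
3-standard-error tests at 200 replicate families, small enough for a
desk machine. `pedigreeInbreeding()` gives the pedigree-expected
\(F\) by tabular kinship recursion (full-sib mating 0.25, half-sib
0.125, first cousins 0.0625), and `truthCompare()` scores a caller
against the tracts (bp sensitivity, boundary error, false-positive bp,
mean \(F_{ROH}\) vs pedigree \(F\)).

What the generators deliberately do not emulate: genotyping error and
missing calls (the simulated matrices are clean unless the caller adds
noise), linkage-disequilibrium structure in the founder pool (founder
haplotypes are mutually unrelated), background relatedness beyond the
declared pedigree, new mutations within the pedigree, crossover
interference, and allele-frequency spectra shaped by demography (the
HWE generator draws frequencies uniformly). Passing the recovery tests
therefore shows the *detector* is correct under its own model — clean
homozygosity-by-state tracts at realistic marker density — not that
real low-coverage data will behave as well; the window allowances exist
precisely for the error processes the simulator omits.

# Numerical choices and degenerate inputs

* Boundary semantics, fixed throughout: genotype masks and site filters
  keep values *at* a threshold (DP 10, GQ 15, QUAL 30, MAF 0.05);
  missingness removal and HWE removal are strict (`>=` 10 % missing
  removed, `>` 1.96 removed, so \(|FISN|\) exactly at the cutoff
  survives); ROH support is `>=`.
* Window allowances use `floor(frac * windowSnps)` — "up to 8 %" of a
  100-SNP window is 8 SNPs, never 9.
* BED exclusion masks are 0-based half-open; VCF positions 1-based
  inclusive. The conversion lives in one function (`readBedMask()`, via
  `rtracklayer`).
* Longest-*N* scaffold selection breaks length ties by name, so the
  selection is deterministic.
* π windows with no genotyped comparison report NA, not 0; an
  individual with no genotyped site gets NA heterozygosity with a
  warning; an empty window set makes the genome-wide π NA with a
  warning rather than an error.
* Monomorphic records have no QUAL; NA QUAL passes the QUAL filter.
* The seeded generators are bit-reproducible; derived family seeds are
  drawn below \(2^{31}\).

# Validation problem sizes

The test suite validates each stage at sizes chosen to give the
statistical checks real power while staying desk-scale: the FISN null
on 20,000 sites × 100 diploids; exact oracle equivalence of the ROH
caller against a brute-force window/support enumeration on 100 random
2,000-SNP scaffolds; π against all-pairs enumeration on ≤ 50-site
matrices; folded-SFS χ² against the \(1/i + 1/(2n-i)\) neutral
expectation on 10,000 sites; and \(F_{ROH}\) recovery on 200 replicate
full-sib families over 10 × 50 Mb genomes at 0.003/bp founder
heterozygosity, where the called mean must sit within three standard
errors of the pedigree value 0.25 and boundary errors within one window
span (with the ~167 bp marker spacing that density implies, a window
spans ~17 kb; observed boundary errors are an order of magnitude
smaller).

# Known limitations

* The ROH caller is the windowed, genotype-based family of methods; it
  does not model genotyping error probabilistically and cannot separate
  identity-by-state from identity-by-descent for very short runs —
  hence the 0.5 Mb floor, below which linkage alone creates
  homozygous stretches.
* \(F_{ROH}\) inherits every upstream choice (MAF cutoff, mappability
  mask, scaffold subset); comparisons across studies are only as good
  as the matched configuration, which is why every run echoes its full
  configuration to the output directory.
* The hypergeometric SFS projection allocates expected (fractional)
  counts; it does not propagate projection variance into downstream
  inference.
* Multi-allelic sites are dropped rather than decomposed into
  biallelic records; panels where they matter should pre-split them
  (e.g. `bcftools norm`) before loading.
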