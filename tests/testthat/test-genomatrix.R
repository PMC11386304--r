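# VCF I/O and the site/genotype filtering cascade.

test_that("loadVcf reads a toy VCF faithfully and round-trips", {
  path <- writeToyVcf(c(
    rec("s1", 100, "A", "G", "50", "0/0:30:60", "0/1:25:50"),
    rec("s1", 250, "C", "T", "40", "1/1:28:70", "./.:.:."),
    rec("s2", 10, "G", "A", "99.5", "0/1:31:80", "0/0:22:45")))
  gm <- loadVcf(path)
  expect_s4_class(gm, "GenotypeMatrix")
  expect_equal(nSites(gm), 3L)
  expect_equal(nIndividuals(gm), 2L)
  expect_equal(positions(gm), c(100L, 250L, 10L))
  expect_equal(scaffolds(gm), c("s1", "s1", "s2"))
  expect_equal(calls(gm)[, "ind1"], c(0L, 2L, 1L))
  expect_equal(calls(gm)[, "ind2"], c(1L, NA, 0L))
  expect_equal(unname(readDepth(gm)[1, ]), c(30L, 25L))
  expect_equal(unname(genoQual(gm)[3, ]), c(80L, 45L))
  expect_equal(siteQual(gm), c(50, 40, 99.5))

  # round trip: write, re-load, compare normalized records
  out <- tempfile(fileext = ".vcf")
  writeVcf(gm, out)
  gm2 <- loadVcf(out)
  expect_equal(calls(gm2), calls(gm))
  expect_equal(positions(gm2), positions(gm))
  expect_equal(refAllele(gm2), refAllele(gm))
  expect_equal(altAllele(gm2), altAllele(gm))
  expect_equal(siteQual(gm2), siteQual(gm))
  # independent text-level check of the record fields
  norm <- function(p) {
    l <- grep("^[^#]", readLines(p), value = TRUE)
    f <- do.call(rbind, strsplit(l, "\t"))
    gtOnly <- function(x) sub(":.*", "", x)
    cbind(f[, c(1, 2, 4, 5)], gtOnly(f[, 10]), gtOnly(f[, 11]))
  }
  expect_equal(norm(out), norm(path))
})

test_that("monomorphic ALT='.' records honour keepMonomorphic", {
  path <- writeToyVcf(c(
    rec("s1", 100, "A", ".", ".", "0/0:30:60", "0/0:25:50"),
    rec("s1", 200, "A", "G", "50", "0/1:30:60", "0/0:25:50")))
  all <- loadVcf(path, keepMonomorphic = TRUE)
  expect_equal(nSites(all), 2L)
  expect_equal(isMonomorphic(all), c(TRUE, FALSE))
  poly <- loadVcf(path, keepMonomorphic = FALSE)
  expect_equal(positions(poly), 200L)
})

test_that("loadVcf rejects duplicates and malformed input", {
  dup <- writeToyVcf(c(
    rec("s1", 100, "A", "G", "50", "0/0:30:60", "0/1:25:50"),
    rec("s1", 100, "A", "T", "50", "0/0:30:60", "0/1:25:50")))
  expect_error(loadVcf(dup), "duplicated")
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "not a vcf line"), bad)
  expect_error(loadVcf(bad), "malformed|scanVcf|header",
               ignore.case = TRUE)
  expect_error(loadVcf(tempfile(fileext = ".vcf")), "not found")
})

test_that("half-calls, haploid and multi-allelic genotypes become missing", {
  path <- writeToyVcf(c(
    rec("s1", 100, "A", "G,T", "50", "1/2:30:60", "0/1:25:50"),
    rec("s1", 200, "A", "G", "50", "./1:30:60", "1:25:50")))
  gm <- loadVcf(path)
  expect_equal(isMultiallelic(gm), c(TRUE, FALSE))
  expect_true(is.na(calls(gm)[1, 1]))    # allele index 2
  expect_equal(unname(calls(gm)[1, 2]), 1L)
  expect_true(all(is.na(calls(gm)[2, ])))  # ./1 and haploid
})

test_that("maskGenotypes applies depth/GQ thresholds at the boundary", {
  gt <- rbind(c(0L, 1L), c(2L, 1L), c(1L, 0L))
  dp <- rbind(c(9L, 10L), c(30L, 30L), c(15L, 10L))
  gq <- rbind(c(99L, 15L), c(60L, 14L), c(15L, 15L))
  gm <- gmFromCalls(gt, depth = dp, genoQual = gq,
                    individuals = c("a", "b"))
  masked <- maskGenotypes(gm, filterConfig())
  expect_true(is.na(calls(masked)[1, 1]))    # depth 9 < 10, despite GQ 99
  expect_equal(unname(calls(masked)[1, 2]), 1L)      # DP 10, GQ 15: boundary kept
  expect_true(is.na(calls(masked)[2, 2]))    # GQ 14 < 15
  expect_equal(calls(masked)[3, ], calls(gm)[3, ])

  allGood <- gmFromCalls(gt, depth = matrix(30L, 3, 2),
                         genoQual = matrix(60L, 3, 2),
                         individuals = c("a", "b"))
  expect_equal(calls(maskGenotypes(allGood)), calls(allGood))
  bare <- gmFromCalls(gt, individuals = c("a", "b"))
  expect_warning(out <- maskGenotypes(bare), "no DP or GQ")
  expect_equal(calls(out), calls(bare))
})

test_that("filterSites enforces QUAL, missingness (strict), indels, depth", {
  # 15 individuals; site 2 has 2 missing calls (13.3% >= 10% -> removed),
  # site 3 has 1 missing (6.7% -> kept)
  gt <- matrix(1L, 4, 15)
  gt[2, 1:2] <- NA
  gt[3, 1] <- NA
  gm <- GenotypeMatrix(scaffold = rep("s1", 4), pos = 1:4 * 100,
                       calls = gt, ref = rep("A", 4),
                       alt = rep("G", 4),
                       qual = c(29.9, 50, 50, 30))
  suppressMessages(out <- filterSites(gm, filterConfig()))
  expect_equal(positions(out), c(300L, 400L))  # QUAL 29.9 and missing removed

  # exactly 10% missing is removed (strict <)
  gt10 <- matrix(0L, 2, 10); gt10[1, 1] <- NA
  gm10 <- gmFromCalls(gt10, qual = c(50, 50),
                      individuals = sprintf("i%d", 1:10))
  suppressMessages(out10 <- filterSites(gm10, filterConfig()))
  expect_equal(nSites(out10), 1L)

  # indels and multi-allelic records removed
  gmi <- GenotypeMatrix(scaffold = rep("s1", 3), pos = c(1, 2, 3),
                        calls = matrix(1L, 3, 4),
                        ref = c("A", "AT", "A"),
                        alt = c("G,T", "A", "G"), qual = rep(50, 3))
  suppressMessages(outi <- filterSites(gmi, filterConfig()))
  expect_equal(positions(outi), 3L)

  # summed-depth bounds, explicit config
  gtd <- matrix(1L, 3, 2)
  dpd <- rbind(c(5L, 4L), c(20L, 20L), c(90L, 95L))
  gmd <- gmFromCalls(gtd, depth = dpd, qual = rep(50, 3),
                     individuals = c("a", "b"))
  cfg <- filterConfig(siteDepthLow = 15, siteDepthHigh = 200,
                      genoMinDepth = 0, genoMinGq = 0)
  suppressMessages(outd <- filterSites(gmd, cfg))
  expect_equal(positions(outd), c(200L, 300L))

  expect_error(filterConfig(siteDepthLow = 50, siteDepthHigh = 40))
})

test_that("filterSites is idempotent and monotone with resolved bounds", {
  set.seed(42)
  gm <- simulateHweGenotypes(10, 200)
  dp <- matrix(rpois(2000, 30), 200, 10)
  gm2 <- gmFromCalls(calls(gm), pos = positions(gm), depth = dp,
                     qual = runif(200, 20, 80),
                     individuals = sampleIds(gm))
  cfg <- resolveDepthBounds(gm2, filterConfig())
  suppressMessages(once <- filterSites(gm2, cfg))
  suppressMessages(twice <- filterSites(once, cfg))
  expect_equal(positions(twice), positions(once))
  expect_equal(calls(twice), calls(once))
  expect_true(all(positions(once) %in% positions(gm2)))
})

test_that("mafFilter keeps MAF >= cutoff computed over called alleles", {
  # 15 diploids, exactly 1 alt allele: MAF 1/30 < 0.05 -> removed
  gt <- matrix(0L, 2, 15)
  gt[1, 1] <- 1L                      # singleton
  gt[2, 1:3] <- c(1L, 1L, 1L)         # 3/30 = 0.10 -> kept
  gm <- gmFromCalls(gt, individuals = sprintf("i%d", 1:15))
  suppressMessages(out <- mafFilter(gm, 0.05))
  expect_equal(positions(out), 200L)

  # MAF exactly at the cutoff is kept: 10 diploids, 1 alt of 20 = 0.05
  gt2 <- matrix(0L, 1, 10); gt2[1, 1] <- 1L
  gm2 <- gmFromCalls(gt2, individuals = sprintf("i%d", 1:10))
  suppressMessages(expect_equal(nSites(mafFilter(gm2, 0.05)), 1L))

  # mafMin = 0 is the identity
  suppressMessages(expect_equal(nSites(mafFilter(gm, 0)), 2L))

  # missing calls are excluded from the denominator
  gt3 <- matrix(NA_integer_, 1, 10); gt3[1, 1:2] <- c(1L, 0L)
  gm3 <- gmFromCalls(gt3, individuals = sprintf("i%d", 1:10))
  suppressMessages(expect_equal(nSites(mafFilter(gm3, 0.2)), 1L)) # 1/4
})

test_that("subsetScaffolds selects longest-N and applies BED exclusions", {
  lens <- setNames(c(500, 400, 300, 200), paste0("s", 1:4))
  gt <- matrix(0L, 8, 2)
  gm <- GenotypeMatrix(scaffold = rep(paste0("s", 1:4), each = 2),
                       pos = rep(c(50, 150), 4), calls = gt,
                       alt = rep("G", 8))
  suppressMessages(top2 <- subsetScaffolds(gm, longestN = 2,
                                           scaffoldLengths = lens))
  expect_equal(unique(scaffolds(top2)), c("s1", "s2"))

  bed <- tempfile(fileext = ".bed")
  writeLines("s1\t40\t60", bed)  # 0-based half-open: covers pos 41..60
  suppressMessages(ex <- subsetScaffolds(gm, excludeBed = bed))
  expect_false(any(scaffolds(ex) == "s1" & positions(ex) == 50))
  expect_true(any(scaffolds(ex) == "s1" & positions(ex) == 150))

  emptyBed <- tempfile(fileext = ".bed")
  writeLines(character(0), emptyBed)
  suppressMessages(same <- subsetScaffolds(gm, excludeBed = emptyBed))
  expect_equal(nSites(same), nSites(gm))

  expect_error(subsetScaffolds(gm, include = "nope"), "unknown scaffold")
})

test_that("longest-N tie-break and 150-scaffold selection are exact", {
  lens <- setNames(rep(c(1000, 500), times = c(100, 50)),
                   sprintf("scf%03d", 1:150))
  gt <- matrix(0L, 150, 1)
  gm <- GenotypeMatrix(scaffold = sprintf("scf%03d", 1:150),
                       pos = rep(10L, 150), calls = gt,
                       alt = rep("G", 150))
  suppressMessages(sel <- subsetScaffolds(gm, longestN = 100,
                                          scaffoldLengths = lens))
  expect_equal(sort(unique(scaffolds(sel))), sprintf("scf%03d", 1:100))
})
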