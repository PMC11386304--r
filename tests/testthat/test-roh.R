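# Sliding-window ROH detection, support trimming, F_ROH, age mapping.

test_that("window verdicts enforce het and missing allowances exactly", {
  cfg <- rohConfig()
  hom <- rep(0L, 100)
  expect_true(windowVerdicts(hom, cfg))
  het8 <- hom; het8[1:8] <- 1L
  expect_true(windowVerdicts(het8, cfg))
  het9 <- hom; het9[1:9] <- 1L
  expect_false(windowVerdicts(het9, cfg))
  mis15 <- hom; mis15[1:15] <- NA
  expect_true(windowVerdicts(mis15, cfg))
  mis16 <- hom; mis16[1:16] <- NA
  expect_false(windowVerdicts(mis16, cfg))
  expect_length(windowVerdicts(rep(0L, 99), cfg), 0L)  # < one window
  expect_length(windowVerdicts(rep(0L, 150), cfg), 51L)
})

test_that("SNP support is eligible-covering / covering with >= threshold", {
  cfg <- rohConfig()
  nSnps <- 300L
  verdicts <- rep(FALSE, nSnps - 100L + 1L)
  # SNP 150 is covered by windows 51..150
  verdicts[51:55] <- TRUE
  s <- snpSupport(verdicts, nSnps, cfg)
  expect_equal(s$nCovering[150], 100L)
  expect_equal(s$support[150], 0.05)
  expect_true(s$included[150])            # minimum 5% is attainable
  verdicts[55] <- FALSE
  s4 <- snpSupport(verdicts, nSnps, cfg)
  expect_equal(s4$support[150], 0.04)
  expect_false(s4$included[150])
  # edge SNPs use the true covering count
  expect_equal(s$nCovering[1], 1L)
  expect_equal(s$nCovering[nSnps], 1L)
})

test_that("a fully heterozygous scaffold yields no included SNP", {
  cfg <- rohConfig()
  callsV <- rep(1L, 400)
  v <- windowVerdicts(callsV, cfg)
  s <- snpSupport(v, 400L, cfg)
  expect_false(any(s$included))
  expect_equal(nrow(rohScaffold(callsV, seq_len(400) * 1000, cfg)), 0L)
})

test_that("support trimming removes exactly 4 SNPs per flank of a block", {
  cfg <- rohConfig()
  # heterozygous flanks, homozygous centre
  callsV <- c(rep(1L, 300), rep(0L, 700), rep(1L, 300))
  v <- windowVerdicts(callsV, cfg)
  block <- range(which(v))
  s <- snpSupport(v, length(callsV), cfg)
  inc <- range(which(s$included))
  expect_equal(inc[1], block[1] + 4L)
  expect_equal(inc[2], block[2] + cfg@windowSnps - 1L - 4L)
})

test_that("assembleRuns applies SNP-count, length, density and gap rules", {
  cfg <- rohConfig()
  # 99 included SNPs spanning 0.9 Mb: fails the 100-SNP minimum
  pos99 <- seq(1, 9e5, length.out = 99)
  expect_equal(nrow(assembleRuns(pos99, rep(TRUE, 99), cfg)), 0L)
  # 100 SNPs spanning 0.4 Mb: fails the 0.5 Mb minimum
  pos04 <- seq(1, 4e5, length.out = 100)
  expect_equal(nrow(assembleRuns(pos04, rep(TRUE, 100), cfg)), 0L)
  # 100 SNPs spanning 0.6 Mb: passes everything
  pos06 <- round(seq(1, 6e5, length.out = 100))
  r <- assembleRuns(pos06, rep(TRUE, 100), cfg)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_snps, 100L)
  expect_equal(r$length_bp, 6e5)
  # 150 SNPs spanning 2 Mb: density 13,333 bp/SNP fails
  pos2m <- round(seq(1, 2e6, length.out = 150))
  expect_equal(nrow(assembleRuns(pos2m, rep(TRUE, 150), cfg)), 0L)
  # a > 100 kb gap splits a run
  posGap <- c(seq(1, 6e5, length.out = 120),
              seq(6e5 + 150001, 6e5 + 150000 + 6e5, length.out = 120))
  rs <- assembleRuns(posGap, rep(TRUE, 240), cfg)
  expect_equal(nrow(rs), 2L)
  expect_error(assembleRuns(c(3, 2, 1), rep(TRUE, 3), cfg), "sorted")
})

test_that("a planted homozygous tract is recovered with tight boundaries", {
  set.seed(301)
  cfg <- rohConfig()
  spacing <- 5000
  n <- 1200
  pos <- seq_len(n) * spacing
  callsV <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                   prob = c(0.3, 0.5, 0.2))
  tract <- 401:800                       # 2 Mb at 5 kb/SNP
  callsV[tract] <- sample(c(0L, 2L), length(tract), replace = TRUE)
  runs <- rohScaffold(callsV, pos, cfg)
  expect_equal(nrow(runs), 1L)
  expect_lt(abs(runs$start - pos[401]), (cfg@windowSnps + 1) * spacing)
  expect_lt(abs(runs$end - pos[800]), (cfg@windowSnps + 1) * spacing)
  # matches the brute-force oracle exactly
  expect_equal(runs, oracleRoh(callsV, pos, cfg))
})

test_that("the caller matches the brute-force oracle on random scaffolds", {
  set.seed(555)
  cfg <- rohConfig()
  for (i in 1:10) {
    sc <- randomRohScaffold(nSnps = 600, spacingBp = 2000)
    got <- rohScaffold(sc$calls, sc$pos, cfg)
    want <- oracleRoh(sc$calls, sc$pos, cfg)
    expect_equal(got, want)
  }
})

test_that("detectRoh is deterministic and respects scaffold structure", {
  set.seed(77)
  n <- 900
  pos <- seq_len(n) * 3000
  mk <- function() {
    v <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
    v[301:600] <- 0L
    v
  }
  gt <- cbind(mk(), mk())
  gm <- GenotypeMatrix(scaffold = rep("s1", n), pos = pos, calls = gt,
                       alt = rep("G", n), individuals = c("a", "b"),
                       scaffoldLengths = c(s1 = 3e6))
  segs1 <- detectRoh(gm)
  segs2 <- detectRoh(gm)
  expect_identical(as.data.frame(segs1), as.data.frame(segs2))
  expect_setequal(unique(mcols(segs1)$individual), c("a", "b"))
  expect_true(all(mcols(segs1)$length_bp >= 5e5))
  expect_true(all(mcols(segs1)$n_snps >= 100))
  # no two segments of one individual overlap
  for (id in c("a", "b")) {
    s <- segs1[mcols(segs1)$individual == id]
    expect_true(all(GenomicRanges::countOverlaps(s, s) == 1))
  }
})

test_that("relaxing the het allowance never deletes ROH coverage", {
  set.seed(88)
  for (i in 1:3) {
    n <- 800
    pos <- seq_len(n) * 2000          # uniform spacing: density is safe
    v <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
    v[101:500] <- sample(c(0L, 2L), 400, replace = TRUE)
    v[sample(101:500, 12)] <- 1L
    strict <- rohScaffold(v, pos, rohConfig(maxHetFracWindow = 0.04))
    relaxed <- rohScaffold(v, pos, rohConfig(maxHetFracWindow = 0.12))
    cov <- function(r) {
      if (!nrow(r)) return(IRanges::IRanges())
      IRanges::IRanges(r$start, r$end)
    }
    missing <- IRanges::setdiff(cov(strict), cov(relaxed))
    expect_equal(sum(IRanges::width(missing)), 0)
  }
})

test_that("classifyFroh computes F_ROH and class decomposition", {
  cfg <- rohConfig()
  gr <- GRanges(c("s1", "s2"), IRanges(c(1, 1), c(6e5, 15e5)))
  mcols(gr) <- DataFrame(individual = c("a", "a"),
                         n_snps = c(120L, 300L),
                         length_bp = c(6e5, 15e5),
                         size_class = factor(c("0.5-1Mb", "1-2Mb"),
                           levels = c("0.5-1Mb", "1-2Mb", "2-4Mb",
                                      ">4Mb")),
                         gen_min = c(50, 25), gen_max = c(100, 50))
  fr <- classifyFroh(gr, lAutoBp = 230.1e6, individuals = c("a", "b"),
                     config = cfg)
  expect_equal(fr$f_roh[fr$individual == "a"], 2.1e6 / 230.1e6)
  expect_equal(fr$f_roh[fr$individual == "b"], 0)
  a <- fr[fr$individual == "a", ]
  expect_equal(a$`f_0.51Mb` + a$`f_12Mb` + a$`f_24Mb` + a$`f_4Mb`,
               a$f_roh)
  expect_equal(a$n_roh, 2)
  # segment beyond its scaffold is an error
  expect_error(classifyFroh(gr, 230.1e6, scaffoldLengths = c(s1 = 1e5,
                                                             s2 = 2e6)),
               "outside")
})

test_that("segment length classes follow the configured edges", {
  cfg <- rohConfig()
  lab <- levels(rohdiv:::.classify(1, cfg@classEdgesBp))
  expect_equal(lab, c("0.5-1Mb", "1-2Mb", "2-4Mb", ">4Mb"))
  expect_equal(as.character(rohdiv:::.classify(1.5e6, cfg@classEdgesBp)),
               "1-2Mb")
  expect_equal(as.character(rohdiv:::.classify(6e5, cfg@classEdgesBp)),
               "0.5-1Mb")
  expect_equal(as.character(rohdiv:::.classify(5e6, cfg@classEdgesBp)),
               ">4Mb")
})

test_that("ROH age mapping inverts expected IBD segment length", {
  expect_equal(ageFromLength(4e6), 12.5)
  expect_equal(ageFromLength(2e6), 25)
  expect_equal(ageFromLength(1e6), 50)
  expect_equal(ageFromLength(5e5), 100)
  expect_equal(ageFromLength(1e6, cmPerMb = 2), 25)
  expect_equal(ageFromLength(2e6) / ageFromLength(1e6), 0.5)
  expect_error(ageFromLength(0), "positive")
  expect_error(ageFromLength(-1), "positive")
})
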