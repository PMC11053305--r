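test_that("fragment BED reading derives lengths and applies the MAPQ filter", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t267", bed)
  f <- readFragments(bed)
  expect_equal(f$length, 167)

  # 1000 fragments, 100 at MAPQ 20 -> 900 retained at mapqMin 30
  set.seed(1)
  n <- 1000
  df <- data.frame(chrom = "chr1", start = seq_len(n) * 10,
                   end = seq_len(n) * 10 + 160, name = "f",
                   mapq = c(rep(20, 100), rep(60, 900)))
  write.table(df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  f <- readFragments(bed, mapqMin = 30)
  expect_equal(nrow(f), 900)
  expect_equal(attr(f, "n_dropped_mapq"), 100)

  # zero-span fragment skipped with a warning counter
  writeLines(c("chr1\t100\t100", "chr1\t200\t360"), bed)
  expect_warning(f <- readFragments(bed), "non-positive")
  expect_equal(nrow(f), 1)
  expect_equal(attr(f, "n_skipped"), 1)
})

test_that("paired-end BAM reading yields one fragment per proper pair", {
  sam <- withr::local_tempfile(fileext = ".sam")
  # 60 proper pairs on chr1: fragment i spans [1000*i, 1000*i + 167),
  # the first 10 pairs at MAPQ 20, the rest at 60
  n <- 60
  pos1 <- 1000 * seq_len(n) + 1     # 1-based leftmost
  tlen <- 167
  mapq <- c(rep(20, 10), rep(60, n - 10))
  seq50 <- strrep("A", 50)
  r1 <- sprintf("frag%03d\t99\tchr1\t%d\t%d\t50M\t=\t%d\t%d\t%s\t*",
                seq_len(n), pos1, mapq, pos1 + tlen - 50, tlen, seq50)
  r2 <- sprintf("frag%03d\t147\tchr1\t%d\t%d\t50M\t=\t%d\t%d\t%s\t*",
                seq_len(n), pos1 + tlen - 50, mapq, pos1, -tlen, seq50)
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr1\tLN:5000000",
               as.vector(rbind(r1, r2))), sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)
  f <- readFragments(bam, mapqMin = 30)
  expect_equal(nrow(f), 50)
  expect_true(all(f$length == 167))
  expect_equal(f$start, 1000 * 11:60)   # 0-based outer starts
})

test_that("profile proportions respect the inclusive 100-167 size window", {
  bs <- makeBinSet(cohortConfig(nBins = 2, nArms = 1, binSpan = 5e6))
  # all fragments length 150 -> occupied bins saturate at 1.0
  f <- data.frame(chrom = "chr1", start = c(10, 20, 5e6 + 10),
                  end = c(160, 170, 5e6 + 160))
  p <- computeProfile(f, bs, sampleId = "s1")
  expect_equal(unname(proportionMatrix(p)[1, ]), c(1, 1))

  # boundary lengths 99/100/167/168 in one bin -> 2/4
  f <- data.frame(chrom = "chr1", start = rep(100, 4),
                  end = 100 + c(99, 100, 167, 168))
  p <- computeProfile(f, bs)
  expect_equal(unname(proportionMatrix(p)[1, 1]), 0.5)
  expect_true(is.na(proportionMatrix(p)[1, 2]))

  # no fragments at all -> all-missing profile failing QC
  p <- computeProfile(f[0, ], bs)
  expect_true(all(is.na(proportionMatrix(p))))
  expect_false(qcPass(p)[[1]])
})

test_that("profile counting matches a naive double loop and conserves totals", {
  set.seed(11)
  bs <- makeBinSet(cohortConfig(nBins = 6, nArms = 2, binSpan = 1e6))
  n <- 3000
  f <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                  start = floor(runif(n, 0, 3.2e6)))
  f$end <- f$start + sample(c(60:400, 1200), n, replace = TRUE)
  p <- computeProfile(f, bs)
  oracle <- naiveProfileCounts(f, binsAsDf(bs))
  expect_equal(unname(shortCounts(p)[, 1]), oracle$short)
  expect_equal(unname(totalCounts(p)[, 1]), oracle$total)

  # conservation: summed short counts = retained in-window short fragments
  len <- f$end - f$start
  assigned <- !is.na(assignBin(f, bs)) & len <= 1000
  expect_equal(sum(shortCounts(p)),
               sum(assigned & len >= 100 & len <= 167))

  # order invariance
  p2 <- computeProfile(f[sample(n), ], bs)
  expect_equal(shortCounts(p2), shortCounts(p))
})

test_that("estimated proportions recover programmed per-bin truth", {
  # genome-scale bin count: at most ~1% of the 504 bins should sit outside
  # three binomial standard errors of the programmed proportion
  cfg <- cohortConfig(seed = 3, nBins = 504, nArms = 5,
                      fragmentsPerSample = 1e5, enrichment = 2,
                      tumorFraction = 1)
  set.seed(cfg$seed)
  lat <- cohortLatents(cfg)
  sc <- sampleProfileCounts(cfg, lat, isCase = TRUE, timeBeforeDxYears = 0,
                            tau = 1)
  se3 <- 3 * sqrt(sc$p * (1 - sc$p) / pmax(sc$total, 1))
  within <- abs(sc$short / sc$total - sc$p) <= se3
  expect_gte(mean(within), 0.99)
})

test_that("depth QC uses the configured threshold", {
  bs <- makeBinSet(cohortConfig(nBins = 1, nArms = 1))
  tot <- matrix(c(4999999, 5000000, 12e6), 1)
  ps <- profileSetFromCounts(matrix(0, 1, 3), tot, bs)
  ps <- qcFilter(ps, 5e6)
  expect_identical(unname(qcPass(ps)), c(FALSE, TRUE, TRUE))
  expect_true(all(qcPass(qcFilter(ps, 0))))
})

test_that("row centering is exact, idempotent and guards empty rows", {
  expect_equal(unname(centerRows(matrix(c(0.2, 0.4, 0.6), 1))[1, ]),
               c(-0.2, 0, 0.2))
  set.seed(5)
  m <- matrix(runif(20 * 50), 20,
              dimnames = list(paste0("s", 1:20), NULL))
  cm <- centerRows(m)
  expect_true(all(abs(rowMeans(cm)) < 1e-12))
  expect_equal(unname(centerRows(cm)), unname(cm))
  m[3, ] <- NA
  expect_error(centerRows(m), "s3")
})

test_that("case/control ratios report programmed enrichment", {
  p0 <- runif(20, 0.15, 0.25)
  ctrl <- matrix(rep(p0, each = 10), 10, byrow = FALSE)
  case <- ctrl
  case[, 1:4] <- case[, 1:4] * 2
  m <- rbind(case, ctrl)
  lab <- rep(c("case", "control"), each = 10)
  r <- caseControlRatio(m, lab)
  expect_equal(unname(r[1:4]), rep(2, 4))
  expect_equal(unname(r[5:20]), rep(1, 16))
  expect_error(caseControlRatio(m, rep("case", 20)), "control")
  m2 <- m; m2[11:20, 1] <- 0
  expect_warning(r2 <- caseControlRatio(m2, lab), "zero control mean")
  expect_true(is.na(r2[1]))
})

test_that("hierarchical clustering separates structured profiles", {
  # duplicated blocks are recovered exactly by the two-group cut
  m <- rbind(matrix(rep(c(1, 0, 0), each = 5), 5),
             matrix(rep(c(0, 1, 1), each = 5), 5))
  rownames(m) <- paste0("s", 1:10)
  cl <- clusterSamples(m, center = FALSE)
  expect_equal(twoGroupAgreement(cl$groups, rep(1:2, each = 5)), 1)

  expect_error(clusterSamples(m[1, , drop = FALSE]), "2 samples")

  # a single outlier row is the last merge
  m2 <- matrix(0.2, 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  m2 <- m2 + matrix(rnorm(60, 0, 1e-4), 6)
  m2[6, ] <- 5
  cl2 <- clusterSamples(m2, center = FALSE)
  lastMerge <- cl2$hclust$merge[nrow(cl2$hclust$merge), ]
  expect_true(-6 %in% lastMerge)

  # full-strength tumour signal separates cases from controls
  cfg <- cohortConfig(seed = 9, nCases = 20, nControls = 20, nBins = 40,
                      nArms = 4, fragmentsPerSample = 2e4,
                      enrichment = 2, tumorFraction = 1,
                      tumorFractionSdLog = 0)
  co <- makeCohort(cfg)
  cl3 <- clusterSamples(co$profiles)
  expect_gt(twoGroupAgreement(cl3$groups, co$metadata$label), 0.9)
})
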