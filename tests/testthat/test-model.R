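makeNullModel <- function(features = c("1q_1", "1q_2"), coefs = numeric(0),
                          intercept = 0, cutoff = 0.5) {
  new("FragModel", featureNames = features, coefficients = coefs,
      intercept = intercept, lambda = 0.1, cutoff = cutoff,
      featureSd = setNames(rep(1, length(features)), features),
      featureMean = setNames(rep(0, length(features)), features),
      seed = 1L, nFolds = 5L, nRepeats = 5L, cvCurve = data.frame())
}

test_that("a lone informative feature is selected with the largest weight", {
  set.seed(21)
  n <- 60
  x <- matrix(rnorm(n * 10, 0.2, 0.02), n,
              dimnames = list(sprintf("s%02d", 1:n), paste0("b", 1:10)))
  lab <- rep(c("case", "control"), each = n / 2)
  x[lab == "case", 4] <- x[lab == "case", 4] + 0.1
  mod <- trainFragModel(x, lab, seed = 2)
  expect_true("b4" %in% names(modelCoefficients(mod)))
  expect_equal(names(featureImportance(mod))[1], "b4")
})

test_that("degenerate training inputs raise errors", {
  x <- matrix(runif(40), 8, dimnames = list(paste0("s", 1:8), NULL))
  expect_error(trainFragModel(x, rep("case", 8)), "two classes")
  expect_error(trainFragModel(x, rep(c("case", "control"), 4), nFolds = 5),
               "nFolds")
  expect_error(trainFragModel(rbind(x, x, x),
                              rep(c("case", "control"), 12), nFolds = 30),
               "folds")
})

test_that("scores are the logistic transform of the linear predictor", {
  expect_equal(unname(scoreSamples(makeNullModel(),
                                   matrix(rnorm(4), 2,
                                          dimnames = list(NULL,
                                                          c("1q_1", "1q_2"))))),
               c(0.5, 0.5))
  satur <- makeNullModel(intercept = 10)
  expect_gt(min(scoreSamples(satur,
                             matrix(0, 1, 2,
                                    dimnames = list(NULL, c("1q_1", "1q_2"))))),
            0.9999)

  # oracle: recompute eta by an independent dot product on random rows
  set.seed(31)
  feats <- paste0("f", 1:8)
  coefs <- setNames(rnorm(5), feats[c(1, 3, 4, 6, 8)])
  mod <- makeNullModel(features = feats, coefs = coefs, intercept = -0.7)
  x <- matrix(rnorm(100 * 8), 100, dimnames = list(NULL, feats))
  got <- scoreSamples(mod, x)
  want <- vapply(seq_len(100), function(i) {
    eta <- -0.7
    for (f in names(coefs)) eta <- eta + coefs[[f]] * x[i, f]
    1 / (1 + exp(-eta))
  }, 0.0)
  expect_equal(unname(got), want, tolerance = 1e-12)

  expect_error(scoreSamples(mod, x[, 1:4]), "f6")
})

test_that("importance percentages are standardized-coefficient shares", {
  m1 <- makeNullModel(coefs = c("1q_1" = 0.3))
  expect_equal(unname(featureImportance(m1)), 100)
  m3 <- makeNullModel(features = c("a", "b", "c"),
                      coefs = c(a = 2, b = -1, c = 1))
  expect_equal(featureImportance(m3), c(a = 50, b = 25, c = 25))
  expect_error(featureImportance(makeNullModel()), "nonzero")

  set.seed(41)
  x <- matrix(rnorm(60 * 12, 0.2, 0.02), 60,
              dimnames = list(sprintf("s%02d", 1:60), paste0("b", 1:12)))
  lab <- rep(c("case", "control"), 30)
  x[lab == "case", 1:3] <- x[lab == "case", 1:3] + 0.05
  mod <- trainFragModel(x, lab, seed = 3)
  expect_equal(sum(featureImportance(mod)), 100, tolerance = 1e-9)
})

test_that("classification at the cutoff uses the >= convention", {
  expect_identical(as.character(classifyScores(0.494, 0.494)), "positive")
  expect_identical(as.character(classifyScores(c(0.258, 0.846), 0.494)),
                   c("negative", "positive"))
  expect_true(all(classifyScores(runif(20), 0) == "positive"))
})

test_that("subject-window aggregation averages scores before classification", {
  one <- data.frame(subject_id = "a", window = "0-1y", score = 0.7)
  expect_equal(aggregateSubjectWindow(one)$score, 0.7)

  two <- data.frame(subject_id = "a", window = "0-1y", score = c(0.4, 0.6))
  expect_equal(aggregateSubjectWindow(two)$score, 0.5)

  set.seed(51)
  df <- data.frame(subject_id = sample(letters[1:6], 40, replace = TRUE),
                   window = sample(c("0-1y", "1-2y"), 40, replace = TRUE),
                   score = runif(40))
  agg <- aggregateSubjectWindow(df)
  for (i in seq_len(nrow(agg))) {
    sel <- df$subject_id == agg$subject_id[i] & df$window == agg$window[i]
    expect_equal(agg$score[i], mean(df$score[sel]))
    expect_equal(agg$n_samples[i], sum(sel))
  }
})

test_that("training is invariant to sample order and serializes exactly", {
  cfg <- cohortConfig(seed = 13, nCases = 25, nControls = 25, nBins = 20,
                      nArms = 2, fragmentsPerSample = 2e4, enrichment = 2,
                      tumorFraction = 0.6)
  co <- makeCohort(cfg)
  m <- proportionMatrix(co$profiles)
  lab <- co$metadata$label
  mod1 <- trainFragModel(m, lab, seed = 5)
  perm <- sample(nrow(m))
  mod2 <- trainFragModel(m[perm, ], lab[perm], seed = 5)
  expect_identical(names(modelCoefficients(mod1)),
                   names(modelCoefficients(mod2)))
  expect_equal(modelCoefficients(mod1), modelCoefficients(mod2))

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeFragModel(mod1, f1)
  writeFragModel(mod1, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- readFragModel(f1)
  expect_equal(modelCoefficients(back), modelCoefficients(mod1))
  expect_equal(back@intercept, mod1@intercept)
  expect_equal(scoreSamples(back, m), scoreSamples(mod1, m))
})

test_that("held-out discrimination grows with tumour signal", {
  aucAt <- function(tau, seed) {
    cfg <- cohortConfig(seed = seed, nCases = 25, nControls = 25,
                        nBins = 30, nArms = 3, fragmentsPerSample = 2e4,
                        enrichment = 2, tumorFraction = tau)
    tr <- makeCohort(cfg)
    te <- makeCohort(cohortConfig(seed = seed + 100, nCases = 25,
                                  nControls = 25, nBins = 30, nArms = 3,
                                  fragmentsPerSample = 2e4, enrichment = 2,
                                  tumorFraction = tau,
                                  affectedBins = tr$truth$affected_idx))
    mod <- trainFragModel(proportionMatrix(tr$profiles),
                          tr$metadata$label, seed = seed)
    sc <- scoreSamples(mod, proportionMatrix(te$profiles))
    rocAuc(sc, te$metadata$label)$auc
  }
  aLow <- aucAt(0.05, 61)
  aHigh <- aucAt(0.8, 61)
  expect_gt(aHigh, 0.95)
  expect_gt(aHigh, aLow - 0.02)
})

test_that("control scores sit below case scores under enrichment", {
  cfg <- cohortConfig(seed = 71, nCases = 100, nControls = 100, nBins = 30,
                      nArms = 3, fragmentsPerSample = 2e4, enrichment = 1.8,
                      tumorFraction = 0.6)
  co <- makeCohort(cfg)
  mod <- trainFragModel(proportionMatrix(co$profiles), co$metadata$label,
                        seed = 8)
  sc <- scoreSamples(mod, proportionMatrix(co$profiles))
  isCase <- co$metadata$label == "case"
  expect_gt(mean(sc[isCase]), mean(sc[!isCase]))
  expect_gt(mean(outer(sc[isCase], sc[!isCase], `>`)), 0.5)
})
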