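test_that("gamma_theta tracks a planted hinge rotation", {
  for (ang in c(60, 120, 150)) {
    fx <- makeFixturePair(fixtureSpec(seed = 31, rotation = ang))
    rep1 <- compareChains(fx$closed, fx$open)
    expect_equal(rep1@factors$gamma_theta, ang / 180, tolerance = 0.05)
  }
})

test_that("gamma_theta is 0 for co-oriented swapped domains", {
  fx <- getFixture(1, noise_sigma = 0)
  sw <- fx$swapped[1]:fx$swapped[2]
  id <- list(R = diag(3), t = c(0, 0, 0))
  gt <- gammaTheta(fx$closed, fx$closed, sw, sw, fx$pivots[1], fx$pivots[1],
                   id)
  expect_equal(gt, 0, tolerance = 1e-8)
})

test_that("gamma_d normalizes displacement by the bounding-box diagonal", {
  fx <- getFixture(1, noise_sigma = 0)
  sw <- fx$swapped[1]:fx$swapped[2]
  id <- list(R = diag(3), t = c(0, 0, 0))
  pairs <- data.frame(iQ = sw, iS = sw)
  expect_equal(gammaD(fx$closed, fx$closed, pairs, sw, sw, id), 0)
  # planted rigid displacement of a known fraction of the diagonal
  r <- residues(fx$closed)
  cloud0 <- caCoords(fx$closed)[sw, ]
  shifted <- fx$closed
  d0 <- vnorm(apply(cloud0, 2, max) - apply(cloud0, 2, min))
  # shift along x by delta: new diagonal from the union cloud
  delta <- 30
  r2 <- r; r2[sw, "x"] <- r2[sw, "x"] + delta
  ch2 <- newProteinChain("shifted", r2, fx$closed@sseRecords)
  got <- gammaD(fx$closed, ch2, pairs, sw, sw, id)
  cloud <- rbind(cloud0, caCoords(ch2)[sw, ])
  dmax <- vnorm(apply(cloud, 2, max) - apply(cloud, 2, min))
  expect_equal(got, delta / dmax, tolerance = 1e-8)
  expect_true(is.na(gammaD(fx$closed, ch2, pairs[0, ], sw, sw, id)))
})

test_that("mu_sd is RMSD over normalized coverage", {
  mkAln <- function(n, rmsd)
    new("StructAlignment", pairs = data.frame(iQ = 1:n, iS = 1:n),
        transform = list(R = diag(3), t = c(0, 0, 0)), rmsd = rmsd, nE = n)
  expect_equal(muSD(mkAln(20, 0), 20, 20), 0)       # identical domains
  expect_equal(muSD(mkAln(20, 1.5), 20, 25), 1.5)   # full coverage
  # halving the coverage doubles mu_sd at equal rmsd
  expect_equal(muSD(mkAln(10, 1.5), 20, 25), 3.0)
})

test_that("the DS score clamps, gates and stays monotone", {
  model <- defaultDSModel()
  base <- list(gamma_theta = 0.6, gamma_d = 0.5, mu_sd = 0.5, s0 = 0.9,
               eta = 1)
  expect_equal(dsScore(modifyList(base, list(eta = 0)), model), 0)
  expect_equal(dsScore(modifyList(base, list(s0 = 0)), model), 0)
  # no penalty at the maximal swap signature
  full <- modifyList(base, list(gamma_theta = 1, gamma_d = 1, mu_sd = 0))
  expect_equal(dsScore(full, model), full$s0)
  # randomized fuzzing: always in [0, 1]
  withr::with_seed(13, {
    for (k in 1:200) {
      f <- list(gamma_theta = runif(1), gamma_d = runif(1),
                mu_sd = rexp(1), s0 = runif(1), eta = sample(0:1, 1))
      m <- list(m0 = runif(1, 0, 5), m1 = runif(1, 0, 5),
                m2 = runif(1, 0, 5))
      s <- dsScore(f, m)
      expect_gte(s, 0); expect_lte(s, 1)
    }
  })
  # monotone: up in gamma_theta and gamma_d, down in mu_sd
  s0 <- dsScore(base, model)
  expect_gte(dsScore(modifyList(base, list(gamma_theta = 0.8)), model), s0)
  expect_gte(dsScore(modifyList(base, list(gamma_d = 0.8)), model), s0)
  expect_lte(dsScore(modifyList(base, list(mu_sd = 1.5)), model), s0)
})

test_that("classification metrics match the confusion-matrix formulas", {
  perfect <- classificationMetrics(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  inverted <- classificationMetrics(c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
  expect_equal(inverted$mcc, -1)
  # reference sensitivity of the C-terminal group: TP 614 of 676
  pred <- c(rep(TRUE, 614), rep(FALSE, 62), rep(FALSE, 100), rep(TRUE, 10))
  lab <- c(rep(TRUE, 676), rep(FALSE, 110))
  m <- classificationMetrics(pred, lab)
  expect_equal(round(m$sensitivity, 3), 0.908)
  undef <- classificationMetrics(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(undef$mcc, 0)
  expect_false(undef$mcc_defined)
})

test_that("grid training separates separable factor sets", {
  pos <- lapply(1:8, function(k)
    list(gamma_theta = 0.7, gamma_d = 0.6, mu_sd = 0.3, s0 = 0.9, eta = 1))
  neg <- lapply(1:8, function(k)
    list(gamma_theta = NA_real_, gamma_d = NA_real_, mu_sd = NA_real_,
         s0 = 0.95, eta = 0))
  model <- trainDSModel(c(pos, neg), rep(c(TRUE, FALSE), each = 8),
                        m_grid = seq(0, 2, 0.5))
  expect_equal(model@trainMCC, 1)
  # the cutoff lies in the gap between the two classes' scores
  scorePos <- dsScore(pos[[1]], model)
  expect_gt(scorePos, model@cutoff)
  expect_lt(0, model@cutoff)
  expect_error(trainDSModel(pos, rep(TRUE, 8)), "positive and one negative")
})

test_that("label permutation drives the training MCC towards zero", {
  withr::with_seed(21, {
    factors <- lapply(1:20, function(k)
      list(gamma_theta = runif(1), gamma_d = runif(1), mu_sd = rexp(1, 3),
           s0 = runif(1, 0.5, 1), eta = 1))
    mccs <- vapply(1:5, function(r) {
      trainDSModel(factors, sample(rep(c(TRUE, FALSE), 10)),
                   m_grid = seq(0, 2, 1),
                   cutoff_grid = seq(0.1, 0.9, 0.2))@trainMCC
    }, numeric(1))
    # an optimized cutoff overfits somewhat, but nowhere near separability
    expect_lt(mean(mccs), 0.6)
  })
})

test_that("models round-trip through JSON", {
  m <- new("DSModel", m0 = 1.25, m1 = 0.5, m2 = 2, cutoff = 0.35,
           grid = list(), trainMCC = 0.93)
  f <- tempfile(fileext = ".json")
  writeDSModel(m, f)
  m2 <- readDSModel(f)
  expect_equal(m2@m0, 1.25)
  expect_equal(m2@cutoff, 0.35)
  expect_equal(m2@trainMCC, 0.93)
})
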