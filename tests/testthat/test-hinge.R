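test_that("the A-D product anchors at its normalization constants", {
  expect_equal(adProduct(0, 0), 0)
  expect_equal(adProduct(180, 25), 1)
  expect_equal(adProduct(90, 12.5), 0.25)
})

test_that("morphological smoothing removes spikes but keeps plateaus", {
  expect_equal(smoothProfile(c(1, 1, 9, 1, 1)), rep(1, 5))
  expect_equal(smoothProfile(c(5, 5, 0.2, 5, 5)), rep(5, 5))
  const <- rep(2.5, 8)
  expect_equal(smoothProfile(const), const)
  # plateaus at least as wide as the element survive
  step <- c(rep(1, 4), rep(6, 3), rep(5.8, 3))
  expect_equal(smoothProfile(step), step)
  expect_warning(out <- smoothProfile(c(1, 2)), "shorter than 3")
  expect_equal(out, c(1, 2))
})

test_that("transition detection reproduces the crystallin worked example", {
  p <- c(1.10, 1.10, 1.10, 1.10, 4.50, 4.50, 4.50, 4.37, 4.37, 4.37)
  sm <- smoothProfile(p)
  expect_equal(sm, p)                       # already morphologically clean
  tr <- detectTransitions(sm)
  expect_equal(tr$diffs, c(0, 0, 0, 3.40, 0, 0, 0.13, 0, 0),
               tolerance = 1e-9)
  expect_equal(tr$threshold, 0.92, tolerance = 0.005)
  expect_equal(tr$significant, 4L)          # only the 3.40 jump, p4 -> p5
})

test_that("zero-variance difference sequences yield no transitions", {
  expect_length(detectTransitions(rep(1, 6))$significant, 0)
  expect_length(detectTransitions(c(1, 2, 3, 4))$significant, 0)  # equal diffs
})

test_that("DS-type classification follows the high region's position", {
  mk <- function(x) detectTransitions(x)
  pC <- c(rep(0.1, 4), rep(2, 3))
  expect_equal(classifyDSType(pC, mk(pC))$type, "C")
  pN <- rev(pC)
  expect_equal(classifyDSType(pN, mk(pN))$type, "N")
  pM <- c(rep(0.1, 3), rep(2, 3), rep(0.1, 3))
  cl <- classifyDSType(pM, mk(pM))
  expect_equal(cl$type, "middle")
  expect_equal(cl$boundaries, c(3L, 6L))
  flat <- rep(0.2, 8)
  expect_equal(classifyDSType(flat, mk(flat))$type, "none")
})

test_that("initial opening points follow the three terminal rules", {
  sses <- toySSEs(matrix(0, 4, 3), matrix(rep(c(0, 0, 1), 4), 4, 3,
                                          byrow = TRUE),
                  first = c(10L, 41L, 80L, 100L))
  sses$last <- c(20L, 52L, 90L, 112L)
  prof <- data.frame(sseQ = 1:4, sseS = 1:4)
  # N-swap: first residue of SSE_C (the SSE after the transition)
  expect_equal(initialOpeningPoint("N", prof, 1L, sses, "Q"), 41L)
  # C-swap: last residue of SSE_N
  expect_equal(initialOpeningPoint("C", prof, 3L, sses, "Q"), 90L)
  # middle: C-swap rule on the N side, N-swap rule on the C side
  expect_equal(initialOpeningPoint("middle", prof, c(1L, 3L), sses, "Q"),
               c(20L, 100L))
})

test_that("PF/BL refinement places the opening point at the boundary", {
  cfg <- adswapConfig()
  # clean boundary: aligned main region then an unaligned tail
  mask <- c(rep(TRUE, 40), rep(FALSE, 20))
  expect_equal(refineOpeningPoint(40L, mask, -1L, cfg), 41L)
  # isolated unaligned singletons inside the main region are tolerated
  mask2 <- mask; mask2[c(10, 20)] <- FALSE
  expect_equal(refineOpeningPoint(40L, mask2, -1L, cfg), 41L)
  # all-aligned mask: the probe reaches the terminus, candidate rejected
  expect_null(refineOpeningPoint(40L, rep(TRUE, 60), -1L, cfg))
  # N-swap mirror
  maskN <- c(rep(FALSE, 15), rep(TRUE, 45))
  expect_equal(refineOpeningPoint(16L, maskN, +1L, cfg), 15L)
})

test_that("PF stage requires more than five consecutive aligned residues", {
  cfg <- adswapConfig()
  # interleaved aligned singletons never form a long run; the first long
  # run sits at positions 1..8
  mask <- c(rep(TRUE, 8), rep(c(TRUE, FALSE), 12), rep(FALSE, 6))
  op <- refineOpeningPoint(30L, mask, -1L, cfg)
  # hand trace: the probe skips the alternating singleton runs and only
  # stops inside 1..8 (at position 4, run of 6); BL then walks C-wards,
  # accumulating unaligned residues 10, 12, 14, 16, 18 — the count exceeds
  # T_N at 18, which follows the aligned residue 17
  expect_equal(op, 18L)
})

test_that("hinge validation accepts true swaps and rejects junk", {
  fx <- getFixture(1, noise_sigma = 0)
  sw <- fx$swapped[1]:fx$swapped[2]
  alignedQ <- rep(TRUE, chainLength(fx$closed)); alignedQ[sw] <- FALSE
  ok <- validateHinge(fx$closed, fx$open, sw, sw, alignedQ, "start")
  expect_equal(ok$eta, 1)
  expect_lt(ok$swap_aln@rmsd, 1e-6)
  # fragment mostly aligned by the main superposition: quick rejection
  res <- validateHinge(fx$closed, fx$open, sw, sw, rep(TRUE, 90), "start")
  expect_equal(res$eta, 0)
  expect_match(res$reason, "mostly aligned")
  # unrelated fragments (extended strand vs ideal helix) fail the
  # similarity rules once they are long enough for shape to matter
  seg <- buildIdealSegment(30, -57, -47)
  mkChain <- function(ca, id) newProteinChain(id, data.frame(
    resno = seq_len(nrow(ca)), insert = "", aa = "A",
    x = ca[, 1], y = ca[, 2], z = ca[, 3]))
  line <- cbind(3.8 * (0:29), 0, 0)
  res2 <- validateHinge(mkChain(seg$CA, "helix"), mkChain(line, "strand"),
                        1:30, 1:30, rep(FALSE, 30), "start")
  expect_equal(res2$eta, 0)
  expect_match(res2$reason, "ratio too small")
  # too-short fragment
  expect_equal(validateHinge(fx$closed, fx$open, 1:2, 1:2, alignedQ,
                             "start")$eta, 0)
})

test_that("hinge range extension follows the torsion rule and collapses", {
  fx <- getFixture(1, noise_sigma = 0)
  rep1 <- compareChains(fx$closed, fx$open)
  h <- rep1@hinges$Q[[1]]
  expect_equal(h$theta0, 25)
  # the hinge range contains the opening point and stays near the pivot
  expect_true(h$range[1] <= h$opening_point &&
              h$opening_point <= h$range[2])
  expect_lt(abs(h$range[1] - fx$pivots[1]), 8)
  # no torsion divergence anywhere: hinge collapses to the minimal region
  pairsAll <- data.frame(i = 1:90, j = 1:90)
  hr <- determineHingeRange(45L, pairsAll, fx$closed, fx$closed,
                            list(list(R = diag(3), t = c(0, 0, 0))),
                            n_hl = 1)
  expect_equal(hr$range, c(45, 45))
})

test_that("theta0 doubles for middle swaps and restricts the range", {
  fxm <- getFixture(11, "middle")
  repm <- compareChains(fxm$closed, fxm$open)
  expect_equal(repm@dsType, "middle")
  expect_length(repm@hinges$Q, 2)
  expect_equal(repm@hinges$Q[[1]]$theta0, 50)
  # rerun the first hinge extension with n_hl = 1: the stricter n_hl = 2
  # range must be a subset
  aln <- repm@alignments
  pooled <- rbind(data.frame(i = aln$main@pairs$iQ, j = aln$main@pairs$iS),
                  data.frame(i = aln$swap@pairs$iQ, j = aln$swap@pairs$iS))
  op <- repm@hinges$Q[[1]]$opening_point
  trans <- list(aln$main@transform, aln$swap@transform)
  r1 <- determineHingeRange(op, pooled, fxm$closed, fxm$open, trans,
                            n_hl = 1)
  r2 <- determineHingeRange(op, pooled, fxm$closed, fxm$open, trans,
                            n_hl = 2)
  expect_gte(r2$range[1], r1$range[1])
  expect_lte(r2$range[2], r1$range[2])
})

test_that("small swapped domains are proposed from unaligned regions", {
  # flat profile with an unaligned N-tail
  sses <- toySSEs(matrix(0, 3, 3),
                  matrix(rep(c(0, 0, 1), 3), 3, 3, byrow = TRUE),
                  first = c(20L, 40L, 60L))
  sses$last <- c(28L, 48L, 68L)
  prof <- data.frame(sseQ = 1:3, sseS = 1:3)
  aligned <- rep(TRUE, 80); aligned[1:15] <- FALSE
  cs <- assignSmallSwappedDomain(aligned, sses, prof, "Q")
  expect_equal(cs$type, "N")
  expect_equal(cs$o, 20L)
  # fully aligned homolog: no candidate
  expect_null(assignSmallSwappedDomain(rep(TRUE, 80), sses, prof, "Q"))
  # interior unaligned fragment: middle candidate at the bifurcation edges
  aligned2 <- rep(TRUE, 80); aligned2[33:40] <- FALSE
  cs2 <- assignSmallSwappedDomain(aligned2, sses, prof, "Q")
  expect_equal(cs2$type, "middle")
  expect_equal(cs2$o, c(32L, 41L))
})

test_that("eta is zero for self-comparison and common homologs", {
  fx <- getFixture(2)
  selfRep <- compareChains(fx$closed, fx$closed)
  expect_equal(selfRep@eta, 0)
  expect_equal(selfRep@score, 0)
  hom <- makeCommonHomolog(fx$closed, 0.5, seed = 77)
  homRep <- compareChains(fx$closed, hom)
  expect_equal(homRep@eta, 0)
  expect_equal(homRep@score, 0)
  expect_gt(homRep@measures$virtual$v_ratio, 95)
})
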