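test_that("identical images give every point its self-pairing at maximal score", {
  fx <- getFixture(1)
  cfg <- adswapConfig()
  img <- buildADImage(sseVectors(fx$closed), "Q", cfg)
  v <- candidateVertices(img, img, cfg)
  self <- v[v$qi == v$si, ]
  expect_equal(nrow(self), nrow(img@points))
  expect_equal(self$s, rep(cfg$s_c, nrow(self)))
  expect_true(all(v$s > 0))
})

test_that("pruned vertex set is a subset of the brute-force positive set", {
  fx <- getFixture(2)
  cfg <- adswapConfig()
  imgQ <- buildADImage(sseVectors(fx$closed), "Q", cfg)
  imgS <- buildADImage(sseVectors(fx$open), "S", cfg)
  pruned <- candidateVertices(imgQ, imgS, cfg)
  full <- candidateVertices(imgQ, imgS, cfg, prune = FALSE)
  key <- function(v) paste(v$qi, v$si)
  expect_true(all(key(pruned) %in% key(full)))
  expect_true(all(full$s > 0))
})

test_that("a query point can pair with several nearby subject points", {
  # two subject points close to one query point in the A-D plane
  cent <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  vec <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0))
  imgQ <- buildADImage(toySSEs(cent, vec))
  cent2 <- cent + matrix(c(0.3, 0, 0), 3, 3, byrow = TRUE) * 0.5
  imgS <- buildADImage(toySSEs(cent2, vec))
  v <- candidateVertices(imgQ, imgS)
  expect_gte(max(table(v$qi)), 2)
})

test_that("edges are rejected between vertices sharing one side's point", {
  fx <- getFixture(1)
  cfg <- adswapConfig()
  img <- buildADImage(sseVectors(fx$closed), "Q", cfg)
  g <- buildPairGraph(img, img, cfg)
  v <- g@vertices; e <- g@edges
  expect_true(all(v$qi[e$p] != v$qi[e$q]))
  expect_true(all(v$si[e$p] != v$si[e$q]))
  expect_true(all(e$p < e$q))                    # no flipped duplicates
  expect_equal(anyDuplicated(e[, c("p", "q")]), 0)
})

test_that("structurally identical inputs give maximal edge terms", {
  fx <- getFixture(1)
  cfg <- adswapConfig()
  img <- buildADImage(sseVectors(fx$closed), "Q", cfg)
  g <- buildPairGraph(img, img, cfg)
  v <- g@vertices; e <- g@edges
  self <- which(v$qi == v$si)
  sel <- e$p %in% self & e$q %in% self
  expect_true(any(sel))
  expect_equal(e$t_d[sel], rep(1, sum(sel)))
  expect_equal(e$t_alpha[sel], rep(1, sum(sel)), tolerance = 1e-8)
  expect_equal(e$t_gamma[sel], rep(1, sum(sel)), tolerance = 1e-8)
})

test_that("vertex weights sum positive incident edges only", {
  fx <- getFixture(1)
  img <- buildADImage(sseVectors(fx$closed))
  g <- new("PairGraph",
           vertices = data.frame(qi = 1:4, si = 1:4, s = 1, w = 0),
           edges = data.frame(p = c(1L, 1L, 1L, 2L), q = c(2L, 3L, 4L, 3L),
                              weight = c(0.61, 0.51, 0.33, -0.4),
                              t_d = 0, t_alpha = 0, t_beta = 0, t_gamma = 0),
           imgQ = img, imgS = img)
  g <- vertexWeights(g)
  expect_equal(g@vertices$w[1], 1.45)
  expect_equal(g@vertices$w[2], 0.61)    # the -0.4 edge is excluded
  expect_equal(g@vertices$w[4], 0.33)
  g2 <- g; g2@edges <- g@edges[0, ]
  expect_equal(vertexWeights(g2)@vertices$w, rep(0, 4))  # isolated vertices
})

test_that("SSE pair scores sum qualifying vertex weights (voting)", {
  cent <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0))
  vec <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  img <- buildADImage(toySSEs(cent, vec))   # points: (1,2) (1,3) (2,3)
  g <- new("PairGraph",
           vertices = data.frame(qi = c(1L, 2L, 3L, 1L),
                                 si = c(1L, 2L, 3L, 2L), s = 1,
                                 w = c(1.45, 1.00, 0.61, 0.61)),
           edges = data.frame(p = integer(), q = integer(),
                              weight = numeric(), t_d = numeric(),
                              t_alpha = numeric(), t_beta = numeric(),
                              t_gamma = numeric()),
           imgQ = img, imgS = img)
  sc <- ssePairScores(g)
  m11 <- sc$mRaw[sc$sseQ == 1 & sc$sseS == 1]
  expect_equal(m11, 1.45 + 1.00 + 0.61)    # rows containing 1_Q and 1_S
  # brute-force oracle over all vertices
  v <- g@vertices; p <- img@points
  brute <- sum(v$w[(p$sse_a[v$qi] == 1 | p$sse_b[v$qi] == 1) &
                   (p$sse_a[v$si] == 1 | p$sse_b[v$si] == 1)])
  expect_equal(m11, brute)
  # identical sizes: g = 1, so weighted equals raw
  expect_equal(sc$mWeighted, sc$mRaw)
})

test_that("size-dissimilar SSE pairs are down-weighted", {
  cent <- rbind(c(0, 0, 0), c(8, 0, 0))
  vec <- rbind(c(0, 0, 1), c(0, 1, 0))
  ssesQ <- toySSEs(cent, vec, L = c(10, 10), n = c(8L, 8L))
  ssesS <- toySSEs(cent, vec, L = c(5, 10), n = c(4L, 8L))
  imgQ <- buildADImage(ssesQ); imgS <- buildADImage(ssesS)
  g <- new("PairGraph",
           vertices = data.frame(qi = 1L, si = 1L, s = 1, w = 2),
           edges = data.frame(p = integer(), q = integer(),
                              weight = numeric(), t_d = numeric(),
                              t_alpha = numeric(), t_beta = numeric(),
                              t_gamma = numeric()),
           imgQ = imgQ, imgS = imgS)
  sc <- ssePairScores(g)
  r11 <- sc[sc$sseQ == 1 & sc$sseS == 1, ]
  expect_equal(r11$mWeighted, r11$mRaw / (1 + 0.5 + 0.5))
})

test_that("greedy matching respects order and one-to-one constraints", {
  scores <- data.frame(sseQ = c(2L, 1L, 3L, 1L),
                       sseS = c(2L, 3L, 3L, 1L),
                       mRaw = c(5, 4, 3, 2), mWeighted = c(5, 4, 3, 2))
  seqm <- matchSSEs(scores, sequential = TRUE)
  # (1,3) crosses the established (2,2); (3,3) reuses SSE 3_S after... it is
  # free; (1,1) fits before (2,2)
  expect_equal(seqm@pairs$sseQ, c(1L, 2L, 3L))
  expect_equal(seqm@pairs$sseS, c(1L, 2L, 3L))
  oim <- matchSSEs(scores, sequential = FALSE)
  expect_true(all(c(2, 1) %in% oim@pairs$sseQ))      # (1,3) now accepted
  expect_equal(anyDuplicated(oim@pairs$sseQ), 0)
  expect_equal(anyDuplicated(oim@pairs$sseS), 0)
})

test_that("identical chains match as the identity over all SSEs", {
  fx <- getFixture(1)
  m <- matchChains(fx$closed, fx$closed)
  e <- nrow(sseVectors(fx$closed))
  expect_equal(m$match@pairs$sseQ, seq_len(e))
  expect_equal(m$match@pairs$sseS, seq_len(e))
})

test_that("matching spans both domains of a closed/open pair", {
  # the central superposition-free claim: SSEs of the rotated (swapped)
  # domain are matched together with the main domain's
  for (seed in c(1, 4)) {
    fx <- getFixture(seed)
    m <- matchChains(fx$closed, fx$open)
    sse <- sseVectors(fx$closed)
    sw <- fx$swapped[1]:fx$swapped[2]
    inSwap <- sse$index[sse$first >= min(sw)]
    inMain <- sse$index[sse$last <= max(fx$pivots)]
    expect_true(all(inSwap %in% m$match@pairs$sseQ))
    expect_true(all(inMain %in% m$match@pairs$sseQ))
  }
})

test_that("matching is symmetric in the two chains", {
  fx <- getFixture(2)
  m1 <- matchChains(fx$closed, fx$open)$match@pairs
  m2 <- matchChains(fx$open, fx$closed)$match@pairs
  expect_equal(m1$sseQ, m2$sseS)
  expect_equal(m1$sseS, m2$sseQ)
})

test_that("sequential matches are strictly monotone on both sides", {
  for (seed in 1:3) {
    fx <- getFixture(seed)
    p <- matchChains(fx$closed, fx$open)$match@pairs
    expect_true(all(diff(p$sseQ) > 0))
    expect_true(all(diff(p$sseS) > 0))
  }
})
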