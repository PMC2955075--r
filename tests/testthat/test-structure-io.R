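test_that("readChain returns residues in order and excludes missing C-alphas", {
  f <- tempfile(fileext = ".pdb")
  rows <- data.frame(resno = 1:100, x = seq(0, 99) * 3.8, y = 0, z = 0)
  writeToyPDB(f, rows)
  ch <- readChain(f, "A")
  expect_s4_class(ch, "ProteinChain")
  expect_equal(chainLength(ch), 100)
  expect_equal(residues(ch)$resno, 1:100)

  # one residue without CA drops out
  f2 <- tempfile(fileext = ".pdb")
  writeToyPDB(f2, rows, skip_ca = 42)
  expect_equal(chainLength(readChain(f2, "A")), 99)
})

test_that("missing chain errors name the available chains", {
  f <- tempfile(fileext = ".pdb")
  writeToyPDB(f, data.frame(resno = 1:5, x = (1:5) * 3.8, y = 0, z = 0))
  expect_error(readChain(f, "B"), "available chains.*A")
  expect_error(readChain(tempfile(), "A"), "not found")
})

test_that("extractSSEs honours records, the 3-residue rule and ordering", {
  f <- tempfile(fileext = ".pdb")
  rows <- data.frame(resno = 1:40, x = (1:40) * 3.8, y = 0, z = 0)
  # records deliberately out of file order; one 2-residue helix to drop
  recs <- data.frame(kind = c("strand", "helix", "helix"),
                     start = c(30, 10, 24), end = c(35, 20, 25))
  writeToyPDB(f, rows, records = recs)
  ch <- readChain(f, "A")
  sse <- extractSSEs(ch)
  expect_equal(nrow(sse), 2)
  expect_equal(sse$kind, c("helix", "strand"))
  expect_equal(sse$start, c(10, 30))
  expect_equal(sse$end, c(20, 35))
  expect_true(all(diff(sse$first) > 0))
})

test_that("empty SSE set comes back as a zero-row table", {
  f <- tempfile(fileext = ".pdb")
  writeToyPDB(f, data.frame(resno = 1:10, x = (1:10) * 3.8, y = 0, z = 0))
  expect_equal(nrow(extractSSEs(readChain(f, "A"))), 0)
})

test_that("vectorizeSegment fits the principal axis with N->C orientation", {
  xyz <- cbind(seq(0, by = 3.5, length.out = 10), 0, 0)
  v <- vectorizeSegment(xyz)
  expect_equal(v$vector, c(1, 0, 0), tolerance = 1e-10)
  expect_equal(v$L, 31.5, tolerance = 1e-8)

  rev_v <- vectorizeSegment(xyz[10:1, ])
  expect_equal(rev_v$vector, c(-1, 0, 0), tolerance = 1e-10)

  # symmetric cloud centred at origin
  sym <- rbind(c(-1, -1, 0), c(1, 1, 0), c(-2, 2, 0), c(2, -2, 0))
  expect_equal(vectorizeSegment(sym)$centroid, c(0, 0, 0))

  expect_error(vectorizeSegment(matrix(1, 5, 3)), "degenerate")
  expect_error(vectorizeSegment(xyz[1:2, ]), "at least 3")
})

test_that("vectorizeSegment is rotation/translation equivariant", {
  withr::with_seed(7, {
    xyz <- matrix(rnorm(30, sd = 5), 10, 3)
    for (k in 1:5) {
      ax <- rnorm(3); th <- runif(1, 0, 360); shift <- rnorm(3, sd = 20)
      R <- rotationMatrix(ax, th)
      v0 <- vectorizeSegment(xyz)
      v1 <- vectorizeSegment(sweep(xyz %*% t(R), 2, shift, "+"))
      expect_equal(as.numeric(R %*% v0$vector), v1$vector, tolerance = 1e-8)
      expect_equal(as.numeric(R %*% v0$centroid) + shift, v1$centroid,
                   tolerance = 1e-8)
      expect_equal(v0$L, v1$L, tolerance = 1e-8)
    }
  })
})

test_that("backbone torsions reproduce the generator's canonical helix", {
  seg <- buildIdealSegment(12, -57, -47)
  res <- data.frame(resno = 1:12, insert = "", aa = "A",
                    x = seg$CA[, 1], y = seg$CA[, 2], z = seg$CA[, 3],
                    nx = seg$N[, 1], ny = seg$N[, 2], nz = seg$N[, 3],
                    cx = seg$C[, 1], cy = seg$C[, 2], cz = seg$C[, 3])
  ch <- newProteinChain("helix", res)
  tor <- backboneTorsions(ch)
  expect_true(is.na(tor$phi[1]))       # N-terminus
  expect_true(is.na(tor$psi[12]))      # C-terminus
  expect_equal(tor$phi[2:12], rep(-57, 11), tolerance = 1e-6)
  expect_equal(tor$psi[1:11], rep(-47, 11), tolerance = 1e-6)
})

test_that("torsions are undefined across a chain break", {
  seg <- buildIdealSegment(10, -57, -47)
  shift <- matrix(rep(c(30, 0, 0), each = 5), 5, 3)   # translate residues 6-10
  res <- data.frame(resno = 1:10, insert = "", aa = "A",
                    x = seg$CA[, 1], y = seg$CA[, 2], z = seg$CA[, 3],
                    nx = seg$N[, 1], ny = seg$N[, 2], nz = seg$N[, 3],
                    cx = seg$C[, 1], cy = seg$C[, 2], cz = seg$C[, 3])
  res[6:10, c("x", "nx", "cx")] <- res[6:10, c("x", "nx", "cx")] + 30
  ch <- newProteinChain("broken", res)
  tor <- backboneTorsions(ch)
  expect_true(is.na(tor$psi[5]))
  expect_true(is.na(tor$phi[6]))
  expect_false(is.na(tor$phi[5]))
  expect_false(is.na(tor$psi[6]))
})

test_that("angle arithmetic wraps periodically", {
  expect_equal(angleDiff(-179, 179), 2)
  expect_equal(angleDiff(10, -10), 20)
  withr::with_seed(3, {
    a <- runif(200, -180, 180); b <- runif(200, -180, 180)
    expect_true(all(angleDiff(a, b) <= 180))
  })
})

test_that("SSE spans never overlap and sum within chain length", {
  for (seed in 1:3) {
    fx <- getFixture(seed)
    sse <- extractSSEs(fx$closed)
    expect_true(all(sse$first[-1] > sse$last[-nrow(sse)]))
    expect_lte(sum(sse$n), chainLength(fx$closed))
  }
})
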