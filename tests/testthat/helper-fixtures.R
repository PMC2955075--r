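# Shared helpers for the adswap test suite.

# Memoized fixture pairs: generating a pair costs ~0.1 s and several test
# files reuse the same seeds.
.fxCache <- new.env(parent = emptyenv())
getFixture <- function(seed = 1, side = "C", ...) {
  key <- paste(seed, side, paste(c(...), collapse = "_"), sep = "|")
  if (is.null(.fxCache[[key]]))
    .fxCache[[key]] <- makeFixturePair(fixtureSpec(swap_side = side,
                                                   seed = seed, ...))
  .fxCache[[key]]
}

.repCache <- new.env(parent = emptyenv())
getReport <- function(seed = 1, side = "C", ...) {
  key <- paste(seed, side, paste(c(...), collapse = "_"), sep = "|")
  if (is.null(.repCache[[key]])) {
    fx <- getFixture(seed, side, ...)
    .repCache[[key]] <- compareChains(fx$closed, fx$open)
  }
  .repCache[[key]]
}

# Independent minimal-RMSD oracle: Horn's closed-form quaternion method
# (largest eigenvalue of the 4x4 form of the cross-covariance), sharing no
# code path with the SVD-based Kabsch implementation.
hornRMSD <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  M <- t(B0) %*% A0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A0^2) + sum(B0^2) - 2 * lambda) / n))
}

# A small handcrafted SSE table in sseVectors() format.
toySSEs <- function(centroids, vectors, L = NULL, n = NULL,
                    first = NULL) {
  k <- nrow(centroids)
  if (is.null(L)) L <- rep(10, k)
  if (is.null(n)) n <- rep(8L, k)
  if (is.null(first)) first <- seq(1L, by = 12L, length.out = k)
  data.frame(index = seq_len(k), kind = "helix",
             start = first, end = first + n - 1L,
             first = first, last = first + n - 1L, n = n, L = L,
             vx = vectors[, 1], vy = vectors[, 2], vz = vectors[, 3],
             cx = centroids[, 1], cy = centroids[, 2], cz = centroids[, 3])
}

# Write a minimal hand-built PDB file; `rows` is a data.frame with resno,
# and x/y/z (CA); records is the HELIX/SHEET span table.
writeToyPDB <- function(path, rows, records = NULL, chain = "A",
                        skip_ca = integer(0)) {
  lines <- character(0)
  if (!is.null(records)) {
    for (i in seq_len(nrow(records))) {
      if (records$kind[i] == "helix")
        lines <- c(lines, sprintf(
          "HELIX  %3d %3d ALA %s %4d  ALA %s %4d  1%36d", i, i, chain,
          records$start[i], chain, records$end[i],
          records$end[i] - records$start[i] + 1))
      else
        lines <- c(lines, sprintf(
          "SHEET  %3d   S 1 ALA %s%4d  ALA %s%4d  0", i, chain,
          records$start[i], chain, records$end[i]))
    }
  }
  serial <- 0L
  for (i in seq_len(nrow(rows))) {
    if (i %in% skip_ca) next
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, chain, rows$resno[i], rows$x[i], rows$y[i], rows$z[i]))
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}
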