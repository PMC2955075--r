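# The angle-distance (A-D) image: one point per unordered SSE pair.
# Because angles and centroid distances are internal coordinates, the image
# is invariant under rigid-body transformation of the chain.

#' Build the A-D image of a chain's SSEs
#'
#' Each unordered pair of SSE vectors becomes one point recording the angle
#' between the vectors (degrees), the Euclidean distance between their
#' centroids (Angstrom), the dihedral the two vectors form about the
#' centroid-connecting axis (folded to \[0, 180\]), and the number of
#' residues strictly between the two spans. The (distance, angle) position
#' is normalized — angle by 180 degrees, distance by \code{d_norm} with
#' clamping at 1 — and assigned to a 10 x 10 block grid.
#'
#' @param sses SSE table from \code{\link{sseVectors}} (>= 2 rows).
#' @param chainId identifier carried into the image.
#' @param config see \code{\link{adswapConfig}}.
#' @return An \linkS4class{ADImage}.
#' @examples
#' fx <- makeFixturePair(fixtureSpec(seed = 1))
#' img <- buildADImage(sseVectors(fx$closed))
#' nrow(img@points)   # E(E-1)/2
#' @export
buildADImage <- function(sses, chainId = "chain", config = adswapConfig()) {
  e <- nrow(sses)
  if (e < 2) stop("too few SSEs: an A-D image needs at least 2")
  V <- as.matrix(sses[, c("vx", "vy", "vz")])
  Cm <- as.matrix(sses[, c("cx", "cy", "cz")])
  idx <- utils::combn(e, 2)
  a <- idx[1, ]; b <- idx[2, ]
  ang <- dist <- dih <- numeric(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    ang[k] <- angleBetween(V[a[k], ], V[b[k], ])
    dist[k] <- vnorm(Cm[a[k], ] - Cm[b[k], ])
    # torsion of (tip of a, centroid a, centroid b, tip of b), folded
    pa <- Cm[a[k], ] + V[a[k], ] * sses$L[a[k]] / 2
    pb <- Cm[b[k], ] + V[b[k], ] * sses$L[b[k]] / 2
    d <- torsionAngle(pa, Cm[a[k], ], Cm[b[k], ], pb)
    dih[k] <- if (is.na(d)) 0 else abs(d)
  }
  sep <- sses$first[b] - sses$last[a] - 1L
  nx <- pmin(dist / config$d_norm, 1)
  ny <- ang / 180
  pts <- data.frame(sse_a = a, sse_b = b, angle = ang, dist = dist,
                    dihedral = dih, chain_sep = sep, nx = nx, ny = ny,
                    bx = pmin(floor(nx * 10), 9),
                    by = pmin(floor(ny * 10), 9),
                    cx = (Cm[a, 1] + Cm[b, 1]) / 2,
                    cy = (Cm[a, 2] + Cm[b, 2]) / 2,
                    cz = (Cm[a, 3] + Cm[b, 3]) / 2)
  new("ADImage", chainId = chainId, points = pts, sses = sses,
      dNorm = config$d_norm)
}

#' Points of another image within a point's block neighborhood
#'
#' Returns the row indices of \code{image}'s points whose 10 x 10 block lies
#' within Chebyshev distance 2 of the query point's block (the block plus
#' its nearest 24 blocks, clipped at the grid edges).
#'
#' @param point one-row slice of an ADImage's point table (or a list with
#'   bx, by).
#' @param image the subject \linkS4class{ADImage}.
#' @return integer vector of point row indices (possibly empty).
#' @export
blockNeighborhood <- function(point, image) {
  p <- image@points
  which(abs(p$bx - point$bx) <= 2 & abs(p$by - point$by) <= 2)
}

#' Write an A-D image as TSV
#'
#' @param image an ADImage.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeADImage <- function(image, path) {
  utils::write.table(image@points[, c("sse_a", "sse_b", "angle", "dist")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
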