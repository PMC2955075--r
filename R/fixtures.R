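# Seeded generator of synthetic closed/open two-domain chains.
#
# Chains are assembled from ideal-geometry secondary structure segments
# (built residue-by-residue from standard bond lengths/angles and canonical
# phi/psi, so backbone torsions are exact) arranged side by side and joined
# by circular-arc loops with ~3.8 A C-alpha steps. The open form is the
# closed form with one domain rigidly rotated about an axis through the
# hinge C-alpha, emulating the hinge-bending motion of domain swapping.

IDEAL <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
              a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
              helix = c(phi = -57, psi = -47),
              strand = c(phi = -120, psi = 130),
              coil = c(phi = -75, psi = 145))

nerfPlace <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- -chi * pi / 180   # right-handed IUPAC torsion
  bc <- unitv(C - B)
  n <- unitv(crossp(B - A, bc))
  m <- crossp(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  C + as.numeric(cbind(bc, m, n) %*% d)
}

#' Build an ideal-geometry backbone segment
#'
#' Constructs n residues of N/CA/C backbone with constant phi/psi (trans
#' peptide), using standard bond lengths and angles. Interior torsions of
#' the result reproduce the requested values exactly.
#'
#' @param n number of residues (>= 2).
#' @param phi,psi backbone torsions in degrees.
#' @return list(N, CA, C): n x 3 coordinate matrices.
#' @export
buildIdealSegment <- function(n, phi, psi) {
  stopifnot(n >= 2)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(IDEAL$b_n_ca, 0, 0)
  a <- IDEAL$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + IDEAL$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in 2:n) {
    N[i, ] <- nerfPlace(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                        IDEAL$b_c_n, IDEAL$a_ca_c_n, psi)
    CA[i, ] <- nerfPlace(CA[i - 1, ], C[i - 1, ], N[i, ],
                         IDEAL$b_n_ca, IDEAL$a_c_n_ca, 180)
    C[i, ] <- nerfPlace(C[i - 1, ], N[i, ], CA[i, ],
                        IDEAL$b_ca_c, IDEAL$a_n_ca_c, phi)
  }
  list(N = N, CA = CA, C = C)
}

# Rotation taking unit vector u onto unit vector w.
alignRotation <- function(u, w) {
  u <- unitv(u); w <- unitv(w)
  d <- sum(u * w)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {                # pick any perpendicular axis
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotationMatrix(crossp(u, ref), 180))
  }
  rotationMatrix(crossp(u, w), acos(d) * 180 / pi)
}

# n interior points joining p to q on a circular arc whose n + 1 chords all
# have length `step`, bulging towards `perp`. The subtended angle solves
# step * sin(Phi/2) / sin(Phi / (2(n+1))) = |q - p|.
arcLoop <- function(p, q, n, step = 3.8, perp = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  D <- vnorm(q - p)
  if ((n + 1) * step < D) stop("loop too short to span ", round(D, 1), " A")
  e1 <- unitv(q - p)
  if (is.null(perp)) {
    ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    perp <- crossp(q - p, ref)
  }
  perp <- unitv(perp - sum(perp * e1) * e1)
  chordFn <- function(phi) step * sin(phi / 2) / sin(phi / (2 * (n + 1))) - D
  phi <- stats::uniroot(chordFn, c(1e-9, 2 * pi - 1e-9), tol = 1e-10)$root
  R <- step / (2 * sin(phi / (2 * (n + 1))))
  ctr <- (p + q) / 2 - sqrt(max(R^2 - (D / 2)^2, 0)) * perp
  nrm <- crossp(e1, perp)
  out <- matrix(NA_real_, n, 3)
  for (sgn in c(1, -1)) {
    for (k in seq_len(n))
      out[k, ] <- ctr + as.numeric(rotationMatrix(nrm, sgn * phi * k / (n + 1) *
                                                  180 / pi) %*% (p - ctr))
    endpt <- ctr + as.numeric(rotationMatrix(nrm, sgn * phi * 180 / pi) %*%
                              (p - ctr))
    if (vnorm(endpt - q) < 1e-6) break
  }
  out
}

#' Specification of a synthetic closed/open fixture pair
#'
#' Defines a two-domain (or three-domain, for middle swaps) chain built
#' from ideal helix/strand segments, the hinge loop(s) joining the domains,
#' the rigid rotation that produces the open form, and the coordinate noise
#' emulating experimental uncertainty.
#'
#' @param swap_side "C", "N" or "middle": which domain is swapped.
#' @param rotation rigid rotation of the swapped domain, degrees.
#' @param noise_sigma per-atom Gaussian coordinate noise, Angstrom.
#' @param seed integer seed; identical spec + seed gives identical
#'   coordinates.
#' @param loop_len residues per intra-domain loop.
#' @param hinge_len residues per inter-domain (hinge) loop.
#' @param spacing lateral spacing of SSE slots, Angstrom.
#' @param gap extra lateral gap between domains, Angstrom.
#' @param layout optional list of domains, each a list of c(kind, len)
#'   pairs (kind: "helix", "strand" or "coil"; coil segments get no SSE
#'   record). Defaults depend on \code{swap_side}.
#' @return list of class "fixtureSpec".
#' @export
fixtureSpec <- function(swap_side = c("C", "N", "middle"), rotation = 120,
                        noise_sigma = 0.3, seed = 1L, loop_len = 4L,
                        hinge_len = 6L, spacing = 6, gap = 10,
                        layout = NULL) {
  swap_side <- match.arg(swap_side)
  if (is.null(layout)) {
    big <- list(list("helix", 9L), list("strand", 6L), list("helix", 9L),
                list("strand", 6L), list("helix", 9L))
    small <- list(list("strand", 6L), list("helix", 9L), list("strand", 6L))
    layout <- switch(swap_side,
      C = list(big, small),
      N = list(small, big),
      middle = list(list(list("helix", 9L), list("strand", 6L),
                         list("helix", 9L)),
                    small,
                    list(list("helix", 9L), list("strand", 6L),
                         list("helix", 9L))))
  }
  structure(list(swap_side = swap_side, rotation = rotation,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 loop_len = as.integer(loop_len),
                 hinge_len = as.integer(hinge_len), spacing = spacing,
                 gap = gap, layout = layout),
            class = "fixtureSpec")
}

# Sequential plan of the chain: one row per segment with residue positions.
layoutPlan <- function(spec) {
  rows <- list()
  pos <- 0L
  slot <- 0L
  ndom <- length(spec$layout)
  for (d in seq_len(ndom)) {
    if (d > 1) {
      rows[[length(rows) + 1]] <- data.frame(
        domain = NA_integer_, type = "hinge", kind = "coil",
        len = spec$hinge_len, first = pos + 1L, last = pos + spec$hinge_len,
        slot = NA_real_, dir = NA_real_)
      pos <- pos + spec$hinge_len
    }
    segs <- spec$layout[[d]]
    for (k in seq_along(segs)) {
      if (k > 1) {
        rows[[length(rows) + 1]] <- data.frame(
          domain = d, type = "loop", kind = "coil", len = spec$loop_len,
          first = pos + 1L, last = pos + spec$loop_len,
          slot = NA_real_, dir = NA_real_)
        pos <- pos + spec$loop_len
      }
      slot <- slot + 1L
      len <- as.integer(segs[[k]][[2]])
      rows[[length(rows) + 1]] <- data.frame(
        domain = d, type = "sse", kind = as.character(segs[[k]][[1]]),
        len = len, first = pos + 1L, last = pos + len,
        slot = slot + (d - 1) * spec$gap / spec$spacing,
        dir = if (slot %% 2 == 1) 1 else -1)
      pos <- pos + len
    }
  }
  plan <- do.call(rbind, rows)
  swapDomain <- switch(spec$swap_side, C = ndom, N = 1L, middle = 2L)
  hingeRows <- which(plan$type == "hinge")
  hingeIdx <- switch(spec$swap_side,
                     C = hingeRows[length(hingeRows)],
                     N = hingeRows[1],
                     middle = hingeRows)
  pivots <- vapply(hingeIdx, function(i)
    as.integer(floor((plan$first[i] + plan$last[i]) / 2)), integer(1))
  swapped <- switch(spec$swap_side,
    C = c(plan$last[hingeIdx] + 1L, pos),
    N = c(1L, plan$first[hingeIdx] - 1L),
    middle = c(plan$last[hingeIdx[1]] + 1L, plan$first[hingeIdx[2]] - 1L))
  list(plan = plan, n = pos, pivots = pivots, swapped = swapped,
       swapDomain = swapDomain)
}

# Place loop backbone N/C atoms sequentially from the C-alpha trace,
# attached to the preceding/following peptide so no artificial chain break
# (C-N > 2.5 A) appears, and tilted off the bond axis so torsions stay
# defined.
synthesizeLoopAtoms <- function(N, CA, C, idx) {
  n <- nrow(CA)
  for (i in sort(idx)) {
    uPrev <- if (i > 1) CA[i, ] - CA[i - 1, ] else CA[i + 1, ] - CA[i, ]
    ref <- if (abs(unitv(uPrev)[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    perp <- unitv(crossp(uPrev, ref))
    if (i > 1 && !anyNA(C[i - 1, ])) {
      N[i, ] <- C[i - 1, ] +
        IDEAL$b_c_n * unitv(unitv(CA[i, ] - C[i - 1, ]) + 0.25 * perp)
    } else {
      N[i, ] <- CA[i, ] - IDEAL$b_n_ca * unitv(unitv(uPrev) + 0.3 * perp)
    }
    if (i < n && !anyNA(N[i + 1, ])) {
      C[i, ] <- N[i + 1, ] -
        IDEAL$b_c_n * unitv(unitv(N[i + 1, ] - CA[i, ]) + 0.25 * perp)
    } else if (i < n) {
      C[i, ] <- CA[i, ] + IDEAL$b_ca_c * unitv(unitv(CA[i + 1, ] - CA[i, ]) +
                                               0.3 * perp)
    } else {
      C[i, ] <- CA[i, ] + IDEAL$b_ca_c * unitv(unitv(uPrev) + 0.3 * perp)
    }
  }
  list(N = N, CA = CA, C = C)
}

#' Build the closed form of a synthetic fixture
#'
#' Noise-free ideal geometry; add noise with \code{\link{perturbChain}} or
#' use \code{\link{makeFixturePair}}.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return A \linkS4class{ProteinChain} with consistent HELIX/SHEET spans.
#' @export
makeClosedForm <- function(spec) {
  lp <- layoutPlan(spec)
  plan <- lp$plan
  n <- lp$n
  N <- CA <- C <- matrix(NA_real_, n, 3)
  sseRows <- which(plan$type == "sse")
  for (i in sseRows) {
    seg <- buildIdealSegment(plan$len[i], IDEAL[[plan$kind[i]]]["phi"],
                             IDEAL[[plan$kind[i]]]["psi"])
    v <- seg$CA[plan$len[i], ] - seg$CA[1, ]
    R <- alignRotation(v, c(0, 0, plan$dir[i]))
    ctr <- colMeans(seg$CA)
    target <- c((plan$slot[i] - 1) * spec$spacing, 0, 0)
    for (m in c("N", "CA", "C"))
      seg[[m]] <- sweep(sweep(seg[[m]], 2, ctr) %*% t(R), 2, target, "+")
    rng <- plan$first[i]:plan$last[i]
    N[rng, ] <- seg$N; CA[rng, ] <- seg$CA; C[rng, ] <- seg$C
  }
  loopRows <- which(plan$type %in% c("loop", "hinge"))
  for (i in loopRows) {
    p <- CA[plan$first[i] - 1L, ]
    q <- CA[plan$last[i] + 1L, ]
    CA[plan$first[i]:plan$last[i], ] <-
      arcLoop(p, q, plan$len[i], perp = c(0, 1, 0))
  }
  loopIdx <- unlist(lapply(loopRows, function(i) plan$first[i]:plan$last[i]))
  atoms <- synthesizeLoopAtoms(N, CA, C, loopIdx)
  sse <- plan[plan$type == "sse" & plan$kind != "coil", , drop = FALSE]
  res <- data.frame(resno = seq_len(n), insert = "", aa = "A",
                    x = atoms$CA[, 1], y = atoms$CA[, 2], z = atoms$CA[, 3],
                    nx = atoms$N[, 1], ny = atoms$N[, 2], nz = atoms$N[, 3],
                    cx = atoms$C[, 1], cy = atoms$C[, 2], cz = atoms$C[, 3])
  newProteinChain("closed_A", res,
                  data.frame(kind = sse$kind, start = sse$first,
                             end = sse$last))
}

# Residue positions of the swapped domain plus its hinge side(s).
swappedPositions <- function(lp) lp$swapped[1]:lp$swapped[2]

# Axis through the hinge pivot(s), perpendicular to both the swapped
# domain's principal axis and its displacement from the pivot, so the
# planted rotation is fully expressed in the domain's representative
# vectors.
swapAxis <- function(ca, lp) {
  sw <- swappedPositions(lp)
  if (length(lp$pivots) == 2) {
    ax <- ca[lp$pivots[2], ] - ca[lp$pivots[1], ]
    return(unitv(ax))
  }
  pivot <- ca[lp$pivots[1], ]
  w <- colMeans(ca[sw, , drop = FALSE]) - pivot
  v <- svd(sweep(ca[sw, , drop = FALSE], 2, colMeans(ca[sw, , drop = FALSE])),
           nu = 0, nv = 1)$v[, 1]
  ax <- crossp(v, w)
  if (vnorm(ax) < 1e-6) {
    ref <- if (abs(unitv(w)[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    ax <- crossp(w, ref)
  }
  unitv(ax)
}

#' Build the open form from a closed form
#'
#' Residues of the swapped domain (beyond, before, or between the hinge
#' pivots) are rigidly rotated about an axis through the hinge C-alpha(s);
#' Gaussian coordinate noise is then applied. If the rotation brings any
#' two C-alphas closer than 1 A the axis is perturbed and the rotation
#' retried (with a warning).
#'
#' @param closed the closed-form ProteinChain from \code{\link{makeClosedForm}}.
#' @param spec the same \code{\link{fixtureSpec}}.
#' @return A \linkS4class{ProteinChain} (id "open_A").
#' @export
makeOpenForm <- function(closed, spec) {
  lp <- layoutPlan(spec)
  r <- residues(closed)
  ca <- caCoords(closed)
  # everything distal to the pivot moves with the swapped domain, so the
  # chain stays connected at the hinge
  sw <- switch(spec$swap_side,
               C = (lp$pivots[1] + 1L):lp$n,
               N = 1L:(lp$pivots[1] - 1L),
               middle = (lp$pivots[1] + 1L):(lp$pivots[2] - 1L))
  axis <- swapAxis(ca, lp)
  pivot <- ca[lp$pivots[1], ]
  rotate <- function(axis) {
    R <- rotationMatrix(axis, spec$rotation)
    r2 <- r
    for (cols in list(c("x", "y", "z"), c("nx", "ny", "nz"),
                      c("cx", "cy", "cz"))) {
      m <- as.matrix(r[sw, cols])
      r2[sw, cols] <- sweep(sweep(m, 2, pivot) %*% t(R), 2, pivot, "+")
    }
    r2
  }
  r2 <- rotate(axis)
  ca2 <- as.matrix(r2[, c("x", "y", "z")])
  minpair <- function(m) {
    a <- m[sw, , drop = FALSE]; b <- m[-sw, , drop = FALSE]
    min(sqrt(outer(rowSums(a^2), rep(1, nrow(b))) +
             outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)))
  }
  tries <- 0
  while (spec$rotation != 0 && minpair(ca2) < 1 && tries < 6) {
    warning("steric collapse after rotation; regenerating axis")
    axis <- unitv(rotationMatrix(unitv(colMeans(ca[sw, , drop = FALSE]) - pivot),
                                 30) %*% axis)
    r2 <- rotate(axis); ca2 <- as.matrix(r2[, c("x", "y", "z")])
    tries <- tries + 1
  }
  open <- newProteinChain("open_A", r2, closed@sseRecords)
  if (spec$noise_sigma > 0)
    open <- perturbChain(open, spec$noise_sigma, spec$seed + 1L, id = "open_A")
  open
}

#' Perturb every atom of a chain with Gaussian noise
#'
#' @param chain a ProteinChain.
#' @param noise_sigma standard deviation per coordinate, Angstrom.
#' @param seed integer seed (local RNG; global random state untouched).
#' @param id identifier of the perturbed chain.
#' @return A ProteinChain with torsions recomputed.
#' @export
perturbChain <- function(chain, noise_sigma, seed, id = NULL) {
  r <- residues(chain)
  cols <- c("x", "y", "z", "nx", "ny", "nz", "cx", "cy", "cz")
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    for (cl in cols) r[[cl]] <- r[[cl]] + stats::rnorm(nrow(r), 0, noise_sigma)
  })
  newProteinChain(if (is.null(id)) chainId(chain) else id, r,
                  chain@sseRecords)
}

#' Generate a common-structural-homolog control
#'
#' Per-atom Gaussian perturbation with no domain rotation: structurally the
#' same fold in the same conformational state, the negative control that a
#' DS detector must not flag (eta = 0).
#'
#' @inheritParams perturbChain
#' @export
makeCommonHomolog <- function(chain, noise_sigma, seed) {
  stopifnot(noise_sigma < 2)
  perturbChain(chain, noise_sigma, seed, id = "homolog_A")
}

#' Generate a matched closed/open fixture pair with ground truth
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return list: \code{closed}, \code{open} (ProteinChain, independently
#'   perturbed at \code{noise_sigma}), \code{pivots} (planted hinge
#'   residue positions), \code{swapped} (position range of the swapped
#'   domain), \code{rotation}, \code{swap_side}.
#' @examples
#' fx <- makeFixturePair(fixtureSpec(seed = 7))
#' fx$pivots
#' @export
makeFixturePair <- function(spec) {
  lp <- layoutPlan(spec)
  closed0 <- makeClosedForm(spec)
  open <- makeOpenForm(closed0, spec)
  closed <- if (spec$noise_sigma > 0)
    perturbChain(closed0, spec$noise_sigma, spec$seed + 2L, id = "closed_A")
    else closed0
  list(closed = closed, open = open, pivots = lp$pivots,
       swapped = lp$swapped, rotation = spec$rotation,
       swap_side = spec$swap_side)
}

#' Write a chain as a PDB file with HELIX/SHEET records
#'
#' Backbone N/CA/C atoms only; chain identifier "A".
#'
#' @param chain a ProteinChain.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFixturePDB <- function(chain, path) {
  r <- residues(chain)
  sse <- chain@sseRecords
  lines <- character(0)
  hel <- which(sse$kind == "helix")
  for (k in seq_along(hel)) {
    i <- hel[k]
    lines <- c(lines, sprintf(
      "HELIX  %3d %3s ALA A %4d  ALA A %4d  1%36d",
      k, sprintf("%3d", k), sse$start[i], sse$end[i],
      sse$end[i] - sse$start[i] + 1))
  }
  sht <- which(sse$kind == "strand")
  for (k in seq_along(sht)) {
    i <- sht[k]
    lines <- c(lines, sprintf(
      "SHEET  %3d   S 1 ALA A%4d  ALA A%4d  0",
      k, sse$start[i], sse$end[i]))
  }
  serial <- 0L
  aa3 <- c(A = "ALA", G = "GLY", X = "UNK")
  for (i in seq_len(nrow(r))) {
    res3 <- aa3[r$aa[i]]; if (is.na(res3)) res3 <- "ALA"
    emit <- function(name, x, y, z, el) {
      if (anyNA(c(x, y, z))) return(NULL)
      serial <<- serial + 1L
      sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
              serial, paste0(" ", name), res3, r$resno[i], x, y, z, el)
    }
    lines <- c(lines,
               emit("N", r$nx[i], r$ny[i], r$nz[i], "N"),
               emit("CA", r$x[i], r$y[i], r$z[i], "C"),
               emit("C", r$cx[i], r$cy[i], r$cz[i], "C"))
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}
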