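# Reading PDB chains, backbone torsions, SSE extraction and vectorization.

aa321 <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out)] <- "X"
  out
}

#' Construct a ProteinChain from a residue table
#'
#' Low-level constructor shared by the PDB reader and the synthetic
#' generator. Residues are sorted by author numbering (insertion codes
#' lexicographic after the numeric part) and backbone torsions are computed.
#'
#' @param id chain identifier.
#' @param residues data.frame with at least resno, insert, aa, x, y, z;
#'   optionally nx,ny,nz,cx,cy,cz backbone N/C coordinates.
#' @param sseRecords data.frame(kind, start, end) in author numbering.
#' @return A \linkS4class{ProteinChain}.
#' @export
newProteinChain <- function(id, residues,
                            sseRecords = data.frame(kind = character(),
                                                    start = integer(),
                                                    end = integer())) {
  for (col in c("nx", "ny", "nz", "cx", "cy", "cz"))
    if (is.null(residues[[col]])) residues[[col]] <- NA_real_
  if (is.null(residues$insert)) residues$insert <- ""
  if (is.null(residues$aa)) residues$aa <- "X"
  residues <- residues[order(residues$resno, residues$insert), , drop = FALSE]
  rownames(residues) <- NULL
  tor <- computeTorsions(residues)
  residues$phi <- tor$phi
  residues$psi <- tor$psi
  new("ProteinChain", id = id, residues = residues, sseRecords = sseRecords)
}

# phi_i = torsion(C_{i-1}, N_i, CA_i, C_i); psi_i = torsion(N_i, CA_i, C_i,
# N_{i+1}); undefined at termini and across chain breaks (C-N > 2.5 A).
computeTorsions <- function(r) {
  n <- nrow(r)
  phi <- psi <- rep(NA_real_, n)
  if (n < 2) return(list(phi = phi, psi = psi))
  Nm <- as.matrix(r[, c("nx", "ny", "nz")])
  Am <- as.matrix(r[, c("x", "y", "z")])
  Cm <- as.matrix(r[, c("cx", "cy", "cz")])
  linked <- function(i) {              # peptide bond i -> i+1 intact
    if (anyNA(Cm[i, ]) || anyNA(Nm[i + 1, ])) return(FALSE)
    vnorm(Cm[i, ] - Nm[i + 1, ]) <= 2.5
  }
  lk <- vapply(seq_len(n - 1), linked, logical(1))
  for (i in seq_len(n)) {
    if (i > 1 && lk[i - 1] && !anyNA(c(Cm[i - 1, ], Nm[i, ], Am[i, ], Cm[i, ])))
      phi[i] <- torsionAngle(Cm[i - 1, ], Nm[i, ], Am[i, ], Cm[i, ])
    if (i < n && lk[i] && !anyNA(c(Nm[i, ], Am[i, ], Cm[i, ], Nm[i + 1, ])))
      psi[i] <- torsionAngle(Nm[i, ], Am[i, ], Cm[i, ], Nm[i + 1, ])
  }
  list(phi = phi, psi = psi)
}

#' Read one chain from a PDB-format file
#'
#' Parses ATOM records of the requested chain (first model only, waters and
#' hetero residues excluded, alternate locations reduced to ""/"A"),
#' collects HELIX/SHEET records for that chain, and computes backbone
#' torsions. Residues without a C-alpha atom are dropped.
#'
#' @param path PDB file path.
#' @param chain one-letter chain identifier.
#' @return A \linkS4class{ProteinChain}.
#' @examples
#' spec <- fixtureSpec(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeFixturePDB(makeClosedForm(spec), f)
#' ch <- readChain(f, "A")
#' chainLength(ch)
#' @export
readChain <- function(path, chain) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- sort(unique(at$chain))
  if (!chain %in% chains)
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain & at$alt %in% c("", NA, "A"), , drop = FALSE]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  key <- paste(at$resno, ins, sep = "|")
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
  if (nrow(ca) == 0) stop("chain '", chain, "' has no C-alpha atoms")
  kca <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert), sep = "|")
  pick <- function(elety, col) {
    sub <- at[at$elety == elety, , drop = FALSE]
    ksub <- paste(sub$resno, ifelse(is.na(sub$insert), "", sub$insert), sep = "|")
    sub[[col]][match(kca, ksub)]
  }
  res <- data.frame(
    resno = ca$resno,
    insert = ifelse(is.na(ca$insert), "", ca$insert),
    aa = aa321(ca$resid),
    x = ca$x, y = ca$y, z = ca$z,
    nx = pick("N", "x"), ny = pick("N", "y"), nz = pick("N", "z"),
    cx = pick("C", "x"), cy = pick("C", "y"), cz = pick("C", "z"),
    stringsAsFactors = FALSE)
  sse <- data.frame(kind = character(), start = integer(), end = integer())
  hx <- pdb$helix
  if (!is.null(hx) && length(hx$start)) {
    sel <- hx$chain == chain
    if (any(sel))
      sse <- rbind(sse, data.frame(kind = "helix",
                                   start = as.integer(hx$start[sel]),
                                   end = as.integer(hx$end[sel])))
  }
  sh <- pdb$sheet
  if (!is.null(sh) && length(sh$start)) {
    sel <- sh$chain == chain
    if (any(sel))
      sse <- rbind(sse, data.frame(kind = "strand",
                                   start = as.integer(sh$start[sel]),
                                   end = as.integer(sh$end[sel])))
  }
  id <- paste(sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path)), chain, sep = "_")
  newProteinChain(id, res, sse)
}

#' Extract usable SSE spans of a chain
#'
#' Returns the helix/strand spans from the chain's HELIX/SHEET records,
#' clipped to residues present in the chain, sequence-ordered, and with
#' segments shorter than \code{min_len} residues dropped (short segments
#' carry no stable direction). A C-alpha geometry fallback
#' (\code{source = "geometry"}) assigns helices and strands from
#' characteristic i/i+3 and i/i+2 C-alpha distances for record-less files.
#'
#' @param chain a ProteinChain.
#' @param source "records" (default) or "geometry".
#' @param min_len minimum residues per SSE.
#' @return data.frame(kind, start, end, first, last, n): author-numbering
#'   span plus 1-based residue positions. Zero rows when no SSE is found.
#' @export
extractSSEs <- function(chain, source = c("records", "geometry"),
                        min_len = 3L) {
  source <- match.arg(source)
  r <- residues(chain)
  if (source == "records") {
    sse <- chain@sseRecords
  } else {
    sse <- geometrySSEs(r)
  }
  if (nrow(sse) == 0)
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      first = integer(), last = integer(), n = integer()))
  pos <- function(resno, side) {
    # first/last residue position with resno inside the span
    if (side == "first") match(TRUE, r$resno >= resno)
    else length(r$resno) + 1L - match(TRUE, rev(r$resno <= resno))
  }
  first <- vapply(sse$start, pos, integer(1), side = "first")
  last <- vapply(sse$end, pos, integer(1), side = "last")
  ok <- !is.na(first) & !is.na(last) & last >= first
  sse <- sse[ok, , drop = FALSE]; first <- first[ok]; last <- last[ok]
  n <- last - first + 1L
  keep <- n >= min_len
  out <- data.frame(kind = sse$kind, start = sse$start, end = sse$end,
                    first = first, last = last, n = n)[keep, , drop = FALSE]
  out <- out[order(out$first), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Minimal C-alpha-geometry SSE heuristic: helices have d(i,i+3) ~ 5 A,
# strands d(i,i+2) ~ 6.7 A. Used only for files without HELIX/SHEET records.
geometrySSEs <- function(r) {
  xyz <- as.matrix(r[, c("x", "y", "z")])
  n <- nrow(xyz)
  lab <- rep("coil", n)
  if (n >= 5) {
    d3 <- sqrt(rowSums((xyz[1:(n - 3), , drop = FALSE] -
                        xyz[4:n, , drop = FALSE])^2))
    d2 <- sqrt(rowSums((xyz[1:(n - 2), , drop = FALSE] -
                        xyz[3:n, , drop = FALSE])^2))
    for (i in seq_len(n - 3)) if (d3[i] > 4.2 && d3[i] < 6.0) lab[i:(i + 3)] <- "helix"
    for (i in seq_len(n - 2)) if (lab[i] == "coil" && d2[i] > 6.2 && d2[i] < 7.3)
      lab[i:(i + 2)] <- "strand"
  }
  rl <- rle(lab)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values != "coil"
  data.frame(kind = rl$values[keep],
             start = r$resno[starts[keep]], end = r$resno[ends[keep]])
}

#' Vectorize one SSE segment
#'
#' Fits the least-squares 3D line through the C-alpha coordinates (principal
#' axis of the point cloud), orients it N-terminus to C-terminus, and
#' measures the segment length as the distance between the projections of
#' the first and last C-alpha onto the line.
#'
#' @param xyz n x 3 C-alpha coordinate matrix (n >= 3) in sequence order.
#' @return list(vector = unit direction, centroid, L = length in Angstrom).
#' @examples
#' xyz <- cbind(seq(0, 31.5, by = 3.5), 0, 0)
#' vectorizeSegment(xyz)$L
#' @export
vectorizeSegment <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("need at least 3 coordinates to vectorize an SSE")
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  if (max(abs(X)) < 1e-9) stop("degenerate SSE: all points identical")
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  span <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(v * span) < 0) v <- -v          # N -> C orientation
  proj <- X %*% v
  list(vector = as.numeric(v), centroid = as.numeric(ctr),
       L = as.numeric(proj[nrow(xyz)] - proj[1]))
}

#' Vectorized SSEs of a chain
#'
#' @param chain a ProteinChain.
#' @param sse optional SSE span table from \code{\link{extractSSEs}};
#'   extracted from records when missing.
#' @param ... passed to \code{\link{extractSSEs}}.
#' @return data.frame: index, kind, start, end, first, last, n, L,
#'   vx,vy,vz (unit N->C direction), cx,cy,cz (centroid).
#' @export
sseVectors <- function(chain, sse = NULL, ...) {
  if (is.null(sse)) sse <- extractSSEs(chain, ...)
  xyz <- caCoords(chain)
  if (nrow(sse) == 0)
    return(data.frame(index = integer(), kind = character(),
                      start = integer(), end = integer(), first = integer(),
                      last = integer(), n = integer(), L = numeric(),
                      vx = numeric(), vy = numeric(), vz = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric()))
  vecs <- lapply(seq_len(nrow(sse)), function(k)
    vectorizeSegment(xyz[sse$first[k]:sse$last[k], , drop = FALSE]))
  data.frame(index = seq_len(nrow(sse)), kind = sse$kind,
             start = sse$start, end = sse$end,
             first = sse$first, last = sse$last, n = sse$n,
             L = vapply(vecs, `[[`, numeric(1), "L"),
             vx = vapply(vecs, function(v) v$vector[1], numeric(1)),
             vy = vapply(vecs, function(v) v$vector[2], numeric(1)),
             vz = vapply(vecs, function(v) v$vector[3], numeric(1)),
             cx = vapply(vecs, function(v) v$centroid[1], numeric(1)),
             cy = vapply(vecs, function(v) v$centroid[2], numeric(1)),
             cz = vapply(vecs, function(v) v$centroid[3], numeric(1)))
}

#' Backbone torsions of a chain
#'
#' @param chain a ProteinChain.
#' @return data.frame(resno, insert, phi, psi) in degrees, NA where
#'   undefined (termini, chain breaks, missing backbone atoms).
#' @export
backboneTorsions <- function(chain) {
  r <- residues(chain)
  data.frame(resno = r$resno, insert = r$insert, phi = r$phi, psi = r$psi)
}
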