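# Superposition-dependent residue alignment: Kabsch superposition, a
# sequence-monotone dynamic program over post-superposition C-alpha
# distances, and iterative refinement until the RMSD stabilizes. Because
# equivalent pairs beyond the distance cutoff are eliminated, the aligner
# converges onto one rigid unit — in a closed/open pair, normally the
# larger (main) domain.

#' Kabsch superposition of paired coordinates
#'
#' Least-squares optimal proper rotation (det = +1) and translation taking
#' \code{coords_b} onto \code{coords_a}, by singular value decomposition of
#' the cross-covariance matrix.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (n >= 3).
#' @return list(R, t, rmsd): the transform \code{x R^T + t} applied to rows
#'   of \code{coords_b}, and the post-superposition RMSD in Angstrom.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' kabschSuperpose(a, a)$rmsd
#' @export
kabschSuperpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B))) stop("coordinate sets must have equal size")
  if (nrow(A) < 3) stop("need at least 3 paired coordinates")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ca - as.numeric(R %*% cb)
  Bt <- sweep(B %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((A - Bt)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

# Sequence-monotone DP maximizing the number of residue pairs with
# post-superposition distance below the cutoff, with a small linear gap
# cost to keep alignments compact and a tiny distance bonus so equal-count
# registers resolve towards the closer pairs. Returns strictly increasing
# pair lists.
dpAlign <- function(D, cutoff, gap = 0.1) {
  n <- nrow(D); m <- ncol(D)
  S <- ifelse(D < cutoff, 1 + 0.01 * (1 - D / cutoff), -1e6)
  H <- matrix(0, n + 1, m + 1)
  H[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) {
    H[i + 1, 1] <- H[i, 1] - gap
    cand <- pmax(H[i, 1:m] + S[i, ], H[i, 2:(m + 1)] - gap)
    # left moves cost `gap` per skipped column: prefix running max
    adj <- cand + gap * seq_len(m)
    H[i + 1, 2:(m + 1)] <- cummax(pmax(adj, H[i + 1, 1])) - gap * seq_len(m)
  }
  # traceback
  i <- n; j <- m
  iQ <- integer(0); iS <- integer(0)
  repeat {
    if (i == 0 || j == 0) break
    h <- H[i + 1, j + 1]
    if (abs(h - (H[i, j] + S[i, j])) < 1e-9) {
      if (S[i, j] > 0) { iQ <- c(i, iQ); iS <- c(j, iS) }
      i <- i - 1; j <- j - 1
    } else if (abs(h - (H[i, j + 1] - gap)) < 1e-9) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(iQ = iQ, iS = iS)
}

newAlignment <- function(iQ, iS, transform, rmsd) {
  new("StructAlignment",
      pairs = data.frame(iQ = as.integer(iQ), iS = as.integer(iS)),
      transform = transform[c("R", "t")], rmsd = rmsd, nE = length(iQ))
}

# Iterate superpose / re-derive pairs / eliminate distant pairs until the
# RMSD stabilizes. `iQ`, `iS` seed the first superposition.
iterateAlignment <- function(xyzQ, xyzS, iQ, iS, config,
                             rowsQ = seq_len(nrow(xyzQ)),
                             rowsS = seq_len(nrow(xyzS))) {
  if (length(iQ) < 3) stop("alignment failed: fewer than 3 seed pairs")
  prev <- Inf
  trans <- kabschSuperpose(xyzQ[iQ, , drop = FALSE],
                           xyzS[iS, , drop = FALSE])
  for (it in seq_len(config$max_iter)) {
    St <- applyTransform(xyzS[rowsS, , drop = FALSE], trans)
    Qm <- xyzQ[rowsQ, , drop = FALSE]
    D <- sqrt(pmax(outer(rowSums(Qm^2), rep(1, nrow(St))) +
                   outer(rep(1, nrow(Qm)), rowSums(St^2)) -
                   2 * Qm %*% t(St), 0))
    dp <- dpAlign(D, config$pair_cutoff, config$gap_penalty)
    if (length(dp$iQ) < 3) stop("alignment failed: no surviving pairs")
    iQ <- rowsQ[dp$iQ]; iS <- rowsS[dp$iS]
    trans <- kabschSuperpose(xyzQ[iQ, , drop = FALSE],
                             xyzS[iS, , drop = FALSE])
    # drop pairs that still exceed the cutoff after re-superposition
    St2 <- applyTransform(xyzS[iS, , drop = FALSE], trans)
    keep <- sqrt(rowSums((xyzQ[iQ, , drop = FALSE] - St2)^2)) <
      config$pair_cutoff
    if (sum(keep) >= 3 && any(!keep)) {
      iQ <- iQ[keep]; iS <- iS[keep]
      trans <- kabschSuperpose(xyzQ[iQ, , drop = FALSE],
                               xyzS[iS, , drop = FALSE])
    }
    if (abs(prev - trans$rmsd) < config$rmsd_tol) break
    prev <- trans$rmsd
  }
  newAlignment(iQ, iS, trans, trans$rmsd)
}

#' Residue alignment seeded by matched SSEs
#'
#' Residues within each matched SSE pair are paired positionally as seed
#' anchors; the seeds are superposed, all residues re-aligned by dynamic
#' programming on post-superposition C-alpha distances, and pairs beyond
#' the distance cutoff eliminated, iterating until the RMSD changes by
#' less than the tolerance. With a closed/open pair this aligns (in
#' general) only the larger, main domain.
#'
#' @param chainQ,chainS ProteinChain objects.
#' @param match an \linkS4class{SSEMatch} (or the list from
#'   \code{\link{matchChains}}).
#' @param config see \code{\link{adswapConfig}}.
#' @return A \linkS4class{StructAlignment} (transform applies to the
#'   subject, chainS).
#' @export
alignWithAnchors <- function(chainQ, chainS, match,
                             config = adswapConfig()) {
  if (is.list(match)) match <- match$match
  pairs <- match@pairs
  if (nrow(pairs) == 0) stop("alignment failed: empty SSE match")
  ssesQ <- sseVectors(chainQ, min_len = config$min_sse_len)
  ssesS <- sseVectors(chainS, min_len = config$min_sse_len)
  anchorPairs <- function(rows) {
    iQ <- iS <- integer(0)
    for (k in rows) {
      aq <- ssesQ[pairs$sseQ[k], ]
      as_ <- ssesS[pairs$sseS[k], ]
      n <- min(aq$n, as_$n)
      off_q <- floor((aq$n - n) / 2)
      off_s <- floor((as_$n - n) / 2)
      iQ <- c(iQ, aq$first + off_q + seq_len(n) - 1L)
      iS <- c(iS, as_$first + off_s + seq_len(n) - 1L)
    }
    list(iQ = iQ, iS = iS)
  }
  # a single seed over all anchors can start from a compromise transform
  # between the two rigid bodies of a closed/open pair; seeding also from
  # the N- and C-side halves of the anchor list lets the iteration settle
  # on the largest rigid unit (the main domain)
  k <- nrow(pairs)
  seeds <- list(seq_len(k))
  if (k >= 2) {
    h <- ceiling(k / 2)
    seeds <- c(seeds, list(seq_len(h), (k - h + 1):k))
  }
  best <- NULL
  for (s in seeds) {
    ap <- anchorPairs(s)
    if (length(ap$iQ) < 3) next
    aln <- tryCatch(
      iterateAlignment(caCoords(chainQ), caCoords(chainS), ap$iQ, ap$iS,
                       config),
      error = function(e) NULL)
    if (is.null(aln)) next
    if (is.null(best) || aln@nE > best@nE ||
        (aln@nE == best@nE && aln@rmsd < best@rmsd))
      best <- aln
  }
  if (is.null(best)) stop("alignment failed: no surviving pairs")
  best
}

#' Rigid alignment of two residue ranges (fragments)
#'
#' Same iterative aligner, seeded by pairing the fragments positionally
#' from the end nearest the hinge, and restricted to the given ranges.
#'
#' @param chainQ,chainS ProteinChain objects.
#' @param rangeQ,rangeS integer vectors of residue positions.
#' @param anchor "start" or "end": which end the positional seed is
#'   anchored at.
#' @param config see \code{\link{adswapConfig}}.
#' @return A \linkS4class{StructAlignment} with pair indices into the full
#'   chains.
#' @export
alignFragments <- function(chainQ, chainS, rangeQ, rangeS,
                           anchor = c("start", "end"),
                           config = adswapConfig()) {
  anchor <- match.arg(anchor)
  n <- min(length(rangeQ), length(rangeS))
  if (n < 3) stop("alignment failed: fragment shorter than 3 residues")
  if (anchor == "start") {
    iQ <- rangeQ[seq_len(n)]; iS <- rangeS[seq_len(n)]
  } else {
    iQ <- rev(rev(rangeQ)[seq_len(n)]); iS <- rev(rev(rangeS)[seq_len(n)])
  }
  iterateAlignment(caCoords(chainQ), caCoords(chainS), iQ, iS, config,
                   rowsQ = rangeQ, rowsS = rangeS)
}

#' Alignment ratio (percent)
#'
#' \code{100 * n_e / ((n_c + n_o) / 2)}: equivalent residue pairs over the
#' mean of the two region sizes.
#'
#' @param nE number of equivalent residue pairs.
#' @param nC,nO sizes (residues) of the closed- and open-form region.
#' @return percentage.
#' @examples
#' alignmentRatio(125.6, 139.4, 139.4)  # 90.1
#' @export
alignmentRatio <- function(nE, nC, nO) 100 * nE / ((nC + nO) / 2)

#' Similarity measures of an alignment
#'
#' Alignment ratio, Q-score and structural diversity (S-div, RMSD divided
#' by the normalized alignment size).
#'
#' @param alignment a \linkS4class{StructAlignment} (or list with nE and
#'   rmsd).
#' @param nC,nO region sizes in residues (closed, open).
#' @param config see \code{\link{adswapConfig}} (Q-score R0).
#' @return list(rmsd, alignment_ratio, q_score, s_div); s_div is NA when
#'   nE = 0.
#' @export
computeMeasures <- function(alignment, nC, nO, config = adswapConfig()) {
  nE <- if (is(alignment, "StructAlignment")) alignment@nE else alignment$nE
  rmsd <- if (is(alignment, "StructAlignment")) alignment@rmsd
          else alignment$rmsd
  if (nE == 0)
    return(list(rmsd = rmsd, alignment_ratio = 0, q_score = 0,
                s_div = NA_real_))
  list(rmsd = rmsd,
       alignment_ratio = alignmentRatio(nE, nC, nO),
       q_score = nE^2 / (nC * nO) / (1 + (rmsd / config$q_r0)^2),
       s_div = rmsd / (nE / min(nC, nO)))
}

#' Virtual similarity measures from two independent superpositions
#'
#' Combines the main-domain and swapped-domain alignments, each under its
#' own optimal transform, into the virtual alignment size, virtual RMSD
#' (pooled over the union of pairs) and the virtual ratio, Q-score and
#' S-div of the whole proteins.
#'
#' @param main_aln,swap_aln \linkS4class{StructAlignment}s over disjoint
#'   residue ranges.
#' @param nC,nO whole-protein sizes (residues).
#' @param config see \code{\link{adswapConfig}}.
#' @return list(v_alignment_size, v_ratio, v_rmsd, v_q_score, v_s_div).
#' @export
virtualCombine <- function(main_aln, swap_aln, nC, nO,
                           config = adswapConfig()) {
  if (!is.null(swap_aln)) {
    overlap <- intersect(main_aln@pairs$iQ, swap_aln@pairs$iQ)
    if (length(overlap))
      stop("main and swapped alignments overlap at ",
           length(overlap), " residue(s)")
  }
  nM <- main_aln@nE
  nS <- if (is.null(swap_aln)) 0 else swap_aln@nE
  vN <- nM + nS
  vr <- if (is.null(swap_aln)) main_aln@rmsd else
    sqrt((main_aln@rmsd^2 * nM + swap_aln@rmsd^2 * nS) / vN)
  list(v_alignment_size = vN,
       v_ratio = alignmentRatio(vN, nC, nO),
       v_rmsd = vr,
       v_q_score = vN^2 / (nC * nO) / (1 + (vr / config$q_r0)^2),
       v_s_div = if (vN > 0) vr / (vN / min(nC, nO)) else NA_real_)
}
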