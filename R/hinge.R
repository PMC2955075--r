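# Hinge-loop detection: the profile of the angle-distance product over
# matched SSE pairs separates the well-superposed main domains (low values)
# from the matched-but-displaced swapped domains (high values); the
# transition zone localizes the hinge. Opening points are then refined
# against the residue alignment mask, validated by aligning the candidate
# swapped fragments, and the hinge range is determined from backbone
# torsion differences.

#' Angle-distance product of one matched SSE pair
#'
#' \code{P_ad = (theta / theta_u) * (d / d_u)} with theta_u = 180 degrees
#' and d_u = 25 Angstrom: the product of the normalized inter-vector angle
#' and centroid distance of corresponding SSEs after superposition.
#' Unbounded above (d may exceed d_u).
#'
#' @param theta angle between the matched SSE vectors, degrees.
#' @param d distance between their centroids, Angstrom.
#' @param config see \code{\link{adswapConfig}}.
#' @return numeric P_ad >= 0.
#' @export
adProduct <- function(theta, d, config = adswapConfig()) {
  (theta / config$theta_u) * (d / config$d_u)
}

#' Profile of the A-D product over matched SSE pairs
#'
#' Applies the main-domain transform to the subject SSE vectors and
#' centroids and computes one P_ad entry per matched SSE pair, in query
#' sequence order.
#'
#' @param matchres list from \code{\link{matchChains}}.
#' @param alignment the rigid \linkS4class{StructAlignment} whose transform
#'   superposes the two chains.
#' @param config see \code{\link{adswapConfig}}.
#' @return data.frame(sseQ, sseS, theta, dist, p_ad).
#' @export
adProfile <- function(matchres, alignment, config = adswapConfig()) {
  pairs <- matchres$match@pairs
  sq <- matchres$ssesQ
  ss <- matchres$ssesS
  R <- alignment@transform$R
  t <- alignment@transform$t
  out <- data.frame(sseQ = pairs$sseQ, sseS = pairs$sseS,
                    theta = NA_real_, dist = NA_real_, p_ad = NA_real_)
  for (k in seq_len(nrow(pairs))) {
    q <- sq[pairs$sseQ[k], ]
    s <- ss[pairs$sseS[k], ]
    vS <- as.numeric(R %*% c(s$vx, s$vy, s$vz))
    cS <- as.numeric(R %*% c(s$cx, s$cy, s$cz)) + t
    out$theta[k] <- angleBetween(c(q$vx, q$vy, q$vz), vS)
    out$dist[k] <- vnorm(c(q$cx, q$cy, q$cz) - cS)
    out$p_ad[k] <- adProduct(out$theta[k], out$dist[k], config)
  }
  out[order(out$sseQ), , drop = FALSE]
}

rollEdge <- function(x, f) {
  n <- length(x)
  xp <- c(x[1], x, x[n])
  vapply(seq_len(n), function(i) f(xp[i:(i + 2)]), numeric(1))
}

#' Morphological smoothing of a 1-D profile
#'
#' Grayscale opening (erosion then dilation) followed by closing (dilation
#' then erosion) with a flat width-3 structuring element, edges replicated.
#' Removes isolated single-point peaks and valleys while preserving
#' plateaus of length >= 3.
#'
#' @param entries numeric profile.
#' @return smoothed profile of the same length; returned unchanged (with a
#'   warning) when shorter than 3.
#' @examples
#' smoothProfile(c(1, 1, 9, 1, 1))
#' @export
smoothProfile <- function(entries) {
  if (length(entries) < 3) {
    warning("profile shorter than 3: returned unchanged")
    return(entries)
  }
  op <- rollEdge(rollEdge(entries, min), max)     # opening
  rollEdge(rollEdge(op, max), min)                # closing
}

#' Significant transitions in a smoothed profile
#'
#' The absolute differences between adjacent profile points are tested
#' against the upper bound of the two-sided 80 percent confidence interval
#' of their mean (Student t, df = n - 1); differences above the bound are
#' significant transitions.
#'
#' @param smoothed smoothed profile (>= 2 points).
#' @param config see \code{\link{adswapConfig}} (confidence level).
#' @return list(diffs, threshold, significant): the difference sequence,
#'   the t-threshold, and indices k such that |p_(k+1) - p_k| exceeds it.
#' @examples
#' p <- c(rep(1.10, 4), rep(4.50, 3), rep(4.37, 3))
#' detectTransitions(p)$threshold   # 0.92
#' @export
detectTransitions <- function(smoothed, config = adswapConfig()) {
  d <- abs(diff(smoothed))
  n <- length(d)
  if (n < 2 || stats::sd(d) < 1e-12)
    return(list(diffs = d, threshold = NA_real_, significant = integer()))
  alpha <- 1 - config$conf
  thr <- mean(d) + stats::qt(1 - alpha / 2, n - 1) * stats::sd(d) / sqrt(n)
  list(diffs = d, threshold = thr, significant = which(d > thr))
}

#' Classify the domain-swapping type from the profile
#'
#' The contiguous high-valued region of the smoothed profile (above the
#' midpoint of its range) marks the candidate swapped domain: at the
#' N-terminal end, the C-terminal end, or in the interior. Profiles with no
#' significant transition are "none" (the small-swapped-domain path).
#'
#' @param smoothed smoothed profile.
#' @param transitions result of \code{\link{detectTransitions}}.
#' @return list(type = "N"|"C"|"middle"|"none", high = index range of the
#'   high region or NULL, boundaries = transition indices flanking it).
#' @export
classifyDSType <- function(smoothed, transitions) {
  none <- list(type = "none", high = NULL, boundaries = integer())
  if (!length(transitions$significant)) return(none)
  n <- length(smoothed)
  mid <- (max(smoothed) + min(smoothed)) / 2
  high <- smoothed > mid
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  if (!length(hi)) return(none)
  hi <- hi[which.max(r$lengths[hi])]          # largest high region
  h1 <- starts[hi]; h2 <- ends[hi]
  if (h1 == 1 && h2 == n) return(none)
  type <- if (h1 == 1) "N" else if (h2 == n) "C" else "middle"
  bnd <- c(if (h1 > 1) h1 - 1L, if (h2 < n) h2)
  list(type = type, high = c(h1, h2), boundaries = as.integer(bnd))
}

#' Approximate opening point of a candidate hinge loop
#'
#' With the candidate hinge located between two consecutive matched SSEs
#' (SSE_N and SSE_C), the opening point is the first residue of SSE_C for
#' an N-terminal swap and the last residue of SSE_N for a C-terminal swap;
#' a middle swap combines both rules for its two hinge loops.
#'
#' @param ds_type "N", "C" or "middle".
#' @param profile the \code{\link{adProfile}} table.
#' @param boundaries transition indices from \code{\link{classifyDSType}}.
#' @param sses the chain's SSE table; \code{side} selects which protein.
#' @param side "Q" or "S".
#' @return integer vector of opening points (residue positions): length 1,
#'   or 2 (N-side, C-side) for middle swaps.
#' @export
initialOpeningPoint <- function(ds_type, profile, boundaries, sses,
                                side = c("Q", "S")) {
  side <- match.arg(side)
  col <- if (side == "Q") "sseQ" else "sseS"
  sseAt <- function(k) profile[[col]][k]
  firstRes <- function(sse) sses$first[sse]
  lastRes <- function(sse) sses$last[sse]
  if (ds_type == "N") {
    b <- boundaries[1]
    return(firstRes(sseAt(b + 1L)))          # first residue of SSE_C
  }
  if (ds_type == "C") {
    b <- boundaries[length(boundaries)]
    return(lastRes(sseAt(b)))                # last residue of SSE_N
  }
  if (ds_type == "middle") {
    bN <- boundaries[1]; bC <- boundaries[2]
    return(c(lastRes(sseAt(bN)), firstRes(sseAt(bC + 1L))))
  }
  stop("no opening point for ds_type 'none'")
}

#' Propose a small swapped domain in a flat profile
#'
#' When the profile shows no significant transition, an unaligned terminal
#' region before the first (or after the last) aligned SSE pair is proposed
#' as an N-/C-terminal swapped-domain candidate; an interior unaligned
#' fragment is proposed as a middle candidate with two opening points at
#' the bifurcation edges.
#'
#' @param aligned logical mask over the chain's residues (TRUE = aligned by
#'   the rigid alignment).
#' @param sses SSE table of the chain.
#' @param profile the \code{\link{adProfile}} table.
#' @param side "Q" or "S".
#' @param min_len minimum residues for a candidate fragment.
#' @return list(type, o) or NULL when no unaligned region qualifies.
#' @export
assignSmallSwappedDomain <- function(aligned, sses, profile,
                                     side = c("Q", "S"), min_len = 3L) {
  side <- match.arg(side)
  col <- if (side == "Q") "sseQ" else "sseS"
  alignedSSEs <- profile[[col]]
  if (!length(alignedSSEs)) return(NULL)
  firstA <- sses$first[min(alignedSSEs)]
  lastA <- sses$last[max(alignedSSEs)]
  n <- length(aligned)
  leadRun <- match(TRUE, aligned, nomatch = n + 1L) - 1L
  trailRun <- match(TRUE, rev(aligned), nomatch = n + 1L) - 1L
  if (leadRun >= min_len && leadRun < firstA)
    return(list(type = "N", o = firstA))
  if (trailRun >= min_len && n - trailRun > lastA - 1L)
    return(list(type = "C", o = lastA))
  # interior unaligned fragment: longest run of unaligned residues strictly
  # inside the aligned span
  inner <- seq(firstA, lastA)
  r <- rle(!aligned[inner])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_len)
  if (!length(runs)) return(NULL)
  k <- runs[which.max(r$lengths[runs])]
  list(type = "middle",
       o = c(inner[starts[k]] - 1L, inner[ends[k]] + 1L))
}

#' Refine the opening point of a candidate hinge loop
#'
#' Two-stage scan of the residue alignment mask: peak first (PF) — the
#' probe moves from the initial opening point towards the well-superposed
#' region until more than \code{pf_run} consecutive residues are aligned;
#' bifurcation last (BL) — from that stop point back towards the
#' bifurcation, unaligned residues are counted, and once the count exceeds
#' \code{t_n} the opening point is fixed at the first unaligned residue
#' after the last aligned one (the boundary between the superimposable and
#' non-superimposable regions). A probe that reaches the terminus without
#' exceeding the count rejects the candidate as over-extended.
#'
#' @param o initial opening point (residue position).
#' @param aligned logical alignment mask over the chain's residues.
#' @param toward_peak +1 if the well-superposed region lies C-terminal of
#'   the hinge, -1 if N-terminal.
#' @param config see \code{\link{adswapConfig}}.
#' @return integer o-prime, or NULL when the candidate is rejected.
#' @export
refineOpeningPoint <- function(o, aligned, toward_peak,
                               config = adswapConfig()) {
  n <- length(aligned)
  # PF stage
  p <- max(1L, min(n, o))
  run <- 0L
  repeat {
    if (aligned[p]) run <- run + 1L else run <- 0L
    if (run > config$pf_run) break
    p <- p + toward_peak
    if (p < 1L || p > n) { p <- p - toward_peak; break }
  }
  # BL stage
  nu <- 0L
  lastAligned <- NA_integer_
  firstUnaligned <- NA_integer_
  q <- p
  repeat {
    q <- q - toward_peak
    if (q < 1L || q > n) return(NULL)          # over-extended candidate
    if (aligned[q]) {
      lastAligned <- q
      firstUnaligned <- NA_integer_
    } else {
      nu <- nu + 1L
      if (is.na(firstUnaligned)) firstUnaligned <- q
      if (nu > config$t_n) return(as.integer(firstUnaligned))
    }
  }
}

#' Validate a candidate hinge loop and swapped domain
#'
#' Quick screen: the fraction of the candidate swapped fragment left
#' unaligned by the main-domain superposition must reach \code{t_l}. The
#' two fragments are then rigidly aligned; the candidate is accepted
#' (eta = 1) iff the aligned residues reach half the smaller fragment and
#' the RMSD stays below 4 Angstrom.
#'
#' @param chainQ,chainS the two chains.
#' @param fragQ,fragS integer residue-position ranges of the candidate
#'   swapped fragments.
#' @param alignedQ logical mask of chainQ residues aligned by the
#'   main-domain alignment.
#' @param anchor "start" or "end" (hinge end of the fragments).
#' @param config see \code{\link{adswapConfig}}.
#' @return list(eta = 0/1, swap_aln = StructAlignment or NULL, reason).
#' @export
validateHinge <- function(chainQ, chainS, fragQ, fragS, alignedQ,
                          anchor = "start", config = adswapConfig()) {
  if (length(fragQ) < 3 || length(fragS) < 3)
    return(list(eta = 0, swap_aln = NULL, reason = "fragment too short"))
  unalignedFrac <- mean(!alignedQ[fragQ])
  if (unalignedFrac < config$t_l)
    return(list(eta = 0, swap_aln = NULL,
                reason = "fragment mostly aligned by main superposition"))
  aln <- tryCatch(
    alignFragments(chainQ, chainS, fragQ, fragS, anchor = anchor,
                   config = config),
    error = function(e) NULL)
  if (is.null(aln))
    return(list(eta = 0, swap_aln = NULL, reason = "fragment alignment failed"))
  minFrag <- min(length(fragQ), length(fragS))
  if (aln@nE < config$frag_min_ratio * minFrag)
    return(list(eta = 0, swap_aln = NULL, reason = "alignment ratio too small"))
  if (aln@rmsd >= config$frag_max_rmsd)
    return(list(eta = 0, swap_aln = NULL, reason = "RMSD too large"))
  list(eta = 1, swap_aln = aln, reason = "validated")
}

#' Determine the range of a hinge loop
#'
#' Starting from the refined opening point, the hinge is extended at both
#' ends over aligned residue pairs while the backbone torsion difference
#' (max of the wrapped phi and psi differences) stays at or above
#' \code{theta0 = 25 degrees * n_hl}. Extension at an end stops when two
#' consecutive aligned pairs fall below theta0, when each of the last three
#' included pairs has a C-alpha distance at or below 2.6 Angstrom under the
#' closer superposition, when the residual swapped domain would shrink to
#' 10 residues or fewer, or when torsions become undefined. With
#' \code{config$eisenberg} the fixed-cutoff variant of the original manual
#' procedure is used (no distance or residual-size conditions).
#'
#' @param oprime refined opening point (residue position, this protein).
#' @param pairsAll data.frame(i, j): all equivalent residue pairs (main and
#'   swapped alignments pooled), i = positions in this protein.
#' @param chain,other this protein and its partner.
#' @param transforms list of transforms (applied to \code{other}) whose
#'   minimum pair distance is used for the distance stop condition.
#' @param n_hl number of hinge loops of the swapped domain (1 or 2).
#' @param swapRange residue positions of the candidate swapped domain.
#' @param config see \code{\link{adswapConfig}}.
#' @return list(range = c(lo, hi) residue positions, theta0).
#' @export
determineHingeRange <- function(oprime, pairsAll, chain, other, transforms,
                                n_hl = 1, swapRange = integer(),
                                config = adswapConfig()) {
  theta0 <- if (config$eisenberg) config$eisenberg_theta0
            else config$theta0_base * n_hl
  rQ <- residues(chain)
  rS <- residues(other)
  caQ <- caCoords(chain)
  caS <- caCoords(other)
  partner <- rep(NA_integer_, nrow(rQ))
  partner[pairsAll$i] <- pairsAll$j
  torDiff <- function(i) {
    j <- partner[i]
    if (is.na(j)) return(NA_real_)
    dphi <- angleDiff(rQ$phi[i], rS$phi[j])
    dpsi <- angleDiff(rQ$psi[i], rS$psi[j])
    if (is.na(dphi) && is.na(dpsi)) return(NA_real_)
    max(dphi, dpsi, na.rm = TRUE)
  }
  caDist <- function(i) {
    j <- partner[i]
    if (is.na(j)) return(NA_real_)
    min(vapply(transforms, function(tr)
      vnorm(caQ[i, ] - as.numeric(tr$R %*% caS[j, ] + tr$t)), numeric(1)))
  }
  n <- nrow(rQ)
  alignedPos <- which(!is.na(partner))
  lo <- hi <- oprime
  for (dir in c(-1L, 1L)) {
    below <- 0L
    included <- numeric(0)   # C-alpha distances of included aligned pairs
    i <- oprime
    repeat {
      i <- i + dir
      if (i < 1L || i > n) break
      if (is.na(partner[i])) {
        # unaligned residues adjacent to the opening point belong to the
        # non-superimposable hinge zone; extend through them, but never
        # into an unaligned terminal tail
        if (dir > 0 && !any(alignedPos > i)) break
        if (dir < 0 && !any(alignedPos < i)) break
        if (dir < 0) lo <- i else hi <- i
        next
      }
      td <- torDiff(i)
      if (is.na(td)) break                    # torsions undefined: stop
      if (td < theta0) {
        below <- below + 1L
        if (below >= 2L) break
      } else {
        below <- 0L
        if (dir < 0) lo <- i else hi <- i
        included <- c(included, caDist(i))
        if (!config$eisenberg) {
          k <- length(included)
          if (k >= 3 && all(utils::tail(included, 3) <= config$ca_stop))
            break
          if (length(swapRange) &&
              sum(!swapRange %in% seq(lo, hi)) <= config$min_swap)
            break
        }
      }
    }
  }
  list(range = c(lo, hi), theta0 = theta0)
}
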