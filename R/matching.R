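# Pair-graph SSE matching. Vertices pair A-D points across the two images;
# edges score the geometric compatibility of two pairings; vertex weights
# are voted down to SSE pair scores from which the SSE equivalence is read
# greedily. None of this depends on a structural superposition, which is
# why both domains of a closed/open pair can be matched at once.

# Per-protein geometry between A-D points, indexed [i, u] over points:
# distance between point centers, angles of each point's two SSE vectors
# with the center-connecting axis, and the two cross angles between
# corresponding component vectors.
pointPairGeometry <- function(image) {
  p <- image@points
  s <- image@sses
  P <- nrow(p)
  V <- as.matrix(s[, c("vx", "vy", "vz")])
  ctr <- as.matrix(p[, c("cx", "cy", "cz")])
  D <- as.matrix(stats::dist(ctr))
  a1 <- b1 <- a2 <- b2 <- g1 <- g2 <- matrix(0, P, P)
  for (i in seq_len(P)) for (u in seq_len(P)) {
    if (i == u) next
    ax <- ctr[u, ] - ctr[i, ]
    if (vnorm(ax) < 1e-9) ax <- c(1, 0, 0)
    a1[i, u] <- angleBetween(V[p$sse_a[i], ], ax)
    b1[i, u] <- angleBetween(V[p$sse_b[i], ], ax)
    a2[i, u] <- angleBetween(V[p$sse_a[u], ], ax)
    b2[i, u] <- angleBetween(V[p$sse_b[u], ], ax)
    g1[i, u] <- angleBetween(V[p$sse_a[i], ], V[p$sse_a[u], ])
    g2[i, u] <- angleBetween(V[p$sse_b[i], ], V[p$sse_b[u], ])
  }
  list(D = D, a1 = a1, b1 = b1, a2 = a2, b2 = b2, g1 = g1, g2 = g2)
}

#' Candidate vertices of the pair graph
#'
#' Pairs each query point with the subject points in its 5 x 5 block
#' neighborhood and scores the pairing as
#' \code{S = S_c - (k1 * d + k2 * d_dihedral + k3 * d_chainsep)} where d is
#' the Euclidean distance between the two points in the normalized A-D
#' plane. Only pairings with positive score become vertices.
#'
#' @param imgQ,imgS query and subject \linkS4class{ADImage}s (identical
#'   normalization).
#' @param config see \code{\link{adswapConfig}}.
#' @param prune use the block neighborhood (default); \code{FALSE} scores
#'   all point pairs.
#' @return data.frame(qi, si, s): point row indices and the score.
#' @export
candidateVertices <- function(imgQ, imgS, config = adswapConfig(),
                              prune = TRUE) {
  pq <- imgQ@points
  ps <- imgS@points
  out <- vector("list", nrow(pq))
  for (i in seq_len(nrow(pq))) {
    js <- if (prune) blockNeighborhood(pq[i, ], imgS) else seq_len(nrow(ps))
    if (!length(js)) next
    d <- sqrt((pq$nx[i] - ps$nx[js])^2 + (pq$ny[i] - ps$ny[js])^2)
    ddih <- abs(pq$dihedral[i] - ps$dihedral[js])
    dsep <- abs(pq$chain_sep[i] - ps$chain_sep[js])
    s <- config$s_c - (config$k1 * d + config$k2 * ddih + config$k3 * dsep)
    keep <- s > 0
    if (any(keep))
      out[[i]] <- data.frame(qi = i, si = js[keep], s = s[keep])
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(qi = integer(), si = integer(),
                                      s = numeric())
  rownames(out) <- NULL
  out
}

#' Build and score the pair graph
#'
#' Forms edges between all vertex pairs that share no A-D point on either
#' side (pairs sharing a point on exactly one side are contradictory and
#' rejected; the unordered point representation makes flipped duplicates
#' impossible). Each edge gets the weight
#' \code{exp(-(dbar/d_t)^2) * (t_d + t_alpha + t_beta + t_gamma)} where
#' dbar is the mean of the two intra-protein center distances, t_d is an
#' elastic distance-agreement term and the three angle terms compare the
#' six inter-SSE angles of the two pairings.
#'
#' @inheritParams candidateVertices
#' @param vertices optional precomputed vertex table.
#' @return A \linkS4class{PairGraph} with vertex weights filled.
#' @export
buildPairGraph <- function(imgQ, imgS, config = adswapConfig(),
                           vertices = NULL) {
  if (is.null(vertices)) vertices <- candidateVertices(imgQ, imgS, config)
  vertices$w <- 0
  edges <- data.frame(p = integer(), q = integer(), weight = numeric(),
                      t_d = numeric(), t_alpha = numeric(),
                      t_beta = numeric(), t_gamma = numeric())
  nv <- nrow(vertices)
  if (nv >= 2) {
    gq <- pointPairGeometry(imgQ)
    gs <- pointPairGeometry(imgS)
    cmb <- utils::combn(nv, 2)
    p <- cmb[1, ]; q <- cmb[2, ]
    ok <- vertices$qi[p] != vertices$qi[q] & vertices$si[p] != vertices$si[q]
    p <- p[ok]; q <- q[ok]
    iq <- cbind(vertices$qi[p], vertices$qi[q])
    is <- cbind(vertices$si[p], vertices$si[q])
    dq <- gq$D[iq]; ds <- gs$D[is]
    rad <- pi / 180
    t_d <- 1 - abs(dq - ds) / config$k_dist
    t_a <- 1 - config$k_alpha * rad *
      (abs(gq$a1[iq] - gs$a1[is]) + abs(gq$a2[iq] - gs$a2[is])) / 2
    t_b <- 1 - config$k_beta * rad *
      (abs(gq$b1[iq] - gs$b1[is]) + abs(gq$b2[iq] - gs$b2[is])) / 2
    t_g <- 1 - config$k_gamma * rad *
      (abs(gq$g1[iq] - gs$g1[is]) + abs(gq$g2[iq] - gs$g2[is])) / 2
    w <- exp(-((dq + ds) / 2 / config$d_t)^2) * (t_d + t_a + t_b + t_g)
    edges <- data.frame(p = p, q = q, weight = w, t_d = t_d, t_alpha = t_a,
                        t_beta = t_b, t_gamma = t_g)
  }
  g <- new("PairGraph", vertices = vertices, edges = edges,
           imgQ = imgQ, imgS = imgS)
  vertexWeights(g)
}

#' Fill vertex weights from positive incident edge weights
#'
#' @param graph a \linkS4class{PairGraph}.
#' @return The graph with \code{vertices$w = } sum of positive weights of
#'   incident edges.
#' @export
vertexWeights <- function(graph) {
  v <- graph@vertices
  e <- graph@edges
  w <- rep(0, nrow(v))
  pos <- e$weight > 0
  if (any(pos)) {
    agg <- rowsum(c(e$weight[pos], e$weight[pos]), c(e$p[pos], e$q[pos]))
    w[as.integer(rownames(agg))] <- agg[, 1]
  }
  v$w <- w
  graph@vertices <- v
  graph
}

#' SSE pair matching scores by vertex-weight voting
#'
#' The raw score of SSE pair (a, a') sums the weights of all vertices whose
#' query point contains a and whose subject point contains a'. The weighted
#' score divides by \code{g = 1 + |L_a - L_a'| / max(L) + |n_a - n_a'| /
#' max(n)}, a size-dissimilarity penalty equal to 1 for identically sized
#' SSEs. Zero-score pairs are dropped; the result is sorted by decreasing
#' weighted score.
#'
#' @param graph a \linkS4class{PairGraph} with vertex weights filled.
#' @return data.frame(sseQ, sseS, mRaw, mWeighted).
#' @export
ssePairScores <- function(graph) {
  v <- graph@vertices
  empty <- data.frame(sseQ = integer(), sseS = integer(), mRaw = numeric(),
                      mWeighted = numeric())
  if (nrow(v) == 0) return(empty)
  pq <- graph@imgQ@points
  ps <- graph@imgS@points
  combo <- data.frame(
    sseQ = c(pq$sse_a[v$qi], pq$sse_a[v$qi], pq$sse_b[v$qi], pq$sse_b[v$qi]),
    sseS = c(ps$sse_a[v$si], ps$sse_b[v$si], ps$sse_a[v$si], ps$sse_b[v$si]),
    w = rep(v$w, 4))
  agg <- stats::aggregate(w ~ sseQ + sseS, combo, sum)
  agg <- agg[agg$w > 0, , drop = FALSE]
  if (nrow(agg) == 0) return(empty)
  sq <- graph@imgQ@sses
  ss <- graph@imgS@sses
  La <- sq$L[agg$sseQ]; Lb <- ss$L[agg$sseS]
  na <- sq$n[agg$sseQ]; nb <- ss$n[agg$sseS]
  g <- 1 + abs(La - Lb) / pmax(La, Lb) + abs(na - nb) / pmax(na, nb)
  out <- data.frame(sseQ = agg$sseQ, sseS = agg$sseS, mRaw = agg$w,
                    mWeighted = agg$w / g)
  out <- out[order(-out$mWeighted, out$sseQ + out$sseS, out$sseQ), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy SSE matching from ranked pair scores
#'
#' Walks the descending score list; a candidate pair is accepted iff
#' neither SSE is already used and, in sequential mode, it preserves the
#' sequential order fixed by the already accepted pairs. Ties are broken by
#' smaller index sum, then smaller query index.
#'
#' @param scores data.frame from \code{\link{ssePairScores}}.
#' @param sequential logical; order-dependent matching (default TRUE).
#' @return An \linkS4class{SSEMatch}.
#' @export
matchSSEs <- function(scores, sequential = TRUE) {
  mode <- if (sequential) "sequential" else "order-independent"
  acc <- scores[0, , drop = FALSE]
  for (k in seq_len(nrow(scores))) {
    cand <- scores[k, ]
    if (cand$sseQ %in% acc$sseQ || cand$sseS %in% acc$sseS) next
    if (sequential && nrow(acc) > 0 &&
        any((acc$sseQ - cand$sseQ) * (acc$sseS - cand$sseS) <= 0)) next
    acc <- rbind(acc, cand)
  }
  acc <- acc[order(acc$sseQ), , drop = FALSE]
  rownames(acc) <- NULL
  new("SSEMatch", pairs = acc, mode = mode)
}

#' Match the SSEs of two chains end to end
#'
#' Convenience wrapper: A-D images, pair graph, voting and greedy matching.
#'
#' @param chainQ,chainS ProteinChain objects.
#' @param config see \code{\link{adswapConfig}}.
#' @return list(match, graph, imgQ, imgS, ssesQ, ssesS).
#' @export
matchChains <- function(chainQ, chainS, config = adswapConfig()) {
  ssesQ <- sseVectors(chainQ, min_len = config$min_sse_len)
  ssesS <- sseVectors(chainS, min_len = config$min_sse_len)
  if (nrow(ssesQ) < 2 || nrow(ssesS) < 2)
    stop("too few SSEs for matching (need >= 2 per chain)")
  imgQ <- buildADImage(ssesQ, chainId(chainQ), config)
  imgS <- buildADImage(ssesS, chainId(chainS), config)
  graph <- buildPairGraph(imgQ, imgS, config)
  scores <- ssePairScores(graph)
  match <- matchSSEs(scores, sequential = config$sequential)
  list(match = match, graph = graph, scores = scores,
       imgQ = imgQ, imgS = imgS, ssesQ = ssesQ, ssesS = ssesS)
}

#' Write an SSE match as TSV
#'
#' @param match an SSEMatch.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMatch <- function(match, path) {
  utils::write.table(match@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
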