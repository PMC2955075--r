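#' @import methods
NULL

#' ProteinChain: one chain of a protein structure
#'
#' Holds the residues of a single chain in sequence order (author residue
#' numbering with insertion codes), the C-alpha trace, backbone N/C atoms
#' where present, backbone torsions, and the helix/strand spans taken from
#' the coordinate file's HELIX/SHEET records (or supplied by a generator).
#'
#' @slot id structure+chain identifier, e.g. "2ezm_A".
#' @slot residues data.frame with one row per residue: \code{resno}
#'   (author number), \code{insert} (insertion code, "" if none), \code{aa}
#'   (one-letter code), \code{x,y,z} (C-alpha, Angstrom), \code{nx,ny,nz}
#'   and \code{cx,cy,cz} (backbone N and C, NA when absent), \code{phi,psi}
#'   (degrees in (-180,180], NA at termini/chain breaks).
#' @slot sseRecords data.frame of secondary-structure spans:
#'   \code{kind} ("helix"/"strand"), \code{start}, \code{end} (author resno).
#' @export
setClass("ProteinChain",
  representation(id = "character", residues = "data.frame",
                 sseRecords = "data.frame"))

setValidity("ProteinChain", function(object) {
  r <- object@residues
  need <- c("resno", "insert", "aa", "x", "y", "z")
  if (!all(need %in% names(r))) return("residues lacks required columns")
  if (nrow(r) == 0) return("chain has no residues")
  key <- order(r$resno, r$insert)
  if (!identical(key, seq_len(nrow(r))))
    return("residues must be ordered by author numbering (insertion codes lexicographic)")
  if (anyNA(r$x)) return("all residues must have a C-alpha coordinate")
  TRUE
})

#' @describeIn ProteinChain number of residues in the chain
#' @param x,object a ProteinChain.
#' @export
setGeneric("chainLength", function(x) standardGeneric("chainLength"))

#' @rdname ProteinChain
#' @export
setMethod("chainLength", "ProteinChain", function(x) nrow(x@residues))

#' @describeIn ProteinChain chain identifier
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))

#' @rdname ProteinChain
#' @export
setMethod("chainId", "ProteinChain", function(x) x@id)

#' @describeIn ProteinChain residue table (see slot description)
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname ProteinChain
#' @export
setMethod("residues", "ProteinChain", function(x) x@residues)

#' C-alpha coordinate matrix of a chain
#' @param x a ProteinChain.
#' @return n x 3 matrix of C-alpha coordinates.
#' @export
caCoords <- function(x) {
  stopifnot(is(x, "ProteinChain"))
  as.matrix(x@residues[, c("x", "y", "z")])
}

setMethod("show", "ProteinChain", function(object) {
  cat("ProteinChain", object@id, "with", nrow(object@residues), "residues,",
      nrow(object@sseRecords), "SSE record(s)\n")
})

#' ADImage: the angle-distance image of one chain
#'
#' One point per unordered SSE pair of a chain, recording the inter-vector
#' angle (degrees), the Euclidean distance between SSE centroids (Angstrom),
#' the dihedral formed by the two SSE vectors about the centroid axis, the
#' chain separation in residues, the normalized (distance, angle) position
#' in the unit square and its 10 x 10 block index.
#'
#' @slot chainId character identifier.
#' @slot points data.frame: \code{sse_a}, \code{sse_b} (a < b), \code{angle},
#'   \code{dist}, \code{dihedral}, \code{chain_sep}, \code{nx}, \code{ny}
#'   (normalized coordinates in \[0,1\]), \code{bx}, \code{by} (block indices
#'   0..9), \code{cx,cy,cz} (geometric center of the two SSE centroids).
#' @slot sses data.frame of vectorized SSEs (see \code{\link{sseVectors}}).
#' @slot dNorm distance normalization constant (Angstrom).
#' @export
setClass("ADImage",
  representation(chainId = "character", points = "data.frame",
                 sses = "data.frame", dNorm = "numeric"))

setValidity("ADImage", function(object) {
  p <- object@points
  e <- nrow(object@sses)
  if (nrow(p) != e * (e - 1) / 2) return("point count must be E(E-1)/2")
  if (any(p$angle < 0 | p$angle > 180)) return("angles must lie in [0,180]")
  if (any(p$dist < 0)) return("distances must be non-negative")
  if (any(p$nx < 0 | p$nx > 1 | p$ny < 0 | p$ny > 1))
    return("normalized coordinates must lie in [0,1]^2")
  if (any(p$bx < 0 | p$bx > 9 | p$by < 0 | p$by > 9))
    return("block indices must lie in 0..9")
  TRUE
})

setMethod("show", "ADImage", function(object) {
  cat("ADImage of", object@chainId, "-", nrow(object@sses), "SSEs,",
      nrow(object@points), "points\n")
})

#' PairGraph: scored pairings of A-D points between two images
#'
#' Vertices are candidate pairings of one query point with one subject
#' point; edges score the geometric compatibility of two pairings.
#'
#' @slot vertices data.frame: \code{qi}, \code{si} (row indices into the
#'   point tables of the query/subject images), \code{s} (geometric
#'   similarity score), \code{w} (total vertex weight, filled by
#'   \code{\link{vertexWeights}}).
#' @slot edges data.frame: \code{p}, \code{q} (vertex indices, p < q),
#'   \code{weight} and the component terms \code{t_d,t_alpha,t_beta,t_gamma}.
#' @slot imgQ,imgS the two ADImage objects.
#' @export
setClass("PairGraph",
  representation(vertices = "data.frame", edges = "data.frame",
                 imgQ = "ADImage", imgS = "ADImage"))

setMethod("show", "PairGraph", function(object) {
  cat("PairGraph:", nrow(object@vertices), "vertices,",
      nrow(object@edges), "edges\n")
})

#' SSEMatch: an SSE equivalence between two chains
#'
#' @slot pairs data.frame: \code{sseQ}, \code{sseS} (SSE indices),
#'   \code{mRaw}, \code{mWeighted} (matching scores).
#' @slot mode "sequential" or "order-independent".
#' @export
setClass("SSEMatch",
  representation(pairs = "data.frame", mode = "character"))

setValidity("SSEMatch", function(object) {
  p <- object@pairs
  if (anyDuplicated(p$sseQ) || anyDuplicated(p$sseS))
    return("match must be one-to-one")
  if (object@mode == "sequential" && nrow(p) > 1) {
    o <- order(p$sseQ)
    if (any(diff(p$sseS[o]) <= 0))
      return("sequential match must be strictly increasing on both sides")
  }
  TRUE
})

setMethod("show", "SSEMatch", function(object) {
  cat("SSEMatch (", object@mode, "): ", nrow(object@pairs),
      " SSE pair(s)\n", sep = "")
})

#' StructAlignment: a superposition-dependent residue alignment
#'
#' @slot pairs data.frame: \code{iQ}, \code{iS} (1-based residue positions
#'   in the two chains, strictly increasing in both).
#' @slot transform list(R = 3x3 rotation, t = translation) applied to the
#'   subject coordinates.
#' @slot rmsd RMSD (Angstrom) of the aligned C-alpha pairs.
#' @slot nE number of equivalent residue pairs.
#' @export
setClass("StructAlignment",
  representation(pairs = "data.frame", transform = "list",
                 rmsd = "numeric", nE = "numeric"))

setValidity("StructAlignment", function(object) {
  p <- object@pairs
  if (nrow(p) > 1 && (any(diff(p$iQ) <= 0) || any(diff(p$iS) <= 0)))
    return("alignment pairs must be strictly increasing in both sequences")
  if (length(object@rmsd) && !is.na(object@rmsd) && object@rmsd < 0)
    return("rmsd must be non-negative")
  if (object@nE != nrow(p)) return("nE must equal the number of pairs")
  TRUE
})

#' @describeIn StructAlignment the residue pair table
#' @param x a StructAlignment.
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))

#' @rdname StructAlignment
#' @export
setMethod("alignedPairs", "StructAlignment", function(x) x@pairs)

#' @describeIn StructAlignment RMSD of the superposed pairs (Angstrom)
#' @export
setGeneric("alignmentRMSD", function(x) standardGeneric("alignmentRMSD"))

#' @rdname StructAlignment
#' @export
setMethod("alignmentRMSD", "StructAlignment", function(x) x@rmsd)

setMethod("show", "StructAlignment", function(object) {
  cat("StructAlignment:", object@nE, "residue pairs, RMSD",
      round(object@rmsd, 3), "A\n")
})

#' DSModel: trained parameters of the DS score
#'
#' @slot m0,m1,m2 penalty weights of the exponential penalty function.
#' @slot cutoff decision threshold on the DS score, in (0,1).
#' @slot grid list describing the search grid used in training.
#' @slot trainMCC MCC attained on the training set.
#' @export
setClass("DSModel",
  representation(m0 = "numeric", m1 = "numeric", m2 = "numeric",
                 cutoff = "numeric", grid = "list", trainMCC = "numeric"))

setValidity("DSModel", function(object) {
  if (object@cutoff <= 0 || object@cutoff >= 1)
    return("cutoff must lie in (0,1)")
  TRUE
})

setMethod("show", "DSModel", function(object) {
  cat(sprintf("DSModel: m0=%.3g m1=%.3g m2=%.3g cutoff=%.2f (training MCC %.3f)\n",
              object@m0, object@m1, object@m2, object@cutoff,
              ifelse(length(object@trainMCC), object@trainMCC, NA)))
})

#' DSReport: the result of one pairwise DS comparison
#'
#' @slot score DS score in \[0,1\].
#' @slot isDS logical classification at the model cutoff.
#' @slot dsType "N", "C", "middle" or "none".
#' @slot eta 0/1 hinge-existence gate.
#' @slot factors list with gamma_theta, gamma_d, mu_sd, s0.
#' @slot measures list of rigid and virtual similarity measures.
#' @slot hinges list of hinge-loop descriptions (one per protein).
#' @slot profile data.frame: the A-D product profile over matched SSE pairs.
#' @slot match the SSEMatch used.
#' @slot alignments list(main =, swap =) StructAlignment objects (swap may
#'   be NULL).
#' @export
setClass("DSReport",
  representation(score = "numeric", isDS = "logical", dsType = "character",
                 eta = "numeric", factors = "list", measures = "list",
                 hinges = "list", profile = "data.frame", match = "SSEMatch",
                 alignments = "list"))

#' @describeIn DSReport logical DS classification
#' @param x a DSReport.
#' @export
setGeneric("isDS", function(x) standardGeneric("isDS"))

#' @rdname DSReport
#' @export
setMethod("isDS", "DSReport", function(x) x@isDS)

#' @describeIn DSReport detected swap type
#' @export
setGeneric("dsType", function(x) standardGeneric("dsType"))

#' @rdname DSReport
#' @export
setMethod("dsType", "DSReport", function(x) x@dsType)

setMethod("show", "DSReport", function(object) {
  cat("DSReport\n")
  cat("  DS score :", round(object@score, 4),
      if (object@isDS) "(DS)" else "(not DS)", "\n")
  cat("  type     :", object@dsType, " eta:", object@eta, "\n")
  f <- object@factors
  if (length(f))
    cat(sprintf("  factors  : gamma_theta=%.3f gamma_d=%.3f mu_sd=%.3f s0=%.3f\n",
                f$gamma_theta, f$gamma_d, f$mu_sd, f$s0))
  m <- object@measures
  if (!is.null(m$virtual))
    cat(sprintf("  virtual  : size=%d ratio=%.1f%% vRMSD=%.3f vQ=%.3f\n",
                m$virtual$v_alignment_size, m$virtual$v_ratio,
                m$virtual$v_rmsd, m$virtual$v_q_score))
})
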