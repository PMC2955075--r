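# The DS score: DS = eta * S0 * f_p, where S0 is the virtual Q-score,
# f_p = exp(-(m0 (1 - gamma_theta) + m1 (1 - gamma_d) + m2 mu_sd)) is an
# exponential penalty that suppresses common structural homologs (small
# swap signature) while leaving clear swaps unpenalized, and eta gates on
# the existence of a validated hinge loop.

#' Angular difference factor of the swapped domains
#'
#' With the structures superposed by their main domains, each swapped
#' domain (hinge excluded) is reduced to a representative vector by two
#' methods: (1) the least-squares line fit of its C-alpha cloud, oriented
#' N to C; (2) the vector from the refined opening point to the geometric
#' center of the central and terminal residues. The two inter-form angles
#' theta_x, theta_y are averaged and normalized by 180 degrees.
#'
#' @param chainQ,chainS the two chains.
#' @param swapQ,swapS residue-position ranges of the swapped domains
#'   (hinge loops excluded).
#' @param oQ,oS refined opening points.
#' @param transform main-domain transform (applied to chainS).
#' @return gamma_theta in \[0, 1\].
#' @export
gammaTheta <- function(chainQ, chainS, swapQ, swapS, oQ, oS, transform) {
  caQ <- caCoords(chainQ)
  caS <- applyTransform(caCoords(chainS), transform)
  lineVec <- function(ca, rng) {
    if (length(rng) < 3) return(NULL)
    tryCatch(unitv(vectorizeSegment(ca[rng, , drop = FALSE])$vector),
             error = function(e) NULL)
  }
  termVec <- function(ca, rng, o) {
    centralRes <- rng[ceiling(length(rng) / 2)]
    # terminal residue: the end of the domain farther from the hinge
    termRes <- if (abs(rng[1] - o) > abs(rng[length(rng)] - o))
      rng[1] else rng[length(rng)]
    c0 <- (ca[centralRes, ] + ca[termRes, ]) / 2
    v <- c0 - ca[o, ]
    if (vnorm(v) < 1e-9) NULL else unitv(v)
  }
  v1q <- lineVec(caQ, swapQ); v1s <- lineVec(caS, swapS)
  v2q <- termVec(caQ, swapQ, oQ); v2s <- termVec(caS, swapS, oS)
  thx <- if (!is.null(v1q) && !is.null(v1s)) angleBetween(v1q, v1s) else NA
  thy <- if (!is.null(v2q) && !is.null(v2s)) angleBetween(v2q, v2s) else NA
  if (is.na(thx) && is.na(thy))
    stop("both representative vectors degenerate")
  mean(c(thx, thy), na.rm = TRUE) / 180
}

#' Displacement factor of the swapped domains
#'
#' The mean C-alpha distance of equivalent swapped-domain residue pairs
#' under the main-domain superposition, normalized by the diagonal of the
#' axis-aligned bounding box of the union of both swapped domains.
#'
#' @param chainQ,chainS the two chains.
#' @param swapPairs data.frame(iQ, iS): equivalent swapped-domain residues.
#' @param swapQ,swapS swapped-domain residue ranges.
#' @param transform main-domain transform (applied to chainS).
#' @return gamma_d in \[0, 1\], or NA when no equivalent pairs exist.
#' @export
gammaD <- function(chainQ, chainS, swapPairs, swapQ, swapS, transform) {
  if (is.null(swapPairs) || nrow(swapPairs) == 0) return(NA_real_)
  caQ <- caCoords(chainQ)
  caS <- applyTransform(caCoords(chainS), transform)
  dAvg <- mean(sqrt(rowSums((caQ[swapPairs$iQ, , drop = FALSE] -
                             caS[swapPairs$iS, , drop = FALSE])^2)))
  cloud <- rbind(caQ[swapQ, , drop = FALSE], caS[swapS, , drop = FALSE])
  dMax <- vnorm(apply(cloud, 2, max) - apply(cloud, 2, min))
  if (dMax < 1e-9) return(NA_real_)
  min(dAvg / dMax, 1)
}

#' Minimal structural diversity of the swapped domains
#'
#' \code{mu_sd = rmsd_sd / (N_e,sd / min(N_o,sd, N_c,sd))}: the RMSD of the
#' swapped-fragment alignment divided by its normalized alignment size.
#' Zero iff the swapped domains superpose exactly.
#'
#' @param swap_aln the swapped-fragment \linkS4class{StructAlignment}.
#' @param nC,nO sizes (residues) of the closed- and open-form swapped
#'   domains.
#' @return mu_sd >= 0, or NA when the alignment is empty.
#' @export
muSD <- function(swap_aln, nC, nO) {
  if (is.null(swap_aln) || swap_aln@nE == 0) return(NA_real_)
  swap_aln@rmsd / (swap_aln@nE / min(nC, nO))
}

#' The DS score
#'
#' \code{DS = eta * S0 * exp(-(m0 (1 - gamma_theta) + m1 (1 - gamma_d) +
#' m2 mu_sd))}, clamped to \[0, 1\]. S0 is the virtual Q-score.
#'
#' @param factors list with gamma_theta, gamma_d, mu_sd, eta, s0 (missing
#'   gamma/mu values force the score to 0).
#' @param model a \linkS4class{DSModel} (or list with m0, m1, m2).
#' @return DS score in \[0, 1\].
#' @export
dsScore <- function(factors, model) {
  if (is.null(factors$eta) || factors$eta == 0) return(0)
  if (is.null(factors$s0) || is.na(factors$s0) || factors$s0 <= 0) return(0)
  gt <- factors$gamma_theta; gd <- factors$gamma_d; mu <- factors$mu_sd
  if (anyNA(c(gt, gd, mu))) return(0)
  m0 <- if (is(model, "DSModel")) model@m0 else model$m0
  m1 <- if (is(model, "DSModel")) model@m1 else model$m1
  m2 <- if (is(model, "DSModel")) model@m2 else model$m2
  fp <- exp(-(m0 * (1 - gt) + m1 * (1 - gd) + m2 * mu))
  max(0, min(1, factors$eta * factors$s0 * fp))
}

#' Binary classification metrics
#'
#' Matthews correlation coefficient, sensitivity and specificity from
#' predicted and true labels.
#'
#' @param predictions,labels logical (or 0/1) vectors of equal length.
#' @return list(mcc, sensitivity, specificity, tp, fp, tn, fn,
#'   mcc_defined). An MCC with a zero denominator is reported as 0 with
#'   \code{mcc_defined = FALSE}.
#' @examples
#' classificationMetrics(c(TRUE, FALSE), c(TRUE, FALSE))$mcc
#' @export
classificationMetrics <- function(predictions, labels) {
  p <- as.logical(predictions); l <- as.logical(labels)
  stopifnot(length(p) == length(l))
  tp <- sum(p & l); fp <- sum(p & !l); tn <- sum(!p & !l); fn <- sum(!p & l)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  defined <- den > 0
  mcc <- if (defined) (tp * tn - fp * fn) / den else 0
  list(mcc = mcc,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn, mcc_defined = defined)
}

#' Train the DS-score model by exhaustive grid search
#'
#' Scans (m0, m1, m2) and the decision cutoff over regular grids and keeps
#' the combination maximizing the MCC on the labeled factor sets.
#' Deterministic; ties resolve to smaller parameter magnitudes, then the
#' smaller cutoff.
#'
#' @param factorList list of factor lists (as taken by
#'   \code{\link{dsScore}}).
#' @param labels logical vector (TRUE = DS pair).
#' @param m_grid grid for each of m0, m1, m2.
#' @param cutoff_grid grid for the decision cutoff.
#' @return A \linkS4class{DSModel}.
#' @export
trainDSModel <- function(factorList, labels,
                         m_grid = seq(0, 5, by = 0.25),
                         cutoff_grid = seq(0.05, 0.95, by = 0.05)) {
  labels <- as.logical(labels)
  stopifnot(length(factorList) == length(labels))
  if (!any(labels) || all(labels))
    stop("training needs at least one positive and one negative pair")
  gate <- vapply(factorList, function(f) {
    ok <- !is.null(f$eta) && f$eta == 1 && !is.null(f$s0) &&
      !anyNA(c(f$gamma_theta, f$gamma_d, f$mu_sd))
    if (ok) f$s0 else 0
  }, numeric(1))
  gt <- vapply(factorList, function(f) if (is.null(f$gamma_theta) ||
    is.na(f$gamma_theta)) 0 else f$gamma_theta, numeric(1))
  gd <- vapply(factorList, function(f) if (is.null(f$gamma_d) ||
    is.na(f$gamma_d)) 0 else f$gamma_d, numeric(1))
  mu <- vapply(factorList, function(f) if (is.null(f$mu_sd) ||
    is.na(f$mu_sd)) 0 else f$mu_sd, numeric(1))
  best <- list(mcc = -Inf, m = c(0, 0, 0), cutoff = cutoff_grid[1])
  for (m0 in m_grid) for (m1 in m_grid) for (m2 in m_grid) {
    sc <- pmin(pmax(gate * exp(-(m0 * (1 - gt) + m1 * (1 - gd) + m2 * mu)),
                    0), 1)
    for (ct in cutoff_grid) {
      pred <- sc >= ct
      tp <- sum(pred & labels); fp <- sum(pred & !labels)
      tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
      den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
      mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
      better <- mcc > best$mcc + 1e-12 ||
        (abs(mcc - best$mcc) <= 1e-12 &&
         (sum(c(m0, m1, m2)^2) < sum(best$m^2) - 1e-12 ||
          (abs(sum(c(m0, m1, m2)^2) - sum(best$m^2)) <= 1e-12 &&
           ct < best$cutoff)))
      if (better) best <- list(mcc = mcc, m = c(m0, m1, m2), cutoff = ct)
    }
  }
  new("DSModel", m0 = best$m[1], m1 = best$m[2], m2 = best$m[3],
      cutoff = best$cutoff,
      grid = list(m_grid = m_grid, cutoff_grid = cutoff_grid),
      trainMCC = best$mcc)
}

#' Default (untrained) DS model
#'
#' Unit penalty weights and a 0.5 cutoff; use \code{\link{trainDSModel}}
#' for a calibrated model.
#' @return A \linkS4class{DSModel}.
#' @export
defaultDSModel <- function() {
  new("DSModel", m0 = 1, m1 = 1, m2 = 1, cutoff = 0.5, grid = list(),
      trainMCC = NA_real_)
}

#' Save / load a DS model as JSON
#'
#' @param model a DSModel.
#' @param path file path.
#' @return \code{path} (write) or a DSModel (read).
#' @export
writeDSModel <- function(model, path) {
  jsonlite::write_json(list(m0 = model@m0, m1 = model@m1, m2 = model@m2,
                            cutoff = model@cutoff, grid = model@grid,
                            train_mcc = model@trainMCC),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDSModel
#' @export
readDSModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DSModel", m0 = x$m0, m1 = x$m1, m2 = x$m2, cutoff = x$cutoff,
      grid = if (is.null(x$grid)) list() else x$grid,
      trainMCC = if (is.null(x$train_mcc)) NA_real_ else x$train_mcc)
}
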