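# End-to-end pairwise DS comparison and its report artifacts.

#' Compare two chains for a 3D domain-swap relationship
#'
#' Runs the full pipeline: SSE matching via the pair graph, rigid
#' main-domain alignment, A-D product profile and hinge localization,
#' opening-point refinement and validation, swapped-domain alignment,
#' virtual measures, swap factors and the DS score.
#'
#' @param chainQ,chainS \linkS4class{ProteinChain} objects (closed/query
#'   and open/subject; the method is symmetric in intent, the transform is
#'   applied to chainS).
#' @param model a \linkS4class{DSModel}.
#' @param config see \code{\link{adswapConfig}}.
#' @return A \linkS4class{DSReport}.
#' @examples
#' fx <- makeFixturePair(fixtureSpec(seed = 3))
#' rep <- compareChains(fx$closed, fx$open)
#' dsType(rep)
#' @export
compareChains <- function(chainQ, chainS, model = defaultDSModel(),
                          config = adswapConfig()) {
  mres <- matchChains(chainQ, chainS, config)
  if (nrow(mres$match@pairs) == 0)
    stop("no similarity: SSE matching produced no pairs")
  alnMain <- alignWithAnchors(chainQ, chainS, mres, config)
  nQ <- chainLength(chainQ)
  nS <- chainLength(chainS)
  prof <- adProfile(mres, alnMain, config)
  sm <- smoothProfile(prof$p_ad)
  tr <- detectTransitions(sm, config)
  cls <- classifyDSType(sm, tr)
  prof$smoothed <- sm

  alignedQ <- rep(FALSE, nQ); alignedQ[alnMain@pairs$iQ] <- TRUE
  alignedS <- rep(FALSE, nS); alignedS[alnMain@pairs$iS] <- TRUE
  ssesQ <- mres$ssesQ
  ssesS <- mres$ssesS

  type <- cls$type
  oQ <- oS <- NULL
  if (type != "none") {
    # profile entries ordered by query SSE; the subject-side boundaries
    # follow the same matched pairs
    oQ <- initialOpeningPoint(type, prof, cls$boundaries, ssesQ, "Q")
    oS <- initialOpeningPoint(type, prof, cls$boundaries, ssesS, "S")
  } else {
    csQ <- assignSmallSwappedDomain(alignedQ, ssesQ, prof, "Q")
    csS <- assignSmallSwappedDomain(alignedS, ssesS, prof, "S")
    if (!is.null(csQ) && !is.null(csS) && csQ$type == csS$type) {
      type <- csQ$type
      oQ <- csQ$o
      oS <- csS$o
    }
  }

  emptyReport <- function(reason) {
    meas <- computeMeasures(alnMain, nQ, nS, config)
    virt <- virtualCombine(alnMain, NULL, nQ, nS, config)
    new("DSReport", score = 0, isDS = FALSE, dsType = "none", eta = 0,
        factors = list(gamma_theta = NA_real_, gamma_d = NA_real_,
                       mu_sd = NA_real_, s0 = virt$v_q_score, eta = 0,
                       reason = reason),
        measures = list(main = meas, virtual = virt),
        hinges = list(), profile = prof, match = mres$match,
        alignments = list(main = alnMain, swap = NULL))
  }
  if (is.null(oQ)) return(emptyReport("no candidate hinge loop"))

  refine <- function(o, aligned) {
    if (type == "N") refineOpeningPoint(o, aligned, +1L, config)
    else if (type == "C") refineOpeningPoint(o, aligned, -1L, config)
    else c(refineOpeningPoint(o[1], aligned, -1L, config),
           refineOpeningPoint(o[2], aligned, +1L, config))
  }
  opQ <- refine(oQ, alignedQ)
  opS <- refine(oS, alignedS)
  nOP <- if (type == "middle") 2L else 1L
  if (length(opQ) < nOP || length(opS) < nOP || anyNA(c(opQ, opS)))
    return(emptyReport("opening point rejected (over-extended)"))
  if (type == "middle" && (opQ[1] >= opQ[2] || opS[1] >= opS[2]))
    return(emptyReport("middle-swap opening points crossed"))

  fragRange <- function(op, n) switch(type,
    N = seq_len(op), C = op:n, middle = op[1]:op[2])
  fragQ <- fragRange(opQ, nQ)
  fragS <- fragRange(opS, nS)
  anchor <- if (type == "N") "end" else "start"
  val <- validateHinge(chainQ, chainS, fragQ, fragS, alignedQ, anchor,
                       config)
  if (val$eta == 0)
    return(emptyReport(paste("hinge rejected:", val$reason)))
  swapAln <- val$swap_aln
  # the main alignment has priority over residues claimed by both
  dup <- swapAln@pairs$iQ %in% alnMain@pairs$iQ |
         swapAln@pairs$iS %in% alnMain@pairs$iS
  if (any(dup)) {
    keep <- swapAln@pairs[!dup, , drop = FALSE]
    if (nrow(keep) >= 3) {
      tr2 <- kabschSuperpose(caCoords(chainQ)[keep$iQ, , drop = FALSE],
                             caCoords(chainS)[keep$iS, , drop = FALSE])
      swapAln <- newAlignment(keep$iQ, keep$iS, tr2, tr2$rmsd)
    } else {
      return(emptyReport("swapped-domain alignment absorbed by main domain"))
    }
  }

  # hinge ranges from pooled equivalences and both transforms
  pooledQ <- rbind(data.frame(i = alnMain@pairs$iQ, j = alnMain@pairs$iS),
                   data.frame(i = swapAln@pairs$iQ, j = swapAln@pairs$iS))
  pooledS <- data.frame(i = pooledQ$j, j = pooledQ$i)
  transQ <- list(alnMain@transform, swapAln@transform)
  invT <- function(tr) list(R = t(tr$R), t = as.numeric(-t(tr$R) %*% tr$t))
  transS <- lapply(transQ, invT)
  n_hl <- if (type == "middle") 2L else 1L
  mkHinges <- function(op, chain, other, pairsAll, trans, frag) {
    lapply(seq_along(op), function(k) {
      hr <- determineHingeRange(op[k], pairsAll, chain, other, trans,
                                n_hl = n_hl, swapRange = frag,
                                config = config)
      rr <- residues(chain)
      list(opening_point = rr$resno[op[k]],
           range = rr$resno[hr$range], range_pos = hr$range,
           length = hr$range[2] - hr$range[1] + 1L,
           n_hl = n_hl, theta0 = hr$theta0)
    })
  }
  hingesQ <- mkHinges(opQ, chainQ, chainS, pooledQ, transQ, fragQ)
  hingesS <- mkHinges(opS, chainS, chainQ, pooledS, transS, fragS)

  # swapped domains proper: candidate fragments minus their hinge loops
  trimHinge <- function(frag, hinges) {
    for (h in hinges) frag <- setdiff(frag, h$range_pos[1]:h$range_pos[2])
    frag
  }
  swapQ <- trimHinge(fragQ, hingesQ)
  swapS <- trimHinge(fragS, hingesS)
  if (length(swapQ) < 3 || length(swapS) < 3) { swapQ <- fragQ; swapS <- fragS }

  gt <- tryCatch(
    gammaTheta(chainQ, chainS, swapQ, swapS, opQ[1], opS[1],
               alnMain@transform),
    error = function(e) NA_real_)
  swapPairs <- swapAln@pairs
  gd <- gammaD(chainQ, chainS, swapPairs, swapQ, swapS, alnMain@transform)
  mu <- muSD(swapAln, length(fragQ), length(fragS))

  measMain <- computeMeasures(alnMain, nQ, nS, config)
  virt <- virtualCombine(alnMain, swapAln, nQ, nS, config)
  factors <- list(gamma_theta = gt, gamma_d = gd, mu_sd = mu,
                  s0 = virt$v_q_score, eta = 1)
  score <- dsScore(factors, model)
  new("DSReport", score = score, isDS = score >= model@cutoff,
      dsType = type, eta = 1, factors = factors,
      measures = list(main = measMain,
                      swap = computeMeasures(swapAln, length(fragQ),
                                             length(fragS), config),
                      virtual = virt),
      hinges = list(Q = hingesQ, S = hingesS), profile = prof,
      match = mres$match,
      alignments = list(main = alnMain, swap = swapAln))
}

#' Compare two PDB files
#'
#' Reads the two chains, runs \code{\link{compareChains}} and optionally
#' writes the report artifacts: a JSON report, superposed PDB files for
#' the main domain, the swapped domain and the virtual (fused, two-model)
#' superposition, and the structure-based sequence alignment text with
#' hinge residues highlighted.
#'
#' @param pathQ,pathS PDB files.
#' @param chainQ,chainS chain identifiers.
#' @param model a \linkS4class{DSModel}.
#' @param outdir output directory, or NULL for no artifacts.
#' @param config see \code{\link{adswapConfig}}.
#' @return A \linkS4class{DSReport}, invisibly when writing artifacts.
#' @export
comparePair <- function(pathQ, chainQ = "A", pathS, chainS = "A",
                        model = defaultDSModel(), outdir = NULL,
                        config = adswapConfig()) {
  cq <- readChain(pathQ, chainQ)
  cs <- readChain(pathS, chainS)
  rep <- compareChains(cq, cs, model, config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeReportJSON(rep, file.path(outdir, "report.json"))
    writeAlignmentText(rep, cq, cs, file.path(outdir, "alignment.txt"))
    writeSuperposed(rep, cq, cs, outdir)
    return(invisible(rep))
  }
  rep
}

reportList <- function(rep) {
  num <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) NULL else x
  list(
    ds_score = rep@score, is_ds = rep@isDS, ds_type = rep@dsType,
    eta = rep@eta,
    factors = list(gamma_theta = num(rep@factors$gamma_theta),
                   gamma_d = num(rep@factors$gamma_d),
                   mu_sd = num(rep@factors$mu_sd),
                   s0 = num(rep@factors$s0)),
    measures = rep@measures,
    hinges = rep@hinges,
    profile = rep@profile,
    n_matched_sses = nrow(rep@match@pairs))
}

#' Write a DSReport as JSON
#'
#' @param rep a DSReport.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReportJSON <- function(rep, path) {
  jsonlite::write_json(reportList(rep), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       dataframe = "columns")
  invisible(path)
}

#' Structure-based sequence alignment text
#'
#' FASTA-style paired alignment rows built from the pooled main and
#' swapped equivalences; hinge-loop residues are uppercased in a marker
#' row.
#'
#' @param rep a DSReport.
#' @param chainQ,chainS the compared chains.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentText <- function(rep, chainQ, chainS, path) {
  main <- rep@alignments$main@pairs
  swap <- if (!is.null(rep@alignments$swap)) rep@alignments$swap@pairs
          else main[0, ]
  pairs <- rbind(main, swap)
  pairs <- pairs[order(pairs$iQ), , drop = FALSE]
  rq <- residues(chainQ); rs <- residues(chainS)
  hingeQ <- unlist(lapply(rep@hinges$Q, function(h)
    h$range_pos[1]:h$range_pos[2]))
  hingeS <- unlist(lapply(rep@hinges$S, function(h)
    h$range_pos[1]:h$range_pos[2]))
  sq <- ss <- mk <- character(0)
  iq <- is_ <- 1L
  emit <- function(a, b, m) { sq <<- c(sq, a); ss <<- c(ss, b); mk <<- c(mk, m) }
  for (k in seq_len(nrow(pairs))) {
    while (iq < pairs$iQ[k]) { emit(rq$aa[iq], "-", " "); iq <- iq + 1L }
    while (is_ < pairs$iS[k]) { emit("-", rs$aa[is_], " "); is_ <- is_ + 1L }
    m <- if (iq %in% hingeQ || is_ %in% hingeS) "h" else "|"
    emit(rq$aa[iq], rs$aa[is_], m)
    iq <- iq + 1L; is_ <- is_ + 1L
  }
  while (iq <= nrow(rq)) { emit(rq$aa[iq], "-", " "); iq <- iq + 1L }
  while (is_ <= nrow(rs)) { emit("-", rs$aa[is_], " "); is_ <- is_ + 1L }
  con <- file(path, "w")
  on.exit(close(con))
  width <- 60L
  for (s in seq(1, length(sq), by = width)) {
    e <- min(s + width - 1L, length(sq))
    writeLines(c(paste0("Q ", paste(sq[s:e], collapse = "")),
                 paste0("  ", paste(mk[s:e], collapse = "")),
                 paste0("S ", paste(ss[s:e], collapse = "")), ""), con)
  }
  invisible(path)
}

#' Percent identity of the structure-based alignment
#'
#' @param rep a DSReport.
#' @param chainQ,chainS the compared chains.
#' @return percent identical residues over the pooled equivalences.
#' @export
sequenceIdentity <- function(rep, chainQ, chainS) {
  main <- rep@alignments$main@pairs
  swap <- if (!is.null(rep@alignments$swap)) rep@alignments$swap@pairs
          else main[0, ]
  pairs <- rbind(main, swap)
  if (nrow(pairs) == 0) return(NA_real_)
  rq <- residues(chainQ); rs <- residues(chainS)
  100 * mean(rq$aa[pairs$iQ] == rs$aa[pairs$iS])
}

# Superposed subject coordinates as PDB: main-domain transform, swapped
# transform, and the fused virtual superposition as a two-MODEL file
# (a single rigid transform cannot represent it).
writeSuperposed <- function(rep, chainQ, chainS, outdir) {
  wr <- function(chain, trans, path) {
    r <- residues(chain)
    for (cols in list(c("x", "y", "z"), c("nx", "ny", "nz"),
                      c("cx", "cy", "cz"))) {
      m <- as.matrix(r[, cols])
      ok <- !is.na(m[, 1])
      m[ok, ] <- applyTransform(m[ok, , drop = FALSE], trans)
      r[, cols] <- m
    }
    writeFixturePDB(new("ProteinChain", id = chain@id, residues = r,
                        sseRecords = chain@sseRecords), path)
  }
  wr(chainS, rep@alignments$main@transform,
     file.path(outdir, "subject_main_superposed.pdb"))
  if (!is.null(rep@alignments$swap)) {
    wr(chainS, rep@alignments$swap@transform,
       file.path(outdir, "subject_swap_superposed.pdb"))
    # fused: MODEL 1 = query, MODEL 2/3 = subject under the two transforms
    tmp1 <- tempfile(); tmp2 <- tempfile(); tmp3 <- tempfile()
    writeFixturePDB(chainQ, tmp1)
    wr(chainS, rep@alignments$main@transform, tmp2)
    wr(chainS, rep@alignments$swap@transform, tmp3)
    lines <- c("MODEL     1", readLines(tmp1), "ENDMDL",
               "MODEL     2", readLines(tmp2), "ENDMDL",
               "MODEL     3", readLines(tmp3), "ENDMDL", "END")
    writeLines(lines, file.path(outdir, "virtual_superposition.pdb"))
    unlink(c(tmp1, tmp2, tmp3))
  }
  invisible(NULL)
}

#' Batch evaluation over a manifest of labeled pairs
#'
#' @param manifest data.frame with columns pathQ, chainQ, pathS, chainS,
#'   label (logical/0-1), or the path of a TSV file with those columns.
#' @param model a \linkS4class{DSModel}.
#' @param config see \code{\link{adswapConfig}}.
#' @return list(results = per-pair data.frame, metrics = aggregate
#'   classification metrics, by_type = per-DS-type sensitivity table,
#'   skipped = number of unreadable entries).
#' @export
batchEvaluate <- function(manifest, model = defaultDSModel(),
                          config = adswapConfig()) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  res <- data.frame(pathQ = character(), pathS = character(),
                    score = numeric(), is_ds = logical(),
                    ds_type = character(), label = logical())
  skipped <- 0L
  for (k in seq_len(nrow(manifest))) {
    rep <- tryCatch(
      comparePair(manifest$pathQ[k], manifest$chainQ[k],
                  manifest$pathS[k], manifest$chainS[k],
                  model = model, config = config),
      error = function(e) NULL)
    if (is.null(rep)) { skipped <- skipped + 1L; next }
    res <- rbind(res, data.frame(pathQ = manifest$pathQ[k],
                                 pathS = manifest$pathS[k],
                                 score = rep@score, is_ds = rep@isDS,
                                 ds_type = rep@dsType,
                                 label = as.logical(manifest$label[k])))
  }
  metrics <- classificationMetrics(res$is_ds, res$label)
  byType <- NULL
  if (any(res$label)) {
    pos <- res[res$label, , drop = FALSE]
    byType <- do.call(rbind, lapply(split(pos, pos$ds_type), function(g)
      data.frame(ds_type = g$ds_type[1], total = nrow(g),
                 true_positive = sum(g$is_ds),
                 sensitivity = mean(g$is_ds))))
  }
  list(results = res, metrics = metrics, by_type = byType,
       skipped = skipped)
}

#' Train a DS model from a manifest of labeled structure pairs
#'
#' Runs the pipeline on every pair, collects the swap factors, and grid
#' searches the model (see \code{\link{trainDSModel}}).
#'
#' @inheritParams batchEvaluate
#' @param ... passed to \code{\link{trainDSModel}}.
#' @return list(model, factors, labels).
#' @export
trainFromManifest <- function(manifest, config = adswapConfig(), ...) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  factors <- list()
  labels <- logical(0)
  for (k in seq_len(nrow(manifest))) {
    rep <- tryCatch({
      cq <- readChain(manifest$pathQ[k], manifest$chainQ[k])
      cs <- readChain(manifest$pathS[k], manifest$chainS[k])
      compareChains(cq, cs, config = config)
    }, error = function(e) NULL)
    if (is.null(rep)) next
    factors[[length(factors) + 1]] <- rep@factors
    labels <- c(labels, as.logical(manifest$label[k]))
  }
  model <- trainDSModel(factors, labels, ...)
  list(model = model, factors = factors, labels = labels)
}
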