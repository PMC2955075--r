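#' Default configuration of the DS detection pipeline
#'
#' Every numeric constant of the method is collected here and can be
#' overridden per call. Values stated by the method description are the
#' defaults; reconstructed scaling constants (the vertex and edge scoring
#' terms, whose exact algebraic forms are not published) are exposed so they
#' can be recalibrated.
#'
#' @param ... named overrides of any listed element.
#' @return A named list:
#' \describe{
#'   \item{min_sse_len}{minimum residues for a usable SSE (3).}
#'   \item{d_norm}{A-D image distance normalization constant, Angstrom (25);
#'     distances are clamped to 1 above it.}
#'   \item{s_c}{vertex score threshold constant (3).}
#'   \item{k1,k2,k3}{vertex score scalings: per normalized A-D-plane
#'     distance unit (1/0.1), per degree of dihedral difference (1/30),
#'     per residue of chain-separation difference (1/20).}
#'   \item{d_t}{edge exponential envelope scale, Angstrom (25).}
#'   \item{k_dist}{edge elastic distance scale, Angstrom (10).}
#'   \item{k_alpha,k_beta,k_gamma}{edge angle-term scalings, 1/radian
#'     (4/pi, 4/pi, 3/pi).}
#'   \item{pair_cutoff}{C-alpha distance cutoff for keeping an equivalent
#'     residue pair during iterative alignment, Angstrom (5).}
#'   \item{gap_penalty}{linear gap cost of the residue DP, in
#'     pair-equivalents per gapped residue (0.1).}
#'   \item{rmsd_tol}{RMSD convergence tolerance, Angstrom (0.01).}
#'   \item{max_iter}{iteration cap of the alignment refinement (50).}
#'   \item{q_r0}{Q-score distance constant, Angstrom (3).}
#'   \item{theta_u,d_u}{A-D product scalings: 180 degrees, 25 Angstrom.}
#'   \item{conf}{confidence level of the transition t-test (0.80).}
#'   \item{pf_run}{consecutive aligned residues ending the peak-first scan
#'     (5; the stop requires more than this many).}
#'   \item{t_n}{unaligned-residue cutoff of the bifurcation-last scan (4).}
#'   \item{t_l}{minimum unaligned fraction of a candidate swapped fragment
#'     (0.5).}
#'   \item{frag_min_ratio}{minimum aligned fraction of the smaller swapped
#'     fragment (0.5).}
#'   \item{frag_max_rmsd}{maximum RMSD of the swapped-fragment alignment,
#'     Angstrom (4).}
#'   \item{theta0_base}{hinge extension torsion cutoff per hinge loop,
#'     degrees (25).}
#'   \item{ca_stop}{C-alpha distance ending hinge extension, Angstrom (2.6).}
#'   \item{min_swap}{minimum residues left in a swapped domain (10).}
#'   \item{eisenberg}{logical; use the fixed-cutoff hinge extension of the
#'     original manual procedure instead of the theta0 = 25 * n_hl rule.}
#'   \item{eisenberg_theta0}{fixed cutoff for that mode, degrees (20).}
#'   \item{sequential}{logical; sequential (order-dependent) SSE matching.}
#' }
#' @examples
#' cfg <- adswapConfig(pair_cutoff = 6)
#' cfg$pair_cutoff
#' @export
adswapConfig <- function(...) {
  cfg <- list(
    min_sse_len = 3L,
    d_norm = 25,
    s_c = 3, k1 = 1 / 0.1, k2 = 1 / 30, k3 = 1 / 20,
    d_t = 25, k_dist = 10,
    k_alpha = 4 / pi, k_beta = 4 / pi, k_gamma = 3 / pi,
    pair_cutoff = 5, gap_penalty = 0.1, rmsd_tol = 0.01, max_iter = 50L,
    q_r0 = 3,
    theta_u = 180, d_u = 25,
    conf = 0.80,
    pf_run = 5L, t_n = 4L, t_l = 0.5,
    frag_min_ratio = 0.5, frag_max_rmsd = 4,
    theta0_base = 25, ca_stop = 2.6, min_swap = 10L,
    eisenberg = FALSE, eisenberg_theta0 = 20,
    sequential = TRUE
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}
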