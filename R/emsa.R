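#' Fit a dissociation constant to gel-shift band intensities
#'
#' For a titration series of total protein concentrations, the bound
#' probability including ligand depletion is the positive root of the
#' quadratic binding equilibrium,
#' `p(B; P_T) = (1 + 2 K_D / (P_T - D_T - K_D + sqrt((P_T - D_T - K_D)^2 +
#' 4 K_D P_T)))^-1` with `D_T` the total probe concentration. The measured
#' bound/free band intensities are fitted by least squares with per-band
#' linear intensity scales `alpha_B`, `alpha_F`, which are profiled out
#' analytically; `K_D` is found by 1-D optimization on a log grid. As
#' `D_T -> 0` the curve reduces to the simple hyperbola `P_T/(P_T + K_D)`,
#' and rescaling both intensity channels rescales the alphas but not `K_D`.
#'
#' @param y_bound,y_free Band intensities per concentration point.
#' @param p_totals Total protein concentrations (>= 3 points).
#' @param dna_total Total probe concentration (same units).
#' @return List with `kd`, `alpha_bound`, `alpha_free`, fitted
#'   probabilities `p_bound` and the residual sum of squares.
#' @export
fit_emsa_kd <- function(y_bound, y_free, p_totals, dna_total) {
  stopifnot(length(y_bound) == length(p_totals),
            length(y_free) == length(p_totals))
  if (length(p_totals) < 3L) stop("need at least 3 concentration points")
  if (all(y_bound == 0) && all(y_free == 0)) stop("all band intensities are zero")
  loss <- function(log_kd) {
    p <- emsa_p_bound(p_totals, dna_total, exp(log_kd))
    aB <- if (sum(y_bound^2) > 0) sum(p * y_bound) / sum(y_bound^2) else 0
    aF <- if (sum(y_free^2) > 0) sum((1 - p) * y_free) / sum(y_free^2) else 0
    sum((p - aB * y_bound)^2 + ((1 - p) - aF * y_free)^2)
  }
  span <- log(range(p_totals[p_totals > 0]))
  opt <- stats::optimize(loss, span + c(-12, 12))
  kd <- exp(opt$minimum)
  p <- emsa_p_bound(p_totals, dna_total, kd)
  aB <- if (sum(y_bound^2) > 0) sum(p * y_bound) / sum(y_bound^2) else 0
  aF <- if (sum(y_free^2) > 0) sum((1 - p) * y_free) / sum(y_free^2) else 0
  list(kd = kd, alpha_bound = aB, alpha_free = aF, p_bound = p,
       rss = opt$objective)
}

#' @rdname fit_emsa_kd
#' @param kd Dissociation constant.
#' @export
emsa_p_bound <- function(p_totals, dna_total, kd) {
  disc <- sqrt((p_totals - dna_total - kd)^2 + 4 * kd * p_totals)
  1 / (1 + 2 * kd / (p_totals - dna_total - kd + disc))
}
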