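#' Absolute dissociation constants from input/bound/free sequencing
#'
#' Fits a recognition model to the three fractions of an equilibrium
#' binding reaction — input (I), bound (B) and free (F) — and converts the
#' fitted partition function into absolute dissociation constants. The
#' three columns are modeled non-cumulatively with exponents
#' `rho = (0, 1, 0)` and `gamma = (0, -1, -1)` and activities constant
#' across columns, which makes the bound-column enrichment `Z/(1+Z)` and
#' the free-column factor `1/(1+Z)` — exactly the equilibrium binding and
#' non-binding probabilities with `Z = [P]_F / K_D`. The net bound DNA
#' fraction is recovered from the fitted depth normalizers,
#' `p(B) = (k_B/k_I) (eta_I/eta_B)`; free-protein depletion then gives
#' `[P]_F = [P]_T - [DNA]_I p(B)` and per-probe `K_D = [P]_F / Z`.
#'
#' @param input,bound,free Single-column [count_table()]s over a shared
#'   probe design (or pass a ready 3-column table as `input` with
#'   `bound = free = NULL`).
#' @param p_total Total protein concentration (nM).
#' @param dna_input Total input DNA concentration (nM).
#' @param include_ns Include a non-specific binding floor in `Z`.
#' @param ... Passed on to [probefit()] (e.g. `L`, `greedy`, `seed`).
#' @return An object of class `"kdfit"` extending `"probefit"`, with
#'   elements `p_bound`, `p_free_protein`, `kd` (per-probe K_D, nM) and
#'   `diagnostics` (see [titration_diagnostics()]).
#' @export
kdseq_fit <- function(input, bound = NULL, free = NULL, p_total, dna_input,
                      include_ns = TRUE, ...) {
  tb <- if (is.null(bound)) input
        else bind_count_tables(list(input, bound, free),
                               col_labels = c("I", "B", "F"))
  if (ncol(tb$counts) != 3L) stop("K_D-seq expects exactly three columns (I, B, F)")
  sel <- selection_spec("non_cumulative", rho = c(0, 1, 0), gamma = c(0, -1, -1))
  fit <- probefit(tb, sel, activity_tie = "constant", ns_tie = "constant",
                  include_ns = include_ns, ...)
  class(fit) <- c("kdfit", class(fit))
  fit$p_total <- p_total
  fit$dna_input <- dna_input
  k <- column_totals(tb)
  eta <- exp(fit$acts[[1L]]$log_eta)
  fit$p_bound <- unname((k[2L] / k[1L]) * (eta[1L] / eta[2L]))
  fit$p_free_protein <- p_total - dna_input * fit$p_bound
  if (fit$p_free_protein <= 0)
    stop("titration failure: estimated bound DNA exceeds total protein")
  Z <- predict(fit, type = "zbound")[, 2L]
  fit$kd <- fit$p_free_protein / Z
  names(fit$kd) <- tb$seqs
  fit$diagnostics <- titration_diagnostics(fit)
  fit
}

#' @export
print.kdfit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  p(B) = %.4f  [P]_F = %.2f nM  strongest K_D = %.3g nM\n",
              x$p_bound, x$p_free_protein, min(x$kd)))
  if (x$diagnostics$level != "ok")
    cat("  titration diagnostics:", x$diagnostics$message, "\n")
  invisible(x)
}

#' Titration diagnostics for a K_D-seq fit
#'
#' Reports the estimated fraction of protein molecules bound
#' (`[DNA]_I p(B) / [P]_T`), the bound-DNA fraction `p(B)`, and the
#' depletion of high-affinity probes in the free library. Warns when more
#' than 5% of the protein is bound and flags an error level above 10%
#' (the regime where free-protein depletion makes naive K_D estimates
#' unreliable and the assay should be repeated at lower DNA concentration).
#'
#' @param fit A [kdseq_fit()] result.
#' @param warn_at,error_at Bound-protein fraction thresholds.
#' @return List with `bound_protein_fraction`, `p_bound`,
#'   `free_depletion` (max per-probe relative depletion of the free
#'   library), `level` (`"ok"`, `"warn"`, `"error"`) and `message`.
#' @export
titration_diagnostics <- function(fit, warn_at = 0.05, error_at = 0.10) {
  bpf <- fit$dna_input * fit$p_bound / fit$p_total
  Z <- predict(fit, type = "zbound")[, 2L]
  free_dep <- 1 - 1 / (1 + max(Z))       # depletion of the strongest probe
  level <- if (bpf >= error_at) "error" else if (bpf >= warn_at) "warn" else "ok"
  msg <- switch(level,
    ok = sprintf("%.1f%% of protein bound; no titration concern", 100 * bpf),
    warn = sprintf("%.1f%% of protein bound (>= 5%%); interpret K_D scale with care",
                   100 * bpf),
    error = sprintf("%.1f%% of protein bound (>= 10%%); repeat with less DNA",
                    100 * bpf))
  if (level != "ok") warning(msg)
  list(bound_protein_fraction = bpf, p_bound = fit$p_bound,
       free_depletion = free_dep, level = level, message = msg)
}

#' Binned observed-versus-predicted binding curve
#'
#' Sorts probes by predicted K_D, bins them, and compares the observed
#' bound fraction per bin (from count ratios rescaled by the fitted depth
#' normalizers) with the model's prediction. Flat observed curves at high
#' affinity indicate saturation; missing depletion at low affinity
#' indicates a weak titration signal.
#'
#' @param fit A [kdseq_fit()] result.
#' @param bin_size Probes per bin (default 500; a single bin if fewer
#'   probes than one bin).
#' @return data.frame with per-bin mean `inv_kd` (1/K_D), `observed` and
#'   `predicted` bound fractions, and read totals.
#' @export
binned_binding_curve <- function(fit, bin_size = 500) {
  tb <- fit$experiments[[1L]]$table
  k <- column_totals(tb)
  eta <- exp(fit$acts[[1L]]$log_eta)
  scale <- eta[1L] / eta[2L]
  ord <- order(fit$kd, seq_along(fit$kd))   # ties broken by probe order
  n <- length(ord)
  bins <- ceiling(seq_len(n) / bin_size)
  E <- predict(fit, type = "counts")
  obs <- pred <- inv <- numeric(max(bins))
  for (b in seq_len(max(bins))) {
    ii <- ord[bins == b]
    obs[b] <- (sum(tb$counts[ii, 2L]) / pmax(sum(tb$counts[ii, 1L]), 1)) * scale
    pred[b] <- (sum(E[ii, 2L]) / pmax(sum(E[ii, 1L]), .Machine$double.eps)) * scale
    inv[b] <- mean(1 / fit$kd[ii])
  }
  data.frame(bin = seq_len(max(bins)), inv_kd = inv,
             observed = obs, predicted = pred)
}

#' Solve the coupled binding equilibrium of a probe library
#'
#' Finds the free-protein concentration satisfying mass conservation,
#' `[P]_F = [P]_T - sum_i [DNA_i]_I [P]_F / ([P]_F + K_D,i)`, by the secant
#' method on the bracket `[0, [P]_T]` (bisection fallback), then returns
#' the per-probe bound probabilities `p(B|i) = [P]_F/([P]_F + K_D,i)`.
#'
#' @param kd Per-probe dissociation constants (nM).
#' @param dna_i Per-probe input DNA concentrations (nM; sums to `[DNA]_I`).
#' @param p_total Total protein concentration (nM).
#' @param tol Relative residual tolerance.
#' @return List with `p_free`, `p_bound_i`, `residual`.
#' @export
solve_equilibrium <- function(kd, dna_i, p_total, tol = 1e-12) {
  h <- function(pf) pf - p_total + sum(dna_i * pf / (pf + kd))
  lo <- 0; hi <- p_total
  x0 <- 0.5 * p_total; x1 <- 0.9 * p_total
  f0 <- h(x0); f1 <- h(x1)
  ok <- FALSE
  for (i in 1:100) {
    if (f1 == f0) break
    x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
    if (!is.finite(x2) || x2 < lo || x2 > hi) break
    x0 <- x1; f0 <- f1; x1 <- x2; f1 <- h(x1)
    if (abs(f1) <= tol * max(p_total, 1)) { ok <- TRUE; break }
  }
  if (!ok) {   # bisection fallback (h(0) <= 0, h(p_total) >= 0)
    a <- lo; b <- hi
    for (i in 1:200) {
      m <- (a + b) / 2
      if (h(m) > 0) b <- m else a <- m
      if (abs(h(m)) <= tol * max(p_total, 1)) break
    }
    x1 <- (a + b) / 2
    if (abs(h(x1)) > 1e-6 * max(p_total, 1))
      stop("equilibrium solver failed to converge")
  }
  list(p_free = x1, p_bound_i = x1 / (x1 + kd), residual = h(x1))
}

# per-probe K_D from a ground-truth mode: kd_scale / window-sum, so the
# strongest enumerated sequence has K_D close to kd_scale * min window-sum^-1
truth_kd <- function(truth_mode, seqs, kd_scale,
                     left_flank = "", right_flank = "") {
  tb <- count_table(seqs, rep(1, length(seqs)), left_flank, right_flank,
                    alphabet = truth_mode$alphabet)
  d <- window_design(tb, truth_mode$L, truth_mode$f, truth_mode$strands)
  aff <- mode_probe_sums(truth_mode, d)
  stats::setNames(kd_scale / aff, seqs)
}

#' Simulate K_D-seq libraries at equilibrium
#'
#' Enumerates (or samples) a probe library, assigns ground-truth K_D
#' values from an energy model, solves the coupled equilibrium for the
#' free-protein concentration, and samples the input, bound and free
#' sequencing libraries multinomially.
#'
#' @param truth_mode Ground-truth [binding_mode()].
#' @param kd_scale K_D corresponding to unit window sum (nM); smaller
#'   values make the library stronger overall.
#' @param p_total,dna_input Total protein / DNA concentrations (nM).
#' @param reads Reads per library.
#' @param V Variable-region length (enumerated when `<= 12`).
#' @param base_freqs Input base composition; the default matches a typical
#'   slightly AT-rich random pool (A, C, G, T) = (0.288, 0.265, 0.144,
#'   0.303).
#' @param library Optional explicit library (list `seqs`, `f0`).
#' @param seed RNG seed.
#' @return List with the three [count_table()]s (`input`, `bound`,
#'   `free`), the ground-truth `kd`, `p_free` and the equilibrium residual.
#' @export
simulate_kdseq <- function(truth_mode, kd_scale, p_total, dna_input,
                           reads = 1e6, V = 8,
                           base_freqs = c(0.288, 0.265, 0.144, 0.303),
                           library = NULL, seed = 1L) {
  if (is.null(library))
    library <- enumerate_library(V, truth_mode$alphabet, base_freqs)
  kd <- truth_kd(truth_mode, library$seqs, kd_scale)
  eq <- solve_equilibrium(kd, dna_input * library$f0, p_total)
  pB <- eq$p_bound_i
  tabs <- sample_fraction_tables(library, pB, reads, truth_mode$alphabet, seed)
  c(tabs, list(kd = kd, p_free = eq$p_free, residual = eq$residual,
               p_bound = sum(library$f0 * pB)))
}

#' Simulate K_D-seq libraries with finite incubation time
#'
#' As [simulate_kdseq()], but the bound probability follows the
#' pre-equilibrium kinetic solution under a diffusion-limited on-rate
#' (sequence specificity carried by the off-rate):
#' `p(B|i,t) = [P]_T/([P]_T + K_D,i) * (1 - exp(-koffmin_t (K_D,i + [P]_T)/K_D,min))`
#' with `koffmin_t = k_off,min * t` the dimensionless incubation time.
#' As `koffmin_t -> Inf` this reduces to the equilibrium probabilities.
#'
#' @inheritParams simulate_kdseq
#' @param koffmin_t Dimensionless incubation time `k_off,min * t`.
#' @export
simulate_kdseq_kinetic <- function(truth_mode, kd_scale, p_total, dna_input,
                                   koffmin_t, reads = 1e6, V = 8,
                                   base_freqs = c(0.288, 0.265, 0.144, 0.303),
                                   library = NULL, seed = 1L) {
  stopifnot(koffmin_t > 0)
  if (is.null(library))
    library <- enumerate_library(V, truth_mode$alphabet, base_freqs)
  kd <- truth_kd(truth_mode, library$seqs, kd_scale)
  pB <- kinetic_bound_probability(kd, p_total, koffmin_t)
  tabs <- sample_fraction_tables(library, pB, reads, truth_mode$alphabet, seed)
  c(tabs, list(kd = kd, p_bound = sum(library$f0 * pB)))
}

#' @rdname simulate_kdseq_kinetic
#' @param kd Per-probe K_D values.
#' @export
kinetic_bound_probability <- function(kd, p_total, koffmin_t) {
  kdmin <- min(kd)
  (p_total / (p_total + kd)) *
    (1 - exp(-koffmin_t * (kd + p_total) / kdmin))
}

sample_fraction_tables <- function(library, pB, reads, alphabet, seed) {
  fI <- library$f0
  fB <- library$f0 * pB
  fF <- library$f0 * (1 - pB)
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  draw <- function(f) stats::rmultinom(1L, reads, f / sum(f))[, 1L]
  mk <- function(cnt, lab)
    count_table(library$seqs, cnt, alphabet = alphabet, col_labels = lab)
  list(input = mk(draw(fI), "I"), bound = mk(draw(fB), "B"),
       free = mk(draw(fF), "F"))
}

#' Equilibration time of a binding reaction
#'
#' Closed-form relaxation time of the two-state binding kinetics:
#' `t_eq = 1 / (k_off (1 + [P]_T / K_D))`. Saturated probes
#' (`[P]_T > K_D`) equilibrate faster than `1/k_off`.
#'
#' @param kd Dissociation constant (same units as `p_total`).
#' @param p_total Total protein concentration.
#' @param k_off Off-rate (1/time).
#' @return Equilibration time (time units of `1/k_off`).
#' @examples
#' equilibration_time(kd = 1, p_total = 9, k_off = 1)   # 0.1
#' @export
equilibration_time <- function(kd, p_total, k_off) {
  1 / (k_off * (1 + p_total / kd))
}
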