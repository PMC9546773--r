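#' Probe libraries for simulation
#'
#' `enumerate_library()` lists every sequence of length `V` over the
#' alphabet (capped at `4^12`-sized spaces); `random_library()` draws a
#' fixed set of distinct sequences i.i.d. from a base composition. Both
#' return the sequences together with input frequencies proportional to
#' the per-letter composition.
#'
#' @param V Variable-region length.
#' @param alphabet A [pf_alphabet()].
#' @param base_freqs Per-letter frequencies (alphabet order); default
#'   uniform.
#' @param n Number of distinct sequences to draw.
#' @param seed RNG seed.
#' @return List with `seqs` and `f0` (input frequencies, summing to 1).
#' @export
enumerate_library <- function(V, alphabet = dna_alphabet(), base_freqs = NULL) {
  A <- n_letters(alphabet)
  if (A^V > 4^12) stop("sequence space too large to enumerate; use random_library()")
  grid <- do.call(expand.grid, rep(list(seq_len(A)), V))
  idx <- as.matrix(grid[, rev(seq_len(V)), drop = FALSE])
  seqs <- decode_seqs(idx, alphabet)
  if (is.null(base_freqs)) base_freqs <- rep(1 / A, A)
  lf <- log(base_freqs)
  f0 <- exp(rowSums(matrix(lf[idx], nrow(idx))))
  list(seqs = seqs, f0 = f0 / sum(f0))
}

#' @rdname enumerate_library
#' @export
random_library <- function(n, V, alphabet = dna_alphabet(), base_freqs = NULL,
                           seed = 1L) {
  A <- n_letters(alphabet)
  if (is.null(base_freqs)) base_freqs <- rep(1 / A, A)
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  idx <- matrix(sample.int(A, n * V, TRUE, prob = base_freqs), n, V)
  seqs <- unique(decode_seqs(idx, alphabet))
  lf <- log(base_freqs)
  M <- encode_seqs(seqs, alphabet)
  f0 <- exp(rowSums(matrix(lf[M], nrow(M))))
  list(seqs = seqs, f0 = f0 / sum(f0))
}

#' Simulate a SELEX experiment
#'
#' Forward-simulates selection rounds from a ground-truth recognition
#' model: per-round partition functions give per-round frequencies via the
#' selection spec, and each sequenced column is drawn multinomially at the
#' requested depth. Column 1 is the sequenced input. The ground truth and
#' seeds are recorded in the table metadata, so end-to-end recovery tests
#' need no file bookkeeping.
#'
#' @param truth A [recognition_model()] whose activity columns span the
#'   selected columns of `selection`.
#' @param selection A [selection_spec()]; its `n_columns` sets the number
#'   of table columns.
#' @param depth Reads per column (recycled).
#' @param library A library from [enumerate_library()]/[random_library()],
#'   or `NULL` to enumerate length `V`.
#' @param V Variable-region length when `library` is `NULL`.
#' @param left_flank,right_flank Constant flanks.
#' @param base_freqs Input base composition.
#' @param seed RNG seed (one draw per column, derived deterministically).
#' @return A [count_table()] with observed probes only.
#' @export
simulate_selex <- function(truth, selection, depth = 1e5, library = NULL,
                           V = 10, left_flank = "", right_flank = "",
                           base_freqs = NULL, seed = 1L) {
  alph <- truth$modes[[1L]]$alphabet
  if (is.null(library)) library <- enumerate_library(V, alph, base_freqs)
  R <- selection$n_columns
  depth <- rep_len(depth, R)
  if (any(depth < 1)) stop("each sequenced column needs depth >= 1")
  tb_all <- count_table(library$seqs, rep(1, length(library$seqs)),
                        left_flank, right_flank, alphabet = alph)
  zc <- z_columns(selection)
  Z <- matrix(NA_real_, length(library$seqs), R)
  zmap <- predict_zbound(truth, tb_all, columns = seq_along(zc))
  Z[, zc] <- zmap
  f <- predict_frequencies(Z, selection, f0 = library$f0)
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  counts <- matrix(0, length(library$seqs), R)
  for (r in seq_len(R))
    counts[, r] <- stats::rmultinom(1L, depth[r], f[, r] / sum(f[, r]))
  count_table(library$seqs, counts, left_flank, right_flank, alph,
              metadata = list(seed = seed, depth = depth,
                              truth = truth_digest(truth)))
}

# compact, serializable fingerprint of a ground-truth model
truth_digest <- function(truth) {
  list(n_modes = length(truth$modes),
       L = vapply(truth$modes, `[[`, 1, "L"),
       beta_sum = vapply(truth$modes, function(m) sum(m$beta_mono), 1),
       checksum = sum(unlist(lapply(truth$modes, function(m)
         c(m$beta_mono, unlist(m$beta_pair))))))
}

#' Simulate paired modified/unmodified selection libraries
#'
#' Generates sub-libraries that share one recognition model over an
#' extended alphabet: each sub-library's probes are transliterated by its
#' rule set (e.g. `CG -> cg` for the methylated library) before scoring,
#' mirroring selection on chemically modified pools. All sub-libraries
#' share the input composition.
#'
#' @param truth Recognition model over the extended alphabet.
#' @param selection A [selection_spec()].
#' @param rules Named list of rule sets, one per sub-library; use an empty
#'   rule set (`character()`) for the unmodified library.
#' @param depth,library,V,left_flank,right_flank,base_freqs,seed As in
#'   [simulate_selex()].
#' @return Named list of [count_table()]s (sequences stored transliterated).
#' @export
simulate_episelex <- function(truth, selection, rules, depth = 1e5,
                              library = NULL, V = 10, left_flank = "",
                              right_flank = "", base_freqs = NULL, seed = 1L) {
  alph <- truth$modes[[1L]]$alphabet
  if (is.null(library)) {
    base <- dna_alphabet()
    bf <- base_freqs
    if (is.null(bf)) bf <- rep(1 / 4, 4)
    lib0 <- enumerate_library(V, base, bf)
    library <- lib0
  }
  out <- list()
  for (i in seq_along(rules)) {
    rl <- rules[[i]]
    seqs <- if (length(rl)) transliterate(library$seqs, rl) else library$seqs
    lib_i <- list(seqs = seqs, f0 = library$f0)
    out[[names(rules)[i]]] <- simulate_selex(
      truth, selection, depth = depth, library = lib_i,
      left_flank = left_flank, right_flank = right_flank,
      seed = seed + i - 1L)
  }
  out
}

#' Simulate an enzyme time-course display experiment
#'
#' For each exposure time, splits a peptide library into modified
#' (phosphorylated) and unmodified fractions according to
#' `p = 1 - exp(-k_eff * E * t)` per substrate, and samples both fractions
#' multinomially. Catalytic efficiencies come from the ground-truth mode's
#' window sum times `keff_ref`.
#'
#' @param truth_mode A [binding_mode()] over the peptide alphabet (single
#'   strand); its window sum scales relative efficiency.
#' @param keff_ref Efficiency scale: `k_eff = keff_ref * window_sum`.
#' @param times Exposure times (e.g. minutes).
#' @param enzyme_conc Time-averaged enzyme concentration.
#' @param library Peptide library (list with `seqs`, `f0`).
#' @param depth Reads per fraction per time.
#' @param seed RNG seed.
#' @return List over times; each element a two-column [count_table()]
#'   (`unbound`, `bound` = unmodified, modified).
#' @export
simulate_kinase <- function(truth_mode, keff_ref, times = c(5, 20, 60),
                            enzyme_conc = 1, library, depth = 1e5, seed = 1L) {
  tb <- count_table(library$seqs, rep(1, length(library$seqs)),
                    alphabet = truth_mode$alphabet)
  d <- window_design(tb, truth_mode$L, truth_mode$f, truth_mode$strands)
  keff <- keff_ref * mode_probe_sums(truth_mode, d)
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  out <- list()
  for (i in seq_along(times)) {
    p <- phospho_fraction(keff, enzyme_conc, times[i])
    f_un <- library$f0 * (1 - p)
    f_ph <- library$f0 * p
    counts <- cbind(
      unbound = stats::rmultinom(1L, depth, f_un / sum(f_un))[, 1L],
      bound = stats::rmultinom(1L, depth, f_ph / sum(f_ph))[, 1L])
    out[[paste0("t", times[i])]] <-
      count_table(library$seqs, counts, alphabet = truth_mode$alphabet,
                  col_labels = c("unbound", "bound"),
                  metadata = list(time = times[i], seed = seed,
                                  enzyme_conc = enzyme_conc))
  }
  out
}
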