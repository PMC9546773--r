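# Shared fixtures: random modes/models, small tables and brute-force oracles.

rand_mode <- function(L = 4, alphabet = dna_alphabet(), sd = 0.5,
                      pairs = "none", f = 0, strands = 2, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  A <- length(alphabet$letters)
  pr <- probefit:::resolve_pairs(pairs, L)
  binding_mode(L, alphabet, f = f, strands = strands,
               beta_mono = matrix(rnorm(A * L, sd = sd), A, L),
               pairs = pr,
               beta_pair = lapply(seq_len(nrow(pr)), function(i)
                 matrix(rnorm(A * A, sd = sd / 2), A, A)), ...)
}

rand_seqs <- function(n, V, alphabet = dna_alphabet()) {
  unique(replicate(n, paste(sample(alphabet$letters, V, TRUE), collapse = "")))
}

rand_table <- function(n = 30, V = 6, R = 3, alphabet = dna_alphabet(),
                       lambda = 5, left_flank = "", right_flank = "") {
  seqs <- rand_seqs(n, V, alphabet)
  counts <- matrix(rpois(length(seqs) * R, lambda) + 1L, ncol = R)
  count_table(seqs, counts, left_flank, right_flank, alphabet)
}

all_seqs <- function(L, alphabet = dna_alphabet()) {
  enumerate_library(L, alphabet)$seqs
}

# brute-force partition function: explicit loops over windows and window
# pairs, independent of the vectorized implementation
brute_zbound <- function(model, probe, column = 1L,
                         left_flank = "", right_flank = "") {
  alph <- model$modes[[1L]]$alphabet
  wins <- lapply(model$modes, function(m)
    enumerate_windows(probe, m$L, m$f, m$strands, left_flank, right_flank, alph))
  z <- if (is.null(model$log_alpha_ns)) 0 else exp(model$log_alpha_ns[column])
  for (a in seq_along(model$modes)) {
    m <- model$modes[[a]]
    wa <- wins[[a]]
    if (nrow(wa) == 0L) next
    s <- score_window(m, wa$window)
    z <- z + exp(model$log_alpha[a, column]) * sum(exp(s))
  }
  for (k in seq_along(model$interactions)) {
    it <- model$interactions[[k]]
    wa <- wins[[it$a]]; wb <- wins[[it$b]]
    ma <- model$modes[[it$a]]; mb <- model$modes[[it$b]]
    acc <- 0
    for (i in seq_len(nrow(wa))) for (j in seq_len(nrow(wb))) {
      d <- (wb$fwd_start[j] - mb$f) - (wa$fwd_start[i] - ma$f)
      par <- wa$strand[i] == wb$strand[j]
      lo <- probefit:::coop_logomega(it, d, par)
      if (!is.finite(lo)) next
      acc <- acc + exp(lo) *
        exp(score_window(ma, wa$window[i]) + score_window(mb, wb$window[j]))
    }
    z <- z + exp(model$log_alpha_int[k, column]) * acc
  }
  z
}

# deterministic small SELEX ground truth + simulated table used by several
# fitting tests (kept modest so the whole suite stays fast)
selex_fixture <- function(seed = 11, V = 8, depth = 3e4, sd = 1.0,
                          n_rounds = 2, rho = 1, gamma = 0, L = 8) {
  set.seed(seed)
  al <- dna_alphabet()
  bt <- matrix(rnorm(4 * L, sd = sd), 4, L)
  truth_mode <- binding_mode(L, al, beta_mono = bt)
  truth <- recognition_model(list(truth_mode),
                             log_alpha = matrix(0, 1, n_rounds),
                             log_alpha_ns = rep(0, n_rounds))
  sel <- selection_spec("cumulative", rho = rho, gamma = gamma,
                        n_columns = n_rounds + 1L)
  tb <- simulate_selex(truth, sel, depth = depth, V = V, seed = seed + 1L)
  gt <- truth_mode
  gt$reference <- paste(al$letters[apply(bt, 2L, which.max)], collapse = "")
  list(table = tb, selection = sel, truth = truth, truth_mode = gt,
       truth_gauged = fix_gauge(gt))
}
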