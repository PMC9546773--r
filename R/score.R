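#' Score a binding window
#'
#' Evaluates the additive binding free-energy model `-ddG/RT = sum(beta X)`
#' for windows whose length equals the mode footprint. Linear in the
#' coefficients; includes pairwise couplings when the mode has them.
#'
#' @param mode A [binding_mode()].
#' @param window Character vector of length-`L` sequences.
#' @return Numeric vector of scores (in units of `-ddG/RT`, i.e. RT).
#' @examples
#' m <- seed_mode(iupac = "AC")
#' score_window(m, "AC")
#' @export
score_window <- function(mode, window) {
  if (any(nchar(window) != mode$L))
    stop("window length must equal the mode footprint L")
  idx <- encode_seqs(window, mode$alphabet)
  if (anyNA(idx)) stop("window contains symbols outside the alphabet")
  score_idx(mode, idx)
}

# score an [n x L] letter-index matrix
score_idx <- function(mode, idx) {
  A <- n_letters(mode$alphabet)
  s <- numeric(nrow(idx))
  bm <- mode$beta_mono
  for (p in seq_len(mode$L)) s <- s + bm[idx[, p] + (p - 1L) * A]
  if (nrow(mode$pairs)) {
    for (k in seq_len(nrow(mode$pairs))) {
      x1 <- mode$pairs[k, 1L]; x2 <- mode$pairs[k, 2L]
      s <- s + mode$beta_pair[[k]][idx[, x1] + (idx[, x2] - 1L) * A]
    }
  }
  s
}

#' Relative dissociation constant
#'
#' `K_D(S) / K_D(S0) = exp(ddG(S)/RT) = exp(score(S0) - score(S))`; equals 1
#' for the reference sequence itself.
#'
#' @param mode A [binding_mode()] with its `reference` set.
#' @param sequence Character vector of length-`L` sequences.
#' @return Numeric vector of relative K_D values.
#' @export
relative_kd <- function(mode, sequence) {
  if (is.null(mode$reference)) stop("mode has no reference sequence")
  exp(score_window(mode, mode$reference) - score_window(mode, sequence))
}

# log position-bias per window of a design (0 when no bias configured)
design_posbias <- function(mode, design) {
  if (is.null(mode$position_bias)) return(0)
  pb <- mode$position_bias
  col <- ifelse(design$strand > 0, 1L, 2L)
  # per-strand offset index: forward offset for +, mirrored for - is already
  # the reverse-frame offset; recover it from blocks (offset stored as fwd
  # for + and len-L-fwd for -); we use the forward-frame start for both,
  # clamped to the bias table extent.
  o <- pmin(pmax(design$fwd + 1L, 1L), nrow(pb))
  pb[cbind(o, col)]
}

# per-window Boltzmann weights and per-probe window sums for one mode
mode_window_weights <- function(mode, design) {
  s <- score_idx(mode, design$idx) + design_posbias(mode, design)
  exp(s)
}

accum_by <- function(w, group, n) {
  out <- numeric(n)
  if (length(w)) {
    t <- rowsum(w, group)
    out[as.integer(rownames(t))] <- t
  }
  out
}

# sum_x w_a(x) e^{beta.X(S_x)} per probe
mode_probe_sums <- function(mode, design, weights = NULL) {
  if (is.null(weights)) weights <- mode_window_weights(mode, design)
  accum_by(weights, design$probe, design$n_probes)
}

# Pair (cooperativity) sums per probe for modes a, b with designs da, db.
# Returns list(sum = per-probe sum_{x1,x2} e^{s1+s2} w(d,orient),
#              by_cell = per-(orient,d) per-probe sums for gradients).
coop_probe_sums <- function(coop, wa, wb, da, db, want_cells = FALSE) {
  n <- da$n_probes
  tot <- numeric(n)
  cells <- if (want_cells) list() else NULL
  fa <- da$f; fb <- db$f
  for (ba in da$blocks) {
    ia <- seq.int(ba$first, ba$last)
    for (bb in db$blocks) {
      ib <- seq.int(bb$first, bb$last)
      # blocks within the same length-group share identical probe rows;
      # across groups they are disjoint, so skip unless rows match
      if (ba$n != bb$n || ba$rows[1L] != bb$rows[1L]) next
      d <- (bb$fwd - fb) - (ba$fwd - fa)      # variable-region frame spacing
      par <- ba$strand == bb$strand
      lo <- coop_logomega(coop, d, par)
      if (!is.finite(lo)) next
      contrib <- exp(lo) * wa[ia] * wb[ib]
      tot[ba$rows] <- tot[ba$rows] + contrib
      if (want_cells) {
        key <- paste0(if (par) "P" else "A", d)
        if (is.null(cells[[key]]))
          cells[[key]] <- list(d = d, parallel = par, sum = numeric(n))
        cells[[key]]$sum[ba$rows] <- cells[[key]]$sum[ba$rows] + contrib
      }
    }
  }
  list(sum = tot, cells = cells)
}

#' Partition function of bound states
#'
#' Evaluates `Z_bound` for every probe of a count table in a given column:
#' the non-specific term, plus each mode's activity-weighted window sum,
#' plus every cooperativity term summed over all pairs of windows of the two
#' participating modes (forbidden configurations contribute zero). Strictly
#' positive whenever any activity is.
#'
#' @param model A [recognition_model()].
#' @param table A [count_table()] (or a character vector of variable
#'   regions, converted with unit counts).
#' @param columns Columns of the model's activity matrices to evaluate
#'   (default all).
#' @return Numeric matrix `n_probes x length(columns)` of `Z_bound` values.
#' @export
predict_zbound <- function(model, table, columns = seq_len(model$n_columns)) {
  if (is.character(table))
    table <- count_table(table, rep(1, length(table)))
  n <- length(table$seqs)
  designs <- lapply(model$modes, function(m)
    window_design(table, m$L, m$f, m$strands))
  weights <- Map(mode_window_weights, model$modes, designs)
  msums <- Map(function(m, d, w) mode_probe_sums(m, d, w),
               model$modes, designs, weights)
  isums <- lapply(model$interactions, function(it)
    coop_probe_sums(it, weights[[it$a]], weights[[it$b]],
                    designs[[it$a]], designs[[it$b]])$sum)
  Z <- matrix(0, n, length(columns))
  for (j in seq_along(columns)) {
    r <- columns[j]
    z <- if (is.null(model$log_alpha_ns)) numeric(n)
         else rep(exp(model$log_alpha_ns[r]), n)
    for (a in seq_along(model$modes))
      z <- z + exp(model$log_alpha[a, r]) * msums[[a]]
    for (k in seq_along(model$interactions))
      z <- z + exp(model$log_alpha_int[k, r]) * isums[[k]]
    Z[, j] <- z
  }
  colnames(Z) <- as.character(columns)
  Z
}

#' @rdname predict_zbound
#' @param probe A single variable-region sequence.
#' @param column Single column index.
#' @param left_flank,right_flank Constant flanks for the probe.
#' @export
partition_function <- function(model, probe, column = 1L,
                               left_flank = "", right_flank = "") {
  alph <- model$modes[[1L]]$alphabet
  tb <- count_table(probe, rep(1, length(probe)), left_flank, right_flank,
                    alphabet = alph)
  unname(drop(predict_zbound(model, tb, columns = column)))
}
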