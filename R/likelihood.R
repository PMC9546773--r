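#' Multinomial count log-likelihood
#'
#' The rescaled log-likelihood of a count table given predicted relative
#' frequencies: `sum(k[i,r] log p[r;i]) / k_total` with
#' `p[r;i] = eta_r f[i,r] / sum_r' eta_r' f[i,r']` (constant terms dropped,
#' sum over observed probes only). Invariant to rescaling all `eta` by a
#' common factor or any probe-wise rescaling of `f` — in particular to the
#' input-frequency normalization, so the initial library need not be random.
#'
#' @param counts Count matrix `n x R`.
#' @param f Predicted relative frequencies `n x R` (positive where counts
#'   are positive).
#' @param log_eta Per-column log depth-normalizers (length `R`).
#' @return Scalar log-likelihood (rescaled; constants dropped).
#' @export
count_loglik <- function(counts, f, log_eta = numeric(ncol(counts))) {
  counts <- as.matrix(counts); f <- as.matrix(f)
  if (any(f < 0)) stop("frequencies must be non-negative")
  if (any(f == 0 & counts > 0))
    stop("probe with zero predicted frequency but nonzero count (degenerate model)")
  log_ef <- sweep(log(f), 2L, log_eta, "+")
  M <- row_logsumexp(log_ef)
  sum(counts * (log_ef - M), na.rm = TRUE) / sum(counts)
}

row_logsumexp <- function(x) {
  m <- do.call(pmax, c(as.data.frame(x), na.rm = TRUE))
  m + log(rowSums(exp(x - m), na.rm = TRUE))
}

#' Poisson-form log-likelihood with analytically optimized input frequency
#'
#' The Poisson form `sum(k log(eta f) - eta f)/k_total` where each probe's
#' input frequency is profiled out analytically
#' (`f0* = sum_r k[i,r] / sum_r eta_r g[i,r]`, `g` the per-probe selection
#' shape). Equals the multinomial form up to a parameter-independent
#' constant; exposed mainly as an independent check of that identity.
#'
#' @param counts Count matrix.
#' @param g Selection shape `n x R`: the predicted frequencies with unit
#'   input frequency.
#' @param log_eta Per-column log depth-normalizers.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(counts, g, log_eta = numeric(ncol(counts))) {
  counts <- as.matrix(counts); g <- as.matrix(g)
  eta <- exp(log_eta)
  denom <- as.vector(g %*% eta)
  f0 <- rowSums(counts) / denom
  f <- (f0 * g)
  ef <- sweep(f, 2L, eta, "*")
  sum(counts * log(ef) - ef) / sum(counts)
}

#' Regularization settings
#'
#' Three terms stabilize the maximum-likelihood fit: a small L2 penalty on
#' the full parameter vector (weight `lambda`); a Dirichlet-inspired
#' pseudocount penalty of weight `k_dirichlet / k_total` on the softmax
#' feature probabilities within each feature class (letters at one
#' position, or letter pairs at one position pair); and an exponential
#' barrier at `|theta| = theta_max` that keeps the optimizer out of
#' numerically degenerate regions.
#'
#' @param lambda L2 weight (>= 0); default 1e-6.
#' @param k_dirichlet Pseudocount weight (>= 0).
#' @param theta_max Barrier location (default 40).
#' @return An object of class `"reg_spec"`.
#' @export
reg_spec <- function(lambda = 1e-6, k_dirichlet = 0, theta_max = 40) {
  stopifnot(lambda >= 0, k_dirichlet >= 0, theta_max > 0)
  structure(list(lambda = lambda, k_dirichlet = k_dirichlet,
                 theta_max = theta_max), class = "reg_spec")
}

#' Regularization penalty and its gradient
#'
#' `-lambda ||theta||^2 + (k_dirichlet / k_total) sum_phi log p(phi)
#'  - sum_i (e^(theta_i - theta_max) + e^(-theta_i - theta_max))`,
#' added to the log-likelihood before maximization.
#'
#' @param theta Parameter vector.
#' @param groups List of index vectors partitioning the feature entries of
#'   `theta` into same-class, same-position sets (the softmax groups).
#' @param spec A [reg_spec()].
#' @param k_total Total read count (scales the Dirichlet term).
#' @return List with elements `value` and `grad`.
#' @export
regularization_penalty <- function(theta, groups, spec, k_total = 1) {
  if (any(lengths(groups) == 0L)) stop("empty feature group")
  val <- -spec$lambda * sum(theta^2)
  grad <- -2 * spec$lambda * theta
  bp <- exp(theta - spec$theta_max)
  bm <- exp(-theta - spec$theta_max)
  val <- val - sum(bp + bm)
  grad <- grad - (bp - bm)
  if (spec$k_dirichlet > 0) {
    w <- spec$k_dirichlet / k_total
    for (g in groups) {
      b <- theta[g]
      ls <- max(b) + log(sum(exp(b - max(b))))
      val <- val + w * (sum(b) - length(b) * ls)
      p <- exp(b - ls)
      grad[g] <- grad[g] + w * (1 - length(b) * p)
    }
  }
  list(value = val, grad = grad)
}

#' Experiments: a count table wired to a selection model
#'
#' Binds a count table to a selection family and to the activity wiring
#' used when this experiment's likelihood is computed: which binding modes
#' are active, how their activities vary across columns, and any
#' transliteration (chemical-modification) rules applied to the probe
#' sequences before scoring.
#'
#' @param table A [count_table()].
#' @param selection A [selection_spec()] whose `n_columns` matches the table.
#' @param activity_tie `"free"` (independent per selected column),
#'   `"constant"` (one activity across columns) or `"global"` (one activity
#'   shared across experiments, times a fixed per-experiment scale — used
#'   for concentration series and time courses).
#' @param activity_scale Fixed multiplicative scale for `"global"` ties
#'   (e.g. the exposure time of this experiment).
#' @param include_ns Include the non-specific binding term.
#' @param ns_tie `"free"` or `"constant"` across selected columns.
#' @param active_modes Indices of the model's modes active here (default all).
#' @param transliterate Named character vector of transliteration rules
#'   applied to probe sequences for scoring (e.g. `c(CG = "cg")`).
#' @return An object of class `"pf_experiment"`.
#' @export
experiment <- function(table, selection, activity_tie = c("free", "constant", "global"),
                       activity_scale = 1, include_ns = TRUE,
                       ns_tie = c("free", "constant"),
                       active_modes = NULL, transliterate = NULL) {
  activity_tie <- match.arg(activity_tie)
  ns_tie <- match.arg(ns_tie)
  if (ncol(table$counts) != selection$n_columns)
    stop("table has ", ncol(table$counts), " columns but the selection spec expects ",
         selection$n_columns)
  score_table <- table
  if (!is.null(transliterate))
    score_table$seqs <- transliterate(table$seqs, transliterate)
  structure(list(table = table, score_table = score_table,
                 selection = selection, activity_tie = activity_tie,
                 activity_scale = activity_scale, include_ns = include_ns,
                 ns_tie = ns_tie, active_modes = active_modes,
                 rules = transliterate,
                 k_total = sum(table$counts)),
            class = "pf_experiment")
}

# ---------------------------------------------------------------------------
# Parameter layout: pack the free parameters of (model, experiments) into a
# flat theta vector with per-entry frozen flags and Dirichlet groups.
# Block ids:
#   mode<m>.mono / mode<m>.pair<k> / mode<m>.bias
#   int<k>.omega
#   global.act<m> (global-tie activities), global.actint<k>
#   exp<e>.eta / exp<e>.ns / exp<e>.act<m> / exp<e>.actint<k>
# ---------------------------------------------------------------------------
build_layout <- function(model, experiments) {
  blocks <- list()
  add <- function(id, init, frozen = FALSE) {
    blocks[[id]] <<- list(init = as.numeric(init),
                          frozen = rep(frozen, length(init)))
  }
  for (m in seq_along(model$modes)) {
    mo <- model$modes[[m]]
    add(sprintf("mode%d.mono", m), as.vector(mo$beta_mono))
    if (nrow(mo$pairs))
      for (k in seq_len(nrow(mo$pairs)))
        add(sprintf("mode%d.pair%d", m, k), as.vector(mo$beta_pair[[k]]))
    if (!is.null(mo$position_bias))
      add(sprintf("mode%d.bias", m), as.vector(mo$position_bias))
  }
  for (k in seq_along(model$interactions)) {
    it <- model$interactions[[k]]
    if (it$translational_tie) add(sprintf("int%d.omega", k), c(0, 0))
    else {
      keep <- coop_free_cells(it)
      add(sprintf("int%d.omega", k), it$log_omega[keep])
    }
  }
  # global-tie activities shared across experiments
  any_global <- any(vapply(experiments, function(e) e$activity_tie == "global", TRUE))
  if (any_global) {
    for (m in seq_along(model$modes)) add(sprintf("global.act%d", m), 0)
    for (k in seq_along(model$interactions)) add(sprintf("global.actint%d", k), 0)
  }
  for (e in seq_along(experiments)) {
    ex <- experiments[[e]]
    R <- ncol(ex$table$counts)
    zc <- z_columns(ex$selection)
    eta <- numeric(R); fr <- c(TRUE, rep(FALSE, R - 1L))  # eta gauge: column 1
    blocks[[sprintf("exp%d.eta", e)]] <- list(init = eta, frozen = fr)
    if (ex$include_ns)
      add(sprintf("exp%d.ns", e),
          numeric(if (ex$ns_tie == "constant") 1L else length(zc)))
    if (ex$activity_tie != "global") {
      nact <- if (ex$activity_tie == "constant") 1L else length(zc)
      for (m in active_mode_set(model, ex))
        add(sprintf("exp%d.act%d", e, m), numeric(nact))
      for (k in active_int_set(model, ex))
        add(sprintf("exp%d.actint%d", e, k), numeric(nact))
    }
  }
  sizes <- vapply(blocks, function(b) length(b$init), 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  idx <- Map(function(s, e) seq.int(s, e), starts, ends)
  names(idx) <- names(blocks)
  theta <- unlist(lapply(blocks, `[[`, "init"), use.names = FALSE)
  frozen <- unlist(lapply(blocks, `[[`, "frozen"), use.names = FALSE)
  # Dirichlet groups: per-position letter classes and per-pair classes
  groups <- list()
  A <- n_letters(model$modes[[1L]]$alphabet)
  for (m in seq_along(model$modes)) {
    mo <- model$modes[[m]]
    base <- idx[[sprintf("mode%d.mono", m)]]
    for (p in seq_len(mo$L))
      groups[[length(groups) + 1L]] <- base[(p - 1L) * A + seq_len(A)]
    if (nrow(mo$pairs))
      for (k in seq_len(nrow(mo$pairs)))
        groups[[length(groups) + 1L]] <- idx[[sprintf("mode%d.pair%d", m, k)]]
  }
  list(idx = idx, theta = theta, frozen = frozen, groups = groups)
}

coop_free_cells <- function(it) {
  S <- it$max_spacing
  d <- matrix(rep(seq(-S, S), each = 2L), 2L)
  abs(d) >= it$clash
}

active_mode_set <- function(model, ex) {
  if (is.null(ex$active_modes)) seq_along(model$modes) else ex$active_modes
}
active_int_set <- function(model, ex) {
  act <- active_mode_set(model, ex)
  which(vapply(model$interactions,
               function(it) it$a %in% act && it$b %in% act, TRUE))
}

# Reconstruct model + per-experiment activity matrices from theta
unpack_theta <- function(theta, model, experiments, layout) {
  gx <- function(id) theta[layout$idx[[id]]]
  A <- n_letters(model$modes[[1L]]$alphabet)
  for (m in seq_along(model$modes)) {
    mo <- model$modes[[m]]
    mo$beta_mono <- matrix(gx(sprintf("mode%d.mono", m)), A, mo$L,
                           dimnames = list(mo$alphabet$letters, NULL))
    if (nrow(mo$pairs))
      for (k in seq_len(nrow(mo$pairs)))
        mo$beta_pair[[k]] <- matrix(gx(sprintf("mode%d.pair%d", m, k)), A, A)
    if (!is.null(mo$position_bias))
      mo$position_bias <- matrix(gx(sprintf("mode%d.bias", m)),
                                 nrow(mo$position_bias), 2L)
    if (mo$rc_symmetric) mo <- symmetrize_mode(mo)
    model$modes[[m]] <- mo
  }
  for (k in seq_along(model$interactions)) {
    it <- model$interactions[[k]]
    v <- gx(sprintf("int%d.omega", k))
    if (it$translational_tie) {
      lo <- it$log_omega; lo[1L, ] <- v[1L]; lo[2L, ] <- v[2L]
      keep <- coop_free_cells(it); lo[!keep] <- 0
      it$log_omega <- lo
    } else {
      lo <- it$log_omega
      lo[coop_free_cells(it)] <- v
      it$log_omega <- lo
    }
    model$interactions[[k]] <- it
  }
  # per-experiment activity matrices over that experiment's z-columns
  acts <- vector("list", length(experiments))
  for (e in seq_along(experiments)) {
    ex <- experiments[[e]]
    zc <- z_columns(ex$selection)
    ams <- active_mode_set(model, ex)
    la <- matrix(-Inf, length(model$modes), length(zc))
    for (m in ams) {
      la[m, ] <- if (ex$activity_tie == "global")
        gx(sprintf("global.act%d", m)) + log(ex$activity_scale)
      else rep_len(gx(sprintf("exp%d.act%d", e, m)), length(zc))
    }
    ints <- active_int_set(model, ex)
    li <- if (length(model$interactions))
      matrix(-Inf, length(model$interactions), length(zc)) else NULL
    for (k in ints) {
      li[k, ] <- if (ex$activity_tie == "global")
        gx(sprintf("global.actint%d", k)) + 2 * log(ex$activity_scale)
      else rep_len(gx(sprintf("exp%d.actint%d", e, k)), length(zc))
    }
    lns <- if (ex$include_ns) rep_len(gx(sprintf("exp%d.ns", e)), length(zc)) else NULL
    acts[[e]] <- list(log_alpha = la, log_alpha_int = li, log_ns = lns,
                      log_eta = gx(sprintf("exp%d.eta", e)))
  }
  list(model = model, acts = acts)
}
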