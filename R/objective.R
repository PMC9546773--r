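# Joint penalized log-likelihood objective with analytic gradient.
#
# make_objective() precomputes the window designs once per experiment and
# returns closures evaluating the objective (to be MAXIMIZED) and its exact
# gradient over the packed parameter vector. The gradient follows the chain
# rule through partition function -> selection factors -> multinomial
# column probabilities; a finite-difference check lives in the test suite.

make_objective <- function(model, experiments, reg = reg_spec()) {
  layout <- build_layout(model, experiments)
  alph <- model$modes[[1L]]$alphabet
  for (ex in experiments) {
    if (!identical(ex$table$alphabet$letters, alph$letters))
      stop("experiments and model use inconsistent alphabets")
  }
  designs <- lapply(experiments, function(ex)
    lapply(model$modes, function(m)
      window_design(ex$score_table, m$L, m$f, m$strands)))
  n_exp <- length(experiments)

  eval_all <- function(theta, want_grad = TRUE) {
    up <- unpack_theta(theta, model, experiments, layout)
    md <- up$model
    A <- n_letters(alph)
    total <- 0
    grad <- if (want_grad) numeric(length(theta)) else NULL
    gadd <- function(id, v) {
      ii <- layout$idx[[id]]
      grad[ii] <<- grad[ii] + v
    }
    for (e in seq_len(n_exp)) {
      ex <- experiments[[e]]
      act <- up$acts[[e]]
      des <- designs[[e]]
      counts <- ex$table$counts
      n <- nrow(counts); R <- ncol(counts)
      ktot <- ex$k_total
      sel <- ex$selection
      zc <- z_columns(sel)
      ams <- active_mode_set(md, ex)
      ints <- active_int_set(md, ex)
      w <- vector("list", length(md$modes))
      msum <- vector("list", length(md$modes))
      for (m in ams) {
        w[[m]] <- mode_window_weights(md$modes[[m]], des[[m]])
        msum[[m]] <- accum_by(w[[m]], des[[m]]$probe, n)
      }
      cps <- vector("list", length(md$interactions))
      for (k in ints) {
        it <- md$interactions[[k]]
        cps[[k]] <- coop_probe_sums(it, w[[it$a]], w[[it$b]],
                                    des[[it$a]], des[[it$b]],
                                    want_cells = want_grad)
      }
      nz <- length(zc)
      Z <- matrix(0, n, nz)
      for (j in seq_len(nz)) {
        z <- if (!is.null(act$log_ns)) rep(exp(act$log_ns[j]), n) else numeric(n)
        for (m in ams) z <- z + exp(act$log_alpha[m, j]) * msum[[m]]
        for (k in ints) z <- z + exp(act$log_alpha_int[k, j]) * cps[[k]]$sum
        Z[, j] <- z
      }
      # selection log-factors per z-column, then cumulative/flat assembly
      lgz <- matrix(0, n, nz)
      dldz <- matrix(0, n, nz)    # d lg / dZ
      for (j in seq_len(nz)) {
        r <- zc[j]
        if (sel$family == "cumulative") {
          lgz[, j] <- sel$rho * log(Z[, j]) + sel$gamma * log1p(Z[, j])
          dldz[, j] <- sel$rho / Z[, j] + sel$gamma / (1 + Z[, j])
        } else if (sel$family == "non_cumulative") {
          lgz[, j] <- sel$rho[r] * log(Z[, j]) + sel$gamma[r] * log1p(Z[, j])
          dldz[, j] <- sel$rho[r] / Z[, j] + sel$gamma[r] / (1 + Z[, j])
        } else {
          lgz[, j] <- kinetic_logfactor(Z[, j], sel$delta[r])
          dldz[, j] <- kinetic_dlog(Z[, j], sel$delta[r])
        }
      }
      G <- matrix(0, n, R)
      if (sel$family == "cumulative") {
        for (r in seq_len(R)[-1L]) {
          j <- match(r, zc)
          G[, r] <- G[, r - 1L] + if (!is.na(j)) lgz[, j] else 0
        }
      } else {
        for (j in seq_len(nz)) G[, zc[j]] <- lgz[, j]
      }
      log_ef <- sweep(G, 2L, act$log_eta, "+")
      M <- row_logsumexp(log_ef)
      P <- exp(log_ef - M)
      total <- total + sum(counts * (log_ef - M)) / ktot
      if (!want_grad) next
      resid <- (counts - rowSums(counts) * P) / ktot
      gadd(sprintf("exp%d.eta", e), colSums(resid))
      # u[, j]: coefficient of dZ[, j]
      u <- matrix(0, n, nz)
      if (sel$family == "cumulative") {
        Ctail <- resid                      # Ctail[, r] = rowSums(resid[, r:R])
        for (r in rev(seq_len(R))[-1L])
          Ctail[, r] <- Ctail[, r] + Ctail[, r + 1L]
        for (j in seq_len(nz)) u[, j] <- Ctail[, zc[j]] * dldz[, j]
      } else {
        for (j in seq_len(nz)) u[, j] <- resid[, zc[j]] * dldz[, j]
      }
      if (!is.null(act$log_ns)) {
        gns <- vapply(seq_len(nz), function(j) exp(act$log_ns[j]) * sum(u[, j]), 1)
        gadd(sprintf("exp%d.ns", e),
             if (ex$ns_tie == "constant") sum(gns) else gns)
      }
      # per-mode window weights accumulated over columns and interactions
      ww <- vector("list", length(md$modes))
      for (m in ams) {
        v <- numeric(n)
        galpha <- numeric(nz)
        for (j in seq_len(nz)) {
          am <- exp(act$log_alpha[m, j])
          v <- v + u[, j] * am
          galpha[j] <- am * sum(u[, j] * msum[[m]])
        }
        add_activity_grad(gadd, galpha, ex, e, sprintf("act%d", m),
                          sprintf("global.act%d", m))
        ww[[m]] <- w[[m]] * v[des[[m]]$probe]
      }
      for (k in ints) {
        it <- md$interactions[[k]]
        vint <- numeric(n)
        galpha <- numeric(nz)
        for (j in seq_len(nz)) {
          ai <- exp(act$log_alpha_int[k, j])
          vint <- vint + u[, j] * ai
          galpha[j] <- ai * sum(u[, j] * cps[[k]]$sum)
        }
        add_activity_grad(gadd, galpha, ex, e, sprintf("actint%d", k),
                          sprintf("global.actint%d", k), global_power = 2)
        cg <- coop_grads(it, w[[it$a]], w[[it$b]], des[[it$a]], des[[it$b]], vint)
        ww[[it$a]] <- ww[[it$a]] + cg$ga
        ww[[it$b]] <- ww[[it$b]] + cg$gb
        gadd(sprintf("int%d.omega", k), cg$gomega)
      }
      for (m in ams) {
        mo <- md$modes[[m]]
        d <- des[[m]]
        gm <- matrix(0, A, mo$L)
        for (p in seq_len(mo$L)) gm[, p] <- accum_by(ww[[m]], d$idx[, p], A)
        gps <- NULL
        if (nrow(mo$pairs)) {
          gps <- vector("list", nrow(mo$pairs))
          for (k in seq_len(nrow(mo$pairs))) {
            x1 <- mo$pairs[k, 1L]; x2 <- mo$pairs[k, 2L]
            flat <- d$idx[, x1] + (d$idx[, x2] - 1L) * A
            gps[[k]] <- matrix(accum_by(ww[[m]], flat, A * A), A, A)
          }
        }
        if (mo$rc_symmetric) {
          carrier <- mo; carrier$beta_mono <- gm
          if (!is.null(gps)) carrier$beta_pair <- gps
          carrier <- symmetrize_mode(carrier)
          gm <- carrier$beta_mono
          if (!is.null(gps)) gps <- carrier$beta_pair
        }
        gadd(sprintf("mode%d.mono", m), as.vector(gm))
        if (!is.null(gps))
          for (k in seq_along(gps))
            gadd(sprintf("mode%d.pair%d", m, k), as.vector(gps[[k]]))
        if (!is.null(mo$position_bias)) {
          gb <- matrix(0, nrow(mo$position_bias), 2L)
          for (b in d$blocks) {
            o <- min(max(b$fwd + 1L, 1L), nrow(gb))
            cc <- if (b$strand > 0) 1L else 2L
            gb[o, cc] <- gb[o, cc] + sum(ww[[m]][b$first:b$last])
          }
          gadd(sprintf("mode%d.bias", m), as.vector(gb))
        }
      }
    }
    # penalties (per experiment, then summed)
    pen_val <- 0
    pen_grad <- if (want_grad) numeric(length(theta)) else NULL
    for (e in seq_len(n_exp)) {
      pen <- regularization_penalty(theta, layout$groups, reg,
                                    k_total = experiments[[e]]$k_total)
      pen_val <- pen_val + pen$value
      if (want_grad) pen_grad <- pen_grad + pen$grad
    }
    total <- total + pen_val
    if (want_grad) grad <- grad + pen_grad
    list(value = total, grad = grad)
  }

  cache <- new.env(parent = emptyenv())
  full_eval <- function(theta) {
    key <- theta
    if (!is.null(cache$theta) && identical(cache$theta, key)) return(cache$res)
    res <- eval_all(theta, want_grad = TRUE)
    cache$theta <- key; cache$res <- res
    res
  }
  list(
    layout = layout,
    fn = function(theta) full_eval(theta)$value,
    gr = function(theta) full_eval(theta)$grad,
    value_only = function(theta) eval_all(theta, want_grad = FALSE)$value,
    unpack = function(theta) unpack_theta(theta, model, experiments, layout)
  )
}

add_activity_grad <- function(gadd, galpha, ex, e, local_id, global_id,
                              global_power = 1) {
  if (ex$activity_tie == "global") {
    gadd(global_id, sum(galpha))
  } else if (ex$activity_tie == "constant") {
    gadd(sprintf("exp%d.%s", e, local_id), sum(galpha))
  } else {
    gadd(sprintf("exp%d.%s", e, local_id), galpha)
  }
}

# Window-level gradients through the cooperativity term: for every allowed
# block pair, the doubly-bound Boltzmann weight contributes to both member
# windows' effective weights and to its own log-omega cell.
coop_grads <- function(coop, wa, wb, da, db, vint) {
  ga <- numeric(length(wa))
  gb <- numeric(length(wb))
  S <- coop$max_spacing
  gom <- matrix(0, 2L, 2L * S + 1L)
  fa <- da$f; fb <- db$f
  for (ba in da$blocks) {
    ia <- seq.int(ba$first, ba$last)
    for (bb in db$blocks) {
      if (ba$n != bb$n || ba$rows[1L] != bb$rows[1L]) next
      ib <- seq.int(bb$first, bb$last)
      d <- (bb$fwd - fb) - (ba$fwd - fa)
      par <- ba$strand == bb$strand
      lo <- coop_logomega(coop, d, par)
      if (!is.finite(lo)) next
      contrib <- exp(lo) * wa[ia] * wb[ib] * vint[ba$rows]
      ga[ia] <- ga[ia] + contrib
      gb[ib] <- gb[ib] + contrib
      row <- if (par) 1L else 2L
      gom[row, d + S + 1L] <- gom[row, d + S + 1L] + sum(contrib)
    }
  }
  gomega <- if (coop$translational_tie) rowSums(gom)
            else gom[coop_free_cells(coop)]
  list(ga = ga, gb = gb, gomega = gomega)
}

#' Joint multi-experiment objective
#'
#' The total objective `sum_e log L_e + penalties` and its exact gradient,
#' evaluated at the parameters currently stored in the model and
#' experiments. Mainly a building block for [probefit()], exposed for
#' diagnostics and testing.
#'
#' @param experiments List of [experiment()]s (a single experiment is
#'   wrapped automatically).
#' @param model A [recognition_model()].
#' @param reg A [reg_spec()].
#' @return List with `value`, `grad` (over the packed parameter vector) and
#'   `layout` describing the packing.
#' @export
joint_objective <- function(experiments, model, reg = reg_spec()) {
  if (inherits(experiments, "pf_experiment")) experiments <- list(experiments)
  obj <- make_objective(model, experiments, reg)
  th <- obj$layout$theta
  res <- list(value = obj$fn(th), grad = obj$gr(th), layout = obj$layout)
  res
}
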