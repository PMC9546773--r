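#' @export
print.probefit <- function(x, ...) {
  cat("Sequence-recognition model fit\n")
  cat("  modes:", length(x$model$modes),
      " interactions:", length(x$model$interactions),
      " experiments:", length(x$experiments), "\n")
  cat("  penalized objective:", format(x$objective, digits = 8),
      "  logLik:", format(x$logLik, digits = 8), "\n")
  for (m in seq_along(x$gauged)) {
    g <- x$gauged[[m]]
    cat(sprintf("  mode %d: L=%d f=%d consensus %s (%.2f bits)\n",
                m, g$L, g$f, g$reference, information_content(g)))
  }
  invisible(x)
}

#' Summarize a recognition-model fit
#'
#' Reports per-mode footprints, consensus sequences, information content,
#' fitted activities and depth normalizers, and the likelihood trace.
#'
#' @param object A [probefit()] result.
#' @param ... Unused.
#' @export
summary.probefit <- function(object, ...) {
  modes <- do.call(rbind, lapply(seq_along(object$gauged), function(m) {
    g <- object$gauged[[m]]
    data.frame(mode = m, L = g$L, f = g$f, strands = g$strands,
               consensus = g$reference,
               bits = information_content(g),
               max_ddG = max(-g$beta_mono))
  }))
  acts <- lapply(seq_along(object$acts), function(e) {
    a <- object$acts[[e]]
    list(log_eta = a$log_eta, log_alpha = a$log_alpha, log_ns = a$log_ns)
  })
  out <- list(modes = modes, activities = acts, logLik = object$logLik,
              objective = object$objective, trace = object$trace)
  class(out) <- "summary.probefit"
  out
}

#' @export
print.summary.probefit <- function(x, ...) {
  cat("Mode summary:\n"); print(x$modes, row.names = FALSE)
  cat("logLik:", format(x$logLik, digits = 8), "\n")
  invisible(x)
}

#' Extract gauged energy coefficients
#'
#' Returns the mismatch-gauged monomer coefficient matrix of one mode
#' (`-ddG/RT` per letter and position; reference letters have coefficient
#' zero), or a list of all modes.
#'
#' @param object A [probefit()] result.
#' @param mode Mode index, or `NULL` for all.
#' @param ... Unused.
#' @export
coef.probefit <- function(object, mode = 1L, ...) {
  if (is.null(mode)) lapply(object$gauged, `[[`, "beta_mono")
  else object$gauged[[mode]]$beta_mono
}

#' @export
logLik.probefit <- function(object, ...) {
  structure(object$logLik, class = "logLik",
            df = sum(!object$layout$frozen), nobs = sum(vapply(
              object$experiments, function(e) e$k_total, 1)))
}

#' Predict from a fitted recognition model
#'
#' @param object A [probefit()] result.
#' @param newdata New probe sequences (character vector or [count_table()]);
#'   default: the probes of the chosen experiment's table.
#' @param type `"zbound"` (partition function per column), `"affinity"`
#'   (window-sum relative affinity of mode 1, activity-free), `"frequency"`
#'   (predicted relative library frequencies), or `"counts"` (expected
#'   counts given the observed per-probe totals).
#' @param experiment Experiment index.
#' @param ... Unused.
#' @return Vector or matrix over probes.
#' @export
predict.probefit <- function(object, newdata = NULL,
                             type = c("zbound", "affinity", "frequency",
                                      "counts"),
                             experiment = 1L, ...) {
  type <- match.arg(type)
  ex <- object$experiments[[experiment]]
  tb <- if (is.null(newdata)) ex$score_table
        else if (is.character(newdata))
          count_table(newdata, rep(1, length(newdata)),
                      ex$table$left_flank, ex$table$right_flank,
                      alphabet = ex$table$alphabet)
        else newdata
  up <- list(model = object$model, acts = object$acts)
  ex2 <- ex; ex2$table <- tb; ex2$score_table <- tb
  if (type == "affinity") {
    mo <- object$model$modes[[1L]]
    d <- window_design(tb, mo$L, mo$f, mo$strands)
    return(mode_probe_sums(mo, d))
  }
  Z <- experiment_zbound(up, ex2, experiment)
  if (type == "zbound") return(Z)
  f <- predict_frequencies(Z, ex$selection, f0 = 1)
  if (type == "frequency") return(f)
  # expected counts: multinomial expectation given each probe's total
  log_ef <- sweep(log(f), 2L, object$acts[[experiment]]$log_eta, "+")
  P <- exp(log_ef - row_logsumexp(log_ef))
  if (!is.null(newdata)) stop("type = 'counts' predicts the fitted table only")
  rowSums(ex$table$counts) * P
}

#' Residuals of a recognition-model fit
#'
#' Pearson residuals `(k - E) / sqrt(E)` of observed counts against the
#' multinomial expectation per probe and column.
#'
#' @param object A [probefit()] result.
#' @param experiment Experiment index.
#' @param ... Unused.
#' @export
residuals.probefit <- function(object, experiment = 1L, ...) {
  E <- predict(object, type = "counts", experiment = experiment)
  k <- object$experiments[[experiment]]$table$counts
  (k - E) / sqrt(pmax(E, .Machine$double.eps))
}

#' Plot a fitted energy logo
#'
#' @param x A [probefit()] result.
#' @param mode Mode index.
#' @param ... Unused.
#' @export
plot.probefit <- function(x, mode = 1L, ...) {
  plot_energy_logo(x$gauged[[mode]])
}

#' Simulate count tables from a fitted model
#'
#' Draws new count tables from the fitted recognition model under the
#' experiment's own selection spec and sequencing depths (a parametric
#' bootstrap of the experiment).
#'
#' @param object A [probefit()] result.
#' @param nsim Number of replicate tables.
#' @param seed RNG seed.
#' @param experiment Experiment index.
#' @param ... Unused.
#' @return A list of [count_table()]s (length `nsim`).
#' @export
simulate.probefit <- function(object, nsim = 1, seed = 1L,
                              experiment = 1L, ...) {
  ex <- object$experiments[[experiment]]
  up <- list(model = object$model, acts = object$acts)
  Z <- experiment_zbound(up, ex, experiment)
  f <- predict_frequencies(Z, ex$selection,
                           f0 = rowSums(ex$table$counts) / ex$k_total)
  depth <- round(column_totals(ex$table))
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  lapply(seq_len(nsim), function(i)
    sample_table(ex$table$seqs, f, depth, ex$table))
}

# multinomial sampling of one table realization given frequencies f
sample_table <- function(seqs, f, depth, template) {
  counts <- matrix(0, length(seqs), ncol(f))
  for (r in seq_len(ncol(f))) {
    p <- f[, r]
    if (all(is.na(p))) next
    counts[, r] <- stats::rmultinom(1L, depth[r], p / sum(p))
  }
  count_table(seqs, counts, template$left_flank, template$right_flank,
              template$alphabet, col_labels = colnames(template$counts),
              metadata = template$metadata)
}
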