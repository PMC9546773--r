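#' Count k-mers in a library column
#'
#' Tabulates every length-`k` subsequence of the variable regions, weighted
#' by read counts, over the complete k-mer space of the alphabet.
#'
#' @param table A [count_table()].
#' @param k Word length.
#' @param column Column index.
#' @return Named numeric vector over all `A^k` k-mers.
#' @export
count_kmers <- function(table, k, column = 1L) {
  if (any(nchar(table$seqs) < k)) stop("k exceeds the shortest probe")
  space <- enumerate_library(k, table$alphabet)$seqs
  out <- stats::setNames(numeric(length(space)), space)
  lens <- nchar(table$seqs)
  for (len in unique(lens)) {
    ii <- which(lens == len)
    nw <- len - k + 1L
    for (o in seq_len(nw)) {
      km <- substr(table$seqs[ii], o, o + k - 1L)
      agg <- rowsum(table$counts[ii, column], km)
      out[rownames(agg)] <- out[rownames(agg)] + agg[, 1L]
    }
  }
  out
}

#' Enrichment-based dataset filter
#'
#' Screens a multi-round table for usable selection signal: tabulates
#' 5-mer frequencies per round (pseudocount 5 over the full 5-mer space)
#' and computes, for every pair of rounds with at least `min_reads` reads,
#' the round-distance-rescaled Kullback-Leibler divergence
#' `D_KL(r2, r1) = 1/(r2-r1) sum_k p(k, r2) log2(p(k, r2)/p(k, r1))`.
#' The table passes when any pair exceeds `threshold`. Additional coverage
#' rules: at least two rounds with `min_reads` reads, and at least one
#' such round before round three.
#'
#' @param table A [count_table()] (column order = round order, first
#'   column round 0).
#' @param k Word length (default 5).
#' @param pseudocount Added to every k-mer count (default 5).
#' @param threshold Divergence threshold (default 0.01).
#' @param min_reads Per-round coverage floor (default 10000).
#' @return List with `kl` (data.frame of round pairs and divergences),
#'   `pass`, and `reason` when failing.
#' @export
kl_enrichment_filter <- function(table, k = 5, pseudocount = 5,
                                 threshold = 0.01, min_reads = 1e4) {
  tot <- column_totals(table)
  elig <- which(tot >= min_reads)
  if (length(elig) < 2L)
    return(list(kl = NULL, pass = FALSE,
                reason = "fewer than two rounds with enough reads"))
  if (!any(elig <= 3L))
    return(list(kl = NULL, pass = FALSE,
                reason = "no adequately sequenced round before round three"))
  km <- lapply(elig, function(r) {
    cnt <- count_kmers(table, k, r) + pseudocount
    cnt / sum(cnt)
  })
  pairs <- utils::combn(seq_along(elig), 2L)
  kl <- data.frame(r1 = elig[pairs[1L, ]], r2 = elig[pairs[2L, ]],
                   d_kl = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    p1 <- km[[pairs[1L, i]]]; p2 <- km[[pairs[2L, i]]]
    kl$d_kl[i] <- sum(p2 * log2(p2 / p1)) / (kl$r2[i] - kl$r1[i])
  }
  pass <- any(kl$d_kl > threshold)
  list(kl = kl, pass = pass,
       reason = if (pass) NULL else "no round pair exceeds the divergence threshold")
}

#' Observed and predicted k-mer enrichment
#'
#' Per-k-mer log enrichment between the first and last rounds,
#' `f(k) = log((1 + n(k, last)) / (1 + n(k, first))) / (last - first)`,
#' computed on an observed table and a predicted table, with the squared
#' Pearson correlation between the two.
#'
#' @param observed,predicted [count_table()]s (predicted counts may be
#'   non-integer expectations).
#' @param k Word length (default 8).
#' @param first,last Round (column) indices; default first and last column.
#' @return List with `f_obs`, `f_pred` (named vectors) and `r2`.
#' @export
kmer_enrichment <- function(observed, predicted, k = 8,
                            first = 1L, last = ncol(observed$counts)) {
  f_of <- function(tb) {
    n1 <- count_kmers(tb, k, first)
    n2 <- count_kmers(tb, k, last)
    log((1 + n2) / (1 + n1)) / (last - first)
  }
  fo <- f_of(observed); fp <- f_of(predicted)
  list(f_obs = fo, f_pred = fp, r2 = stats::cor(fo, fp)^2)
}

#' Binned enrichment agreement metrics
#'
#' For each pair of subsequent, adequately sequenced rounds, probes are
#' sorted by predicted enrichment and divided into bins holding about
#' `bin_target` observed reads (summed over the two rounds); per-bin
#' observed and predicted log enrichments (pseudocount 1) are compared.
#' Returns the best-round-pair coefficient of determination between
#' observed and predicted binned enrichments, and the largest observed
#' enrichment fold range across bins.
#'
#' @param observed,predicted [count_table()]s with matching probes.
#' @param bin_target Observed reads per bin (default 1000).
#' @param min_reads Rounds with fewer reads are ignored (default 10000).
#' @return List with `r2_affinity`, `fold_range`, and the per-pair bin
#'   tables.
#' @export
binned_enrichment_metrics <- function(observed, predicted, bin_target = 1000,
                                      min_reads = 1e4) {
  tot <- column_totals(observed)
  elig <- which(tot >= min_reads)
  pairs <- elig[which(diff(elig) >= 1L)]
  if (length(elig) < 2L)
    return(list(r2_affinity = NA_real_, fold_range = NA_real_, bins = NULL,
                flagged = "no eligible round pair"))
  best_r2 <- -Inf; best_fr <- -Inf; bins_out <- list()
  for (i in seq_len(length(elig) - 1L)) {
    r <- elig[i]; nr <- elig[i + 1L]
    pe <- log((1 + predicted$counts[, nr]) / (1 + predicted$counts[, r]))
    ord <- order(pe, seq_along(pe))
    wt <- observed$counts[ord, r] + observed$counts[ord, nr]
    bin <- cumulative_bins(wt, bin_target)
    fo <- fp <- numeric(max(bin))
    for (b in seq_len(max(bin))) {
      ii <- ord[bin == b]
      fo[b] <- log((1 + sum(observed$counts[ii, nr])) /
                   (1 + sum(observed$counts[ii, r]))) / (nr - r)
      fp[b] <- log((1 + sum(predicted$counts[ii, nr])) /
                   (1 + sum(predicted$counts[ii, r]))) / (nr - r)
    }
    if (length(fo) >= 2L && stats::sd(fo) > 0 && stats::sd(fp) > 0) {
      r2 <- r_squared(fo, fp)
      best_r2 <- max(best_r2, r2)
    }
    best_fr <- max(best_fr, exp(max(fo) - min(fo)))
    bins_out[[paste(r, nr, sep = "-")]] <- data.frame(f_obs = fo, f_pred = fp)
  }
  list(r2_affinity = if (is.finite(best_r2)) best_r2 else NA_real_,
       fold_range = best_fr, bins = bins_out)
}

cumulative_bins <- function(weights, target) {
  cw <- cumsum(weights)
  pmin(floor(cw / target) + 1L, max(1L, ceiling(sum(weights) / target)))
}

# coefficient of determination of y against x (1 - SS_res/SS_tot via the
# least-squares line is just squared Pearson correlation; used as such)
r_squared <- function(x, y) stats::cor(x, y)^2

#' Quality score for ranking binding modes
#'
#' `r2_mode + log(I_mono)`: the squared Pearson correlation (across
#' probes) between the log affinity predicted by the single mode plus the
#' non-specific term and the log prediction of the full model, plus the
#' log information content of the mismatch-gauged monomer coefficients.
#' High for the mode that carries the specificity of the full fit; low for
#' flat sequence-bias modes (low information) and contamination modes
#' (low correlation with the full prediction). Zero-information modes
#' score `-Inf` and rank last.
#'
#' @param fit A [probefit()] result.
#' @param mode Mode index.
#' @param experiment Experiment index.
#' @return The scalar score.
#' @export
mode_quality_score <- function(fit, mode = 1L, experiment = 1L) {
  ex <- fit$experiments[[experiment]]
  up <- list(model = fit$model, acts = fit$acts)
  zc <- z_columns(ex$selection)
  Zfull <- experiment_zbound(up, ex, experiment)[, zc[1L]]
  mo <- fit$model$modes[[mode]]
  d <- window_design(ex$score_table, mo$L, mo$f, mo$strands)
  msum <- mode_probe_sums(mo, d)
  a <- exp(fit$acts[[experiment]]$log_alpha[mode, 1L])
  ns <- if (!is.null(fit$acts[[experiment]]$log_ns))
    exp(fit$acts[[experiment]]$log_ns[1L]) else 0
  Zmode <- ns + a * msum
  ic <- information_content(fit$gauged[[mode]])
  if (ic <= 0) return(-Inf)
  r2 <- stats::cor(log(Zmode), log(Zfull))^2
  r2 + log(ic)
}

#' Logistic and log threshold maps
#'
#' Strictly increasing maps of a metric onto the unit interval with the
#' threshold `x0` mapped to exactly 0.5: `F_logit` compares on the logit
#' scale (for metrics already in (0,1)), `F_log` on the log scale (for
#' fold-range-type metrics).
#'
#' @param x Metric value.
#' @param x0 Threshold mapped to 0.5.
#' @export
f_logit <- function(x, x0) stats::plogis(stats::qlogis(x) - stats::qlogis(x0))

#' @rdname f_logit
#' @export
f_log <- function(x, x0) stats::plogis(log(x) - log(x0))

#' Composite training-performance score
#'
#' The mean of six threshold-mapped sub-scores of model performance on the
#' training data: 8-mer enrichment correlation (threshold 0.5), binned
#' affinity R^2 (0.95), affinity fold range (5.0), saturation-transformed
#' scoring R^2 (0.95), the meaningful affinity fold range MAFR (5.0) and
#' the monomer information content in bits (3.0). Missing sub-metrics are
#' excluded from the mean and flagged. A model sitting exactly at every
#' threshold scores 0.5.
#'
#' @param metrics Named list/vector with any of `r2_8mer`, `r2_affinity`,
#'   `fold_range`, `r2_scoring`, `mafr`, `i_mono`.
#' @return List with `score`, the mapped `sub_scores` and `missing` names.
#' @export
training_score <- function(metrics) {
  spec <- list(r2_8mer = c("logit", 0.5), r2_affinity = c("logit", 0.95),
               fold_range = c("log", 5.0), r2_scoring = c("logit", 0.95),
               mafr = c("log", 5.0), i_mono = c("log", 3.0))
  sub <- c(); missing <- character()
  for (nm in names(spec)) {
    x <- metrics[[nm]]
    if (is.null(x) || is.na(x)) { missing <- c(missing, nm); next }
    x0 <- as.numeric(spec[[nm]][2L])
    sub[nm] <- if (spec[[nm]][1L] == "logit") f_logit(x, x0) else f_log(x, x0)
  }
  if (!length(sub)) stop("no sub-metrics available")
  list(score = mean(sub), sub_scores = sub, missing = missing)
}

#' Saturation-transform fit of predicted affinity against signal
#'
#' Fits `yhat = b0 / (1 + (bC (x + bNSB))^-1)` to binned
#' (predicted affinity, signal) pairs, correcting for binding saturation
#' and non-specific background before quantifying agreement. The loss is
#' squared log-ratio for sequencing-derived signals (`b0, bNSB > 0`) or
#' squared difference for array signals (which can be negative);
#' positivity is enforced by log-parameterization and local minima are
#' avoided with multiple starts. Returns the coefficient of determination
#' (log scale for the log loss) and the meaningful affinity fold range
#' `MAFR = max(y) / y_bg`, where `y_bg` is the weakest signal at which the
#' bound set (`yhat > 1.25 * Q1(yhat)`) is still identified at 5% false
#' discovery rate. A flat signal yields `MAFR = 1`; rescaling `y` leaves
#' MAFR unchanged.
#'
#' @param x Binned predicted affinities.
#' @param y Binned observed signals.
#' @param loss `"log"` (sequencing) or `"linear"` (arrays).
#' @param n_starts Random multi-starts for the nonlinear fit.
#' @param fdr False discovery rate for the detection floor.
#' @return List with `beta0`, `beta_c`, `beta_nsb`, `yhat`, `r2`, `mafr`,
#'   `y_bg`.
#' @export
saturation_fit <- function(x, y, loss = c("log", "linear"), n_starts = 5,
                           fdr = 0.05) {
  loss <- match.arg(loss)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  yhat_of <- function(p) {
    b0 <- if (loss == "log") exp(p[1L]) else p[1L]
    bc <- exp(p[2L]); bn <- exp(p[3L])
    b0 / (1 + 1 / (bc * (x + bn)))
  }
  obj <- function(p) {
    yh <- yhat_of(p)
    if (loss == "log") {
      if (any(yh <= 0) || any(y <= 0)) return(1e10)
      sum(log(y / yh)^2)
    } else sum((y - yh)^2)
  }
  y0 <- if (loss == "log") max(abs(y)) else max(y)
  starts <- list(c(if (loss == "log") log(max(y0, 1e-12)) else y0,
                   -log(stats::median(x)), log(stats::median(x) * 0.01 + 1e-12)))
  for (i in seq_len(n_starts - 1L))
    starts[[i + 1L]] <- starts[[1L]] + stats::rnorm(3L, sd = 2)
  best <- NULL
  for (s in starts) {
    r <- tryCatch(stats::optim(s, obj, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
  }
  p <- best$par
  yh <- yhat_of(p)
  r2 <- if (stats::sd(y) == 0 || stats::sd(yh) == 0) NA_real_
        else if (loss == "log") r_squared(log(pmax(y, 1e-300)), log(yh))
        else r_squared(y, yh)
  # detection floor at the requested FDR
  bound <- yh > 1.25 * stats::quantile(yh, 0.25)
  mafr <- 1; y_bg <- max(y)
  if (any(bound) && any(!bound) && stats::sd(y) > 0) {
    ths <- sort(unique(y))
    for (th in ths) {
      called <- y >= th
      if (!any(called)) break
      if (mean(!bound[called]) <= fdr) { y_bg <- th; break }
    }
    mafr <- max(y) / y_bg
  }
  list(beta0 = if (loss == "log") exp(p[1L]) else p[1L],
       beta_c = exp(p[2L]), beta_nsb = exp(p[3L]),
       yhat = yh, r2 = r2, mafr = max(mafr, 1), y_bg = y_bg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated AUPRC over descending score thresholds, with tied
#' scores collapsed into single threshold groups. A constant score yields
#' the positive prevalence; with one positive per two negatives a random
#' classifier scores about 1/3.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1) with at least one positive.
#' @return The AUPRC.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels)) stop("need at least one positive label")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  P <- sum(labels)
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}
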