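#' Gauge freedom of pairwise energy models
#'
#' Models with pairwise letter couplings are over-parameterized: infinitely
#' many coefficient vectors encode the same sequence specificity.
#' `gauge_shift()` applies one generator of that freedom: for a coupled
#' position pair `(x1, x2)` and a letter `n` at `x2`, it adds `A` to the
#' monomer coefficient `beta(x2, n)` and subtracts `A` from every coupling
#' coefficient `beta(x1, x2, m, n)`. Whenever letter `n` occupies `x2`,
#' exactly one coupling feature at `(x1, x2)` is active and compensates the
#' monomer change, so `beta . X(S)` is unchanged for every sequence `S`.
#'
#' @param mode A [binding_mode()] with the pair `(x1, x2)` in its feature set.
#' @param x1,x2 Coupled positions (`x1 < x2`).
#' @param n Letter (character) at `x2`.
#' @param A Transformation coordinate.
#' @return The transformed, score-identical mode.
#' @export
gauge_shift <- function(mode, x1, x2, n, A) {
  k <- which(mode$pairs[, 1L] == x1 & mode$pairs[, 2L] == x2)
  if (length(k) != 1L) stop("pair (x1, x2) is not in the mode's feature set")
  ni <- match(n, mode$alphabet$letters)
  if (is.na(ni)) stop("letter outside alphabet")
  mode$beta_mono[ni, x2] <- mode$beta_mono[ni, x2] + A
  mode$beta_pair[[k]][, ni] <- mode$beta_pair[[k]][, ni] - A
  mode
}

#' Mismatch-gauge canonicalization
#'
#' Re-expresses a mode so that, relative to its reference sequence `S0`:
#' the reference letter's monomer coefficient is zero at every position
#' (so a single-edit variant of `S0` picks up exactly one nonzero monomer
#' coefficient), and every coupling coefficient with a reference letter on
#' either end is zero (so a double-edit variant picks up at most one
#' coupling coefficient). Score differences `score(S) - score(S0)` are
#' exactly preserved, and the gauged reference scores 0. The map is
#' idempotent: an already-gauged mode is returned unchanged.
#'
#' @param mode A [binding_mode()] with a `reference` sequence.
#' @return The gauged mode.
#' @export
fix_gauge <- function(mode) {
  if (is.null(mode$reference)) stop("mismatch gauge requires a reference sequence")
  A <- n_letters(mode$alphabet)
  L <- mode$L
  ref <- drop(encode_seqs(mode$reference, mode$alphabet))
  bm <- mode$beta_mono
  bp <- mode$beta_pair
  new_m <- sweep(bm, 2L, bm[cbind(ref, seq_len(L))], "-")
  if (nrow(mode$pairs)) {
    for (k in seq_len(nrow(mode$pairs))) {
      x1 <- mode$pairs[k, 1L]; x2 <- mode$pairs[k, 2L]
      e <- bp[[k]]
      r1 <- ref[x1]; r2 <- ref[x2]
      # fold the couplings' reference rows/columns into the monomer terms
      new_m[, x1] <- new_m[, x1] + (e[, r2] - e[r1, r2])
      new_m[, x2] <- new_m[, x2] + (e[r1, ] - e[r1, r2])
      bp[[k]] <- e - outer(e[, r2], rep(1, A)) -
        outer(rep(1, A), e[r1, ]) + e[r1, r2]
    }
  }
  mode$beta_mono <- new_m
  mode$beta_pair <- bp
  mode
}

#' Information content of a gauged mode
#'
#' Converts the per-position monomer coefficients to Boltzmann
#' probabilities `p(l) = exp(beta_l) / sum(exp(beta))` and returns the
#' summed Shannon information relative to a uniform background over the
#' mode's alphabet, in bits. Zero for a fully non-specific mode; approaches
#' `log2(A)` bits per position for a single strongly preferred letter.
#'
#' @param mode A [binding_mode()] (gauged or not: the result is invariant
#'   to per-position constant shifts, hence gauge-independent for
#'   monomer-only modes).
#' @return Information content in bits.
#' @export
information_content <- function(mode) {
  b <- mode$beta_mono
  A <- nrow(b)
  ic <- 0
  for (p in seq_len(ncol(b))) {
    w <- exp(b[, p] - max(b[, p]))
    pr <- w / sum(w)
    nz <- pr > 0
    ic <- ic + log2(A) + sum(pr[nz] * log2(pr[nz]))
  }
  ic
}

#' Pearson r-squared between two modes' coefficients
#'
#' Both modes are mismatch-gauged first; returns squared Pearson
#' correlations of the stacked monomer coefficients and (when present) of
#' the stacked coupling coefficients. Used by the Dirichlet-weight
#' stabilization rule and by parameter-recovery checks.
#'
#' @param m1,m2 [binding_mode()]s of the same geometry.
#' @param what `"mono"`, `"pair"` or `"both"` (sum of stacked vectors).
#' @return Squared Pearson correlation.
#' @export
mode_r2 <- function(m1, m2, what = c("mono", "pair")) {
  what <- match.arg(what)
  if (!is.null(m1$reference)) m1 <- fix_gauge(m1)
  if (!is.null(m2$reference)) m2 <- fix_gauge(m2)
  v1 <- if (what == "mono") as.vector(m1$beta_mono)
        else unlist(m1$beta_pair)
  v2 <- if (what == "mono") as.vector(m2$beta_mono)
        else unlist(m2$beta_pair)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(0)
  stats::cor(v1, v2)^2
}

#' Strand-aware coefficient recovery score
#'
#' Squared Pearson correlation between the mismatch-gauged monomer
#' coefficients of two modes, maximized over the reverse-complement flip
#' of the first mode. Both-strand scoring makes a mode and its reverse
#' complement physically identical, so a fit may legitimately return
#' either orientation.
#'
#' @param m Fitted [binding_mode()] (with reference, e.g. from a
#'   `probefit` result's `gauged` list).
#' @param truth Ground-truth mode (reference set).
#' @param method `"pearson"` for the squared correlation (scale-free), or
#'   `"agreement"` for the coefficient of determination about the identity
#'   line — both modes' gauged coefficients are in absolute RT units, so
#'   agreement additionally demands the correct energy scale and is the
#'   stricter recovery criterion (it can be negative for a badly
#'   mis-scaled fit).
#' @return Max of the direct and reverse-complement score.
#' @export
mode_recovery_r2 <- function(m, truth, method = c("pearson", "agreement")) {
  method <- match.arg(method)
  score <- function(a, b) {
    if (method == "pearson") return(mode_r2(a, b))
    if (!is.null(a$reference)) a <- fix_gauge(a)
    if (!is.null(b$reference)) b <- fix_gauge(b)
    v1 <- as.vector(a$beta_mono); v2 <- as.vector(b$beta_mono)
    1 - sum((v1 - v2)^2) / sum((v2 - mean(v2))^2)
  }
  r2 <- score(m, truth)
  if (m$strands == 2 && m$alphabet$double_stranded) {
    mrc <- m
    mrc$beta_mono <- rc_map_mono(m$beta_mono, m$alphabet)
    mrc$reference <- reverse_complement(m$reference, m$alphabet)
    r2 <- max(r2, score(mrc, truth))
  }
  r2
}

#' Energy logo and coupling heat map export
#'
#' Renders the gauged monomer coefficients as an energy logo (letter height
#' proportional to `-ddG/RT` relative to the position's best letter;
#' preferred letters above the axis) and, when couplings exist, a heat map
#' of coupling coefficients. The coefficient table written alongside is
#' bit-exact with the internal parameters. Ungauged modes with a reference
#' are gauged first (with a message).
#'
#' @param mode A [binding_mode()].
#' @param path Output stem; writes `<path>.png` and `<path>.tsv`.
#' @param width,height Image size in pixels.
#' @return Invisibly, the path stem.
#' @export
export_energy_logo <- function(mode, path, width = 760, height = 340) {
  if (!is.null(mode$reference)) {
    gauged <- fix_gauge(mode)
    if (max(abs(gauged$beta_mono - mode$beta_mono)) > 1e-12)
      message("mode was not in mismatch gauge; gauging before export")
    mode <- gauged
  }
  b <- mode$beta_mono
  tsv <- data.frame(position = rep(seq_len(ncol(b)), each = nrow(b)),
                    letter = rep(mode$alphabet$letters, ncol(b)),
                    beta = sprintf("%.17g", as.vector(b)))
  utils::write.table(tsv, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grDevices::png(paste0(path, ".png"), width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot_energy_logo(mode)
  invisible(path)
}

#' @rdname export_energy_logo
#' @export
plot_energy_logo <- function(mode) {
  b <- mode$beta_mono
  # height of letter l at position p: beta relative to the position mean,
  # the standard energy-logo convention (preferred letters point up)
  h <- sweep(b, 2L, colMeans(b), "-")
  L <- ncol(b)
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839",
            c = "#7FB5E6", g = "#FBD78C")
  lcol <- function(l) if (l %in% names(cols)) cols[[l]] else "grey30"
  ylim <- range(0, h) * 1.15
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = ylim, xlab = "position",
                 ylab = expression(-Delta * Delta * G / RT), axes = FALSE)
  graphics::axis(1, at = seq_len(L)); graphics::axis(2)
  graphics::abline(h = 0, col = "grey70")
  for (p in seq_len(L)) {
    up <- which(h[, p] > 0); dn <- which(h[, p] < 0)
    y <- 0
    for (l in up[order(h[up, p])]) {
      graphics::rect(p - 0.42, y, p + 0.42, y + h[l, p],
                     col = grDevices::adjustcolor(lcol(mode$alphabet$letters[l]), 0.25),
                     border = NA)
      graphics::text(p, y + h[l, p] / 2, mode$alphabet$letters[l],
                     cex = 0.6 + 2.2 * h[l, p] / max(abs(ylim)),
                     col = lcol(mode$alphabet$letters[l]), font = 2)
      y <- y + h[l, p]
    }
    y <- 0
    for (l in dn[order(-h[dn, p])]) {
      graphics::rect(p - 0.42, y + h[l, p], p + 0.42, y,
                     col = grDevices::adjustcolor(lcol(mode$alphabet$letters[l]), 0.12),
                     border = NA)
      y <- y + h[l, p]
    }
  }
  if (nrow(mode$pairs)) {
    # inset heat map of the strongest coupling block
    k <- which.max(vapply(mode$beta_pair, function(m) max(abs(m)), 1))
    graphics::mtext(sprintf("strongest coupling: positions %d-%d (|max| = %.2f)",
                            mode$pairs[k, 1L], mode$pairs[k, 2L],
                            max(abs(mode$beta_pair[[k]]))), side = 3, cex = 0.8)
  }
  invisible(mode)
}
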