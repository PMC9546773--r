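#' Binding modes
#'
#' A binding mode describes one protein (or complex subunit) species: a
#' footprint of `L` positions scored by additive free-energy coefficients
#' (`-ddG/RT` units), optional pairwise letter couplings, optional position
#' bias along the probe, a flank depth, and strand handling. The energy of
#' a window S is `sum(beta * X(S))`, where X is the binary feature indicator
#' vector, so `exp(score)` is the relative affinity of that window.
#'
#' @param L Footprint length in positions.
#' @param alphabet A [pf_alphabet()].
#' @param f Flank depth: constant-flank letters included in the sliding sum.
#' @param strands 1 (e.g. RNA, peptides) or 2 (double-stranded DNA).
#' @param beta_mono `A x L` matrix of monomer coefficients
#'   (rows = letters in alphabet order).
#' @param pairs Either `"none"`, `"adjacent"` (dinucleotide couplings),
#'   `"all"`, or a 2-column integer matrix of 1-based position pairs
#'   (`pos1 < pos2`).
#' @param beta_pair List of `A x A` coupling matrices, one per pair
#'   (`[m, n]` = letters at pos1, pos2); zero-filled when omitted.
#' @param position_bias Optional matrix of log position-bias terms
#'   `log w(x)`, rows = window offsets (0-based + 1), columns = strands
#'   (`"+"`, `"-"`). `NULL` means no bias (all zero).
#' @param rc_symmetric Constrain the mode to be reverse-complement
#'   symmetric (beta invariant under position reversal + complementation).
#' @param reference Optional reference sequence `S0` (length `L`) against
#'   which relative affinities and the mismatch gauge are defined.
#' @return An object of class `"binding_mode"`.
#' @export
binding_mode <- function(L, alphabet = dna_alphabet(), f = 0, strands = 2,
                         beta_mono = NULL, pairs = "none", beta_pair = NULL,
                         position_bias = NULL, rc_symmetric = FALSE,
                         reference = NULL) {
  A <- n_letters(alphabet)
  stopifnot(L >= 1, f >= 0, strands %in% c(1, 2))
  if (strands == 2 && !alphabet$double_stranded)
    stop("two-strand mode requires a double-stranded alphabet")
  if (is.null(beta_mono)) beta_mono <- matrix(0, A, L)
  beta_mono <- as.matrix(beta_mono)
  if (!all(dim(beta_mono) == c(A, L))) stop("beta_mono must be A x L")
  rownames(beta_mono) <- alphabet$letters
  pairs <- resolve_pairs(pairs, L)
  if (is.null(beta_pair)) beta_pair <- rep(list(matrix(0, A, A)), nrow(pairs))
  if (length(beta_pair) != nrow(pairs)) stop("beta_pair must match pairs")
  for (k in seq_along(beta_pair)) {
    beta_pair[[k]] <- as.matrix(beta_pair[[k]])
    if (!all(dim(beta_pair[[k]]) == c(A, A))) stop("pair matrices must be A x A")
  }
  if (!is.null(reference)) {
    if (nchar(reference) != L) stop("reference sequence must have length L")
    if (!valid_seq(reference, alphabet)) stop("reference outside alphabet")
  }
  m <- structure(
    list(L = L, f = f, strands = strands, alphabet = alphabet,
         beta_mono = beta_mono, pairs = pairs, beta_pair = beta_pair,
         position_bias = position_bias, rc_symmetric = rc_symmetric,
         reference = reference),
    class = "binding_mode"
  )
  if (rc_symmetric) m <- symmetrize_mode(m)
  m
}

resolve_pairs <- function(pairs, L) {
  if (is.character(pairs)) {
    pairs <- switch(pairs,
      none = matrix(integer(), 0L, 2L),
      adjacent = if (L >= 2) cbind(seq_len(L - 1L), seq_len(L - 1L) + 1L)
                 else matrix(integer(), 0L, 2L),
      all = if (L >= 2) t(utils::combn(L, 2L)) else matrix(integer(), 0L, 2L),
      stop("pairs must be 'none', 'adjacent', 'all' or a 2-column matrix"))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) && any(pairs[, 1L] >= pairs[, 2L] | pairs < 1L | pairs > L))
    stop("pair positions must satisfy 1 <= pos1 < pos2 <= L")
  pairs
}

#' @export
print.binding_mode <- function(x, ...) {
  cat("<binding_mode> L=", x$L, " f=", x$f, " strands=", x$strands,
      " pairs=", nrow(x$pairs),
      if (x$rc_symmetric) " rc-symmetric" else "", "\n", sep = "")
  invisible(x)
}

# Projection onto the reverse-complement symmetric subspace:
# beta[l, p] == beta[comp(l), L+1-p] (and the mirrored pair couplings).
rc_map_mono <- function(beta, alphabet) {
  ci <- match(alphabet$complement[alphabet$letters], alphabet$letters)
  out <- beta[ci, rev(seq_len(ncol(beta))), drop = FALSE]
  rownames(out) <- rownames(beta)
  out
}

symmetrize_mode <- function(mode) {
  a <- mode$alphabet
  if (!a$double_stranded) stop("rc symmetry needs a double-stranded alphabet")
  mode$beta_mono <- (mode$beta_mono + rc_map_mono(mode$beta_mono, a)) / 2
  if (nrow(mode$pairs)) {
    ci <- match(a$complement[a$letters], a$letters)
    L <- mode$L
    # pair (x1,x2,m,n) maps to (L+1-x2, L+1-x1, comp(n), comp(m))
    key <- paste(mode$pairs[, 1L], mode$pairs[, 2L])
    for (k in seq_len(nrow(mode$pairs))) {
      x1 <- mode$pairs[k, 1L]; x2 <- mode$pairs[k, 2L]
      j <- match(paste(L + 1L - x2, L + 1L - x1), key)
      if (is.na(j)) next   # partner pair not in the feature set; leave as is
      mirrored <- t(mode$beta_pair[[j]][ci, ci, drop = FALSE])
      mode$beta_pair[[k]] <- (mode$beta_pair[[k]] + mirrored) / 2
    }
  }
  mode
}

#' Seed a binding mode
#'
#' Random seeding draws small-magnitude coefficients (so the staged
#' optimizer starts near the non-specific null); IUPAC seeding sets a
#' positive coefficient for every letter matched by the degeneracy code and
#' zero elsewhere.
#'
#' @param L Footprint length (for IUPAC seeds, taken from the string).
#' @param alphabet A [pf_alphabet()].
#' @param iupac Optional IUPAC string (standard DNA degeneracy codes).
#' @param scale SD of the random seed noise.
#' @param strength Coefficient given to IUPAC-matched letters.
#' @param ... Passed to [binding_mode()] (`f`, `strands`, `pairs`, ...).
#' @return A [binding_mode()].
#' @examples
#' seed_mode(iupac = "TGACGTCA")
#' @export
seed_mode <- function(L = NULL, alphabet = dna_alphabet(), iupac = NULL,
                      scale = 0.01, strength = 1, ...) {
  A <- n_letters(alphabet)
  if (!is.null(iupac)) {
    codes <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
    ch <- strsplit(toupper(iupac), "")[[1L]]
    if (!all(ch %in% names(codes))) stop("invalid IUPAC code in seed")
    L <- length(ch)
    beta <- matrix(0, A, L)
    for (p in seq_len(L)) {
      hit <- alphabet$letters %in% codes[[ch[p]]]
      if (!any(ch[p] == "N") && any(hit)) beta[hit, p] <- strength
    }
    binding_mode(L, alphabet, beta_mono = beta, ...)
  } else {
    if (is.null(L)) stop("give L or an IUPAC seed")
    beta <- matrix(stats::rnorm(A * L, sd = scale), A, L)
    binding_mode(L, alphabet, beta_mono = beta, ...)
  }
}

#' Cooperativity between two binding modes
#'
#' The cooperativity factor `w(x1, x2)` multiplying the Boltzmann weight of
#' a doubly-bound configuration is indexed by the relative offset
#' `d = fwd_start(b) - fwd_start(a)` (in the shared forward frame of the
#' probe) and by the orientation of the two windows (`parallel` when the
#' strands agree, `antiparallel` otherwise). Forbidden configurations
#' (steric clash, default: exact overlap `d = 0`; or spacings beyond
#' `max_spacing`) carry `w = 0` and are structural zeros, not parameters.
#' `translational_tie` collapses the offset grid to a single value per
#' orientation (translationally symmetric interactions).
#'
#' @param a,b Indices of the interacting modes in the model's mode list.
#' @param max_spacing Largest |d| with a free cooperativity parameter.
#' @param clash Spacings with |d| < `clash` are forbidden (default 1:
#'   exact overlap only).
#' @param log_omega `2 x (2 max_spacing + 1)` matrix of log cooperativities,
#'   rows `parallel` / `antiparallel`, columns `d = -max_spacing .. max_spacing`.
#' @param translational_tie Tie all offsets within an orientation.
#' @return An object of class `"cooperativity"`.
#' @export
cooperativity <- function(a, b, max_spacing = 8, clash = 1,
                          log_omega = NULL, translational_tie = FALSE) {
  nd <- 2L * max_spacing + 1L
  if (is.null(log_omega)) log_omega <- matrix(0, 2L, nd)
  log_omega <- as.matrix(log_omega)
  if (!all(dim(log_omega) == c(2L, nd))) stop("log_omega must be 2 x (2*max_spacing+1)")
  dimnames(log_omega) <- list(c("parallel", "antiparallel"),
                              as.character(seq(-max_spacing, max_spacing)))
  structure(list(a = a, b = b, max_spacing = max_spacing, clash = clash,
                 log_omega = log_omega, translational_tie = translational_tie),
            class = "cooperativity")
}

# log w for (d, orientation); -Inf for forbidden / out-of-grid
coop_logomega <- function(coop, d, parallel) {
  out <- numeric(length(d))
  row <- ifelse(parallel, 1L, 2L)
  col <- d + coop$max_spacing + 1L
  bad <- abs(d) > coop$max_spacing | abs(d) < coop$clash
  col[bad] <- 1L
  out <- coop$log_omega[cbind(row, col)]
  out[bad] <- -Inf
  out
}

#' Recognition models
#'
#' A recognition model bundles binding modes, their pairwise cooperativity
#' terms, and per-column activities (stored in log space): the non-specific
#' activity `a_NS,r`, per-mode activities `a_{m,r}` and per-interaction
#' activities `a_{mn,r}`. Column `r` indexes the selection round, fraction
#' or time point of the experiment the model is evaluated against.
#'
#' @param modes List of [binding_mode()]s.
#' @param interactions List of [cooperativity()] objects.
#' @param log_alpha Matrix `n_modes x n_columns` of log mode activities.
#' @param log_alpha_ns Numeric vector of per-column log non-specific
#'   activities, or `NULL` to omit the non-specific term.
#' @param log_alpha_int Matrix `n_interactions x n_columns`.
#' @return An object of class `"recognition_model"`.
#' @export
recognition_model <- function(modes, interactions = list(),
                              log_alpha = NULL, log_alpha_ns = NULL,
                              log_alpha_int = NULL) {
  if (inherits(modes, "binding_mode")) modes <- list(modes)
  nm <- length(modes)
  ni <- length(interactions)
  R <- if (!is.null(log_alpha)) ncol(as.matrix(log_alpha))
       else if (!is.null(log_alpha_ns)) length(log_alpha_ns) else 1L
  if (is.null(log_alpha)) log_alpha <- matrix(0, nm, R)
  log_alpha <- matrix(log_alpha, nm, R)
  if (is.null(log_alpha_int) && ni) log_alpha_int <- matrix(0, ni, R)
  if (ni) log_alpha_int <- matrix(log_alpha_int, ni, R)
  for (it in interactions) {
    if (it$a > nm || it$b > nm) stop("interaction references a missing mode")
  }
  structure(list(modes = modes, interactions = interactions,
                 log_alpha = log_alpha, log_alpha_ns = log_alpha_ns,
                 log_alpha_int = log_alpha_int, n_columns = R),
            class = "recognition_model")
}

#' @export
print.recognition_model <- function(x, ...) {
  cat("<recognition_model> ", length(x$modes), " mode(s), ",
      length(x$interactions), " interaction(s), ",
      x$n_columns, " column(s); NS term: ",
      if (is.null(x$log_alpha_ns)) "no" else "yes", "\n", sep = "")
  invisible(x)
}
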