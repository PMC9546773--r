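#' Selection models
#'
#' A selection spec maps the per-probe partition function `Z` to relative
#' probe frequencies across the columns of a count table. Three families:
#'
#' * `cumulative`: each round enriches the previous one,
#'   `f[,r] = f[,r-1] * Z[,r]^rho * (1+Z[,r])^gamma`. `(rho, gamma) = (1, 0)`
#'   is the low-concentration linear-enrichment limit; `(1, -1)` adds
#'   binding saturation.
#' * `non_cumulative`: every column derives directly from the input,
#'   `f[,r] = f[,1] * Z[,r]^rho[r] * (1+Z[,r])^gamma[r]` (used e.g. for
#'   input/bound/free fraction designs).
#' * `kinetic`: constant-rate conversion; each column is a survival /
#'   conversion mixture of the input,
#'   `f[,r] = f[,1] * (s(delta) e^-Z + (1-s(delta)) (1-e^-Z))` with
#'   `s = 1/(1+e^-delta)`. `delta = +Inf` selects the unmodified
#'   (surviving) fraction, `delta = -Inf` the modified fraction; `delta = NA`
#'   leaves a column unselected (e.g. the input itself). The two limiting
#'   fractions sum to the total: `e^-Z + (1-e^-Z) = 1`.
#'
#' @param family `"cumulative"`, `"non_cumulative"` or `"kinetic"`.
#' @param rho,gamma Scalars (cumulative; recycled over selected columns) or
#'   per-column vectors (non-cumulative; first entry conventionally 0).
#' @param delta Per-column vector for the kinetic family (`+Inf`, `-Inf`,
#'   finite, or `NA` for an unselected column).
#' @param n_columns Number of table columns the spec applies to.
#' @return An object of class `"selection_spec"`.
#' @export
selection_spec <- function(family = c("cumulative", "non_cumulative", "kinetic"),
                           rho = 1, gamma = 0, delta = NULL, n_columns = NULL) {
  family <- match.arg(family)
  if (family == "kinetic") {
    if (is.null(delta)) stop("kinetic family needs a delta vector")
    n_columns <- length(delta)
  } else if (family == "non_cumulative") {
    if (length(rho) != length(gamma)) stop("rho and gamma must have equal length")
    n_columns <- length(rho)
  } else {
    if (is.null(n_columns)) stop("cumulative family needs n_columns")
    stopifnot(length(rho) == 1L, length(gamma) == 1L)
  }
  structure(list(family = family, rho = rho, gamma = gamma, delta = delta,
                 n_columns = n_columns),
            class = "selection_spec")
}

# columns whose frequency depends on Z
z_columns <- function(spec) {
  switch(spec$family,
    cumulative = if (spec$n_columns >= 2L) seq.int(2L, spec$n_columns) else integer(),
    non_cumulative = which(spec$rho != 0 | spec$gamma != 0),
    kinetic = which(!is.na(spec$delta)))
}

# kinetic selection factor and d log(factor) / dZ
kinetic_factor <- function(Z, delta) {
  if (is.infinite(delta) && delta > 0) return(exp(-Z))
  if (is.infinite(delta) && delta < 0) return(-expm1(-Z))
  s <- 1 / (1 + exp(-delta))
  s * exp(-Z) + (1 - s) * -expm1(-Z)
}
# log of the kinetic factor, exact in the +/-Inf limits even where the
# factor itself underflows (survival branch: log factor is just -Z)
kinetic_logfactor <- function(Z, delta) {
  if (is.infinite(delta) && delta > 0) return(-Z)
  if (is.infinite(delta) && delta < 0) return(log(-expm1(-Z)))
  log(kinetic_factor(Z, delta))
}

kinetic_dlog <- function(Z, delta) {
  if (is.infinite(delta) && delta > 0) return(rep(-1, length(Z)))
  if (is.infinite(delta) && delta < 0) return(exp(-Z) / -expm1(-Z))
  s <- 1 / (1 + exp(-delta))
  g <- s * exp(-Z) + (1 - s) * -expm1(-Z)
  ((1 - 2 * s) * exp(-Z)) / g
}

#' Predict library frequencies from partition functions
#'
#' @param Z Matrix `n_probes x n_columns` of `Z_bound` values (columns not
#'   selected on may be `NA`).
#' @param spec A [selection_spec()].
#' @param f0 Input frequencies (recycled; default uniform 1).
#' @return Matrix of relative frequencies `f[, r]` per probe and column.
#' @examples
#' sp <- selection_spec("cumulative", rho = 1, gamma = 0, n_columns = 2)
#' predict_frequencies(cbind(NA, 2), sp, f0 = 0.1)   # 0.1, then 0.2
#' @export
predict_frequencies <- function(Z, spec, f0 = 1) {
  Z <- as.matrix(Z)
  if (ncol(Z) != spec$n_columns)
    stop("Z has ", ncol(Z), " columns; selection spec expects ", spec$n_columns)
  n <- nrow(Z)
  f <- matrix(NA_real_, n, ncol(Z))
  f0 <- rep_len(f0, n)
  zc <- z_columns(spec)
  if (length(zc) && (anyNA(Z[, zc]) || any(Z[, zc] < 0)))
    stop("Z must be non-negative and non-missing in selected columns")
  switch(spec$family,
    cumulative = {
      f[, 1L] <- f0
      for (r in seq_len(ncol(Z))[-1L])
        f[, r] <- f[, r - 1L] * Z[, r]^spec$rho * (1 + Z[, r])^spec$gamma
    },
    non_cumulative = {
      for (r in seq_len(ncol(Z))) {
        f[, r] <- if (r %in% zc)
          f0 * Z[, r]^spec$rho[r] * (1 + Z[, r])^spec$gamma[r]
        else f0
      }
    },
    kinetic = {
      for (r in seq_len(ncol(Z))) {
        f[, r] <- if (r %in% zc) f0 * kinetic_factor(Z[, r], spec$delta[r])
                  else f0
      }
    })
  f
}
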