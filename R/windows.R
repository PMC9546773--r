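#' Enumerate binding windows of a probe
#'
#' Returns every length-`L` subsequence of the probe's variable region
#' extended by `f` letters of constant flank on each side. Offsets are
#' 0-based and ascending along the extended region; reverse-strand windows
#' are reverse complements, with offsets defined on the reverse-complemented
#' extended sequence, so both strands share one indexing scheme. `fwd_start`
#' gives the forward-frame start of each window (used to compute relative
#' spacings between two bound proteins).
#'
#' @param variable_region Variable-region sequence.
#' @param L Footprint length (>= 1).
#' @param f Flank depth: letters of constant flank included on each side.
#' @param strands 1 or 2.
#' @param left_flank,right_flank Constant flanks (must be at least `f` long).
#' @param alphabet A [pf_alphabet()].
#' @return data.frame with columns `window`, `offset`, `strand`, `fwd_start`.
#'   Zero rows (not an error) when `L` exceeds the available sequence.
#' @examples
#' enumerate_windows("ACGTA", L = 4, f = 0, strands = 1)
#' @export
enumerate_windows <- function(variable_region, L, f = 0, strands = 2,
                              left_flank = "", right_flank = "",
                              alphabet = dna_alphabet()) {
  stopifnot(L >= 1, f >= 0, strands %in% c(1, 2))
  if (f > nchar(left_flank) || f > nchar(right_flank))
    stop("flank depth f exceeds available flank length")
  lf <- if (f > 0) substr(left_flank, nchar(left_flank) - f + 1L, nchar(left_flank)) else ""
  rf <- if (f > 0) substr(right_flank, 1L, f) else ""
  ext <- paste0(lf, variable_region, rf)
  W <- nchar(ext)
  nw <- W - L + 1L
  if (nw <= 0L)
    return(data.frame(window = character(), offset = integer(),
                      strand = character(), fwd_start = integer()))
  fwd <- substring(ext, seq_len(nw), seq_len(nw) + L - 1L)
  out <- data.frame(window = fwd, offset = seq_len(nw) - 1L,
                    strand = "+", fwd_start = seq_len(nw) - 1L,
                    stringsAsFactors = FALSE)
  if (strands == 2) {
    rc <- reverse_complement(ext, alphabet)
    rev <- substring(rc, seq_len(nw), seq_len(nw) + L - 1L)
    out <- rbind(out, data.frame(
      window = rev, offset = seq_len(nw) - 1L, strand = "-",
      fwd_start = W - L - (seq_len(nw) - 1L), stringsAsFactors = FALSE))
  }
  out
}

# ---- vectorized window design over a whole count table --------------------
#
# For scoring and fitting we never materialize window strings; instead we
# build, per (footprint, flank-depth, strands) geometry, an integer design:
#   idx   : [n_windows x L] letter indices into the alphabet
#   probe : [n_windows] probe row each window belongs to
#   strand: [n_windows] +1 / -1
#   fwd   : [n_windows] forward-frame start
# Probes of different variable-region lengths are handled by grouping.
window_design <- function(table, L, f, strands) {
  alph <- table$alphabet
  A <- n_letters(alph)
  comp_idx <- if (alph$double_stranded)
    match(alph$complement[alph$letters], alph$letters) else NULL
  lf <- if (f > 0) substr(table$left_flank, nchar(table$left_flank) - f + 1L,
                          nchar(table$left_flank)) else ""
  rf <- if (f > 0) substr(table$right_flank, 1L, f) else ""
  if (f > nchar(table$left_flank) || f > nchar(table$right_flank))
    stop("flank depth f exceeds available flank length")
  ext <- paste0(lf, table$seqs, rf)
  lens <- nchar(ext)
  idx_list <- list(); probe_list <- list(); strand_list <- list(); fwd_list <- list()
  blocks <- list()   # one entry per constant-(offset,strand) chunk of windows
  add_block <- function(M, rows, strand, fwd) {
    i <- length(idx_list) + 1L
    idx_list[[i]] <<- M
    probe_list[[i]] <<- rows
    strand_list[[i]] <<- rep(strand, length(rows))
    fwd_list[[i]] <<- rep(fwd, length(rows))
    blocks[[i]] <<- list(n = length(rows), strand = strand, fwd = fwd, rows = rows)
  }
  for (len in sort(unique(lens))) {
    rows <- which(lens == len)
    nw <- len - L + 1L
    if (nw <= 0L) next
    M <- encode_seqs(ext[rows], alph)          # [n x len]
    for (o in seq_len(nw))
      add_block(M[, o:(o + L - 1L), drop = FALSE], rows, 1L, o - 1L)
    if (strands == 2) {
      if (is.null(comp_idx)) stop("two-strand scoring needs a double-stranded alphabet")
      Mrc <- matrix(comp_idx[M[, rev(seq_len(len)), drop = FALSE]], nrow = length(rows))
      for (o in seq_len(nw))
        add_block(Mrc[, o:(o + L - 1L), drop = FALSE], rows, -1L, len - L - (o - 1L))
    }
  }
  if (length(idx_list) == 0L) {
    return(list(idx = matrix(integer(), 0L, L), probe = integer(),
                strand = integer(), fwd = integer(), blocks = list(),
                n_probes = length(table$seqs), A = A, L = L, f = f))
  }
  # absolute block start rows into the stacked window matrix
  off <- 0L
  for (i in seq_along(blocks)) {
    blocks[[i]]$first <- off + 1L
    off <- off + blocks[[i]]$n
    blocks[[i]]$last <- off
  }
  list(idx = do.call(rbind, idx_list),
       probe = unlist(probe_list),
       strand = unlist(strand_list),
       fwd = unlist(fwd_list),
       blocks = blocks,
       n_probes = length(table$seqs), A = A, L = L, f = f)
}

#' Number of windows per probe
#'
#' `strands * max(0, V + 2f - L + 1)` for a probe of variable-region
#' length `V`; exposed mostly for sanity checks.
#' @param V Variable-region length.
#' @inheritParams enumerate_windows
#' @export
window_count <- function(V, L, f = 0, strands = 2) {
  strands * max(0L, V + 2L * f - L + 1L)
}
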