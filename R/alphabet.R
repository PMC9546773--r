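#' Sequence alphabets
#'
#' An alphabet is an ordered set of single-character letters, optionally with
#' a complement map for double-stranded molecules. Chemically modified
#' letters (for example methylated cytosine) are supported by simply adding
#' letters and extending the complement map, so one binding model can score
#' modified and unmodified probes on the same footing.
#'
#' @param letters Character vector of unique single-character symbols.
#' @param complement Named character vector mapping each letter to its
#'   complement, or `NULL` for single-stranded alphabets. Must be an
#'   involution covering every letter.
#' @return An object of class `"pf_alphabet"`.
#' @examples
#' dna_alphabet()
#' methyl_alphabet()   # ACcGgT with A<->T, C<->G, c<->g
#' @export
pf_alphabet <- function(letters, complement = NULL) {
  letters <- as.character(letters)
  if (anyDuplicated(letters)) stop("alphabet letters must be unique")
  if (any(nchar(letters) != 1L)) stop("alphabet letters must be single characters")
  if (!is.null(complement)) {
    complement <- complement[letters]
    if (anyNA(complement) || !setequal(names(complement), letters))
      stop("complement map must cover every letter")
    # involution: comp(comp(x)) == x
    if (!identical(unname(complement[complement]), letters))
      stop("complement map must be an involution")
  }
  structure(
    list(letters = letters, complement = complement,
         double_stranded = !is.null(complement)),
    class = "pf_alphabet"
  )
}

#' @rdname pf_alphabet
#' @export
dna_alphabet <- function() {
  pf_alphabet(c("A", "C", "G", "T"),
              c(A = "T", C = "G", G = "C", T = "A"))
}

#' @rdname pf_alphabet
#' @export
methyl_alphabet <- function() {
  # lower-case c/g mark the methylated CpG letters; c pairs with g
  pf_alphabet(c("A", "C", "c", "G", "g", "T"),
              c(A = "T", C = "G", c = "g", G = "C", g = "c", T = "A"))
}

#' @rdname pf_alphabet
#' @export
peptide_alphabet <- function() {
  pf_alphabet(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
}

#' @export
print.pf_alphabet <- function(x, ...) {
  cat("<alphabet> ", paste(x$letters, collapse = ""),
      if (x$double_stranded) " (double-stranded)" else " (single-stranded)",
      "\n", sep = "")
  invisible(x)
}

n_letters <- function(alphabet) length(alphabet$letters)

#' Encode sequences as letter-index matrix
#'
#' Internal workhorse: converts equal-length sequences into an integer matrix
#' (one row per sequence, one column per position) of 1-based indices into
#' `alphabet$letters`. Symbols outside the alphabet yield `NA`.
#' @noRd
encode_seqs <- function(seqs, alphabet) {
  n <- length(seqs)
  if (n == 0L) return(matrix(integer(), 0L, 0L))
  len <- nchar(seqs[1L])
  if (any(nchar(seqs) != len)) stop("encode_seqs requires equal-length sequences")
  if (len == 0L) return(matrix(integer(), n, 0L))
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  idx <- match(chars, alphabet$letters)
  matrix(idx, nrow = n, ncol = len, byrow = TRUE)
}

decode_seqs <- function(idx, alphabet) {
  if (ncol(idx) == 0L) return(rep("", nrow(idx)))
  m <- matrix(alphabet$letters[t(idx)], nrow = ncol(idx))
  apply(m, 2L, paste, collapse = "")
}

#' Reverse complement
#'
#' Reverses a sequence and complements every letter according to the
#' alphabet's complement map. An involution: `reverse_complement()` applied
#' twice returns the input.
#'
#' @param seq Character vector of sequences.
#' @param alphabet A double-stranded [pf_alphabet()]; default DNA.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("ACGT")            # "ACGT" (palindrome)
#' reverse_complement("AcGT", methyl_alphabet())
#' @export
reverse_complement <- function(seq, alphabet = dna_alphabet()) {
  if (!alphabet$double_stranded)
    stop("reverse complement undefined for a single-stranded alphabet")
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    comp <- alphabet$complement[ch]
    if (anyNA(comp)) stop("symbol outside alphabet in '", s, "'")
    paste(rev(comp), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Transliterate probe sequences
#'
#' Replaces every non-overlapping occurrence of each pattern, scanning left
#' to right, with its replacement. Used to mark chemical modifications, e.g.
#' the methylated-CpG rule `CG -> cg`, so that the same count table can be
#' scored under an extended alphabet.
#'
#' @param seq Character vector of sequences.
#' @param rules Named character vector, `c(pattern = replacement)`. Every
#'   replacement must have the same length as its pattern.
#' @return Character vector with rules applied.
#' @examples
#' transliterate("TACGA", c(CG = "cg"))   # "TAcgA"
#' transliterate("CGCGCG", c(CG = "cg"))  # "cgcgcg"
#' @export
transliterate <- function(seq, rules) {
  pats <- names(rules)
  if (is.null(pats) || any(pats == ""))
    stop("rules must be a named character vector (pattern = replacement)")
  if (any(nchar(pats) != nchar(rules)))
    stop("transliteration must preserve length")
  out <- seq
  for (k in seq_along(rules)) {
    out <- gsub(pats[k], rules[[k]], out, fixed = TRUE)
  }
  out
}
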