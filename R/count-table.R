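#' Probe count tables
#'
#' A count table stores the distinct probe variable regions observed in an
#' experiment together with an integer count matrix (one column per
#' selection round / fraction / time point), the constant flanking
#' sequences, and the alphabet. Only observed probes are stored; the
#' likelihood machinery never enumerates unobserved sequences.
#'
#' @param seqs Character vector of distinct variable-region sequences.
#' @param counts Integer matrix (or vector for one column) of read counts,
#'   `length(seqs)` rows.
#' @param left_flank,right_flank Constant sequences attached to every probe.
#' @param alphabet A [pf_alphabet()].
#' @param col_labels Optional column names (e.g. `"r0"`, `"r1"`, ...).
#' @param metadata Optional list carried along (seeds, dropped-read counts,
#'   ground-truth digests from simulators).
#' @return An object of class `"count_table"`.
#' @export
count_table <- function(seqs, counts, left_flank = "", right_flank = "",
                        alphabet = dna_alphabet(), col_labels = NULL,
                        metadata = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"   # counts can exceed int range in theory
  if (length(seqs) != nrow(counts)) stop("seqs and counts disagree in length")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(seqs)) stop("probes must be unique by sequence")
  keep <- rowSums(counts) > 0
  if (!all(keep)) {
    seqs <- seqs[keep]
    counts <- counts[keep, , drop = FALSE]
  }
  if (is.null(col_labels)) col_labels <- paste0("r", seq_len(ncol(counts)) - 1L)
  colnames(counts) <- col_labels
  bad <- !valid_seq(c(seqs, left_flank, right_flank), alphabet)
  if (any(bad)) stop("sequence contains symbols outside the alphabet")
  structure(
    list(seqs = as.character(seqs), counts = counts,
         left_flank = left_flank, right_flank = right_flank,
         alphabet = alphabet, metadata = metadata),
    class = "count_table"
  )
}

valid_seq <- function(seqs, alphabet) {
  ok <- grepl(sprintf("^[%s]*$", paste(alphabet$letters, collapse = "")), seqs)
  ok
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", length(x$seqs), " probes x ", ncol(x$counts),
      " columns; depth ", paste(column_totals(x), collapse = "/"), "\n", sep = "")
  cat("  flanks: ", x$left_flank, "[.]", x$right_flank,
      "  alphabet: ", paste(x$alphabet$letters, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Per-column read totals
#' @param table A [count_table()].
#' @return Numeric vector of column sums (the sequencing depth per column).
#' @export
column_totals <- function(table) colSums(table$counts)

#' Tabulate reads into a count table
#'
#' Counts distinct variable regions in a read list, optionally downsampling
#' to at most `max_reads` reads (shuffle-and-truncate without replacement,
#' seeded, so tabulation is reproducible). Reads containing symbols outside
#' the alphabet, or whose length differs from `expected_length` when given,
#' are dropped; the number dropped is recorded in the metadata and reported
#' as a warning.
#'
#' @param reads Character vector of variable-region reads (one per read).
#' @param left_flank,right_flank Constant flanks attached as metadata.
#' @param max_reads Downsampling cap (default 1e5).
#' @param alphabet A [pf_alphabet()].
#' @param expected_length If non-`NULL`, reads of any other length are dropped.
#' @param seed Integer seed used for the downsampling shuffle.
#' @return A one-column [count_table()].
#' @examples
#' tabulate_reads(c("ACGT", "ACGT", "TTTT"), max_reads = 10)
#' @export
tabulate_reads <- function(reads, left_flank = "", right_flank = "",
                           max_reads = 1e5, alphabet = dna_alphabet(),
                           expected_length = NULL, seed = 1L) {
  stopifnot(max_reads >= 1)
  n_in <- length(reads)
  ok <- valid_seq(reads, alphabet)
  if (!is.null(expected_length)) ok <- ok & nchar(reads) == expected_length
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d/%d reads (invalid symbols or length)",
                    n_dropped, n_in))
    reads <- reads[ok]
  }
  if (length(reads) == 0L) stop("no valid reads to tabulate")
  if (length(reads) > max_reads) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    reads <- reads[sample.int(length(reads), max_reads)]
  }
  tab <- table(reads)
  count_table(names(tab), as.integer(tab),
              left_flank = left_flank, right_flank = right_flank,
              alphabet = alphabet, col_labels = "r0",
              metadata = list(n_input_reads = n_in, n_dropped = n_dropped,
                              max_reads = max_reads, downsample_seed = seed))
}

# Seed discipline: set a local RNG state and restore the caller's afterwards.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Assemble a multi-column table from per-column tables
#'
#' Joins single-column tables (e.g. one per SELEX round) on the probe
#' sequence; probes absent from a column get count 0.
#'
#' @param tables List of [count_table()]s sharing flanks and alphabet.
#' @param col_labels Optional labels, defaults to `r0, r1, ...`.
#' @return A multi-column [count_table()].
#' @export
bind_count_tables <- function(tables, col_labels = NULL) {
  stopifnot(length(tables) >= 1L)
  seqs <- unique(unlist(lapply(tables, `[[`, "seqs")))
  counts <- matrix(0, length(seqs), sum(vapply(tables, function(t) ncol(t$counts), 1L)))
  j <- 0L
  for (t in tables) {
    for (cc in seq_len(ncol(t$counts))) {
      j <- j + 1L
      counts[match(t$seqs, seqs), j] <- t$counts[, cc]
    }
  }
  count_table(seqs, counts, tables[[1L]]$left_flank, tables[[1L]]$right_flank,
              tables[[1L]]$alphabet, col_labels = col_labels,
              metadata = tables[[1L]]$metadata)
}

#' Read sequences from FASTQ or plain sequence lists
#'
#' FASTQ files (plain or gzip) are read through Biostrings; `.txt` files are
#' taken as one sequence per line; 2-column TSV files as (sequence, count)
#' pairs which are expanded implicitly (counts kept, no read expansion).
#'
#' @param path File path.
#' @return For FASTQ/txt, a character vector of reads; for 2-column TSV, a
#'   data.frame with columns `seq` and `count`.
#' @export
read_reads <- function(path) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTQ requires the Biostrings package")
    as.character(Biostrings::readBStringSet(path, format = "fastq"))
  } else {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) {
      df <- utils::read.table(path, sep = "\t", header = FALSE,
                              col.names = c("seq", "count"),
                              colClasses = c("character", "integer"))
      df
    } else readLines(path)
  }
}

#' Write / read a count table as TSV plus JSON sidecar
#'
#' The TSV holds the sequence column and one count column per round; the
#' sidecar (`<path>.json`) records flanks, alphabet, column labels and any
#' metadata (seeds, totals), so the table round-trips exactly.
#'
#' @param table A [count_table()].
#' @param path TSV path; the sidecar is written next to it.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(seq = table$seqs, table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(left_flank = table$left_flank, right_flank = table$right_flank,
               letters = table$alphabet$letters,
               complement = as.list(table$alphabet$complement),
               col_labels = colnames(table$counts),
               totals = as.list(column_totals(table)),
               metadata = table$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "double"
  sidefile <- paste0(path, ".json")
  if (file.exists(sidefile)) {
    side <- jsonlite::read_json(sidefile, simplifyVector = TRUE)
    comp <- if (length(side$complement)) unlist(side$complement) else NULL
    alph <- pf_alphabet(side$letters, comp)
    count_table(df$seq, counts, side$left_flank, side$right_flank, alph,
                col_labels = side$col_labels,
                metadata = if (is.null(side$metadata)) list() else as.list(side$metadata))
  } else {
    count_table(df$seq, counts, col_labels = colnames(counts))
  }
}
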