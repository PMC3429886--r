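#' Read a FASTA file into sequence records
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file. Record ids are
#' the header up to the first whitespace; sequence text is returned exactly as
#' stored (case and ambiguity codes preserved — cleaning is a separate step,
#' see [clean_sequence()]).
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A data.frame with columns `id` and `seq`, one row per record, in
#'   file order. Zero rows for an empty file.
#' @seealso [build_dataset_sequence()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  # readBStringSet silently tolerates some malformed input; enforce the
  # header-first rule ourselves so the error can name the offending line.
  con <- gzfile(path, "r")
  on.exit(close(con), add = TRUE)
  lineno <- 0L
  first <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    lineno <- lineno + 1L
    if (nzchar(trimws(ln))) {
      first <- ln
      break
    }
  }
  if (is.null(first)) {
    return(data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(first, ">")) {
    stop("malformed FASTA: sequence line before any header at line ", lineno,
         " of ", path)
  }
  recs <- Biostrings::readBStringSet(path)
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA: empty record id in ", path)
  }
  data.frame(id = ids, seq = as.character(recs), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Clean a nucleotide string to the A/C/G/T alphabet
#'
#' Uppercases the input and deletes every character outside `{A,C,G,T}`
#' (ambiguity codes, N runs, gaps, whitespace). The relative order of kept
#' characters is preserved; nothing is inserted at deletion points, so k-mers
#' spanning a deletion are counted as contiguous.
#'
#' @param raw Character scalar of nucleotide text.
#' @return Character scalar over `{A,C,G,T}` (possibly empty).
#' @export
clean_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  gsub("[^ACGT]+", "", toupper(raw))
}

#' Reverse complement of an A/C/G/T string
#'
#' @param seq Character scalar over `{A,C,G,T}` (run [clean_sequence()]
#'   first if needed).
#' @return The Watson-Crick reverse complement.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return("")
  if (grepl("[^ACGT]", seq)) {
    stop("reverse_complement requires a cleaned A/C/G/T sequence; ",
         "run clean_sequence() first")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

new_sequence_set <- function(label, sequence, n_records, revcomp_appended) {
  structure(
    list(label = label, sequence = sequence, n_records = n_records,
         revcomp_appended = revcomp_appended),
    class = "SequenceSet"
  )
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat("SequenceSet '", x$label, "': ", nchar(x$sequence), " nt from ",
      x$n_records, " record(s)",
      if (x$revcomp_appended) " (reverse complement appended)", "\n",
      sep = "")
  invisible(x)
}

#' Build the single cleaned sequence for one taxon
#'
#' Concatenates the records of one dataset in file order, cleans the result
#' to `{A,C,G,T}`, and (by default) appends the reverse complement of the
#' whole concatenated sequence, making the k-mer spectrum strand-symmetric up
#' to one junction word. This is the canonical preprocessing every downstream
#' FCGR computation consumes.
#'
#' @param records data.frame with columns `id`, `seq` as from [read_fasta()].
#' @param label Taxon name for the resulting set.
#' @param append_revcomp Append the reverse complement of the concatenated,
#'   cleaned sequence (default `TRUE`).
#' @return A `SequenceSet`: list with `label`, `sequence`, `n_records`,
#'   `revcomp_appended`.
#' @examples
#' recs <- data.frame(id = c("a", "b"), seq = c("AC", "GT"))
#' build_dataset_sequence(recs, "toy")$sequence  # "ACGTACGT"
#' @export
build_dataset_sequence <- function(records, label, append_revcomp = TRUE) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  concat <- clean_sequence(paste(records$seq, collapse = ""))
  if (!nzchar(concat)) {
    stop("empty dataset: no A/C/G/T characters remain after cleaning '",
         label, "'")
  }
  if (append_revcomp) {
    concat <- paste0(concat, reverse_complement(concat))
  }
  new_sequence_set(label, concat, nrow(records), append_revcomp)
}

#' Shred a dataset to a target length by record shuffling and truncation
#'
#' Emulates sequence-length titration experiments: records (contigs or EST
#' reads, not nucleotides) are shuffled by a seeded RNG, concatenated and
#' cleaned, the prefix of `target_length` nucleotides is taken, and the
#' reverse complement of that prefix is appended. If the cleaned concatenation
#' is shorter than `target_length` the full sequence is kept with a warning.
#'
#' @param records data.frame with columns `id`, `seq`.
#' @param label Taxon name.
#' @param target_length Number of nucleotides to keep before the reverse
#'   complement is appended; must be >= 1.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `SequenceSet` of length `2 * min(target_length, available)`.
#' @export
shred_subsample <- function(records, label, target_length, seed) {
  if (!is.numeric(target_length) || target_length < 1) {
    stop("target_length must be >= 1")
  }
  perm <- with_seed(seed, sample.int(nrow(records)))
  concat <- clean_sequence(paste(records$seq[perm], collapse = ""))
  if (!nzchar(concat)) {
    stop("empty dataset: no A/C/G/T characters remain after cleaning '",
         label, "'")
  }
  if (nchar(concat) < target_length) {
    warning("dataset '", label, "' has only ", nchar(concat),
            " nt after cleaning; target ", target_length,
            " not reached, full sequence retained")
  } else {
    concat <- substr(concat, 1L, as.integer(target_length))
  }
  concat <- paste0(concat, reverse_complement(concat))
  new_sequence_set(label, concat, nrow(records), TRUE)
}

#' Write a SequenceSet as single-record FASTA
#'
#' @param ss A `SequenceSet`.
#' @param path Output file path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_sequence_set <- function(ss, path, width = 70L) {
  stopifnot(inherits(ss, "SequenceSet"))
  n <- nchar(ss$sequence)
  starts <- seq(1L, n, by = width)
  lines <- substring(ss$sequence, starts, pmin(starts + width - 1L, n))
  writeLines(c(paste0(">", ss$label), lines), path)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# random stream (Mersenne-Twister pinned for cross-platform reproducibility).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
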