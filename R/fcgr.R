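# CGR vertex convention (image coordinates, y grows downward):
#   C = (0,0) upper left, G = (1,0) upper right,
#   A = (0,1) lower left,  T = (1,1) lower right.
# Per-base half-square bits: bx = 1 for G,T (right half), by = 1 for A,T
# (lower half). Cell (row, col) is 0-based; row 0 is the top of the image.

.base_bits <- local({
  bx <- integer(128L)
  by <- integer(128L)
  ok <- logical(128L)
  for (b in c("A", "C", "G", "T")) {
    i <- utf8ToInt(b)
    ok[i] <- TRUE
    bx[i] <- as.integer(b %in% c("G", "T"))
    by[i] <- as.integer(b %in% c("A", "T"))
  }
  list(bx = bx, by = by, ok = ok)
})

seq_to_bits <- function(seq) {
  codes <- utf8ToInt(seq)
  if (length(codes) && (any(codes > 127L) || !all(.base_bits$ok[codes]))) {
    bad <- which(codes > 127L | !.base_bits$ok[pmin(codes, 127L)])[1L]
    stop("invalid character '", substr(seq, bad, bad), "' at position ", bad,
         "; only A, C, G, T are allowed (run clean_sequence() first)")
  }
  list(bx = .base_bits$bx[codes], by = .base_bits$by[codes])
}

#' Chaos game representation walk of a sequence
#'
#' Starting at the square's centre (0.5, 0.5), each nucleotide moves the
#' current point halfway toward its vertex (C upper left, G upper right,
#' A lower left, T lower right; image coordinates with y growing downward).
#' The resulting point cloud is a unique fingerprint of the sequence.
#'
#' @param seq Character scalar over `{A,C,G,T}`.
#' @return A `CGRTrail`: list with `points` (length(seq) x 2 matrix of
#'   coordinates strictly inside the unit square, columns `x`, `y`) and
#'   `start` (the centre).
#' @examples
#' cgr_walk("GCACT")$points[1, ]  # 0.75 0.25
#' @export
cgr_walk <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  bits <- seq_to_bits(seq)
  n <- length(bits$bx)
  pts <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("x", "y")))
  if (n > 0L) {
    x <- numeric(n)
    y <- numeric(n)
    px <- 0.5
    py <- 0.5
    for (i in seq_len(n)) {
      px <- 0.5 * (px + bits$bx[i])
      py <- 0.5 * (py + bits$by[i])
      x[i] <- px
      y[i] <- py
    }
    pts <- cbind(x = x, y = y)
  }
  structure(list(points = pts, start = c(0.5, 0.5)), class = "CGRTrail")
}

#' @export
print.CGRTrail <- function(x, ...) {
  cat("CGRTrail with", nrow(x$points), "points (start 0.5, 0.5)\n")
  invisible(x)
}

#' Grid cell of a k-mer on the CGR grid
#'
#' Maps a word of length k to the 0-based (row, col) cell of the
#' \eqn{2^k \times 2^k} grid that contains every CGR point whose last k steps
#' spell the word: `col = sum bx(w_i) 2^(i-1)`, `row = sum by(w_i) 2^(i-1)`
#' with bx = 1 for G/T and by = 1 for A/T, so the word's last character sets
#' the high-order bit. Row 0 is the top of the image.
#'
#' @param word Character scalar over `{A,C,G,T}`, length >= 1.
#' @return Integer vector `c(row, col)`, 0-based.
#' @examples
#' word_to_cell("CG")  # 0 2
#' word_to_cell("AA")  # 3 0
#' @export
word_to_cell <- function(word) {
  stopifnot(is.character(word), length(word) == 1L, nchar(word) >= 1L)
  bits <- seq_to_bits(word)
  w <- 2L^(seq_along(bits$bx) - 1L)
  c(row = sum(bits$by * w), col = sum(bits$bx * w))
}

new_fcgr <- function(cells, k, standardized, masked_cells, source_length) {
  structure(
    list(cells = cells, k = k, standardized = standardized,
         masked_cells = masked_cells, source_length = source_length),
    class = "FCGR"
  )
}

#' @export
print.FCGR <- function(x, ...) {
  cat("FCGR k=", x$k, " (", 2L^x$k, "x", 2L^x$k, " cells), ",
      if (x$standardized) "standardized" else "raw counts",
      if (nrow(x$masked_cells)) paste0(", ", nrow(x$masked_cells),
                                       " masked cell(s)"),
      ", source length ", x$source_length, " nt\n", sep = "")
  invisible(x)
}

#' Frequency chaos game representation (k-mer count matrix)
#'
#' Counts every overlapping k-mer window of the set's sequence into the
#' \eqn{2^k \times 2^k} CGR grid (see [word_to_cell()] for the cell layout).
#' This is exactly the binning of the CGR trail points from step k onward —
#' the first k-1 points, whose history is shorter than k, carry no complete
#' word and are excluded — but is computed by exact integer counting, so it
#' is free of floating-point drift and runs in O(kL).
#'
#' @param ss A `SequenceSet` (or a plain A/C/G/T character scalar).
#' @param k Word length, 1..8.
#' @return An `FCGR` with integer `cells` summing to `L - k + 1`.
#' @examples
#' f <- compute_fcgr(build_dataset_sequence(
#'   data.frame(id = "a", seq = "ACGTACGT"), "toy", append_revcomp = FALSE), 2)
#' sum(f$cells)  # 7
#' @export
compute_fcgr <- function(ss, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > 8L || k != round(k)) {
    stop("k must be an integer in 1..8")
  }
  k <- as.integer(k)
  seq <- if (inherits(ss, "SequenceSet")) ss$sequence else ss
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L < k) {
    stop("sequence length (", L, ") is shorter than k (", k, ")")
  }
  bits <- seq_to_bits(seq)
  m <- 2L^k
  nwin <- L - k + 1L
  col <- integer(nwin)
  row <- integer(nwin)
  for (j in seq_len(k)) {
    w <- 2L^(j - 1L)
    col <- col + bits$bx[j:(nwin + j - 1L)] * w
    row <- row + bits$by[j:(nwin + j - 1L)] * w
  }
  counts <- tabulate(row * m + col + 1L, nbins = m * m)
  cells <- matrix(counts, nrow = m, ncol = m, byrow = TRUE)
  new_fcgr(cells, k, standardized = FALSE,
           masked_cells = matrix(integer(0), ncol = 2L,
                                 dimnames = list(NULL, c("row", "col"))),
           source_length = L)
}

#' Standardize an FCGR to remove sequence-length bias
#'
#' Rescales the cell matrix A to `(4^k / sum(A)) * A`, so cells sum to
#' \eqn{4^k} and the mean cell value is 1 regardless of sequence length.
#'
#' @param f An `FCGR` with positive total count, not already standardized.
#' @return The standardized `FCGR`.
#' @export
standardize_fcgr <- function(f) {
  stopifnot(inherits(f, "FCGR"))
  if (f$standardized) stop("FCGR is already standardized")
  total <- sum(f$cells)
  if (total <= 0) stop("cannot standardize empty FCGR (all cells zero)")
  f$cells <- f$cells * (4^f$k / total)
  f$standardized <- TRUE
  f
}

#' Zero the poly-A and poly-T cells of an FCGR
#'
#' cDNA-derived (EST) data carry untrimmed poly-A tails, so the cells holding
#' the A^k and T^k homopolymers are grossly over-counted and, at high
#' resolution (k > 5), dominate distance calculations. This sets those two
#' cells of the raw count matrix to zero; masking precedes standardization so
#' that both the Euclidean path (which standardizes afterwards) and the
#' Pearson path (which uses raw counts) see the masked values.
#'
#' @param f An `FCGR` with raw (non-standardized) counts.
#' @return The `FCGR` with the two homopolymer cells zeroed and recorded in
#'   `masked_cells`. Idempotent.
#' @export
mask_homopolymer_cells <- function(f) {
  stopifnot(inherits(f, "FCGR"))
  if (f$standardized) {
    stop("mask_homopolymer_cells must be applied before standardization")
  }
  targets <- rbind(
    word_to_cell(strrep("A", f$k)),
    word_to_cell(strrep("T", f$k))
  )
  f$cells[targets + 1L] <- 0
  masked <- unique(rbind(f$masked_cells, targets))
  dimnames(masked) <- list(NULL, c("row", "col"))
  f$masked_cells <- masked
  f
}

#' Flatten an FCGR to the cell vector used by distances and the bootstrap
#'
#' Row-major order: cell (row, col) maps to index `row * 2^k + col + 1`.
#'
#' @param f An `FCGR`.
#' @return Numeric vector of length \eqn{4^k}.
#' @export
fcgr_vector <- function(f) {
  stopifnot(inherits(f, "FCGR"))
  as.vector(t(f$cells))
}

#' Write / read an FCGR as plain TSV
#'
#' `2^k` rows by `2^k` columns preceded by comment headers `#k=`,
#' `#standardized=`, `#source_length=` and (if any) `#masked=` with
#' `row,col` pairs.
#'
#' @param f An `FCGR`.
#' @param path Output file path.
#' @return `path` invisibly (`write_fcgr_tsv`); an `FCGR` (`read_fcgr_tsv`).
#' @export
write_fcgr_tsv <- function(f, path) {
  stopifnot(inherits(f, "FCGR"))
  hdr <- c(
    paste0("#k=", f$k),
    paste0("#standardized=", tolower(f$standardized)),
    paste0("#source_length=", f$source_length)
  )
  if (nrow(f$masked_cells)) {
    hdr <- c(hdr, paste0("#masked=", paste(
      paste(f$masked_cells[, 1L], f$masked_cells[, 2L], sep = ","),
      collapse = ";")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(f$cells, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_fcgr_tsv
#' @export
read_fcgr_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("^#", key, "="), "",
                           grep(paste0("^#", key, "="), hdr, value = TRUE))
  k <- as.integer(get("k"))
  standardized <- identical(get("standardized"), "true")
  source_length <- as.integer(get("source_length"))
  masked <- matrix(integer(0), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  mk <- get("masked")
  if (length(mk) == 1L && nzchar(mk)) {
    pairs <- strsplit(strsplit(mk, ";")[[1L]], ",")
    masked <- do.call(rbind, lapply(pairs, function(p) as.integer(p)))
    dimnames(masked) <- list(NULL, c("row", "col"))
  }
  cells <- as.matrix(utils::read.table(
    text = lines[!startsWith(lines, "#")], sep = "\t"))
  dimnames(cells) <- NULL
  new_fcgr(cells, k, standardized, masked, source_length)
}
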