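# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately avoid the code paths they check: cell positions
# come from the floating-point midpoint recursion, counts from a plain
# substring table.

# Cell of a word by running the midpoint walk and locating the final point
# on the 2^k grid (image coordinates, y downward).
oracle_word_cell <- function(word, k = nchar(word)) {
  vx <- c(C = 0, G = 1, A = 0, T = 1)
  vy <- c(C = 0, G = 0, A = 1, T = 1)
  x <- 0.5
  y <- 0.5
  for (ch in strsplit(word, "")[[1L]]) {
    x <- 0.5 * (x + vx[[ch]])
    y <- 0.5 * (y + vy[[ch]])
  }
  c(floor(y * 2^k), floor(x * 2^k))
}

# Naive sliding-window k-mer dictionary counter arranged by the oracle cell.
naive_fcgr_counts <- function(seq, k) {
  L <- nchar(seq)
  words <- substring(seq, 1:(L - k + 1L), k:L)
  tab <- table(words)
  m <- matrix(0L, 2L^k, 2L^k)
  for (w in names(tab)) {
    cell <- oracle_word_cell(w, k)
    m[cell[1L] + 1L, cell[2L] + 1L] <- as.integer(tab[[w]])
  }
  m
}

rc_word <- function(w) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1L]]), collapse = "")
}

all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k))))
}

rand_dna <- function(n, seed, gc = 0.5) random_sequence(n, gc = gc, seed = seed)

# Bare FCGR builder for micro-examples with hand-set cells.
make_fcgr <- function(cells, k, standardized = FALSE) {
  structure(list(cells = cells, k = k, standardized = standardized,
                 masked_cells = matrix(integer(0), ncol = 2L,
                                       dimnames = list(NULL, c("row", "col"))),
                 source_length = sum(cells)),
            class = "FCGR")
}

# Named list of raw FCGRs from random sequences.
random_profiles <- function(n, k, len = 2000L, seed0 = 1L, gc = NULL) {
  profs <- lapply(seq_len(n), function(i) {
    g <- if (is.null(gc)) 0.5 else gc[[i]]
    compute_fcgr(rand_dna(len, seed0 + i, gc = g), k)
  })
  names(profs) <- paste0("tx", seq_len(n))
  profs
}

write_fasta_tmp <- function(lines, ext = ".fasta") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
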