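# Synthetic inputs for validation: random composition-controlled sequences,
# random additive trees (the Neighbor-Joining oracle), and sequence sets
# evolved along a known tree so topology recovery can be scored against the
# truth. The substitution process is i.i.d. Jukes-Cantor-like: the method
# under test reads only k-mer composition, so indels and rate heterogeneity
# are unnecessary for exercising it.

.bases <- c("A", "C", "G", "T")

#' Random nucleotide sequence with controlled GC content
#'
#' i.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length Number of bases (>= 0).
#' @param gc Target GC fraction in `[0, 1]` (default 0.5).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return Character scalar over `{A,C,G,T}`.
#' @export
random_sequence <- function(length, gc = 0.5, seed = 1L) {
  stopifnot(length >= 0)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (length == 0) return("")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, paste(sample(.bases, length, replace = TRUE, prob = probs),
                        collapse = ""))
}

#' Random additive tree and its exact path-length matrix
#'
#' Draws a random unrooted topology with branch lengths uniform on
#' `[0.1, 1]` and returns it with the matrix of exact leaf-to-leaf path
#' lengths. Such a matrix is additive by construction, so distance methods
#' that are consistent on additive input (Neighbor-Joining, least squares)
#' must recover the tree exactly — the oracle used throughout the tests.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param seed Integer seed.
#' @return List with `tree` (`phylo`, tips `t1..tn`) and `matrix` (labeled
#'   symmetric path-length matrix).
#' @export
random_additive_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  tree <- with_seed(seed,
    ape::rtree(n_taxa, rooted = FALSE,
               br = function(n) stats::runif(n, 0.1, 1)))
  m <- ape::cophenetic.phylo(tree)
  m <- m[order(rownames(m)), order(colnames(m))]
  list(tree = tree, matrix = m)
}

#' Define a sequence-evolution scenario along a known tree
#'
#' @param tree `phylo` tree with branch lengths in expected substitutions
#'   per site.
#' @param root_length Root sequence length in nucleotides.
#' @param rate Substitution rate multiplier; the per-site substitution
#'   probability on a branch of length b is `1 - exp(-rate * b)`, to a
#'   uniformly chosen different base.
#' @param gc Root GC fraction.
#' @param seed Integer seed covering the whole scenario.
#' @return A `SimScenario` list.
#' @export
sim_scenario <- function(tree, root_length = 50000L, rate = 1.0, gc = 0.5,
                         seed = 1L) {
  stopifnot(inherits(tree, "phylo"), root_length >= 1, rate >= 0)
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  structure(list(tree = tree, root_length = as.integer(root_length),
                 rate = rate, gc = gc, seed = as.integer(seed)),
            class = "SimScenario")
}

#' Evolve leaf sequences along a scenario's tree
#'
#' Draws an i.i.d. root sequence, then copies it down every branch with
#' per-site substitution probability `1 - exp(-rate * branch_length)` to a
#' uniformly random different base. Only leaf sequences are returned.
#'
#' @param scn A `SimScenario` from [sim_scenario()].
#' @return Named character vector of leaf sequences (names = tip labels).
#' @export
evolve_sequences <- function(scn) {
  stopifnot(inherits(scn, "SimScenario"))
  tree <- scn$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  with_seed(scn$seed, {
    probs <- c((1 - scn$gc) / 2, scn$gc / 2, scn$gc / 2, (1 - scn$gc) / 2)
    L <- scn$root_length
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample.int(4L, L, replace = TRUE, prob = probs)
    # preorder: parents are filled before their children
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1L]
      child <- edges[e, 2L]
      s <- seqs[[parent]]
      p <- 1 - exp(-scn$rate * lens[e])
      hit <- which(stats::runif(L) < p)
      if (length(hit)) {
        s[hit] <- 1L + (s[hit] - 1L +
                          sample.int(3L, length(hit), replace = TRUE)) %% 4L
      }
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(ntip), function(i) {
      paste(.bases[seqs[[i]]], collapse = "")
    }, character(1))
    names(out) <- tree$tip.label
    out
  })
}

#' Preset two-clade eight-taxon tree
#'
#' `((A,B),(C,D))` versus `((E,F),(G,H))`: leaf and within-clade internal
#' edges of 0.05 substitutions/site, central edge 0.20. A clean, clearly
#' resolved truth for recovery experiments.
#'
#' @return A `phylo` tree.
#' @export
two_clade_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.1,",
    "((E:0.05,F:0.05):0.05,(G:0.05,H:0.05):0.05):0.1);"))
}

#' Split a sequence into roughly equal records
#'
#' @param seq Character scalar.
#' @param n_records Number of records.
#' @return data.frame with columns `id`, `seq`.
#' @export
split_records <- function(seq, n_records = 1L) {
  stopifnot(n_records >= 1L)
  L <- nchar(seq)
  bounds <- floor(seq(0, L, length.out = n_records + 1L))
  data.frame(
    id = paste0("rec", seq_len(n_records)),
    seq = substring(seq, bounds[-length(bounds)] + 1L, bounds[-1L]),
    stringsAsFactors = FALSE
  )
}

#' Append poly-A tails to records (EST library emulation)
#'
#' Appends an `A` homopolymer of Poisson-distributed length to the 3' end of
#' every record, emulating untrimmed cDNA poly-A tails. Tail content is
#' independent of the records' phylogenetic signal, which is exactly why
#' unmasked high-resolution FCGRs are misled by it.
#'
#' @param records data.frame with columns `id`, `seq`.
#' @param mean_tail Mean tail length in nucleotides.
#' @param seed Integer seed.
#' @return The records with tails appended.
#' @export
append_polya_tails <- function(records, mean_tail, seed = 1L) {
  stopifnot(mean_tail >= 0)
  lens <- with_seed(seed, stats::rpois(nrow(records), mean_tail))
  records$seq <- paste0(records$seq, strrep("A", lens))
  records
}

#' Write simulated taxa as FASTA files for the pipeline
#'
#' One multi-record FASTA per taxon under `dir`; returns the taxa table
#' [run_config()] expects.
#'
#' @param seqs Named character vector of per-taxon sequences (e.g. from
#'   [evolve_sequences()]).
#' @param dir Output directory (created if needed).
#' @param n_records Records per taxon (sequences are split evenly).
#' @param datatype Datatype tag recorded in the taxa table.
#' @param polya_mean If positive, append poly-A tails of this mean length to
#'   every record; may be a vector, recycled over taxa (per-taxon tail mass
#'   independent of the phylogeny is what misleads unmasked trees).
#' @param seed Seed for tail lengths.
#' @return data.frame with columns `label`, `path`, `datatype`.
#' @export
write_taxa_fasta <- function(seqs, dir, n_records = 1L, datatype = "genome",
                             polya_mean = 0, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  polya_mean <- rep_len(polya_mean, length(seqs))
  paths <- character(length(seqs))
  for (i in seq_along(seqs)) {
    recs <- split_records(seqs[[i]], n_records)
    if (polya_mean[i] > 0) {
      recs <- append_polya_tails(recs, polya_mean[i], seed = seed + i)
    }
    path <- file.path(dir, paste0(names(seqs)[i], ".fasta"))
    con <- file(path, "w")
    for (r in seq_len(nrow(recs))) {
      writeLines(c(paste0(">", recs$id[r]), recs$seq[r]), con)
    }
    close(con)
    paths[i] <- path
  }
  data.frame(label = names(seqs), path = paths, datatype = datatype,
             stringsAsFactors = FALSE)
}
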