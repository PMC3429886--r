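# FCGR bootstrap: the 4^k cells are the resampled characters. One shared
# index vector per replicate is applied to every taxon's flattened profile
# (the taxon-by-character bootstrap, with FCGR cells as characters), so
# cross-taxon comparability is preserved within each replicate.

#' Draw a bootstrap index vector over the FCGR cells
#'
#' `4^k` indices drawn uniformly with replacement from `1..4^k`, using the
#' current RNG stream (or a fixed `seed` when given).
#'
#' @param k Word length, 1..8.
#' @param seed Optional integer seed for an isolated, reproducible draw.
#' @return Integer vector of length `4^k`.
#' @export
resample_cell_indices <- function(k, seed = NULL) {
  stopifnot(k >= 1L, k <= 8L)
  n <- 4L^k
  if (is.null(seed)) sample.int(n, n, replace = TRUE)
  else with_seed(seed, sample.int(n, n, replace = TRUE))
}

#' Resample every taxon's FCGR at a shared set of cell indices
#'
#' @param profiles Named list of raw-count `FCGR`s (or flattened numeric
#'   vectors), all with the same `k`.
#' @param indices Index vector of length `4^k` from
#'   [resample_cell_indices()].
#' @return Named list of resampled flattened profiles (numeric vectors).
#' @export
bootstrap_replicate <- function(profiles, indices) {
  vecs <- lapply(profiles, function(p) {
    if (inherits(p, "FCGR")) fcgr_vector(p) else p
  })
  len <- lengths(vecs)
  if (length(unique(len)) != 1L || len[[1L]] != length(indices)) {
    stop("profiles and index vector disagree in length (mismatched k?)")
  }
  lapply(vecs, function(v) v[indices])
}

# Distance matrix over flattened raw-count profiles. The Euclidean path
# standardizes each vector (sum to 4^k) first, so every bootstrap replicate
# satisfies the standardized-input precondition; the Pearson path uses the
# raw values.
profile_distance_matrix <- function(vecs, metric, k) {
  labels <- names(vecs)
  n <- length(vecs)
  if (metric == "euclidean") {
    vecs <- lapply(vecs, function(v) {
      total <- sum(v)
      if (total <= 0) stop("cannot standardize empty FCGR (all cells zero)")
      v * (4^k / total)
    })
  }
  values <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- if (metric == "euclidean") {
        sqrt(sum((vecs[[i]] - vecs[[j]])^2) / 4^k)
      } else {
        pearson_distance_vec(vecs[[i]], vecs[[j]])
      }
      values[i, j] <- d
      values[j, i] <- d
    }
  }
  new_distance_matrix(values, metric, k)
}

#' Bootstrap a set of FCGR profiles into replicate NJ trees
#'
#' The core resampling engine: draws one shared cell-index vector per
#' replicate, resamples every taxon's raw profile at those cells, computes
#' the replicate distance matrix (re-standardizing on the Euclidean path)
#' and its Neighbor-Joining tree. Replicates whose Pearson distances
#' degenerate (zero weighted variance) are redrawn from the next seed
#' substream; after 10 consecutive failures the run aborts.
#'
#' @param profiles Named list of raw-count `FCGR`s, all with the same `k`.
#' @param metric `"euclidean"` or `"pearson"`.
#' @param replicates Number of bootstrap replicates.
#' @param seed Master seed; replicate r uses the r-th substream seed, so any
#'   replicate is reproducible in isolation.
#' @return List with `trees` (the replicate `phylo` trees) and
#'   `failed_replicates` (number of redrawn degenerate replicates).
#' @export
bootstrap_trees <- function(profiles, metric = c("euclidean", "pearson"),
                            replicates = 500L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(replicates >= 1L)
  k <- profiles[[1L]]$k
  vecs <- lapply(profiles, fcgr_vector)
  rep_seeds <- with_seed(seed,
    sample.int(2147483646L, replicates + 64L, replace = FALSE))
  trees <- vector("list", replicates)
  failed <- 0L
  pos <- 0L
  for (r in seq_len(replicates)) {
    consecutive <- 0L
    repeat {
      pos <- pos + 1L
      if (pos > length(rep_seeds)) {
        stop("bootstrap seed substreams exhausted")
      }
      idx <- resample_cell_indices(k, seed = rep_seeds[pos])
      res <- tryCatch({
        dm <- profile_distance_matrix(
          lapply(vecs, function(v) v[idx]), metric, k)
        neighbor_joining(dm)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      failed <- failed + 1L
      consecutive <- consecutive + 1L
      if (consecutive >= 10L) {
        stop("bootstrap aborted: 10 consecutive degenerate replicates (",
             conditionMessage(res), ")")
      }
    }
    trees[[r]] <- res
  }
  list(trees = trees, failed_replicates = failed)
}
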