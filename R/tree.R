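# Trees are ape "phylo" objects throughout; bootstrap supports live in
# node.label (numeric percentage, NA where undefined, e.g. the root).

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: iteratively joins the pair minimizing
#' the rate-corrected Q criterion and reduces the matrix. Exact on additive
#' matrices. Negative branch-length estimates (possible on non-additive
#' input) are clamped to zero.
#'
#' @param d A `DistanceMatrix` or a labeled symmetric numeric matrix with at
#'   least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  values <- if (inherits(d, "DistanceMatrix")) d$values else d
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (nrow(values) < 3L) stop("Neighbor-Joining needs at least 3 taxa")
  if (any(!is.finite(values))) stop("distance matrix has non-finite entries")
  tree <- ape::nj(values)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

# Canonical bipartition keys of the non-trivial splits of an unrooted tree.
# The key is the sorted label set of the side NOT containing the
# alphabetically first leaf, joined with "\r" (never a label character).
# Returns a character vector named by the internal (child) node of each edge.
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  ntip <- length(labels)
  ref <- sort(labels)[1L]
  internal <- unique(tree$edge[tree$edge[, 2L] > ntip, 2L])
  if (length(internal) == 0L) return(setNames(character(0), integer(0)))
  desc <- phangorn::Descendants(tree, internal, type = "tips")
  keys <- vapply(seq_along(internal), function(i) {
    side <- labels[desc[[i]]]
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    if (ref %in% side) side <- setdiff(labels, side)
    paste(sort(side), collapse = "\r")
  }, character(1))
  keep <- !is.na(keys) & !duplicated(keys)
  setNames(keys[keep], internal[keep])
}

check_same_leaves <- function(trees) {
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("tree ", i, " has a different leaf set from tree 1")
    }
  }
  ref
}

#' Majority-rule consensus tree with split supports
#'
#' Returns the tree containing exactly the bipartitions present in more than
#' `threshold` of the input trees, each internal edge annotated (in
#' `node.label`) with its percentage occurrence. No greedy completion with
#' lower-frequency compatible splits is applied at the default threshold.
#' For `threshold < 0.5` retained splits can conflict; they are then added
#' in decreasing frequency order and incompatible ones dropped with a
#' warning.
#'
#' @param trees List of `phylo` trees over identical leaf sets.
#' @param threshold Fraction in `[0, 1)`; a split is kept when its frequency
#'   strictly exceeds it (default 0.5, majority rule).
#' @return A `phylo` consensus tree without branch lengths; supports as
#'   numeric `node.label` (NA on the root).
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1L, threshold >= 0, threshold < 1)
  labels <- check_same_leaves(trees)
  B <- length(trees)
  all_keys <- unlist(lapply(trees, tree_bipartitions), use.names = FALSE)
  tab <- table(all_keys)
  freq <- as.numeric(tab) / B
  keys <- names(tab)[freq > threshold]
  pct <- 100 * freq[freq > threshold]
  ord <- order(-pct, keys)
  keys <- keys[ord]
  pct <- pct[ord]
  clades <- lapply(strsplit(keys, "\r", fixed = TRUE), identity)
  if (threshold < 0.5 && length(clades) > 1L) {
    keep <- compatible_filter(clades, labels)
    if (!all(keep)) warning(sum(!keep), " conflicting split(s) below the ",
                            "majority threshold were dropped")
    clades <- clades[keep]
    pct <- pct[keep]
  }
  build_tree_from_clades(labels, clades, pct)
}

# Greedily keep pairwise-compatible splits (decreasing-frequency order).
compatible_filter <- function(clades, labels) {
  keep <- logical(length(clades))
  kept <- list()
  for (i in seq_along(clades)) {
    a <- clades[[i]]
    ok <- all(vapply(kept, function(b) {
      length(intersect(a, b)) == 0L || all(a %in% b) || all(b %in% a) ||
        length(union(a, b)) == length(labels)
    }, logical(1)))
    if (ok) {
      keep[i] <- TRUE
      kept <- c(kept, list(a))
    }
  }
  keep
}

# Assemble a phylo tree from a laminar family of clades (label vectors, none
# containing the reference leaf), each with a support percentage.
build_tree_from_clades <- function(labels, clades, pct) {
  ref <- sort(labels)[1L]
  ord <- order(lengths(clades))
  clades <- clades[ord]
  pct <- pct[ord]
  sizes <- lengths(clades)
  nc <- length(clades)
  # parent[i]: index of the smallest clade strictly containing clade i; NA = root
  parent <- rep(NA_integer_, nc)
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        if (sizes[j] > sizes[i] && all(clades[[i]] %in% clades[[j]])) {
          parent[i] <- j
          break
        }
      }
    }
  }
  tip_parent <- vapply(labels, function(tp) {
    holders <- which(vapply(clades, function(cl) tp %in% cl, logical(1)))
    if (length(holders)) holders[which.min(lengths(clades[holders]))]
    else NA_integer_
  }, integer(1))
  quote_label <- function(x) {
    if (grepl("[(),:;\\[\\]' \t]", x)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  render <- function(node) {
    # node: NA for root, else clade index
    if (is.na(node)) {
      child_clades <- which(is.na(parent))
      child_tips <- labels[is.na(tip_parent)]
    } else {
      child_clades <- which(!is.na(parent) & parent == node)
      child_tips <- labels[!is.na(tip_parent) & tip_parent == node]
    }
    parts <- c(vapply(child_tips, quote_label, character(1)),
               vapply(child_clades, render, character(1)))
    inner <- paste(parts, collapse = ",")
    if (is.na(node)) paste0("(", inner, ");")
    else paste0("(", inner, ")", format(pct[node], digits = 10))
  }
  tree <- ape::read.tree(text = render(NA_integer_))
  if (!is.null(tree$node.label)) {
    supports <- suppressWarnings(as.numeric(tree$node.label))
    supports[!nzchar(tree$node.label)] <- NA_real_
    tree$node.label <- supports
  }
  tree
}

#' Annotate a tree's internal edges with bootstrap split frequencies
#'
#' For each internal edge of `tree`, records in `node.label` the percentage
#' of `replicate_trees` that contain the same bipartition. Used to plot
#' supports onto a point-estimate tree whose topology may differ from the
#' consensus.
#'
#' @param tree A `phylo` tree.
#' @param replicate_trees List of `phylo` trees over the same leaf set.
#' @return `tree` with numeric `node.label` supports (NA for the root and
#'   any node not subtending a non-trivial split).
#' @export
annotate_supports <- function(tree, replicate_trees) {
  check_same_leaves(c(list(tree), replicate_trees))
  B <- length(replicate_trees)
  counts <- table(unlist(lapply(replicate_trees, tree_bipartitions),
                         use.names = FALSE))
  keys <- tree_bipartitions(tree)
  supports <- rep(NA_real_, tree$Nnode)
  ntip <- length(tree$tip.label)
  for (i in seq_along(keys)) {
    node <- as.integer(names(keys)[i])
    hit <- counts[keys[i]]
    supports[node - ntip] <- 100 * (if (is.na(hit)) 0 else as.numeric(hit)) / B
  }
  tree$node.label <- supports
  tree
}

#' Least-squares branch lengths on a fixed topology
#'
#' Fits non-negative branch lengths minimizing the Fitch-Margoliash weighted
#' residual \eqn{\sum_{i<j} (d_{ij} - p_{ij})^2 / d_{ij}^2}, where
#' \eqn{p_{ij}} is the tree path length, by non-negative least squares on
#' the pair-by-edge incidence system. The topology (typically a consensus
#' tree, possibly multifurcating) is left untouched. Zero off-diagonal
#' distances get unit weight with a warning.
#'
#' @param topology A `phylo` tree whose leaf set equals the matrix labels.
#' @param d A `DistanceMatrix` or labeled symmetric matrix.
#' @param power Exponent of the weights `1/d^power` (default 2, the
#'   Fitch-Margoliash choice; 0 gives ordinary least squares).
#' @return `topology` with fitted `edge.length`.
#' @export
fit_branch_lengths <- function(topology, d, power = 2) {
  stopifnot(inherits(topology, "phylo"))
  values <- if (inherits(d, "DistanceMatrix")) d$values else d
  labels <- rownames(values)
  if (!setequal(labels, topology$tip.label)) {
    stop("topology leaf set does not match distance matrix labels")
  }
  ntip <- length(topology$tip.label)
  nedge <- nrow(topology$edge)
  tipsets <- phangorn::Descendants(topology, topology$edge[, 2L],
                                   type = "tips")
  tip_index <- match(labels, topology$tip.label)
  inset <- matrix(FALSE, nedge, ntip)  # inset[e, t]: tip t below edge e
  for (e in seq_len(nedge)) inset[e, tipsets[[e]]] <- TRUE
  pairs <- which(upper.tri(values), arr.ind = TRUE)
  npair <- nrow(pairs)
  A <- matrix(0, npair, nedge)
  b <- numeric(npair)
  w <- numeric(npair)
  for (p in seq_len(npair)) {
    i <- tip_index[pairs[p, 1L]]
    j <- tip_index[pairs[p, 2L]]
    A[p, ] <- xor(inset[, i], inset[, j])
    dij <- values[pairs[p, 1L], pairs[p, 2L]]
    b[p] <- dij
    w[p] <- if (dij > 0) dij^(-power) else 1
  }
  if (any(b == 0)) {
    warning("zero off-diagonal distance(s); unit weight used for those pairs")
  }
  sw <- sqrt(w)
  fit <- pracma::lsqnonneg(A * sw, b * sw)
  topology$edge.length <- fit$x
  topology
}

#' Write / parse Newick
#'
#' Thin wrappers over ape's Newick support. `tree_to_newick` writes branch
#' lengths with 6 significant digits and, when requested, supports as
#' internal node labels. `parse_newick` reads numeric internal labels back
#' into numeric supports.
#'
#' @param t A `phylo` tree.
#' @param include_supports Write `node.label` supports (default TRUE when
#'   present).
#' @param digits Significant digits for branch lengths.
#' @return `tree_to_newick`: a Newick string. `parse_newick`: a `phylo`.
#' @export
tree_to_newick <- function(t, include_supports = TRUE, digits = 6) {
  stopifnot(inherits(t, "phylo"))
  if (!include_supports) {
    t$node.label <- NULL
  } else if (!is.null(t$node.label) && is.numeric(t$node.label)) {
    lab <- format(t$node.label, digits = 10, trim = TRUE)
    lab[is.na(t$node.label)] <- ""
    t$node.label <- lab
  }
  ape::write.tree(t, digits = digits)
}

#' @rdname tree_to_newick
#' @param text A Newick string.
#' @export
parse_newick <- function(text) {
  t <- tryCatch(ape::read.tree(text = text),
                error = function(e) stop("Newick parse error: ",
                                         conditionMessage(e)))
  if (is.null(t)) stop("Newick parse error: no tree found in text")
  if (!is.null(t$node.label)) {
    num <- suppressWarnings(as.numeric(t$node.label))
    if (all(is.na(num) == !nzchar(t$node.label))) t$node.label <- num
  }
  t
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees. Zero iff the unrooted topologies agree.
#'
#' @param a,b `phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(a, b) {
  check_same_leaves(list(a, b))
  ka <- tree_bipartitions(a)
  kb <- tree_bipartitions(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
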