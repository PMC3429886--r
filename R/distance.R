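#' Euclidean distance between two standardized FCGRs
#'
#' \eqn{d = (2^k/4^k) \sqrt{\sum_{ij} (\bar a_{ij} - \bar b_{ij})^2}}, the
#' root-mean-square cell difference over the \eqn{4^k} cells. Both inputs
#' must be standardized (see [standardize_fcgr()]) and carry the same mask.
#' The positive prefactor is inert for tree topologies (any rescaling of a
#' distance matrix leaves Neighbor-Joining's choices unchanged).
#'
#' @param a,b Standardized `FCGR`s with equal `k`.
#' @return Non-negative numeric distance.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(inherits(a, "FCGR"), inherits(b, "FCGR"))
  if (a$k != b$k) stop("FCGRs have different k: ", a$k, " vs ", b$k)
  if (!a$standardized || !b$standardized) {
    stop("euclidean_distance requires standardized FCGRs")
  }
  sqrt(sum((a$cells - b$cells)^2) / 4^a$k)
}

#' Weighted Pearson distance between two raw-count FCGRs
#'
#' One minus a Pearson correlation in which each cell pair is weighted by
#' the product of its two values: with flattened profiles x, y and
#' \eqn{n_w = \sum x_i y_i}, the weighted means are
#' \eqn{\bar x_w = \sum x_i^2 y_i / n_w}, \eqn{\bar y_w = \sum y_i^2 x_i / n_w},
#' the weighted standard deviations
#' \eqn{s_x = \sqrt{\sum (x_i - \bar x_w)^2 x_i y_i / n_w}} (and likewise
#' \eqn{s_y}), and
#' \eqn{d = 1 - \sum \frac{x_i - \bar x_w}{s_x}\frac{y_i - \bar y_w}{s_y}
#' \frac{x_i y_i}{n_w}}. Ranges over `[0, 2]` for non-negative profiles.
#' Operates on non-standardized counts; the weighting itself removes the
#' length scale (jointly rescaling both profiles leaves d unchanged).
#'
#' @param a,b Raw-count (non-standardized) `FCGR`s with equal `k`.
#' @return Numeric distance in `[0, 2]`.
#' @export
pearson_distance <- function(a, b) {
  stopifnot(inherits(a, "FCGR"), inherits(b, "FCGR"))
  if (a$k != b$k) stop("FCGRs have different k: ", a$k, " vs ", b$k)
  if (a$standardized || b$standardized) {
    stop("pearson_distance requires non-standardized (raw count) FCGRs")
  }
  pearson_distance_vec(fcgr_vector(a), fcgr_vector(b))
}

# Flattened-profile form shared with the bootstrap path.
pearson_distance_vec <- function(x, y) {
  w <- x * y
  nw <- sum(w)
  if (nw <= 0) stop("no shared support: sum of x_i * y_i is zero")
  xw <- sum(x * w) / nw
  yw <- sum(y * w) / nw
  sx <- sqrt(sum((x - xw)^2 * w) / nw)
  sy <- sqrt(sum((y - yw)^2 * w) / nw)
  if (sx == 0 || sy == 0) {
    stop("degenerate profile: zero weighted variance")
  }
  1 - sum(((x - xw) / sx) * ((y - yw) / sy) * w) / nw
}

new_distance_matrix <- function(values, metric, k) {
  structure(list(labels = rownames(values), values = values,
                 metric = metric, k = k),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("DistanceMatrix (", x$metric, ", k=", x$k, ") over ",
      length(x$labels), " taxa\n", sep = "")
  print(round(x$values, 6))
  invisible(x)
}

#' Pairwise FCGR distance matrix for a set of taxa
#'
#' Computes all n(n-1)/2 pairs once and mirrors them, guaranteeing exact
#' symmetry and a zero diagonal. For `metric = "euclidean"` the profiles must
#' be standardized; for `metric = "pearson"` they must be raw counts.
#'
#' @param profiles Named list of `FCGR`s (names are taxon labels), all with
#'   the same `k`. At least 3.
#' @param metric `"euclidean"` or `"pearson"`.
#' @return A `DistanceMatrix`: list with `labels`, `values` (labeled
#'   symmetric matrix), `metric`, `k`.
#' @export
build_distance_matrix <- function(profiles, metric = c("euclidean", "pearson")) {
  metric <- match.arg(metric)
  labels <- names(profiles)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("profiles must be a named list of FCGRs")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  n <- length(profiles)
  if (n < 3L) stop("need at least 3 profiles, got ", n)
  ks <- vapply(profiles, function(p) p$k, numeric(1))
  if (length(unique(ks)) != 1L) {
    stop("inconsistent k across profiles: ", paste(unique(ks), collapse = ", "))
  }
  dfun <- if (metric == "euclidean") euclidean_distance else pearson_distance
  values <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- dfun(profiles[[i]], profiles[[j]])
      values[i, j] <- d
      values[j, i] <- d
    }
  }
  new_distance_matrix(values, metric, ks[[1L]])
}

#' Write / read a PHYLIP square distance matrix
#'
#' Classic PHYLIP format: first line the number of taxa, then one row per
#' taxon with the name padded to 10 characters followed by the n distances.
#' Names longer than 10 characters are truncated; a truncation that makes
#' two names collide is an error.
#'
#' @param d A `DistanceMatrix` (or a labeled symmetric matrix).
#' @param path Output file path; for `write_phylip` with `path = NULL` the
#'   text is returned instead of written.
#' @return `write_phylip`: the formatted text (invisibly if written to file).
#'   `read_phylip`: a labeled symmetric matrix.
#' @export
write_phylip <- function(d, path = NULL) {
  values <- if (inherits(d, "DistanceMatrix")) d$values else d
  labels <- rownames(values)
  short <- substr(labels, 1L, 10L)
  if (anyDuplicated(short)) {
    dup <- unique(short[duplicated(short)])
    stop("taxon names collide after truncation to 10 characters: ",
         paste(dup, collapse = ", "))
  }
  rows <- vapply(seq_along(labels), function(i) {
    paste0(formatC(short[i], width = -10L),
           paste(sprintf("%.6f", values[i, ]), collapse = " "))
  }, character(1))
  text <- paste(c(length(labels), rows), collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) != n + 1L) {
    stop("malformed PHYLIP distance file: expected ", n, " taxon rows")
  }
  labels <- character(n)
  values <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- lines[i + 1L]
    labels[i] <- trimws(substr(row, 1L, 10L))
    values[i, ] <- as.numeric(strsplit(trimws(substring(row, 11L)),
                                       "\\s+")[[1L]])
  }
  dimnames(values) <- list(labels, labels)
  values
}

#' Write a distance matrix as TSV with full-length labels
#'
#' Lossless alternative to the 10-character PHYLIP format.
#'
#' @param d A `DistanceMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distmat_tsv <- function(d, path) {
  stopifnot(inherits(d, "DistanceMatrix"))
  utils::write.table(d$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
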