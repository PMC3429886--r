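#' Configuration for a full FCGR phylogeny run
#'
#' @param taxa data.frame with columns `label`, `path` (FASTA file, plain or
#'   gzipped) and optionally `datatype` (`"genome"`, `"est"` or `"mito"`;
#'   default `"genome"`). Poly-A/poly-T FCGR cells are masked for `"est"`
#'   datasets.
#' @param k Word length, 1..8 (default 6).
#' @param metric `"euclidean"` (on standardized FCGRs) or `"pearson"` (on
#'   raw counts).
#' @param replicates Bootstrap replicates (default 500).
#' @param seed Master seed for the bootstrap (default 1).
#' @param append_revcomp Append each taxon's reverse complement before
#'   counting (default TRUE).
#' @param consensus_threshold Split-frequency threshold for the consensus
#'   (default 0.5, strict majority).
#' @return A `RunConfig` list, validated.
#' @export
run_config <- function(taxa, k = 6L, metric = c("euclidean", "pearson"),
                       replicates = 500L, seed = 1L, append_revcomp = TRUE,
                       consensus_threshold = 0.5) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(taxa), all(c("label", "path") %in% names(taxa)))
  if (is.null(taxa$datatype)) taxa$datatype <- "genome"
  if (!all(taxa$datatype %in% c("genome", "est", "mito"))) {
    stop("datatype must be one of genome, est, mito")
  }
  if (nrow(taxa) < 3L) stop("need at least 3 taxa")
  if (anyDuplicated(taxa$label)) stop("duplicate taxon labels")
  if (k < 1L || k > 8L) stop("k must be in 1..8")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(taxa = taxa, k = as.integer(k), metric = metric,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 append_revcomp = append_revcomp,
                 consensus_threshold = consensus_threshold),
            class = "RunConfig")
}

#' Raw FCGR profiles for a set of sequence sets
#'
#' Computes the raw-count FCGR of each `SequenceSet` and masks the
#' homopolymer cells where requested (EST-type data).
#'
#' @param sets Named list of `SequenceSet`s.
#' @param k Word length.
#' @param mask Logical scalar or vector (per set): zero the poly-A/poly-T
#'   cells.
#' @return Named list of raw-count `FCGR`s.
#' @export
fcgr_profiles <- function(sets, k, mask = FALSE) {
  mask <- rep_len(mask, length(sets))
  profiles <- lapply(seq_along(sets), function(i) {
    f <- compute_fcgr(sets[[i]], k)
    if (mask[i]) f <- mask_homopolymer_cells(f)
    f
  })
  names(profiles) <- names(sets)
  profiles
}

#' Run the full alignment-free phylogeny pipeline
#'
#' Stages: (1) read and clean each taxon's FASTA into a single sequence
#' (reverse complement appended); (2) raw FCGRs at resolution k, with
#' poly-A/poly-T cells masked for EST datasets; (3) point distance matrix
#' (Euclidean on standardized or weighted Pearson on raw FCGRs) and point
#' Neighbor-Joining tree, annotated with bootstrap supports; (4) bootstrap
#' replicate trees by resampling the 4^k FCGR cells with a shared index
#' vector per replicate; (5) majority-rule consensus with percentage
#' supports; (6) branch lengths fitted on the fixed consensus topology by
#' weighted least squares against the point distance matrix. Fully
#' reproducible given the seed.
#'
#' @param cfg A `RunConfig` from [run_config()].
#' @param outdir Optional directory; when given, Newick trees, the distance
#'   matrix (TSV and, names permitting, PHYLIP) and a MANIFEST are written.
#' @return A `BootstrapResult`: list with `point_tree` (supports annotated),
#'   `consensus` (supports + fitted branch lengths), `replicate_trees`,
#'   `distance_matrix`, `failed_replicates`, `config`.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  sets <- stage("seqio", {
    s <- lapply(seq_len(nrow(cfg$taxa)), function(i) {
      build_dataset_sequence(read_fasta(cfg$taxa$path[i]),
                             cfg$taxa$label[i],
                             append_revcomp = cfg$append_revcomp)
    })
    names(s) <- cfg$taxa$label
    s
  })
  profiles <- stage("fcgr",
    fcgr_profiles(sets, cfg$k, mask = cfg$taxa$datatype == "est"))
  distmat <- stage("distance", {
    if (cfg$metric == "euclidean") {
      build_distance_matrix(lapply(profiles, standardize_fcgr), "euclidean")
    } else {
      build_distance_matrix(profiles, "pearson")
    }
  })
  point_tree <- stage("tree", neighbor_joining(distmat))
  boot <- stage("bootstrap",
    bootstrap_trees(profiles, cfg$metric, cfg$replicates, cfg$seed))
  consensus <- stage("consensus",
    majority_consensus(boot$trees, cfg$consensus_threshold))
  consensus <- stage("branch-lengths", {
    fitted <- fit_branch_lengths(consensus, distmat)
    fitted
  })
  point_tree <- stage("supports", annotate_supports(point_tree, boot$trees))
  result <- structure(
    list(point_tree = point_tree, consensus = consensus,
         replicate_trees = boot$trees, distance_matrix = distmat,
         failed_replicates = boot$failed_replicates, config = cfg),
    class = "BootstrapResult")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

#' @export
print.BootstrapResult <- function(x, ...) {
  cat("BootstrapResult: ", length(x$config$taxa$label), " taxa, k=",
      x$config$k, ", ", x$config$metric, ", ",
      length(x$replicate_trees), " replicates (",
      x$failed_replicates, " redrawn)\n", sep = "")
  cat("consensus: ", tree_to_newick(x$consensus), "\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  put <- function(file, what) {
    manifest <<- c(manifest, paste0(file, "\t", what))
  }
  writeLines(tree_to_newick(result$point_tree),
             file.path(outdir, "point.nwk"))
  put("point.nwk", "NJ point-estimate tree with bootstrap supports")
  writeLines(tree_to_newick(result$consensus),
             file.path(outdir, "consensus.nwk"))
  put("consensus.nwk",
      "majority consensus, supports + fitted branch lengths")
  writeLines(vapply(result$replicate_trees, tree_to_newick, character(1)),
             file.path(outdir, "replicates.nwk"))
  put("replicates.nwk", "bootstrap replicate trees")
  write_distmat_tsv(result$distance_matrix, file.path(outdir, "distmat.tsv"))
  put("distmat.tsv", "point distance matrix (full labels)")
  phy <- tryCatch(write_phylip(result$distance_matrix,
                               file.path(outdir, "distmat.phy")),
                  error = function(e) conditionMessage(e))
  put("distmat.phy", if (file.exists(file.path(outdir, "distmat.phy")))
    "point distance matrix (PHYLIP)" else paste("skipped:", phy))
  cfg <- result$config
  put("config", sprintf(
    "k=%d metric=%s replicates=%d seed=%d append_revcomp=%s threshold=%g restandardize_per_replicate=true",
    cfg$k, cfg$metric, cfg$replicates, cfg$seed, cfg$append_revcomp,
    cfg$consensus_threshold))
  put("failed_replicates", as.character(result$failed_replicates))
  writeLines(manifest, file.path(outdir, "MANIFEST"))
  invisible(outdir)
}
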