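#' Run the full clustering pipeline
#'
#' Executes, in order: allele-sharing similarity, divisive spectral tree,
#' reduced-error pruning into nested partitions, gap-statistic selection of
#' the number of clusters.  All randomness (null-reference simulation) flows
#' from the single \code{seed}; a rerun with the same inputs and seed is
#' byte-identical.
#'
#' @param G a [geno_matrix()] (or path via \code{input}/\code{format}).
#' @param input,format alternative to \code{G}: a file read with
#'   [read_genotype_matrix()].
#' @param k_max maximum number of clusters entered in the gap table
#'   (default 20).
#' @param B number of null datasets for the gap statistic (default 20).
#' @param seed master seed (default 1).
#' @param min_node_size smallest group the spectral step will try to split
#'   (default 3).
#' @param model_names GMM covariance models for the bisection step; see
#'   [bisect()].
#' @param k optional override: skip gap selection and return the stored
#'   k-cluster partition (the nearest realized k not exceeding it if k was
#'   skipped by pruning).
#' @param out_dir optional directory; when given, writes
#'   \code{partition.tsv}, \code{gap_table.tsv}, \code{tree.nwk} and
#'   \code{run_log.txt} there.
#' @return Object of class \code{"ships_result"}: \code{K_hat},
#'   \code{partition} (at K_hat), \code{partitions} (all nested),
#'   \code{ks}, \code{gap} (\code{ships_gap}, NULL if \code{k} given),
#'   \code{tree}, \code{S}.
#' @examples
#' \donttest{
#' sim <- simulate_structured(pop_model("M3", n_per_pop = 20, p = 500), seed = 1)
#' res <- ships_run(sim$genotypes, B = 5, k_max = 5, seed = 1)
#' res$K_hat
#' adjusted_rand_index(res$partition, sim$truth)
#' }
#' @export
ships_run <- function(G = NULL, input = NULL, format = "matrix012",
                      k_max = 20L, B = 20L, seed = 1L, min_node_size = 3L,
                      k = NULL, out_dir = NULL, model_names = "EII") {
  if (is.null(G)) {
    if (is.null(input)) stop("provide a genotype matrix G or an input path")
    G <- read_genotype_matrix(input, format)
  }
  if (nrow(G) < 2L) stop("clustering needs at least 2 samples")
  if (k_max < 1L) stop("k_max must be >= 1")
  set.seed(seed)
  core <- .ships_partitions(G, min_node_size = min_node_size,
                            model_names = model_names)
  gap <- NULL
  if (is.null(k)) {
    gap <- gap_curve(core$partitions, core$D, n = nrow(G), p = ncol(G),
                     B = B, k_max = k_max, min_node_size = min_node_size,
                     model_names = model_names)
    K_hat <- gap$K_hat
  } else {
    avail <- core$ks[core$ks <= k]
    if (!length(avail)) stop("no realized partition with k <= ", k)
    K_hat <- max(avail)
    if (K_hat != k)
      message("k = ", k, " was not realized by pruning; using k = ", K_hat)
  }
  partition <- core$partitions[[which(core$ks == K_hat)[1L]]]
  res <- structure(list(K_hat = K_hat, partition = partition,
                        partitions = core$partitions, ks = core$ks,
                        gap = gap, tree = core$tree, S = core$S,
                        seed = seed, B = B, k_max = k_max,
                        min_node_size = min_node_size),
                   class = "ships_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_partition(partition, file.path(out_dir, "partition.tsv"))
    if (!is.null(gap)) write_gap_table(gap, file.path(out_dir, "gap_table.tsv"))
    write_tree(res$tree, file.path(out_dir, "tree.nwk"))
    writeLines(c(sprintf("samples\t%d", nrow(G)),
                 sprintf("snps\t%d", ncol(G)),
                 sprintf("seed\t%d", seed),
                 sprintf("B\t%d", B),
                 sprintf("k_max\t%d", k_max),
                 sprintf("min_node_size\t%d", min_node_size),
                 sprintf("K_hat\t%d", K_hat)),
               file.path(out_dir, "run_log.txt"))
  }
  res
}

#' @export
print.ships_result <- function(x, ...) {
  cat(sprintf("SHIPS clustering of %d samples\n", length(x$partition)))
  cat(sprintf("  tree leaves built: %d; realized k: %s\n",
              x$tree$n_leaves, paste(sort(x$ks), collapse = ", ")))
  cat(sprintf("  selected K = %d (seed %d, B = %d, k_max = %d)\n",
              x$K_hat, x$seed, x$B, x$k_max))
  cat("  cluster sizes:", paste(table(x$partition), collapse = ", "), "\n")
  invisible(x)
}
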