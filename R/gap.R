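#' Pooled within-cluster dispersion of a partition
#'
#' Tibshirani's pooled within-cluster dispersion applied to squared ASD
#' dissimilarities, without the logarithm:
#' \eqn{W = \sum_r D_r / (2 n_r)} where \eqn{D_r} is the sum over ordered
#' pairs (i, j), i != j, within cluster r of \eqn{D_{ij}^2} and \eqn{n_r}
#' the cluster size.  A partition of singletons has W = 0; the 1-cluster
#' partition gives the total pooled dispersion \eqn{D_{total} / (2n)}.
#'
#' @param partition named integer vector of cluster labels.
#' @param D dissimilarity matrix over the same samples
#'   ([dissimilarity_from_similarity()]).
#' @return Non-negative scalar.
#' @export
within_dispersion <- function(partition, D) {
  D <- unclass(D)
  if (length(partition) != nrow(D))
    stop("partition and dissimilarity matrix cover different sample sets")
  if (!is.null(names(partition)) && !is.null(rownames(D))) {
    if (!setequal(names(partition), rownames(D)))
      stop("partition and dissimilarity matrix cover different sample sets")
    partition <- partition[rownames(D)]
  }
  D2 <- D^2
  W <- 0
  for (r in unique(partition)) {
    idx <- which(partition == r)
    if (length(idx) > 1L)
      W <- W + sum(D2[idx, idx]) / (2 * length(idx))
  }
  W
}

#' Simulate a structureless null genotype matrix
#'
#' Null references for the gap statistic: i.i.d. genotypes uniform on
#' \{0, 1, 2\}, matching the dimensions of the observed data but carrying no
#' population structure.  Frequency features of the observed data are
#' deliberately not matched.
#'
#' @param n,p dimensions (samples x SNPs).
#' @return A [geno_matrix()].
#' @export
simulate_null_matrix <- function(n, p) {
  if (n < 2L || p < 1L) stop("need n >= 2 and p >= 1")
  geno_matrix(matrix(sample(0:2, n * p, replace = TRUE), nrow = n, ncol = p))
}

# run similarity -> tree -> prune on a genotype matrix; the single code path
# shared by the observed data and every null replicate
.ships_partitions <- function(G, min_node_size = 3L, model_names = "EII") {
  S <- asd_similarity(G)
  D <- dissimilarity_from_similarity(S)
  tree <- build_tree(S, min_node_size = min_node_size, model_names = model_names)
  parts <- prune_sequence(tree, S)
  list(S = S, D = D, tree = tree, partitions = parts, ks = attr(parts, "ks"))
}

#' Gap statistic curve over the nested partition sequence
#'
#' For each realized cluster count k (capped at \code{k_max}) compares the
#' observed dispersion \eqn{W_k} with its distribution under B structureless
#' null datasets, each pushed through the full pipeline (similarity, tree,
#' pruning): \eqn{Gap(k) = \bar W^*_k - W_k}, with
#' \eqn{s_k = sd(W^*_k)\sqrt{1 + 1/B}} absorbing the simulation error.  A k
#' not realized by some null replicate is imputed from that replicate's
#' nearest realized coarser partition.
#'
#' @param partitions \code{ships_partitions} from [prune_sequence()].
#' @param D_obs observed dissimilarity matrix.
#' @param n,p dimensions of the observed genotype matrix (null datasets match
#'   them).
#' @param B number of null replicates (default 20; must be >= 2 for the
#'   standard deviation to exist).
#' @param k_max largest cluster count entered in the table (default 20).
#' @param min_node_size passed to the null pipelines (match the observed run).
#' @param model_names GMM covariance models, passed to [bisect()] in the null
#'   pipelines (match the observed run).
#' @return Object of class \code{"ships_gap"}: list with \code{ks}, \code{W},
#'   \code{W_null} (B x |ks|), \code{gap}, \code{sd}, \code{s}, \code{K_hat}.
#' @export
gap_curve <- function(partitions, D_obs, n, p, B = 20L, k_max = 20L,
                      min_node_size = 3L, model_names = "EII") {
  if (B < 2L) stop("B must be at least 2 (null standard deviation undefined)")
  if (k_max < 1L) stop("k_max must be >= 1")
  ks_all <- attr(partitions, "ks")
  keep <- ks_all <= k_max
  ks <- ks_all[keep]
  obs <- partitions[keep]
  ord <- order(ks)
  ks <- ks[ord]; obs <- obs[ord]
  W <- vapply(obs, within_dispersion, numeric(1L), D = D_obs)

  seeds <- sample.int(.Machine$integer.max - 1L, B)
  W_null <- matrix(NA_real_, nrow = B, ncol = length(ks))
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    res <- .ships_partitions(simulate_null_matrix(n, p),
                             min_node_size = min_node_size,
                             model_names = model_names)
    kb <- res$ks
    Wb <- vapply(res$partitions, within_dispersion, numeric(1L), D = res$D)
    for (i in seq_along(ks)) {
      hit <- which(kb == ks[i])
      if (!length(hit)) hit <- which(kb == max(kb[kb <= ks[i]]))[1L]  # nearest coarser
      W_null[b, i] <- Wb[hit[1L]]
    }
  }
  gap <- colMeans(W_null) - W
  sdv <- apply(W_null, 2L, stats::sd)
  s <- sdv * sqrt(1 + 1 / B)
  out <- structure(list(ks = ks, W = W, W_null = W_null, gap = gap,
                        sd = sdv, s = s, partitions = obs),
                   class = "ships_gap")
  out$K_hat <- select_k(out)
  out
}

#' Select the number of clusters from a gap table
#'
#' Dudoit-Fridlyand rule: the smallest realized k such that
#' \eqn{Gap(k) \ge Gap(k') - s(k')} where k' is the next larger realized k.
#' If no k satisfies the rule the largest realized k is returned with a
#' warning.
#'
#' @param gap a \code{ships_gap} object (or list with \code{ks}, \code{gap},
#'   \code{s} in ascending-k order).
#' @return Integer, the selected number of clusters.
#' @export
select_k <- function(gap) {
  ks <- gap$ks
  m <- length(ks)
  if (m == 0L) stop("empty gap table")
  if (m == 1L) return(ks[1L])
  for (i in seq_len(m - 1L))
    if (gap$gap[i] >= gap$gap[i + 1L] - gap$s[i + 1L]) return(ks[i])
  warning("no k satisfied the gap selection rule; returning the largest realized k")
  ks[m]
}

#' @export
as.data.frame.ships_gap <- function(x, ...) {
  data.frame(k = x$ks, W = x$W,
             null_mean = colMeans(x$W_null),
             null_sd = x$sd, gap = x$gap, s = x$s,
             selected = x$ks == x$K_hat)
}

#' @export
print.ships_gap <- function(x, ...) {
  cat("gap statistic over k =", paste(x$ks, collapse = ", "),
      "; selected K =", x$K_hat, "\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Plot the gap curve
#'
#' Observed dispersion gap per cluster count with +/- s error bars and the
#' selected K marked.
#'
#' @param x a \code{ships_gap} object.
#' @param ... passed to [plot()].
#' @export
plot.ships_gap <- function(x, ...) {
  plot(x$ks, x$gap, type = "b", xlab = "number of clusters k",
       ylab = "Gap(k)", ...)
  graphics::arrows(x$ks, x$gap - x$s, x$ks, x$gap + x$s,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(v = x$K_hat, lty = 2)
  invisible(x)
}
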