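#' Normalized graph Laplacian of a similarity matrix
#'
#' \eqn{L = I - D^{-1/2} S D^{-1/2}} with \eqn{D} the diagonal degree matrix
#' of row sums.  With ASD similarity every degree is positive (the diagonal
#' of S is 2), which is asserted.  L is symmetric with eigenvalues in [0, 2];
#' its low eigenvectors embed the samples for spectral clustering.
#'
#' @param S symmetric non-negative similarity matrix.
#' @return Symmetric n x n Laplacian matrix.
#' @export
normalized_laplacian <- function(S) {
  S <- unclass(S)
  deg <- rowSums(S)
  if (any(deg <= 0)) stop("zero-degree row in similarity matrix")
  dis <- 1 / sqrt(deg)
  L <- -S * tcrossprod(dis)
  diag(L) <- diag(L) + 1
  (L + t(L)) / 2
}

#' Spectral embedding from the normalized Laplacian
#'
#' Eigenvectors of L for the k smallest eigenvalues (the "first" eigenvectors
#' in the normalized spectral clustering of Ng, Jordan and Weiss), each ROW
#' then rescaled to unit Euclidean norm so points live on the unit sphere.
#' Rows whose norm falls below \code{tol} are left as zeros.  Eigenvector
#' signs are fixed (first nonzero coordinate positive) for reproducibility.
#'
#' @param L Laplacian from [normalized_laplacian()].
#' @param k number of eigenvectors (2 for bisection).
#' @param tol row-norm threshold below which a row is zeroed rather than
#'   normalized.
#' @return n x k matrix of row-normalized coordinates.
#' @export
spectral_embedding <- function(L, k = 2L, tol = 1e-12) {
  n <- nrow(L)
  if (n < k) stop("need at least k samples for a k-vector embedding")
  es <- eigen(L, symmetric = TRUE)
  U <- es$vectors[, n - seq_len(k) + 1L, drop = FALSE]  # k smallest, ascending
  for (j in seq_len(k)) {
    nz <- which(abs(U[, j]) > tol)
    if (length(nz) && U[nz[1L], j] < 0) U[, j] <- -U[, j]
  }
  norms <- sqrt(rowSums(U^2))
  keep <- norms > tol
  U[keep, ] <- U[keep, , drop = FALSE] / norms[keep]
  U[!keep, ] <- 0
  U
}

#' Bisect a group of samples by normalized spectral clustering
#'
#' Embeds the node's samples with the two low eigenvectors of the normalized
#' Laplacian of its (sliced) similarity matrix and assigns each sample to one
#' of two Gaussian mixture components by maximum posterior (Mclust with
#' G = 2, covariance model selected by BIC over the standard model family).
#' The split is terminal --
#' the group is declared homogeneous -- when the node is smaller than
#' \code{min_node_size}, when one mixture component receives no samples, or
#' when the mixture fit fails (degenerate geometry).
#'
#' @param S_sub similarity matrix sliced to the node's samples.
#' @param min_node_size nodes smaller than this are terminal (default 3; a
#'   mixture fit on fewer points is degenerate).
#' @param model_names Mclust covariance models to consider.  The default
#'   \code{"EII"} (equal-volume spherical components) makes the mixture
#'   assignment behave like k-means with soft posteriors, which keeps the
#'   two components from straddling distant groups; \code{NULL} lets BIC
#'   choose over the full mclust family.
#' @return A list with \code{labels} (integer 1/2 per sample, or NULL if
#'   terminal) and \code{terminal} (logical).
#' @importFrom mclust Mclust mclustBIC
#' @export
bisect <- function(S_sub, min_node_size = 3L, model_names = "EII") {
  n <- nrow(S_sub)
  if (n < max(2L, min_node_size)) return(list(labels = NULL, terminal = TRUE))
  off <- S_sub[upper.tri(S_sub)]
  if (diff(range(off)) < 1e-12)  # constant similarity: homogeneous group
    return(list(labels = NULL, terminal = TRUE))
  emb <- spectral_embedding(normalized_laplacian(S_sub), k = 2L)
  pts <- unique(round(emb, 8))
  if (nrow(pts) < 2L)   # all points coincide: nothing to separate
    return(list(labels = NULL, terminal = TRUE))
  if (nrow(pts) == 2L) {
    # exactly two distinct embedding points (ideal block separation): the
    # mixture likelihood is singular there, but its limit assigns each
    # sample to its point
    labels <- ifelse(rowSums((emb - matrix(pts[1L, ], n, 2L, byrow = TRUE))^2) <
                       rowSums((emb - matrix(pts[2L, ], n, 2L, byrow = TRUE))^2),
                     1L, 2L)
    return(list(labels = labels, terminal = FALSE))
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(emb, G = 2, modelNames = model_names,
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(labels = NULL, terminal = TRUE))
  labels <- as.integer(fit$classification)
  if (length(unique(labels)) < 2L) return(list(labels = NULL, terminal = TRUE))
  list(labels = labels, terminal = FALSE)
}
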