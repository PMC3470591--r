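#' Per-locus allele-sharing score between two genotype codes
#'
#' The allele sharing distance (ASD) scores a pair of diploid genotypes at
#' one SNP by how many alleles they have in common: dissimilarity
#' \eqn{|g_i - g_j|} is 0 for identical genotypes, 2 for opposite homozygotes
#' (no shared allele), 1 otherwise.  Similarity is its 2-complement.
#' Vectorised over loci.
#'
#' @param g_i,g_j genotype codes in \{0, 1, 2\} (reference-allele counts).
#' @return Integer score(s): similarity in \{0, 1, 2\}.
#' @examples
#' locus_similarity(0, 2)   # opposite homozygotes: 0
#' locus_dissimilarity(1, 1) # identical genotypes: 0
#' @export
locus_similarity <- function(g_i, g_j) {
  2L - locus_dissimilarity(g_i, g_j)
}

#' @rdname locus_similarity
#' @export
locus_dissimilarity <- function(g_i, g_j) {
  if (any(!(g_i %in% c(0, 1, 2))) || any(!(g_j %in% c(0, 1, 2))))
    stop("genotype codes must be 0, 1 or 2")
  abs(as.integer(g_i) - as.integer(g_j))
}

#' Allele-sharing similarity matrix
#'
#' Pairwise similarity between all samples: the per-locus allele-sharing
#' similarity averaged over the loci where both samples are observed, giving
#' entries in [0, 2] with 2 on the diagonal.  Averaging (rather than
#' summing) keeps the scale independent of the number of SNPs and of
#' per-pair missingness.  The matrix is computed once for the full data;
#' downstream steps slice sub-matrices per tree node.
#'
#' @param G a [geno_matrix()] (or plain 0/1/2 matrix) with at least 2 rows.
#' @return A symmetric n x n matrix of class \code{"ships_similarity"} with
#'   sample IDs as dimnames.
#' @examples
#' G <- geno_matrix(rbind(a = c(0, 2), b = c(2, 2)))
#' asd_similarity(G)["a", "b"]  # (0 + 2) / 2 = 1
#' @export
asd_similarity <- function(G) {
  if (!is.matrix(G)) stop("G must be a matrix")
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 samples to compute pairwise similarity")
  ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(n))
  Gv <- unclass(G)
  storage.mode(Gv) <- "double"
  M <- !is.na(Gv)
  Gz <- Gv
  Gz[!M] <- 0
  Mn <- M + 0
  # sum over mutually observed loci of (g_i - g_j)^2, then correct 4 -> 2
  # (|d| = d^2 - 2 * [|d| = 2]) to get the summed absolute difference
  sq <- (Gz^2) %*% t(Mn) + Mn %*% t(Gz^2) - 2 * (Gz %*% t(Gz))
  X0 <- (Gz == 0 & M) + 0
  X2 <- (Gz == 2) + 0
  n4 <- X0 %*% t(X2) + X2 %*% t(X0)
  overlap <- Mn %*% t(Mn)
  if (any(overlap[upper.tri(overlap)] == 0)) {
    idx <- which(overlap == 0 & upper.tri(overlap), arr.ind = TRUE)[1L, ]
    stop(sprintf("samples '%s' and '%s' share no observed locus",
                 ids[idx[1L]], ids[idx[2L]]))
  }
  D <- (sq - 2 * n4) / overlap
  S <- 2 - D
  diag(S) <- 2
  S <- (S + t(S)) / 2  # symmetrise away rounding noise
  dimnames(S) <- list(ids, ids)
  class(S) <- c("ships_similarity", class(S))
  S
}

#' Convert between ASD similarity and dissimilarity
#'
#' The two matrices are linearly related, \eqn{D = 2 - S} entrywise (with a
#' zero diagonal), so no recomputation from genotypes is ever needed; the
#' conversion is an involution about 1.
#'
#' @param S similarity matrix from [asd_similarity()].
#' @return The paired dissimilarity matrix (class \code{"ships_dissimilarity"}).
#' @export
dissimilarity_from_similarity <- function(S) {
  D <- 2 - unclass(S)
  diag(D) <- 0
  class(D) <- c("ships_dissimilarity", "matrix", "array")
  D
}
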