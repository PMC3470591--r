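#' Contingency table of two partitions
#'
#' \code{counts[i, j]} is the number of samples in cluster i of U and
#' cluster j of V.  Partitions with names are aligned by sample ID; unnamed
#' ones by position.
#'
#' @param U,V integer (optionally named) cluster-label vectors over the same
#'   samples.
#' @return List of class \code{"ships_contingency"} with \code{counts},
#'   \code{row_sums}, \code{col_sums}, \code{total}.
#' @export
contingency <- function(U, V) {
  if (length(U) != length(V)) stop("partitions cover different sample sets")
  if (!is.null(names(U)) && !is.null(names(V))) {
    if (!setequal(names(U), names(V)))
      stop("partitions cover different sample sets")
    V <- V[names(U)]
  }
  counts <- unclass(table(U, V))
  structure(list(counts = counts,
                 row_sums = rowSums(counts),
                 col_sums = colSums(counts),
                 total = length(U)),
            class = "ships_contingency")
}

#' @export
print.ships_contingency <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected pair-agreement index computed from the
#' contingency table:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{M - E},\quad
#'   E = \frac{\sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2}}{\binom{N}{2}},\quad
#'   M = \tfrac12\left[\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right].}
#' When both partitions place every sample in one cluster the index is
#' undefined (0/0) but the structure is perfectly recovered, so 1 is
#' returned by convention.  If exactly one partition is the single cluster
#' the formula's value, 0, is kept.
#'
#' @inheritParams contingency
#' @return Numeric in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(U, V) {
  ct <- contingency(U, V)
  N <- ct$total
  sum_nij <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$row_sums, 2))
  sum_b <- sum(choose(ct$col_sums, 2))
  E <- sum_a * sum_b / choose(N, 2)
  M <- (sum_a + sum_b) / 2
  if (abs(M - E) < .Machine$double.eps * max(1, M)) return(1)
  (sum_nij - E) / (M - E)
}
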