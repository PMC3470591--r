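# independent oracles and small fixture builders used across test files

# pair-counting adjusted Rand index: classifies every unordered sample pair
# as together/apart in each partition and applies the Hubert-Arabie
# pair-count form, never touching the contingency table
ari_pair_oracle <- function(U, V) {
  n <- length(U)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      su <- U[i] == U[j]
      sv <- V[i] == V[j]
      if (su && sv) a <- a + 1
      else if (su && !sv) b <- b + 1
      else if (!su && sv) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  2 * (a * d - b * cc) / den
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_max + 1L)) {
      rec(c(labels, lab), max(next_max, lab))
    }
  }
  rec(integer(), 0L)
  out
}

# naive per-pair ASD similarity: loops over loci, averaging 2 - |gi - gj|
# over mutually observed loci
asd_naive <- function(G) {
  n <- nrow(G)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { S[i, j] <- 2; next }
      ok <- !is.na(G[i, ]) & !is.na(G[j, ])
      S[i, j] <- mean(2 - abs(G[i, ok] - G[j, ok]))
    }
  }
  dimnames(S) <- list(rownames(G), rownames(G))
  S
}

# block-structured similarity matrix: within-block similarity 2, between 0
block_similarity <- function(sizes) {
  lab <- rep(seq_along(sizes), sizes)
  S <- outer(lab, lab, function(a, b) ifelse(a == b, 2, 0))
  diag(S) <- 2
  dimnames(S) <- list(paste0("s", seq_along(lab)), paste0("s", seq_along(lab)))
  S
}

# genotype matrix with k strongly differentiated blocks: each block draws
# its own extreme allele frequencies, so between-block ASD >> within-block
block_genotypes <- function(sizes, p, seed = 1) {
  set.seed(seed)
  G <- do.call(rbind, lapply(seq_along(sizes), function(b) {
    f <- rbeta(p, 0.2, 0.2)
    matrix(rbinom(sizes[b] * p, 2, rep(f, each = sizes[b])), nrow = sizes[b])
  }))
  geno_matrix(G)
}

# exhaustive within-cluster dispersion: ordered pairs, squared entries
dispersion_naive <- function(partition, D) {
  W <- 0
  for (r in unique(partition)) {
    idx <- which(partition == r)
    if (length(idx) < 2L) next
    tot <- 0
    for (i in idx) for (j in idx) if (i != j) tot <- tot + D[i, j]^2
    W <- W + tot / (2 * length(idx))
  }
  W
}

# direct cross-leaf quality: sum of squared similarities over pairs whose
# members lie in different leaves of the node's subtree
quality_cross_leaf <- function(node, S) {
  leaves <- ships:::.collect_leaves(node)
  q <- 0
  if (length(leaves) < 2L) return(0)
  for (a in seq_len(length(leaves) - 1L)) {
    for (b in (a + 1L):length(leaves)) {
      for (i in leaves[[a]]) for (j in leaves[[b]]) q <- q + S[i, j]^2
    }
  }
  q
}
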