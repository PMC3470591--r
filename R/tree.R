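#' Sum of squared similarities within a node
#'
#' \eqn{SS(G) = \sum_{\{i,j\} \subset G, i \ne j} S_{ij}^2} over unordered
#' distinct pairs; a singleton scores 0.  The diagonal is excluded because
#' self-similarity is constant and uninformative.
#'
#' @param members integer vector of sample indices.
#' @param S full similarity matrix.
#' @return Non-negative scalar.
#' @export
node_ss <- function(members, S) {
  if (length(members) < 2L) return(0)
  sub <- unclass(S)[members, members, drop = FALSE]^2
  (sum(sub) - sum(diag(sub))) / 2
}

#' Build the divisive binary tree
#'
#' Starting from the full sample set, each node is bisected by normalized
#' spectral clustering on the sliced similarity sub-matrix ([bisect()]);
#' terminal nodes become leaves.  Member counts strictly decrease down the
#' tree, so construction always terminates.
#'
#' @param S similarity matrix from [asd_similarity()].
#' @param min_node_size passed to [bisect()].
#' @param model_names GMM covariance models, passed to [bisect()].
#' @return An object of class \code{"ships_tree"}: a list with \code{root}
#'   (nested nodes holding \code{members}, \code{children}, \code{ss},
#'   \code{depth}), \code{n_leaves}, and the sample IDs.
#' @export
build_tree <- function(S, min_node_size = 3L, model_names = "EII") {
  n <- nrow(S)
  ids <- rownames(S)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(n))
  grow <- function(members, depth) {
    node <- list(members = members, children = NULL,
                 ss = node_ss(members, S), depth = depth)
    split <- bisect(unclass(S)[members, members, drop = FALSE],
                    min_node_size = min_node_size, model_names = model_names)
    if (!split$terminal) {
      a <- members[split$labels == 1L]
      b <- members[split$labels == 2L]
      node$children <- list(grow(a, depth + 1L), grow(b, depth + 1L))
    }
    node
  }
  root <- grow(seq_len(n), 0L)
  count_leaves <- function(nd) {
    if (is.null(nd$children)) 1L
    else sum(vapply(nd$children, count_leaves, integer(1L)))
  }
  structure(list(root = root, n_leaves = count_leaves(root), sample_ids = ids),
            class = "ships_tree")
}

#' @export
print.ships_tree <- function(x, ...) {
  cat(sprintf("divisive cluster tree: %d samples, %d leaves\n",
              length(x$sample_ids), x$n_leaves))
  invisible(x)
}

#' Quality of an internal node
#'
#' \eqn{Q(G) = SS(G) - \sum_{F \in leaves(G)} SS(F)}: the sum of squared
#' similarities over pairs of samples lying in different leaves of G's
#' subtree.  The two formulations (SS difference and direct cross-leaf
#' summation) are algebraically identical.
#'
#' @param node a node of a \code{ships_tree} (must be internal).
#' @param S full similarity matrix.
#' @return Non-negative scalar.
#' @export
node_quality <- function(node, S) {
  if (is.null(node$children)) stop("node_quality is defined for internal nodes only")
  leaves <- .collect_leaves(node)
  node_ss(node$members, S) - sum(vapply(leaves, function(l) node_ss(l, S), numeric(1L)))
}

.collect_leaves <- function(node) {
  if (is.null(node$children)) return(list(node$members))
  do.call(c, lapply(node$children, .collect_leaves))
}

# flatten a nested tree into parallel vectors (preorder ids)
.flatten_tree <- function(root) {
  env <- new.env()
  env$members <- list(); env$children <- list(); env$parent <- integer()
  env$ss <- numeric(); env$depth <- integer()
  rec <- function(node, parent) {
    id <- length(env$members) + 1L
    env$members[[id]] <- node$members
    env$children[[id]] <- integer()
    env$parent[id] <- parent
    env$ss[id] <- node$ss
    env$depth[id] <- node$depth
    if (!is.null(node$children))
      env$children[[id]] <- vapply(node$children, rec, integer(1L), parent = id)
    id
  }
  rec(root, 0L)
  as.list(env)
}

#' Nested partition sequence by reduced-error pruning
#'
#' Iteratively collapses the internal node with the lowest quality (its whole
#' subtree is removed and it becomes a leaf); after each collapse the current
#' leaf set defines a partition and all qualities are recomputed on the new
#' topology.  Ties on minimal quality go to the deepest node, then to the
#' node containing the smallest sample index.  The returned partitions start
#' at the unpruned tree (k = number of built leaves) and end at the
#' single-cluster partition; consecutive partitions are nested (each later
#' one merges clusters of earlier ones).  When a collapsed subtree has m > 2
#' leaves, k drops by m - 1 and intermediate k values are skipped.
#'
#' @param tree a \code{ships_tree} from [build_tree()].
#' @param S the similarity matrix the tree was built from.
#' @return List of class \code{"ships_partitions"}: named integer vectors
#'   (sample id -> cluster label 1..k), ordered by decreasing k.
#' @export
prune_sequence <- function(tree, S) {
  ft <- .flatten_tree(tree$root)
  nn <- length(ft$members)
  ids <- tree$sample_ids
  n <- length(ids)
  # cache SS per node id (already stored during build)
  ssv <- ft$ss
  collapsed <- logical(nn)

  live_leaves <- function() {
    # preorder walk stopping at current leaves
    out <- integer(); stack <- 1L
    while (length(stack)) {
      id <- stack[1L]; stack <- stack[-1L]
      if (collapsed[id] || !length(ft$children[[id]])) out <- c(out, id)
      else stack <- c(ft$children[[id]], stack)
    }
    out
  }
  live_internal <- function() {
    out <- integer(); stack <- 1L
    while (length(stack)) {
      id <- stack[1L]; stack <- stack[-1L]
      if (!collapsed[id] && length(ft$children[[id]])) {
        out <- c(out, id)
        stack <- c(ft$children[[id]], stack)
      }
    }
    out
  }
  leaves_under <- function(id) {
    out <- integer(); stack <- ft$children[[id]]
    while (length(stack)) {
      j <- stack[1L]; stack <- stack[-1L]
      if (collapsed[j] || !length(ft$children[[j]])) out <- c(out, j)
      else stack <- c(ft$children[[j]], stack)
    }
    out
  }
  partition_now <- function() {
    lv <- live_leaves()
    # order clusters by smallest member index for contiguous stable labels
    lv <- lv[order(vapply(lv, function(id) min(ft$members[[id]]), numeric(1L)))]
    part <- integer(n)
    for (i in seq_along(lv)) part[ft$members[[lv[i]]]] <- i
    names(part) <- ids
    part
  }

  parts <- list(partition_now())
  while (!(collapsed[1L] || !length(ft$children[[1L]]))) {
    cand <- live_internal()
    q <- vapply(cand, function(id)
      ssv[id] - sum(ssv[leaves_under(id)]), numeric(1L))
    best <- which(q == min(q))
    if (length(best) > 1L) {   # deepest first, then smallest member index
      d <- ft$depth[cand[best]]
      best <- best[d == max(d)]
      if (length(best) > 1L) {
        m <- vapply(cand[best], function(id) min(ft$members[[id]]), numeric(1L))
        best <- best[which.min(m)]
      }
    }
    collapsed[cand[best[1L]]] <- TRUE
    parts <- c(parts, list(partition_now()))
  }
  structure(parts, class = "ships_partitions",
            ks = vapply(parts, max, integer(1L)))
}

#' @export
print.ships_partitions <- function(x, ...) {
  cat("nested partition sequence, k =", paste(attr(x, "ks"), collapse = ", "), "\n")
  invisible(x)
}
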