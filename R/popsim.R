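#' Preset population models
#'
#' Hierarchical allele-frequency drift models with known structure, used to
#' generate test datasets of graded difficulty.  Each branch of the split
#' tree carries an Fst-like drift parameter F in (0, 1); allele frequencies
#' evolve along branches under the Balding-Nichols model and terminal
#' populations draw genotypes binomially.  Presets:
#' \describe{
#'   \item{M1}{one population (no structure), 100 samples x 1000 SNPs.}
#'   \item{M3}{3 populations in a star, F = 0.1, 50 samples each, 2000 SNPs.}
#'   \item{M5}{5 populations in a star, F = 0.1, 50 samples each, 2000 SNPs.}
#'   \item{M10}{2 super-populations (F = 0.10) of 5 leaves each (F = 0.05),
#'     30 samples per leaf, 3000 SNPs.}
#'   \item{M20}{4 super-populations (F = 0.10) of 5 leaves each (F = 0.05),
#'     25 samples per leaf, 3000 SNPs.}
#' }
#' The nested presets are harder than the star ones because leaf populations
#' within a super-population are separated only by the smaller leaf-level
#' drift.
#'
#' @param scenario one of \code{"M1"}, \code{"M3"}, \code{"M5"},
#'   \code{"M10"}, \code{"M20"}.
#' @param n_per_pop samples per terminal population (default: preset value).
#' @param p number of SNPs (default: preset value).
#' @param ancestral_freq_range interval within (0, 1) for the ancestral
#'   allele frequency of each locus.
#' @return List of class \code{"pop_model"}: \code{tree} (nested branches
#'   with \code{F} and either \code{children} or a leaf \code{name}),
#'   \code{n_per_pop}, \code{p}, \code{n_pops}, \code{ancestral_freq_range}.
#' @export
pop_model <- function(scenario = c("M1", "M3", "M5", "M10", "M20"),
                      n_per_pop = NULL, p = NULL,
                      ancestral_freq_range = c(0.05, 0.95)) {
  scenario <- match.arg(scenario)
  leaf <- function(name, F) list(F = F, name = name)
  star <- function(k, F) {
    list(F = 0, children = lapply(seq_len(k), function(i)
      leaf(paste0("pop", i), F)))
  }
  nested <- function(n_super, per_super, F_super, F_leaf) {
    list(F = 0, children = lapply(seq_len(n_super), function(s) {
      list(F = F_super, children = lapply(seq_len(per_super), function(i)
        leaf(paste0("pop", (s - 1L) * per_super + i), F_leaf)))
    }))
  }
  preset <- switch(scenario,
    M1  = list(tree = leaf("pop1", 0), n = 100L, p = 1000L),
    M3  = list(tree = star(3L, 0.1), n = 50L, p = 2000L),
    M5  = list(tree = star(5L, 0.1), n = 50L, p = 2000L),
    M10 = list(tree = nested(2L, 5L, 0.10, 0.08), n = 30L, p = 3000L),
    M20 = list(tree = nested(4L, 5L, 0.10, 0.08), n = 25L, p = 3000L))
  count_pops <- function(nd) {
    if (is.null(nd$children)) 1L else sum(vapply(nd$children, count_pops, integer(1L)))
  }
  structure(list(tree = preset$tree,
                 n_per_pop = if (is.null(n_per_pop)) preset$n else as.integer(n_per_pop),
                 p = if (is.null(p)) preset$p else as.integer(p),
                 n_pops = count_pops(preset$tree),
                 ancestral_freq_range = ancestral_freq_range,
                 scenario = scenario),
            class = "pop_model")
}

# Balding-Nichols drift of allele frequencies f along a branch with
# differentiation F: f' ~ Beta(f (1-F)/F, (1-f) (1-F)/F)
.bn_drift <- function(f, F) {
  if (F < 0 || F >= 1) stop("drift parameter F must be in [0, 1)")
  if (F == 0) return(f)
  stats::rbeta(length(f), f * (1 - F) / F, (1 - f) * (1 - F) / F)
}

#' Simulate structured genotype data under hierarchical drift
#'
#' Draws an ancestral allele frequency per locus uniformly on the model's
#' frequency range, evolves it down the split tree by Balding-Nichols draws
#' with each branch's F, and samples genotypes at every terminal population
#' as binomial(2, frequency) independently per locus (no linkage).  A
#' single-population model yields unstructured data.
#'
#' @param model a [pop_model()].
#' @param seed optional integer seed for reproducibility.
#' @return List with \code{genotypes} (a [geno_matrix()]) and \code{truth}
#'   (named integer vector: terminal population of each sample).
#' @export
simulate_structured <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- model$p
  rng <- model$ancestral_freq_range
  f0 <- stats::runif(p, rng[1L], rng[2L])
  leaves <- list()
  descend <- function(node, f) {
    f <- .bn_drift(f, node$F)
    if (is.null(node$children)) {
      leaves[[length(leaves) + 1L]] <<- list(name = node$name, freq = f)
    } else {
      for (ch in node$children) descend(ch, f)
    }
  }
  descend(model$tree, f0)
  n <- model$n_per_pop
  blocks <- lapply(leaves, function(lf)
    matrix(stats::rbinom(n * p, 2L, rep(lf$freq, each = n)), nrow = n))
  G <- do.call(rbind, blocks)
  pops <- vapply(leaves, `[[`, character(1L), "name")
  ids <- unlist(lapply(pops, function(nm) paste0(nm, "_", seq_len(n))))
  truth <- stats::setNames(rep(seq_along(pops), each = n), ids)
  list(genotypes = geno_matrix(G, sample_ids = ids), truth = truth)
}

#' Simulate a discretely admixed population by iterated random mating
#'
#' Generation 1 offspring each draw, at every locus, one allele from a
#' randomly chosen parent in source A and one from a randomly chosen parent
#' in source B (allele transmitted with probability genotype/2), so their
#' expected ancestry is 50/50.  Subsequent generations mate randomly within
#' the admixed pool.  The returned dataset combines both sources and the
#' admixed pool with three truth labels.
#'
#' @param G_A,G_B source genotype matrices sharing the same loci (no missing
#'   entries).
#' @param n_admixed size of the admixed pool (default 60).
#' @param generations number of random-mating rounds (>= 1, default 5).
#' @param seed optional integer seed.
#' @return List with \code{genotypes} (sources stacked above the admixed
#'   pool) and \code{truth} (1 = source A, 2 = source B, 3 = admixed).
#' @export
simulate_admixed <- function(G_A, G_B, n_admixed = 60L, generations = 5L,
                             seed = NULL) {
  if (ncol(G_A) != ncol(G_B)) stop("source populations must share the same loci")
  if (anyNA(G_A) || anyNA(G_B)) stop("source genotypes must be complete (no missing)")
  if (generations < 1L) stop("need at least one generation of mating")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(G_A)
  gamete <- function(parent_row) stats::rbinom(p, 1L, parent_row / 2)
  offspring <- function(pool_a, pool_b) {
    t(vapply(seq_len(n_admixed), function(o) {
      gamete(pool_a[sample.int(nrow(pool_a), 1L), ]) +
        gamete(pool_b[sample.int(nrow(pool_b), 1L), ])
    }, integer(p)))
  }
  pool <- offspring(unclass(G_A), unclass(G_B))
  if (generations > 1L) {
    for (g in seq_len(generations - 1L)) pool <- offspring(pool, pool)
  }
  ids <- c(paste0("A_", seq_len(nrow(G_A))), paste0("B_", seq_len(nrow(G_B))),
           paste0("ADM_", seq_len(n_admixed)))
  G <- rbind(unclass(G_A), unclass(G_B), pool)
  truth <- stats::setNames(rep(1:3, c(nrow(G_A), nrow(G_B), n_admixed)), ids)
  list(genotypes = geno_matrix(G, sample_ids = ids), truth = truth)
}

#' Simulate the discrete-admixture scenario (Madx)
#'
#' Two differentiated source populations (star model, drift F) plus an
#' admixed pool generated by [simulate_admixed()]; the expected structure is
#' three discrete clusters.
#'
#' @param n_source samples per source population.
#' @param n_admixed samples in the admixed pool.
#' @param p number of SNPs.
#' @param F drift separating the two sources (default 0.15).
#' @param generations random-mating rounds (default 5).
#' @param seed optional integer seed.
#' @return As [simulate_admixed()].
#' @export
simulate_madx <- function(n_source = 60L, n_admixed = 60L, p = 2000L,
                          F = 0.15, generations = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- pop_model("M3", n_per_pop = n_source, p = p)
  model$tree$children <- model$tree$children[1:2]
  for (i in 1:2) model$tree$children[[i]]$F <- F
  src <- simulate_structured(model)
  a <- which(src$truth == 1L)
  b <- which(src$truth == 2L)
  simulate_admixed(src$genotypes[a, , drop = FALSE],
                   src$genotypes[b, , drop = FALSE],
                   n_admixed = n_admixed, generations = generations)
}
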