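# Mutation overlay and nucleotide diversity.

DNA_BASES <- c("A", "C", "G", "T")

#' Drop mutations on a gene tree
#'
#' Mutations are placed as a Poisson process at rate `mu * L` per branch
#' generation. Sites follow infinite-sites bookkeeping: each mutation hits a
#' distinct position drawn uniformly in `[1, L]`, with the ancestral state
#' drawn uniformly from the four bases and the derived state uniformly from
#' the remaining three (the Jukes-Cantor single-hit scheme; at the diversities
#' produced by these simulations multiple hits are negligible, see the
#' methods vignette).
#'
#' @param tree a `gene_tree`.
#' @param mu mutation rate per site per generation.
#' @param L sequence length in bp.
#' @return a `sequence_set`: per-tip haplotypes stored as segregating sites
#'   (`positions` sorted 1-based, `ancestral`/`derived` states, and `carriers`,
#'   the list of tip indices carrying each derived allele).
#' @export
#' @examples
#' set.seed(1)
#' tr <- coalescent_burn_in(5, 750, marker = "mtDNA")
#' seqs <- drop_mutations(tr, mu = 5.5e-7, L = 1e4)
#' pairwise_pi(seqs)
drop_mutations <- function(tree, mu, L) {
  stopifnot(inherits(tree, "gene_tree"), mu >= 0, L >= 1)
  st <- tree_branch_stats(tree)
  idx <- which(st$has_parent & st$n_desc < tree$n_tips)
  n_mut <- stats::rpois(length(idx), mu * L * st$blen[idx])
  S <- sum(n_mut)
  if (S > L) {
    stop("more mutations than sites: increase L or lower mu", call. = FALSE)
  }
  hit <- idx[n_mut > 0L]
  times <- n_mut[n_mut > 0L]
  carriers <- rep(lapply(tree_tip_sets(tree, hit), sort), times = times)
  positions <- sample.int(L, S)   # without replacement: infinite sites
  ord <- order(positions)
  ancestral <- sample(DNA_BASES, S, replace = TRUE)
  derived <- vapply(ancestral,
                    function(a) sample(setdiff(DNA_BASES, a), 1L), "")
  structure(list(marker = tree$marker, L = as.numeric(L), mu = mu,
                 n_tips = tree$n_tips, labels = tree$labels,
                 positions = positions[ord],
                 ancestral = unname(ancestral[ord]),
                 derived = unname(derived[ord]),
                 carriers = carriers[ord]),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set>", x$marker, "marker,", x$n_tips, "haplotypes,",
      length(x$positions), "segregating sites over", format(x$L), "bp\n")
  invisible(x)
}

#' Haplotype matrix of a sequence set
#'
#' @param x a `sequence_set`.
#' @param ... unused.
#' @return character matrix (tips x segregating sites) of nucleotide states;
#'   column names are the 1-based positions.
#' @export
as.matrix.sequence_set <- function(x, ...) {
  S <- length(x$positions)
  m <- matrix(rep(x$ancestral, each = x$n_tips), nrow = x$n_tips, ncol = S)
  for (j in seq_len(S)) m[x$carriers[[j]], j] <- x$derived[j]
  dimnames(m) <- list(x$labels, x$positions)
  m
}

#' Nucleotide diversity (pi)
#'
#' Mean per-site number of pairwise differences among a set of sequences.
#'
#' @param x a `sequence_set`, or a matrix of per-site states with one row per
#'   sequence.
#' @param ... passed to methods.
#' @return pi, a single number (differences per site).
#' @export
pairwise_pi <- function(x, ...) UseMethod("pairwise_pi")

#' @rdname pairwise_pi
#' @export
pairwise_pi.sequence_set <- function(x, ...) {
  n <- x$n_tips
  if (n < 2L) stop("pi requires at least two sequences", call. = FALSE)
  k <- lengths(x$carriers)
  sum(k * (n - k)) / (n * (n - 1) / 2) / x$L
}

#' @rdname pairwise_pi
#' @param L alignment length used for the per-site normalisation (defaults to
#'   the number of columns of the matrix).
#' @export
pairwise_pi.matrix <- function(x, L = ncol(x), ...) {
  n <- nrow(x)
  if (n < 2L) stop("pi requires at least two sequences", call. = FALSE)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      total <- total + sum(x[i, ] != x[j, ])
    }
  }
  total / (n * (n - 1) / 2) / L
}
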