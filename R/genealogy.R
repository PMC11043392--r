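# Gene trees for the uniparental markers.
#
# A `gene_tree` is a rooted, possibly multifurcating coalescent tree stored as
# flat arrays: nodes 1..n_tips are the sampled individuals (time 0 = the
# sampling generation), internal nodes follow, `parent[i]` gives the parent
# node (0 for the root) and `time[i]` the node age in generations before
# sampling. Same-generation samples make the tree ultrametric.

new_gene_tree <- function(n_tips, parent, time, labels = NULL,
                          marker = c("Y", "mtDNA")) {
  marker <- match.arg(marker)
  structure(list(n_tips = as.integer(n_tips), parent = as.integer(parent),
                 time = as.numeric(time),
                 labels = if (is.null(labels)) as.character(seq_len(n_tips))
                          else as.character(labels),
                 marker = marker),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree>", x$marker, "marker,", x$n_tips, "tips, tMRCA",
      format(max(x$time), digits = 5), "generations\n")
  invisible(x)
}

#' Coalescent initialisation of founder lineages
#'
#' Replaces the long neutral panmictic phase that precedes the introduction of
#' kinship rules: the genealogy of the founder lineages of a uniparental
#' marker is drawn from the standard (Kingman) coalescent for a haploid
#' population of constant size, with branch lengths in generations. The
#' resulting tree is grafted beneath the forward-time pedigree genealogy by
#' [extract_gene_tree()]. For a sample of two lineages the expected time to
#' the common ancestor equals `haploid_size` generations.
#'
#' @param n_lineages number of founder lineages (tips); e.g. 750 founder males
#'   for the Y chromosome in the default population.
#' @param haploid_size constant haploid population size of the pre-structure
#'   phase (defaults to `n_lineages`).
#' @param marker marker label carried by the tree.
#' @return a `gene_tree` whose tips are founder lineages. Internal nodes are
#'   stored in coalescence-time order, which downstream grafting relies on.
#' @export
#' @examples
#' set.seed(1)
#' tr <- coalescent_burn_in(10, haploid_size = 750)
#' max(tr$time)  # sample tMRCA, in generations
coalescent_burn_in <- function(n_lineages, haploid_size = n_lineages,
                               marker = c("Y", "mtDNA")) {
  marker <- match.arg(marker)
  n <- as.integer(n_lineages)
  stopifnot(n >= 1L, haploid_size > 0)
  if (n == 1L) {
    tree <- new_gene_tree(1L, 0L, 0, marker = marker)
    tree$children <- matrix(integer(0), ncol = 2L)
    return(tree)
  }
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  children <- matrix(0L, nrow = n - 1L, ncol = 2L)
  active <- seq_len(n)
  t_cur <- 0
  for (i in seq_len(n - 1L)) {
    k <- n - i + 1L
    t_cur <- t_cur + stats::rexp(1L, rate = k * (k - 1) / 2 / haploid_size)
    pick <- sample.int(k, 2L)
    node <- n + i
    time[node] <- t_cur
    parent[active[pick]] <- node
    children[i, ] <- active[pick]
    active <- c(active[-pick], node)
  }
  tree <- new_gene_tree(n, parent, time, marker = marker)
  tree$children <- children
  tree
}

#' Extract the gene tree of a uniparental sample
#'
#' Collapses the forward-time pedigree paths of a same-generation sample into
#' a coalescent tree: paternal (`marker = "Y"`) or maternal
#' (`marker = "mtDNA"`) links are followed back one generation at a time, and
#' lineages sharing an ancestor merge at that generation. Lineages still
#' distinct among the founders are joined through the coalescent
#' initialisation tree ([coalescent_burn_in()]), so branch lengths extend
#' seamlessly into the pre-structure past.
#'
#' @param sample_ids pedigree ids of the sampled individuals (all born in the
#'   same generation). For `marker = "Y"` all must be male; mtDNA lineages can
#'   be traced through individuals of either sex.
#' @param ped the pedigree.
#' @param burn_in the founder-lineage `gene_tree` for this marker.
#' @param founder_tips integer vector mapping founder pedigree id to tip index
#'   in `burn_in` (NA for founders that do not carry the marker lineage).
#' @param n_generations generation of the sample (number of pedigree steps
#'   back to the founders).
#' @param marker `"Y"` or `"mtDNA"`.
#' @return a `gene_tree` with `length(sample_ids)` tips and branch lengths in
#'   generations.
#' @export
extract_gene_tree <- function(sample_ids, ped, burn_in, founder_tips,
                              n_generations, marker = c("Y", "mtDNA")) {
  marker <- match.arg(marker)
  n <- length(sample_ids)
  stopifnot(n >= 1L)
  if (marker == "Y" && any(ped$sex[sample_ids] != 1L)) {
    stop("Y-chromosome samples must be male", call. = FALSE)
  }
  link <- if (marker == "Y") ped$father else ped$mother
  n_nodes_max <- 2L * n - 1L
  parent <- integer(n_nodes_max)
  time <- numeric(n_nodes_max)
  nn <- n
  node_of <- seq_len(n)
  anc <- sample_ids
  g <- 0L
  while (length(anc) > 1L && g < n_generations) {
    g <- g + 1L
    anc <- link[anc]
    if (anyDuplicated(anc)) {
      first <- !duplicated(anc)
      dup_anc <- unique(anc[duplicated(anc)])
      for (a in dup_anc) {
        idx <- which(anc == a)
        nn <- nn + 1L
        time[nn] <- g
        parent[node_of[idx]] <- nn
        node_of[idx[1L]] <- nn
      }
      node_of <- node_of[first]
      anc <- anc[first]
    }
  }
  if (length(anc) > 1L) {
    # graft the uncoalesced founder lineages onto the burn-in tree
    tips <- founder_tips[anc]
    if (anyNA(tips)) {
      stop("sample lineage reached a founder without a ", marker,
           " burn-in tip", call. = FALSE)
    }
    nb <- burn_in$n_tips
    bmap <- integer(2L * nb - 1L)
    bmap[tips] <- node_of
    remaining <- length(anc)
    for (i in seq_len(nb - 1L)) {
      c1 <- burn_in$children[i, 1L]
      c2 <- burn_in$children[i, 2L]
      m1 <- bmap[c1]
      m2 <- bmap[c2]
      node <- nb + i
      if (m1 > 0L && m2 > 0L) {
        nn <- nn + 1L
        time[nn] <- n_generations + burn_in$time[node]
        parent[c(m1, m2)] <- nn
        bmap[node] <- nn
        remaining <- remaining - 1L
        if (remaining == 1L) break
      } else if (m1 > 0L) {
        bmap[node] <- m1
      } else if (m2 > 0L) {
        bmap[node] <- m2
      }
    }
  }
  new_gene_tree(n, parent[seq_len(nn)], time[seq_len(nn)],
                labels = sample_ids, marker = marker)
}

# Branch lengths and per-branch descendant tip counts.
# Children always pre-date their parent, so a single pass over nodes sorted by
# age accumulates tip counts bottom-up.
tree_branch_stats <- function(tree) {
  n_nodes <- length(tree$parent)
  n <- tree$n_tips
  count <- c(rep(1L, n), rep(0L, n_nodes - n))
  ord <- order(tree$time)
  for (i in ord) {
    p <- tree$parent[i]
    if (p > 0L) count[p] <- count[p] + count[i]
  }
  has_parent <- tree$parent > 0L
  blen <- numeric(n_nodes)
  blen[has_parent] <- tree$time[tree$parent[has_parent]] -
    tree$time[has_parent]
  list(blen = blen, n_desc = count, has_parent = has_parent)
}

# Total branch length in generations.
tree_total_length <- function(tree) {
  sum(tree_branch_stats(tree)$blen)
}

# Tip sets below each requested node.
tree_tip_sets <- function(tree, nodes) {
  n_nodes <- length(tree$parent)
  kids <- split(seq_len(n_nodes), factor(tree$parent, levels = seq_len(n_nodes)))
  below <- function(node) {
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (v <= tree$n_tips) out <- c(out, v)
      else stack <- c(stack, kids[[v]])
    }
    out
  }
  lapply(nodes, below)
}

#' Convert a gene tree to an ape "phylo" object
#'
#' @param x a `gene_tree`.
#' @param generation_time if supplied, branch lengths are converted from
#'   generations to years by this factor.
#' @param ... unused.
#' @return an [ape::as.phylo] compatible `phylo` object.
#' @method as.phylo gene_tree
#' @export
as.phylo.gene_tree <- function(x, generation_time = NULL, ...) {
  n <- x$n_tips
  n_nodes <- length(x$parent)
  internal <- seq.int(n + 1L, n_nodes)
  # root must become node n+1 in ape numbering; order internals by decreasing
  # age so ancestors precede descendants
  internal <- internal[order(x$time[internal], decreasing = TRUE)]
  new_id <- integer(n_nodes)
  new_id[seq_len(n)] <- seq_len(n)
  new_id[internal] <- n + seq_along(internal)
  child <- which(x$parent > 0L)
  edge <- cbind(new_id[x$parent[child]], new_id[child])
  blen <- x$time[x$parent[child]] - x$time[child]
  if (!is.null(generation_time)) blen <- blen * generation_time
  phy <- list(edge = edge, edge.length = blen, tip.label = x$labels,
              Nnode = n_nodes - n)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}
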