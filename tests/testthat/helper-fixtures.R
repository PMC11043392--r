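# Shared fixtures: small configurations and hand-built population states.

# A down-scaled but structurally valid configuration (5 villages of 30,
# three groups of 10 each).
small_config <- function(...) {
  sim_config(n_total = 150L, n_villages = 5L, village_init_size = 30L,
             group_init_size = 10L, sample_per_village = 5L, ...)
}

# Minimal hand-built population state for operator-level tests.
# sex: 1 = male, 2 = female.
make_test_pop <- function(sex, village, group = rep(NA_integer_,
                                                    length(sex)),
                          n_villages = max(village), generation = 0L,
                          fitness = NULL, last_fission = NULL) {
  sex <- as.integer(sex)
  village <- as.integer(village)
  group <- as.integer(group)
  gids <- sort(unique(group[!is.na(group)]))
  groups <- if (length(gids)) {
    data.frame(
      id = gids,
      village = vapply(gids, function(g) village[match(g, group)],
                       integer(1L)),
      fitness = if (is.null(fitness)) rep(0.01, length(gids)) else fitness,
      last_fission = if (is.null(last_fission)) rep(-1000, length(gids))
                     else last_fission)
  } else {
    data.frame(id = integer(0), village = integer(0), fitness = numeric(0),
               last_fission = numeric(0))
  }
  list(generation = generation, n_villages = n_villages,
       id = seq_along(sex), sex = as.integer(sex),
       village = as.integer(village), group = as.integer(group),
       groups = groups, next_group_id = max(c(gids, 0L)) + 1L,
       events = list(), group_sizes = list(), village_sizes = list())
}

# Pedigree with explicit parent links: founders first (father = mother = 0).
make_test_ped <- function(father, mother, sex) {
  ped <- patriseg:::new_pedigree(length(father))
  patriseg:::ped_add(ped, as.integer(father), as.integer(mother),
                     as.integer(sex))
  ped
}

# Brute-force pairwise MRCA oracle on the pedigree + burn-in tree: returns
# the coalescence time (generations before sampling) of two individuals'
# marker lineages.
oracle_pair_tmrca <- function(id1, id2, ped, burn_in, founder_tips,
                              n_generations, marker) {
  link <- if (marker == "Y") ped$father else ped$mother
  a <- id1
  b <- id2
  for (g in seq_len(n_generations)) {
    a <- link[a]
    b <- link[b]
    if (a == b) return(g)
  }
  # join through the burn-in tree: walk root-ward paths
  t1 <- founder_tips[a]
  t2 <- founder_tips[b]
  path <- function(tip) {
    nodes <- tip
    while (burn_in$parent[nodes[length(nodes)]] > 0L) {
      nodes <- c(nodes, burn_in$parent[nodes[length(nodes)]])
    }
    nodes
  }
  common <- intersect(path(t1), path(t2))
  n_generations + min(burn_in$time[common])
}

# Pairwise TMRCA matrix read off a gene_tree.
tree_pair_tmrca <- function(tree, i, j) {
  path <- function(node) {
    nodes <- node
    while (tree$parent[nodes[length(nodes)]] > 0L) {
      nodes <- c(nodes, tree$parent[nodes[length(nodes)]])
    }
    nodes
  }
  common <- intersect(path(i), path(j))
  min(tree$time[common])
}
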