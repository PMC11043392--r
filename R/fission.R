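# Fission of over-large descent groups.

# Truncated-normal split proportion: Normal(0.5, variance 0.5) by rejection,
# kept within [0, 1].
draw_split_proportion <- function() {
  repeat {
    p <- stats::rnorm(1L, mean = 0.5, sd = sqrt(0.5))
    if (p >= 0 && p <= 1) return(p)
  }
}

#' Partition a group's males along paternal clades (lineal fission)
#'
#' Builds the paternal genealogy of the group's living males from the
#' pedigree and cuts it into two sets of complete paternal clades: the
#' top-level clades are the descendants of the children of the males' most
#' recent common male-line ancestor (or the distinct founder patrilines when
#' no common ancestor exists within the pedigree). Clades are packed
#' greedily, largest first, each clade joining the first set whenever that
#' moves its male fraction closer to `target_proportion`. Both returned sets
#' are therefore unions of complete clades ("males having different most
#' recent common ancestors through the male line"). When every male is a son
#' of the same father (star genealogy) the clades are singletons and the
#' partition degenerates to a random split, which is flagged.
#'
#' @param male_ids pedigree ids of the group's males (all same generation).
#' @param ped the pedigree.
#' @param n_generations generation of the males.
#' @param target_proportion desired fraction of males in the first set.
#' @return list with `set_a`, `set_b` (pedigree ids), `proportion` (realised
#'   fraction in `set_a`) and `star` (TRUE when the genealogy was degenerate).
#' @export
lineal_partition <- function(male_ids, ped, n_generations,
                             target_proportion) {
  M <- length(male_ids)
  stopifnot(M >= 2L, target_proportion >= 0, target_proportion <= 1)
  # walk back through father links; clade labels one step below the MRCA
  anc <- ped$father[male_ids]
  clade <- match(anc, unique(anc))
  if (length(unique(clade)) == 1L) {
    # all brothers: star genealogy, no clade structure below the father
    clade <- seq_len(M)
    star <- TRUE
  } else {
    star <- FALSE
    g <- 1L
    while (g < n_generations) {
      g <- g + 1L
      anc <- ped$father[anc]
      new_clade <- match(anc, unique(anc))
      if (length(unique(new_clade)) == 1L) break  # merged: MRCA reached
      clade <- new_clade
    }
  }
  sizes <- tabulate(clade)
  in_a <- greedy_clade_pack(sizes, target_proportion)
  set_a <- male_ids[clade %in% which(in_a)]
  set_b <- setdiff(male_ids, set_a)
  if (!length(set_a)) {
    # extreme target: the smallest clade still crosses over
    set_a <- male_ids[clade == which.min(sizes)]
    set_b <- setdiff(male_ids, set_a)
  } else if (!length(set_b)) {
    set_b <- male_ids[clade == which.min(sizes)]
    set_a <- setdiff(male_ids, set_b)
  }
  list(set_a = set_a, set_b = set_b,
       proportion = length(set_a) / M, star = star)
}

# Greedy packing: clades visited largest-first join the first set whenever
# that does not move the realised fraction away from the target.
greedy_clade_pack <- function(sizes, target) {
  total <- sum(sizes)
  in_a <- logical(length(sizes))
  sum_a <- 0
  for (i in order(sizes, decreasing = TRUE)) {
    if (abs((sum_a + sizes[i]) / total - target) <=
        abs(sum_a / total - target)) {
      in_a[i] <- TRUE
      sum_a <- sum_a + sizes[i]
    }
  }
  in_a
}

#' Check fission triggers and execute splits
#'
#' A group fissions when twice its male count exceeds the threshold `N_max`
#' and its last fission lies more than `fission_cooldown` generations in the
#' past. The male split proportion is drawn from a normal distribution with
#' mean 0.5 and variance 0.5 truncated to \[0, 1\]; males are partitioned at
#' random or along paternal clades ([lineal_partition()]) according to the
#' fission type, and females are split so each daughter group keeps the same
#' female as male fraction (balanced sex ratio). Daughters draw fresh
#' relative fitnesses from Normal(mean = r_parent, sd = sigma2) and inherit the current
#' generation as their last fission time. A draw leaving a daughter empty is
#' redrawn.
#'
#' @param pop population state (cohort of the current generation).
#' @param ped the pedigree.
#' @param params effective phase parameters (fission_threshold,
#'   fission_cooldown, fission_type, sigma2).
#' @return list: updated `pop` and `outcomes`, one record per executed
#'   fission.
#' @export
check_and_execute_fissions <- function(pop, ped, params) {
  outcomes <- list()
  if (!nrow(pop$groups)) return(list(pop = pop, outcomes = outcomes))
  t_now <- pop$generation
  male_count <- function(g) sum(pop$group == g & pop$sex == 1L, na.rm = TRUE)
  candidates <- pop$groups$id[
    vapply(pop$groups$id, function(g) 2L * male_count(g), integer(1L)) >
      params$fission_threshold &
    (t_now - pop$groups$last_fission) > params$fission_cooldown]
  for (gid in candidates) {
    members <- which(!is.na(pop$group) & pop$group == gid)
    males <- members[pop$sex[members] == 1L]
    females <- members[pop$sex[members] == 2L]
    M <- length(males)
    if (M < 2L) next
    row <- which(pop$groups$id == gid)
    for (attempt in seq_len(50L)) {
      p <- draw_split_proportion()
      if (params$fission_type == "lineal") {
        part <- lineal_partition(pop$id[males], ped, t_now, p)
        a_males <- males[pop$id[males] %in% part$set_a]
        pa <- part$proportion
      } else {
        n_a <- max(0L, min(M, round(p * M)))
        a_males <- if (n_a > 0L) males[sample.int(M, n_a)] else integer(0)
        pa <- n_a / M
      }
      n_af <- max(0L, min(length(females), round(pa * length(females))))
      a_females <- if (n_af > 0L) {
        females[sample.int(length(females), n_af)]
      } else integer(0)
      size_a <- length(a_males) + length(a_females)
      size_b <- length(members) - size_a
      if (size_a > 0L && size_b > 0L) break
      if (attempt == 50L) {  # force an even split
        a_males <- males[seq_len(M %/% 2L)]
        a_females <- females[seq_len(length(females) %/% 2L)]
        pa <- 0.5
      }
    }
    id_a <- pop$next_group_id
    id_b <- pop$next_group_id + 1L
    pop$next_group_id <- pop$next_group_id + 2L
    vill <- pop$groups$village[row]
    r_parent <- pop$groups$fitness[row]
    child_fitness <- stats::rnorm(2L, mean = r_parent, sd = params$sigma2)
    a_all <- c(a_males, a_females)
    b_all <- setdiff(members, a_all)
    pop$group[a_all] <- id_a
    pop$group[b_all] <- id_b
    pop$groups <- pop$groups[-row, , drop = FALSE]
    pop$groups <- rbind(pop$groups, data.frame(
      id = c(id_a, id_b), village = vill, fitness = child_fitness,
      last_fission = t_now))
    out <- list(generation = t_now, type = "fission", village = vill,
                group = gid, child1 = id_a, child2 = id_b,
                proportion = pa, fission_type = params$fission_type,
                size1 = length(a_all), size2 = length(b_all))
    outcomes[[length(outcomes) + 1L]] <- out
    pop$events[[length(pop$events) + 1L]] <- out
  }
  list(pop = pop, outcomes = outcomes)
}

#' Post-fission migration of the smaller daughter group
#'
#' When enabled, the smaller daughter of each fission relocates wholesale to
#' another village. With a single fission in the population the destination
#' is uniform among the other villages; when several villages fission in the
#' same generation they exchange daughter groups (each mover is sent to
#' another mover's village of origin), which keeps village sizes as balanced
#' as possible.
#'
#' @param pop population state.
#' @param outcomes fission records from [check_and_execute_fissions()].
#' @return updated population state.
#' @export
post_fission_migrate <- function(pop, outcomes) {
  if (!length(outcomes)) return(pop)
  movers <- vapply(outcomes, function(o) {
    if (o$size1 <= o$size2) o$child1 else o$child2
  }, integer(1L))
  sources <- vapply(outcomes, `[[`, numeric(1L), "village")
  V <- pop$n_villages
  k <- length(movers)
  dest <- integer(k)
  if (k == 1L || length(unique(sources)) == 1L) {
    for (i in seq_len(k)) {
      others <- setdiff(seq_len(V), sources[i])
      dest[i] <- others[sample.int(length(others), 1L)]
    }
  } else {
    # exchange: a random derangement of the source villages
    for (attempt in seq_len(100L)) {
      perm <- sample.int(k)
      if (all(sources[perm] != sources)) break
    }
    if (any(sources[perm] == sources)) {
      for (i in seq_len(k)) {
        bad <- sources[perm[i]] == sources[i]
        if (bad) {
          others <- setdiff(seq_len(V), sources[i])
          dest[i] <- others[sample.int(length(others), 1L)]
        } else dest[i] <- sources[perm[i]]
      }
    } else dest <- sources[perm]
  }
  for (i in seq_len(k)) {
    g <- movers[i]
    pop$groups$village[pop$groups$id == g] <- dest[i]
    pop$village[!is.na(pop$group) & pop$group == g] <- dest[i]
    pop$events[[length(pop$events) + 1L]] <- list(
      generation = pop$generation, type = "group_migration",
      village = sources[i], group = g, to = dest[i])
  }
  pop
}
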