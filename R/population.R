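# Population state and the per-generation cycle:
# migration -> reproduction -> violence -> fission / extinction
# (-> post-fission migration), with non-overlapping generations.

#' Initialise the structured population
#'
#' Creates the founder generation: `n_villages` villages of
#' `village_init_size` individuals with alternating sexes. In patrilineal
#' phases each village is partitioned into three descent groups of equal size
#' and balanced sex ratio, with relative fitnesses drawn from
#' Normal(mean = growth_rate, sd = sigma2).
#'
#' @param config a [sim_config()].
#' @param phase the first [sim_phase()] of the schedule.
#' @param ped a pedigree to register the founders in (created if NULL).
#' @return a population state list (see package internals); the pedigree is
#'   attached as attribute `"ped"` when it was created here.
#' @export
init_population <- function(config, phase, ped = NULL) {
  created <- is.null(ped)
  if (created) ped <- new_pedigree(config$n_total * 4L)
  V <- config$n_villages
  N0 <- config$village_init_size
  village <- rep(seq_len(V), each = N0)
  sex <- rep(rep_len(c(1L, 2L), N0), times = V)
  ids <- ped_add(ped, integer(V * N0), integer(V * N0), sex)
  pop <- list(generation = 0L, n_villages = V, id = ids, sex = sex,
              village = village, group = rep(NA_integer_, V * N0),
              groups = data.frame(id = integer(0), village = integer(0),
                                  fitness = numeric(0),
                                  last_fission = numeric(0)),
              next_group_id = 1L, events = list(), group_sizes = list(),
              village_sizes = list())
  params <- phase_params(phase, config)
  if (params$descent == "patrilineal") {
    pop <- seed_descent_groups(pop, config, params$sigma2)
  }
  pop <- log_group_sizes(pop)
  pop <- log_village_sizes(pop)
  if (created) attr(pop, "ped") <- ped
  pop
}

# Partition every village into three equal descent groups with balanced
# sexes and fresh fitness draws.
seed_descent_groups <- function(pop, config, sigma2) {
  V <- pop$n_villages
  n_groups <- 3L
  gids <- pop$next_group_id + seq_len(V * n_groups) - 1L
  pop$next_group_id <- pop$next_group_id + V * n_groups
  fitness <- stats::rnorm(V * n_groups, mean = config$growth_rate,
                          sd = sigma2)
  reg <- data.frame(id = gids, village = rep(seq_len(V), each = n_groups),
                    fitness = fitness,
                    last_fission = pop$generation)
  for (v in seq_len(V)) {
    vg <- gids[reg$village == v]
    for (s in 1:2) {
      idx <- which(pop$village == v & pop$sex == s)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      pop$group[idx] <- vg[ceiling(seq_along(idx) / (length(idx) / n_groups))]
    }
  }
  pop$groups <- reg
  pop
}

log_group_sizes <- function(pop) {
  if (!nrow(pop$groups)) return(pop)
  g <- pop$group[!is.na(pop$group)]
  s <- pop$sex[!is.na(pop$group)]
  size <- vapply(pop$groups$id, function(id) sum(g == id), integer(1L))
  males <- vapply(pop$groups$id, function(id) sum(g == id & s == 1L),
                  integer(1L))
  pop$group_sizes[[length(pop$group_sizes) + 1L]] <- data.frame(
    generation = pop$generation, group = pop$groups$id,
    village = pop$groups$village, size = size, males = males,
    fitness = pop$groups$fitness)
  pop
}

log_village_sizes <- function(pop) {
  pop$village_sizes[[length(pop$village_sizes) + 1L]] <- data.frame(
    generation = pop$generation, village = seq_len(pop$n_villages),
    size = as.integer(tabulate(pop$village, pop$n_villages)))
  pop
}

# Village target size under the deterministic exponential growth law.
village_target_size <- function(config, generation) {
  round(config$village_init_size * exp(config$growth_rate * generation))
}

#' Advance the population by one generation
#'
#' Runs the generation cycle: (1) individual migration of the standing
#' adults; (2) reproduction, each village producing exactly
#' `round(N0 * exp(r * t))` children through monogamous couples (with
#' descent-group exogamy and group-fitness-weighted paternity in patrilineal
#' phases, or uniform/polygynous mating in bilateral ones); (3) violent
#' competition, removing males from the newborn cohort when the violence
#' rate is positive; (4) fission checks, extinctions and post-fission group
#' migration. Generations do not overlap: the parents are replaced by their
#' children.
#'
#' @param pop population state.
#' @param ped the pedigree.
#' @param phase the phase in force for this cycle.
#' @param config a [sim_config()].
#' @return the updated population state, with `generation` incremented.
#' @export
run_generation <- function(pop, ped, phase, config) {
  params <- phase_params(phase, config)
  t_next <- pop$generation + 1L
  patrilineal <- params$descent == "patrilineal"

  pop <- migrate_individuals(pop, params$female_mig_rate,
                             params$male_mig_rate)

  # reproduction, village by village
  V <- pop$n_villages
  target <- village_target_size(config, t_next)
  child_father <- child_mother <- child_group <- child_village <-
    child_sex <- vector("list", V)
  for (v in seq_len(V)) {
    males <- which(pop$village == v & pop$sex == 1L)
    females <- which(pop$village == v & pop$sex == 2L)
    if (!length(males) || !length(females)) {
      stop("village ", v, " lost one sex entirely at generation ", t_next,
           call. = FALSE)
    }
    if (params$polygyny && !patrilineal) {
      kids <- assign_offspring_polygynous(males, females, target,
                                          p = params$polygyny_p)
    } else if (patrilineal) {
      pairs <- form_mating_pairs(males, females, group = pop$group)
      mg <- pop$group[males]
      mc <- table(factor(mg, levels = unique(mg)))
      male_counts <- stats::setNames(as.integer(mc), names(mc))
      fit <- stats::setNames(pop$groups$fitness,
                             as.character(pop$groups$id))
      kids <- assign_offspring(pairs, pair_group = pop$group[pairs$male],
                               male_counts = male_counts, fitness = fit,
                               n_children = target)
    } else {
      pairs <- form_mating_pairs(males, females, group = NULL)
      kids <- assign_offspring(pairs, n_children = target)
    }
    child_father[[v]] <- pop$id[kids$father]
    child_mother[[v]] <- pop$id[kids$mother]
    child_group[[v]] <- kids$group
    child_sex[[v]] <- kids$sex
    child_village[[v]] <- rep(v, length(kids$sex))
  }
  sex <- unlist(child_sex)
  ids <- ped_add(ped, unlist(child_father), unlist(child_mother), sex)
  pop$id <- ids
  pop$sex <- sex
  pop$village <- unlist(child_village)
  pop$group <- unlist(child_group)
  pop$generation <- t_next
  pop <- log_village_sizes(pop)   # at-birth census: exact growth law

  # violence on the newborn male cohort
  if (params$violence_rate > 0) {
    vio <- apply_violence(pop$sex, pop$group, params$violence_rate)
    if (length(vio$killed)) {
      for (g in names(vio$kills_per_group)) {
        cnt <- vio$kills_per_group[[g]]
        if (cnt > 0L) {
          pop$events[[length(pop$events) + 1L]] <- list(
            generation = t_next, type = "kills",
            village = NA_integer_,
            group = suppressWarnings(as.integer(g)), count = cnt,
            fallback = vio$fallback)
        }
      }
      keep <- setdiff(seq_along(pop$id), vio$killed)
      pop$id <- pop$id[keep]
      pop$sex <- pop$sex[keep]
      pop$village <- pop$village[keep]
      pop$group <- pop$group[keep]
    }
  }

  if (patrilineal) {
    fiss <- check_and_execute_fissions(pop, ped, params)
    pop <- fiss$pop
    pop <- remove_extinct_groups(pop)
    if (params$post_fission_migration) {
      pop <- post_fission_migrate(pop, fiss$outcomes)
    }
    pop <- log_group_sizes(pop)
  }
  pop
}

#' Apply a phase transition to the standing population
#'
#' Entering a patrilineal phase partitions every village into three equal
#' descent groups with balanced sexes and fresh fitness draws (children
#' follow their father's group thereafter); leaving one dissolves the group
#' registry and disables the fission machinery. A transition between two
#' patrilineal phases keeps group membership and redraws fitnesses under the
#' new sigma^2.
#'
#' @param pop population state.
#' @param new_phase the phase starting at the current generation.
#' @param config a [sim_config()].
#' @return updated population state.
#' @export
apply_phase_transition <- function(pop, new_phase, config) {
  if (new_phase$start != pop$generation) {
    stop("phase starts at generation ", new_phase$start,
         " but the population is at generation ", pop$generation,
         call. = FALSE)
  }
  params <- phase_params(new_phase, config)
  was_patrilineal <- nrow(pop$groups) > 0L
  if (params$descent == "patrilineal") {
    if (was_patrilineal) {
      pop$groups$fitness <- stats::rnorm(nrow(pop$groups),
                                         mean = config$growth_rate,
                                         sd = params$sigma2)
    } else {
      pop <- seed_descent_groups(pop, config, params$sigma2)
      pop <- log_group_sizes(pop)
    }
  } else {
    pop$group <- rep(NA_integer_, length(pop$id))
    pop$groups <- pop$groups[0, , drop = FALSE]
  }
  pop
}
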