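# Whole-replicate driver: burn-in initialisation, generation loop with phase
# transitions, periodic diversity sampling.

#' Simulate one replicate of a scenario
#'
#' Runs the full forward simulation for one replicate: founder initialisation,
#' coalescent initialisation of standing Y and mtDNA diversity
#' ([coalescent_burn_in()]), then `total_generations` cycles of
#' [run_generation()], applying phase transitions where the schedule demands.
#' Every `sample_interval` generations the within-village and pooled (global)
#' nucleotide diversities of both markers are measured on samples of
#' `sample_per_village` males (Y) and females (mtDNA) per village, via
#' [extract_gene_tree()], [drop_mutations()] and [pairwise_pi()], and
#' converted to effective sizes with [ne_from_pi()].
#'
#' @param scenario a preset name (see [preset_names()]), a `scenario_preset`,
#'   or a [sim_config()] (combined with `schedule`).
#' @param seed integer seed for this replicate (base R RNG).
#' @param overrides named list of configuration overrides.
#' @param schedule optional [phase_schedule()] when `scenario` is a config.
#' @param total_generations optional override of the preset's duration.
#' @param track_group_pi if TRUE, also record the mean within-descent-group
#'   Y diversity at each sampling point (groups with at least 2 males).
#' @param keep_state if TRUE, the returned object retains the final
#'   population state, pedigree and burn-in trees, enabling
#'   [export_sample()].
#' @return a `patriseg_run` with elements `diversity` (data frame:
#'   generation, scope, pi_Y, pi_mt, ne_Y, ne_mt, ratio), `events`,
#'   `group_sizes`, `village_sizes`, `demography` (see [group_demography()]),
#'   `config`, `schedule`, `seed`.
#' @export
#' @examples
#' \donttest{
#' run <- simulate_replicate("2g", seed = 1)
#' subset(run$diversity, scope == "within_village_mean")
#' }
simulate_replicate <- function(scenario, seed = NULL, overrides = list(),
                               schedule = NULL, total_generations = NULL,
                               track_group_pi = FALSE, keep_state = FALSE) {
  if (is.character(scenario)) {
    scenario <- scenario_preset(scenario, overrides = overrides)
  } else if (inherits(scenario, "scenario_preset") && length(overrides)) {
    scenario <- scenario_preset(scenario$name, overrides = overrides)
  } else if (inherits(scenario, "sim_config")) {
    if (is.null(schedule)) {
      schedule <- phase_schedule(sim_phase(0L, "patrilineal", "patrilocal"))
    }
    if (length(overrides)) {
      scenario <- do.call(sim_config,
                          utils::modifyList(unclass(scenario), overrides))
    }
    scenario <- structure(list(name = "custom", config = scenario,
                               schedule = schedule,
                               total_generations =
                                 if (is.null(total_generations)) 100L
                                 else as.integer(total_generations)),
                          class = "scenario_preset")
  }
  stopifnot(inherits(scenario, "scenario_preset"))
  config <- scenario$config
  total <- if (is.null(total_generations)) scenario$total_generations
           else as.integer(total_generations)
  if (!is.null(seed)) set.seed(as.integer(seed))

  ped <- new_pedigree(config$n_total * 8L)
  pop <- init_population(config, scenario$schedule[[1L]], ped = ped)
  founder_males <- pop$id[pop$sex == 1L]
  founder_females <- pop$id[pop$sex == 2L]
  burn_Y <- coalescent_burn_in(length(founder_males), marker = "Y")
  burn_mt <- coalescent_burn_in(length(founder_females), marker = "mtDNA")
  tips_Y <- rep(NA_integer_, config$n_total)
  tips_Y[founder_males] <- seq_along(founder_males)
  tips_mt <- rep(NA_integer_, config$n_total)
  tips_mt[founder_females] <- seq_along(founder_females)

  div <- list()
  measure <- function(pop) {
    div[[length(div) + 1L]] <<- measure_diversity(
      pop, ped, burn_Y, burn_mt, tips_Y, tips_mt, config,
      track_group_pi = track_group_pi)
  }
  measure(pop)

  starts <- vapply(scenario$schedule, `[[`, integer(1L), "start")
  for (t_next in seq_len(total)) {
    hit <- which(starts == pop$generation & starts > 0L)
    if (length(hit)) {
      pop <- apply_phase_transition(pop, scenario$schedule[[hit]], config)
    }
    phase <- phase_at(scenario$schedule, pop$generation)
    pop <- run_generation(pop, ped, phase, config)
    if (pop$generation %% config$sample_interval == 0L ||
        pop$generation == total) {
      measure(pop)
    }
  }

  res <- list(
    scenario = scenario$name,
    config = config,
    schedule = scenario$schedule,
    seed = seed,
    total_generations = total,
    diversity = do.call(rbind, div),
    events = events_to_df(pop$events),
    group_sizes = if (length(pop$group_sizes)) {
      do.call(rbind, pop$group_sizes)
    } else data.frame(),
    village_sizes = do.call(rbind, pop$village_sizes))
  # bilateral-only runs have no group log; skip the op-level warning
  res$demography <- if (nrow(res$group_sizes)) {
    group_demography(res$group_sizes, res$events)
  } else {
    empty_group_demography()
  }
  if (keep_state) {
    res$state <- pop
    res$ped <- ped
    res$burn_in <- list(Y = burn_Y, mtDNA = burn_mt)
    res$founder_tips <- list(Y = tips_Y, mtDNA = tips_mt)
  }
  class(res) <- "patriseg_run"
  res
}

#' @export
print.patriseg_run <- function(x, ...) {
  cat("<patriseg_run> scenario", x$scenario, "-", x$total_generations,
      "generations, seed", if (is.null(x$seed)) "NULL" else x$seed, "\n")
  w <- subset(x$diversity, x$diversity$scope == "within_village_mean")
  cat("  final within-village Ne_Y:", format(w$ne_Y[nrow(w)], digits = 4),
      " Ne_mt:", format(w$ne_mt[nrow(w)], digits = 4), "\n")
  invisible(x)
}

# One diversity measurement: within-village mean and pooled/global pi for
# both markers, converted to Ne.
measure_diversity <- function(pop, ped, burn_Y, burn_mt, tips_Y, tips_mt,
                              config, track_group_pi = FALSE) {
  V <- pop$n_villages
  t <- pop$generation
  k <- config$sample_per_village
  pi_with <- function(ids, marker, burn, tips) {
    if (length(ids) < 2L) return(NA_real_)
    tree <- extract_gene_tree(ids, ped, burn, tips, t, marker)
    mu <- if (marker == "Y") config$mu_Y else config$mu_mt
    L <- if (marker == "Y") config$len_Y else config$len_mt
    pairwise_pi(drop_mutations(tree, mu, L))
  }
  sample_ids <- function(v, sexcode) {
    idx <- which(pop$village == v & pop$sex == sexcode)
    if (length(idx) > k) idx <- idx[sample.int(length(idx), k)]
    pop$id[idx]
  }
  piY_v <- numeric(V)
  pimt_v <- numeric(V)
  poolY <- poolmt <- integer(0)
  for (v in seq_len(V)) {
    sY <- sample_ids(v, 1L)
    smt <- sample_ids(v, 2L)
    piY_v[v] <- pi_with(sY, "Y", burn_Y, tips_Y)
    pimt_v[v] <- pi_with(smt, "mtDNA", burn_mt, tips_mt)
    poolY <- c(poolY, sY)
    poolmt <- c(poolmt, smt)
  }
  rows <- data.frame(
    generation = t,
    scope = c("within_village_mean", "global"),
    pi_Y = c(mean(piY_v, na.rm = TRUE),
             pi_with(poolY, "Y", burn_Y, tips_Y)),
    pi_mt = c(mean(pimt_v, na.rm = TRUE),
              pi_with(poolmt, "mtDNA", burn_mt, tips_mt)))
  rows$ne_Y <- ne_from_pi(rows$pi_Y, config$mu_Y)
  rows$ne_mt <- ne_from_pi(rows$pi_mt, config$mu_mt)
  rows$ratio <- ifelse(rows$ne_Y > 0, rows$ne_mt / rows$ne_Y, NA_real_)
  if (track_group_pi) {
    gpis <- numeric(0)
    for (g in pop$groups$id) {
      idx <- which(!is.na(pop$group) & pop$group == g & pop$sex == 1L)
      if (length(idx) < 2L) next
      if (length(idx) > k) idx <- idx[sample.int(length(idx), k)]
      gpis <- c(gpis, pi_with(pop$id[idx], "Y", burn_Y, tips_Y))
    }
    rows$pi_Y_within_group <- if (length(gpis)) mean(gpis) else NA_real_
  }
  rows
}

# Flatten the event accumulator into a data frame with stable columns.
events_to_df <- function(events) {
  if (!length(events)) {
    return(data.frame(generation = integer(0), type = character(0),
                      village = integer(0), group = integer(0),
                      child1 = integer(0), child2 = integer(0),
                      proportion = numeric(0), fission_type = character(0),
                      size1 = integer(0), size2 = integer(0),
                      count = integer(0), to = integer(0),
                      fallback = logical(0)))
  }
  cols <- c("generation", "type", "village", "group", "child1", "child2",
            "proportion", "fission_type", "size1", "size2", "count", "to",
            "fallback")
  rows <- lapply(events, function(e) {
    e <- e[intersect(cols, names(e))]
    miss <- setdiff(cols, names(e))
    e[miss] <- NA
    as.data.frame(e[cols], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
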