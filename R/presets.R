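#' Define a simulation phase
#'
#' A phase fixes the descent rule, the residence rule and optional parameter
#' overrides from a given generation onwards. The residence rule sets the
#' default migration regime: patrilocal uses the configured
#' `female_mig_rate`/`male_mig_rate` (10% of females and 0 or 2% of males by
#' default), matrilocal swaps the bias (10% of males, no females), multilocal
#' moves 5% of each sex. Phase `overrides` win over both.
#'
#' @param start first generation (from t0 = 0) at which the phase applies.
#' @param descent `"patrilineal"` or `"bilateral"`.
#' @param residence `"patrilocal"`, `"matrilocal"` or `"multilocal"`.
#' @param overrides named list of per-phase overrides (e.g. `sigma2`,
#'   `fission_type`, `violence_rate`, `female_mig_rate`, `male_mig_rate`,
#'   `post_fission_migration`, `polygyny`).
#' @return a `sim_phase` object.
#' @export
sim_phase <- function(start, descent = c("patrilineal", "bilateral"),
                      residence = c("patrilocal", "matrilocal", "multilocal"),
                      overrides = list()) {
  descent <- match.arg(descent)
  residence <- match.arg(residence)
  stopifnot(is.numeric(start), length(start) == 1L, start >= 0,
            start == round(start))
  allowed <- c("sigma2", "fission_type", "violence_rate", "female_mig_rate",
               "male_mig_rate", "post_fission_migration", "polygyny",
               "fission_threshold", "fission_cooldown")
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), allowed)
    if (length(unknown)) {
      stop("unknown phase override(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(start = as.integer(start), descent = descent,
                 residence = residence, overrides = overrides),
            class = "sim_phase")
}

#' Assemble an ordered phase schedule
#'
#' @param ... `sim_phase` objects with strictly increasing start generations;
#'   the first phase must start at generation 0.
#' @return a `phase_schedule` object (a list of phases).
#' @export
phase_schedule <- function(...) {
  phases <- list(...)
  if (length(phases) == 1L && !inherits(phases[[1L]], "sim_phase") &&
      is.list(phases[[1L]])) {
    phases <- phases[[1L]]
  }
  stopifnot(length(phases) >= 1L,
            all(vapply(phases, inherits, logical(1L), "sim_phase")))
  starts <- vapply(phases, `[[`, integer(1L), "start")
  if (starts[1L] != 0L) stop("the first phase must start at generation 0",
                             call. = FALSE)
  if (length(starts) > 1L && any(diff(starts) <= 0L)) {
    stop("phase start generations must be strictly increasing", call. = FALSE)
  }
  structure(phases, class = "phase_schedule")
}

#' Phase in force at a given generation
#' @keywords internal
#' @noRd
phase_at <- function(schedule, generation) {
  starts <- vapply(schedule, `[[`, integer(1L), "start")
  schedule[[max(which(starts <= generation))]]
}

#' Effective per-phase parameters
#'
#' Resolves the configuration against a phase: residence-rule migration
#' defaults, then phase overrides.
#' @keywords internal
#' @noRd
phase_params <- function(phase, config) {
  p <- unclass(config)
  p$descent <- phase$descent
  p$residence <- phase$residence
  if (phase$residence == "matrilocal") {
    p$male_mig_rate <- 0.1
    p$female_mig_rate <- 0
  } else if (phase$residence == "multilocal") {
    p$male_mig_rate <- 0.05
    p$female_mig_rate <- 0.05
  }
  for (k in names(phase$overrides)) p[[k]] <- phase$overrides[[k]]
  p
}

.preset_names <- c("1", "2a", "2b", "2c", "2d", "2e", "2f", "2g", "2h",
                   "3a", "3b", "3c", "4a", "4b", "4c", "polygyny")

#' Names of the available scenario presets
#' @return character vector of preset names.
#' @export
preset_names <- function() .preset_names

#' Scenario presets
#'
#' Returns a named scenario as a configuration plus phase schedule:
#' \itemize{
#'   \item `"1"`: bilateral descent, patrilocal villages, 100 generations.
#'   \item `"2a"`--`"2h"`: patrilineal patrilocal villages for 100
#'     generations; the three letters toggle fission type (random for
#'     a/b/e/f, lineal for c/d/g/h), variance in group reproductive success
#'     (sigma^2 = 0 for a--d, 0.1 for e--h) and violent competition
#'     (15% of males killed per generation for b/d/f/h).
#'   \item `"3a"`--`"3c"`: 100 generations of bilateral descent (patrilocal,
#'     multilocal or matrilocal residence respectively) followed by 100
#'     generations of the `"2g"` settings.
#'   \item `"4a"`: 200 generations of the `"2g"` settings.
#'   \item `"4b"`: 100 generations of `"2g"` then 100 generations of
#'     bilateral patrilocal descent.
#'   \item `"4c"`: 100 generations of `"2g"` then 100 generations of
#'     patrilineal descent without variance (the `"2c"` settings).
#'   \item `"polygyny"`: bilateral patrilocal villages with Kipsigis-like
#'     polygyny (geometric mating weights, p = 1/2), 100 generations.
#' }
#' Migration variants (2% male migration, post-fission group migration) are
#' obtained by overriding `male_mig_rate` / `post_fission_migration`, e.g.
#' through the `overrides` argument of [run_scenario()].
#'
#' @param name one of [preset_names()].
#' @param overrides named list of configuration overrides applied on top of
#'   the preset's base configuration.
#' @return a `scenario_preset`: list with `name`, `config`, `schedule` and
#'   `total_generations`.
#' @export
#' @examples
#' p <- scenario_preset("2g")
#' p$config$fission_type
#' p$total_generations
scenario_preset <- function(name, overrides = list()) {
  name <- as.character(name)
  if (!name %in% .preset_names) {
    stop("unknown scenario preset: '", name, "'", call. = FALSE)
  }
  two_x <- function(letter) {
    lineal <- letter %in% c("c", "d", "g", "h")
    variance <- letter %in% c("e", "f", "g", "h")
    violent <- letter %in% c("b", "d", "f", "h")
    list(fission_type = if (lineal) "lineal" else "random",
         sigma2 = if (variance) 0.1 else 0,
         violence_rate = if (violent) 0.15 else 0)
  }
  base <- list()
  total <- 100L
  if (name == "1") {
    base <- list(sigma2 = 0, violence_rate = 0)
    schedule <- phase_schedule(sim_phase(0L, "bilateral", "patrilocal"))
  } else if (grepl("^2", name)) {
    base <- two_x(substring(name, 2L))
    schedule <- phase_schedule(sim_phase(0L, "patrilineal", "patrilocal"))
  } else if (grepl("^3", name)) {
    res <- switch(substring(name, 2L), a = "patrilocal", b = "multilocal",
                  c = "matrilocal")
    base <- two_x("g")
    total <- 200L
    schedule <- phase_schedule(
      sim_phase(0L, "bilateral", res),
      sim_phase(100L, "patrilineal", "patrilocal"))
  } else if (name == "4a") {
    base <- two_x("g")
    total <- 200L
    schedule <- phase_schedule(sim_phase(0L, "patrilineal", "patrilocal"))
  } else if (name == "4b") {
    base <- two_x("g")
    total <- 200L
    schedule <- phase_schedule(
      sim_phase(0L, "patrilineal", "patrilocal"),
      sim_phase(100L, "bilateral", "patrilocal"))
  } else if (name == "4c") {
    base <- two_x("g")
    total <- 200L
    schedule <- phase_schedule(
      sim_phase(0L, "patrilineal", "patrilocal"),
      sim_phase(100L, "patrilineal", "patrilocal",
                overrides = list(sigma2 = 0, fission_type = "lineal",
                                 violence_rate = 0)))
  } else if (name == "polygyny") {
    base <- list(sigma2 = 0, violence_rate = 0, polygyny = TRUE)
    schedule <- phase_schedule(sim_phase(0L, "bilateral", "patrilocal"))
  }
  cfg_vals <- utils::modifyList(base, overrides)
  structure(list(name = name,
                 config = do.call(sim_config, cfg_vals),
                 schedule = schedule,
                 total_generations = total),
            class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("<scenario_preset>", x$name, "-", x$total_generations, "generations\n")
  for (ph in x$schedule) {
    cat(sprintf("  t >= %3d: %s descent, %s residence", ph$start, ph$descent,
                ph$residence))
    if (length(ph$overrides)) {
      cat(" [", paste(names(ph$overrides), unlist(ph$overrides), sep = "=",
                      collapse = ", "), "]")
    }
    cat("\n")
  }
  cat("  fission:", x$config$fission_type, " sigma2:", x$config$sigma2,
      " violence:", x$config$violence_rate, "\n")
  invisible(x)
}
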