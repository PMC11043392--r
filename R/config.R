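#' Build a simulation configuration
#'
#' Assembles and validates the full parameter set of the socio-demographic
#' simulator. Defaults describe the standard study population: 1500 founders
#' split into 5 villages of 300, each village holding three descent groups of
#' 100 when descent is patrilineal, growing at 1% per generation, with
#' patrilocal migration (10% of females, 0 or 2% of males per generation),
#' a fission threshold of 150 individuals, an intermediate variance in
#' group reproductive success (sigma^2 = 0.1), lineal fission and no violence.
#'
#' @param ... named parameter overrides; unknown names are an error.
#'
#' @details Parameters (units in brackets):
#' \describe{
#'   \item{n_total}{founder count; must equal `village_init_size * n_villages`.}
#'   \item{n_villages}{number of villages.}
#'   \item{village_init_size}{initial village size N0 \[individuals\].}
#'   \item{group_init_size}{initial descent-group size K \[individuals\];
#'     `3 * K` must equal `village_init_size`.}
#'   \item{growth_rate}{village growth rate r \[per generation\]; village size
#'     at generation t is `round(N0 * exp(r * t))`.}
#'   \item{sigma2}{dispersion of the normal distribution from which group
#'     relative fitnesses are drawn (used as the standard deviation of the
#'     draws, both at initialisation and at fission); the scenario grid uses
#'     0, 0.05, 0.1 and 0.2. Zero means every group shares the baseline
#'     growth rate.}
#'   \item{female_mig_rate, male_mig_rate}{per-individual migration
#'     probabilities per generation under patrilocal residence.}
#'   \item{fission_threshold}{N_max \[individuals\]: a group splits when twice
#'     its male count exceeds this.}
#'   \item{fission_cooldown}{minimum number of generations between two
#'     fissions of the same group lineage.}
#'   \item{fission_type}{`"lineal"` (split along paternal clades) or
#'     `"random"`.}
#'   \item{post_fission_migration}{if `TRUE`, the smaller daughter group
#'     relocates to another village after each fission.}
#'   \item{violence_rate}{e: fraction of males killed per generation
#'     (0 disables violent competition).}
#'   \item{polygyny, polygyny_p}{Kipsigis-like polygyny switch and the
#'     geometric parameter p of the per-male mating weights.}
#'   \item{mu_Y, mu_mt}{mutation rates \[mutations/site/generation\].}
#'   \item{len_Y, len_mt}{marker lengths \[bp\].}
#'   \item{sample_per_village, sample_interval}{diversity sampling design:
#'     individuals sampled per village, and the generation interval.}
#'   \item{generation_time}{\[years\], used only when exporting trees with
#'     branch lengths in years.}
#'   \item{seed}{optional integer seed recorded with the configuration.}
#' }
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [load_config()], [scenario_preset()]
#' @export
#' @examples
#' cfg <- sim_config()
#' cfg$fission_threshold
#' cfg2 <- sim_config(sigma2 = 0.2, violence_rate = 0.15)
sim_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  cfg <- config_defaults()
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (k in nm) cfg[[k]] <- overrides[[k]]
  }
  cfg <- coerce_config_types(cfg)
  validate_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

config_defaults <- function() {
  list(
    n_total = 1500L,
    n_villages = 5L,
    village_init_size = 300L,
    group_init_size = 100L,
    growth_rate = 0.01,
    sigma2 = 0.1,
    female_mig_rate = 0.1,
    male_mig_rate = 0,
    fission_threshold = 150L,
    fission_cooldown = 3L,
    fission_type = "lineal",
    post_fission_migration = FALSE,
    violence_rate = 0,
    polygyny = FALSE,
    polygyny_p = 0.5,
    mu_Y = 2.5e-8,
    mu_mt = 5.5e-7,
    len_Y = 1e6,
    len_mt = 1e4,
    sample_per_village = 20L,
    sample_interval = 20L,
    generation_time = 25,
    seed = NA_integer_
  )
}

coerce_config_types <- function(cfg) {
  int_keys <- c("n_total", "n_villages", "village_init_size",
                "group_init_size", "fission_threshold", "fission_cooldown",
                "sample_per_village", "sample_interval")
  for (k in int_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
      stop("configuration key '", k, "' must be a single integer", call. = FALSE)
    }
    cfg[[k]] <- as.integer(v)
  }
  num_keys <- c("growth_rate", "sigma2", "female_mig_rate", "male_mig_rate",
                "violence_rate", "polygyny_p", "mu_Y", "mu_mt", "len_Y",
                "len_mt", "generation_time")
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("configuration key '", k, "' must be a single number", call. = FALSE)
    }
    cfg[[k]] <- as.numeric(v)
  }
  for (k in c("post_fission_migration", "polygyny")) {
    v <- cfg[[k]]
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      stop("configuration key '", k, "' must be TRUE or FALSE", call. = FALSE)
    }
  }
  if (!is.na(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(key, why) {
    stop("invalid value for configuration key '", key, "': ", why,
         call. = FALSE)
  }
  pos_int <- c("n_total", "n_villages", "village_init_size",
               "group_init_size", "fission_threshold")
  for (k in pos_int) if (cfg[[k]] <= 0L) fail(k, "must be a positive integer")
  if (cfg$fission_cooldown < 0L) fail("fission_cooldown", "must be >= 0")
  rates <- c("female_mig_rate", "male_mig_rate", "violence_rate")
  for (k in rates) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1) fail(k, "rates must lie in [0, 1]")
  }
  if (cfg$sigma2 < 0) fail("sigma2", "a variance cannot be negative")
  if (cfg$polygyny_p <= 0 || cfg$polygyny_p > 1) {
    fail("polygyny_p", "must lie in (0, 1]")
  }
  for (k in c("mu_Y", "mu_mt")) if (cfg[[k]] <= 0) fail(k, "must be > 0")
  for (k in c("len_Y", "len_mt")) {
    if (cfg[[k]] < 1 || cfg[[k]] != round(cfg[[k]])) {
      fail(k, "must be a positive integer number of sites")
    }
  }
  if (!cfg$fission_type %in% c("random", "lineal")) {
    fail("fission_type", "must be 'random' or 'lineal'")
  }
  if (cfg$village_init_size * cfg$n_villages != cfg$n_total) {
    fail("n_total", "must equal village_init_size * n_villages")
  }
  if (cfg$group_init_size * 3L != cfg$village_init_size) {
    fail("group_init_size", "three initial groups must tile a village exactly")
  }
  if (cfg$sample_per_village < 2L) {
    fail("sample_per_village", "at least 2 individuals are needed for pi")
  }
  if (cfg$sample_interval < 1L) fail("sample_interval", "must be >= 1")
  if (cfg$growth_rate < 0) fail("growth_rate", "must be >= 0")
  if (cfg$generation_time <= 0) fail("generation_time", "must be > 0")
  invisible(cfg)
}

#' Load a configuration from a file or a named list
#'
#' Reads a flat key-value YAML file (or takes a named list of overrides),
#' fills in defaults and validates the result. Unknown keys are rejected with
#' an error naming the offending key.
#'
#' @param source path to a YAML file, or a named list of overrides.
#' @return a [sim_config()] object.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("sigma2: 0.2\nviolence_rate: 0.15", f)
#' cfg <- load_config(f)
#' cfg$sigma2
load_config <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) {
      stop("configuration file not found: ", source, call. = FALSE)
    }
    vals <- yaml::read_yaml(source)
    if (is.null(vals)) vals <- list()
  } else if (is.list(source)) {
    vals <- source
  } else {
    stop("'source' must be a file path or a named list", call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' Serialize a configuration to a YAML file
#'
#' Round-tripping through [write_config()] then [load_config()] reproduces the
#' configuration exactly.
#'
#' @param config a [sim_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  if (is.na(vals$seed)) vals$seed <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
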