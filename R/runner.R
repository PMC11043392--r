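# Seeded replicate orchestration and file outputs.

# Deterministic per-replicate seeds from a base seed: the i-th derived seed
# depends only on (base_seed, i), so results do not depend on how replicates
# are batched.
derive_seeds <- function(base_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(base_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a scenario over replicates
#'
#' Runs `n_replicates` independent replicates of a scenario preset (each with
#' a deterministically derived seed), summarises the diversity series across
#' replicates and pools the descent-group demography. With `out_dir`,
#' per-replicate diversity, pooled event logs, per-generation summary tables
#' and a reproducibility manifest are written as CSV/JSON.
#'
#' @param name scenario preset name (see [preset_names()]).
#' @param n_replicates number of replicates.
#' @param seed base integer seed.
#' @param overrides named list of configuration overrides (e.g.
#'   `list(male_mig_rate = 0.02)` or `list(post_fission_migration = TRUE)`).
#' @param out_dir optional output directory.
#' @param B bootstrap resamples for the confidence intervals.
#' @param track_group_pi forwarded to [simulate_replicate()].
#' @param keep_runs if TRUE the individual `patriseg_run` objects are
#'   returned (memory permitting); the pooled logs are always returned.
#' @return a `patriseg_scenario` list: `manifest`, `summary`
#'   (a [summarize_replicates()] result), `diversity` (all replicates),
#'   `demography` (pooled), `events`, `failures`, and optionally `runs`.
#' @export
#' @examples
#' \donttest{
#' res <- run_scenario("2a", n_replicates = 4, seed = 42)
#' res$summary$male_reduction_factor
#' }
run_scenario <- function(name, n_replicates, seed, overrides = list(),
                         out_dir = NULL, B = 10000L,
                         track_group_pi = FALSE, keep_runs = FALSE) {
  stopifnot(n_replicates >= 1L)
  seeds <- derive_seeds(seed, n_replicates)
  preset <- scenario_preset(name, overrides = overrides)
  t0 <- proc.time()[["elapsed"]]
  runs <- vector("list", n_replicates)
  failures <- character(0)
  for (i in seq_len(n_replicates)) {
    runs[[i]] <- tryCatch(
      simulate_replicate(preset, seed = seeds[i],
                         track_group_pi = track_group_pi),
      error = function(e) {
        failures <<- c(failures, sprintf("replicate %d (seed %d): %s", i,
                                         seeds[i], conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(runs, is.null, logical(1L))
  if (!any(ok)) stop("all replicates failed: ", failures[1L], call. = FALSE)
  if (length(failures)) {
    warning(length(failures), " replicate(s) failed and were excluded")
  }
  runs <- runs[ok]
  diversity <- do.call(rbind, lapply(seq_along(runs), function(i) {
    d <- runs[[i]]$diversity
    d$replicate <- which(ok)[i]
    d
  }))
  events <- do.call(rbind, lapply(seq_along(runs), function(i) {
    e <- runs[[i]]$events
    e$replicate <- rep(which(ok)[i], nrow(e))
    e
  }))
  summary <- if (sum(ok) >= 2L) {
    summarize_replicates(diversity, B = B,
                         n_males_t0 = preset$config$n_total / 2)
  } else NULL
  demography <- pool_group_demography(runs)
  elapsed <- proc.time()[["elapsed"]] - t0
  manifest <- list(
    scenario = name,
    config = unclass(preset$config),
    overrides = overrides,
    total_generations = preset$total_generations,
    n_replicates = n_replicates,
    n_completed = sum(ok),
    base_seed = as.integer(seed),
    replicate_seeds = seeds,
    package_version = as.character(utils::packageVersion("patriseg")),
    elapsed_seconds = round(elapsed, 2),
    seconds_per_replicate = round(elapsed / n_replicates, 3))
  out <- list(manifest = manifest, summary = summary, diversity = diversity,
              events = events, demography = demography, failures = failures)
  if (keep_runs) out$runs <- runs
  class(out) <- "patriseg_scenario"
  if (!is.null(out_dir)) write_scenario_outputs(out, out_dir)
  out
}

#' @export
print.patriseg_scenario <- function(x, ...) {
  cat("<patriseg_scenario>", x$manifest$scenario, "-",
      x$manifest$n_completed, "replicates\n")
  if (!is.null(x$summary)) {
    cat(sprintf("  reduction factor %.2f, max ratio %.2f\n",
                x$summary$male_reduction_factor, x$summary$max_ratio))
  }
  invisible(x)
}

write_scenario_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pfx <- file.path(out_dir, paste0("scenario_", res$manifest$scenario))
  utils::write.csv(res$diversity, paste0(pfx, "_diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(res$events, paste0(pfx, "_events.csv"), row.names = FALSE)
  if (!is.null(res$summary)) {
    utils::write.csv(res$summary$per_generation,
                     paste0(pfx, "_summary.csv"), row.names = FALSE)
    tab <- data.frame(
      scenario = res$manifest$scenario,
      n_replicates = res$manifest$n_completed,
      reduction_factor = res$summary$male_reduction_factor,
      reduction_lo = res$summary$male_reduction_factor_ci[1L],
      reduction_hi = res$summary$male_reduction_factor_ci[2L],
      max_ratio = res$summary$max_ratio)
    utils::write.csv(tab, paste0(pfx, "_table.csv"), row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, paste0(pfx, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
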