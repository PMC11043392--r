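# pi-based effective sizes, replicate summaries with BCa bootstrap CIs, and
# descent-group demography for calibration.

#' Effective population size from nucleotide diversity
#'
#' For a haploid uniparental marker at mutation-drift equilibrium,
#' `Ne = pi / (2 * mu)`.
#'
#' @param pi nucleotide diversity (per site); vectorised.
#' @param mu mutation rate per site per generation (> 0).
#' @return effective population size(s).
#' @export
#' @examples
#' ne_from_pi(3.75e-5, 2.5e-8)   # 750
#' ne_from_pi(1.1e-4, 5.5e-7)    # 100
ne_from_pi <- function(pi, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0) {
    stop("mu must be a single positive number", call. = FALSE)
  }
  if (any(pi < 0, na.rm = TRUE)) stop("pi cannot be negative", call. = FALSE)
  pi / (2 * mu)
}

# BCa confidence interval for a statistic over replicates, via the boot
# package (jackknife acceleration). Degenerate samples (all values equal, or
# a failing BCa adjustment) fall back to the percentile interval.
bca_ci <- function(values, statistic = mean, B = 10000L, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) return(c(NA_real_, NA_real_))
  est <- statistic(values)
  if (n == 1L || length(unique(values)) == 1L) return(c(est, est))
  bt <- boot::boot(values, function(d, i) statistic(d[i]), R = B)
  ci <- tryCatch(boot::boot.ci(bt, conf = conf, type = "bca"),
                 error = function(e) NULL)
  if (!is.null(ci) && !is.null(ci$bca) && !anyNA(ci$bca[4:5])) {
    return(as.numeric(ci$bca[4:5]))
  }
  as.numeric(stats::quantile(bt$t, c((1 - conf) / 2, (1 + conf) / 2),
                             na.rm = TRUE))
}

# BCa CI for the ratio mean(num)/mean(den) over paired replicate values.
bca_ci_ratio <- function(num, den, B = 10000L, conf = 0.95) {
  ok <- !is.na(num) & !is.na(den)
  num <- num[ok]
  den <- den[ok]
  n <- length(num)
  if (n == 0L || mean(den) == 0) return(c(NA_real_, NA_real_))
  if (n == 1L) return(rep(num / den, 2L))
  d <- cbind(num, den)
  stat <- function(d, i) mean(d[i, 1L]) / mean(d[i, 2L])
  if (length(unique(num)) == 1L && length(unique(den)) == 1L) {
    return(rep(stat(d, seq_len(n)), 2L))
  }
  bt <- boot::boot(d, stat, R = B)
  ci <- tryCatch(boot::boot.ci(bt, conf = conf, type = "bca"),
                 error = function(e) NULL)
  if (!is.null(ci) && !is.null(ci$bca) && !anyNA(ci$bca[4:5])) {
    return(as.numeric(ci$bca[4:5]))
  }
  as.numeric(stats::quantile(bt$t, c((1 - conf) / 2, (1 + conf) / 2),
                             na.rm = TRUE))
}

#' Summarise diversity across replicates
#'
#' Per-generation means of the male and female effective sizes with 95% BCa
#' bootstrap confidence intervals over replicates, the female-to-male ratio
#' of mean effective sizes, the male reduction factor (initial male count
#' divided by the mean male Ne at the final generation) and the maximum
#' female-to-male ratio over the sampling grid.
#'
#' @param diversity data frame with columns `replicate`, `generation`,
#'   `scope`, `ne_Y`, `ne_mt` (e.g. the `diversity` element of
#'   [run_scenario()]'s result), or a list of `patriseg_run` objects.
#' @param scope which diversity scope to summarise.
#' @param B bootstrap resamples.
#' @param n_males_t0 initial male count used in the reduction factor.
#' @param reduction_at generation at which the reduction factor is assessed
#'   (defaults to the last sampled generation).
#' @return a `replicate_summary`: list with `per_generation` (data frame),
#'   `male_reduction_factor` (with CI), `max_ratio`, `n_replicates`.
#' @export
summarize_replicates <- function(diversity, scope = "within_village_mean",
                                 B = 10000L, n_males_t0 = 750,
                                 reduction_at = NULL) {
  if (is.list(diversity) && !is.data.frame(diversity)) {
    diversity <- do.call(rbind, lapply(seq_along(diversity), function(i) {
      d <- diversity[[i]]$diversity
      d$replicate <- i
      d
    }))
  }
  stopifnot(is.data.frame(diversity),
            all(c("replicate", "generation", "scope", "ne_Y", "ne_mt") %in%
                  names(diversity)))
  d <- diversity[diversity$scope == scope, , drop = FALSE]
  if (!nrow(d)) stop("no diversity rows for scope '", scope, "'",
                     call. = FALSE)
  n_rep <- length(unique(d$replicate))
  if (n_rep < 2L) stop("at least two replicates are required", call. = FALSE)
  gens <- sort(unique(d$generation))
  per_gen <- do.call(rbind, lapply(gens, function(g) {
    dg <- d[d$generation == g, , drop = FALSE]
    ciY <- bca_ci(dg$ne_Y, B = B)
    cimt <- bca_ci(dg$ne_mt, B = B)
    cir <- bca_ci_ratio(dg$ne_mt, dg$ne_Y, B = B)
    data.frame(generation = g, n = nrow(dg),
               ne_Y_mean = mean(dg$ne_Y, na.rm = TRUE),
               ne_Y_lo = ciY[1L], ne_Y_hi = ciY[2L],
               ne_mt_mean = mean(dg$ne_mt, na.rm = TRUE),
               ne_mt_lo = cimt[1L], ne_mt_hi = cimt[2L],
               ratio = mean(dg$ne_mt, na.rm = TRUE) /
                 mean(dg$ne_Y, na.rm = TRUE),
               ratio_lo = cir[1L], ratio_hi = cir[2L])
  }))
  if (is.null(reduction_at)) reduction_at <- max(gens)
  fin <- per_gen[per_gen$generation == reduction_at, , drop = FALSE]
  rf <- n_males_t0 / fin$ne_Y_mean
  rf_ci <- sort(n_males_t0 / c(fin$ne_Y_hi, fin$ne_Y_lo))
  out <- list(per_generation = per_gen,
              male_reduction_factor = rf,
              male_reduction_factor_ci = rf_ci,
              reduction_at = reduction_at,
              max_ratio = max(per_gen$ratio, na.rm = TRUE),
              n_replicates = n_rep,
              scope = scope,
              n_males_t0 = n_males_t0)
  class(out) <- "replicate_summary"
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("<replicate_summary>", x$n_replicates, "replicates,", x$scope, "\n")
  cat(sprintf("  male Ne reduction factor at generation %d: %.2f [%.2f, %.2f]\n",
              x$reduction_at, x$male_reduction_factor,
              x$male_reduction_factor_ci[1L], x$male_reduction_factor_ci[2L]))
  cat(sprintf("  max female-to-male Ne ratio: %.2f\n", x$max_ratio))
  print(utils::head(x$per_generation, 12L), row.names = FALSE)
  invisible(x)
}

#' Reduction factor at an arbitrary generation
#'
#' @param summary a `replicate_summary`.
#' @param at generation of assessment.
#' @param n_males_t0 initial male count.
#' @return the reduction factor `n_males_t0 / mean Ne_Y(at)`.
#' @export
reduction_factor <- function(summary, at, n_males_t0 = summary$n_males_t0) {
  pg <- summary$per_generation
  row <- pg[pg$generation == at, , drop = FALSE]
  if (!nrow(row)) stop("generation ", at, " was not sampled", call. = FALSE)
  n_males_t0 / row$ne_Y_mean
}

#' Descent-group demography from the event and size logs
#'
#' Growth rates are computed per group per generation from the recorded size
#' trajectories, between fission events (a fission replaces the parent by
#' two fresh daughter ids, so trajectories never straddle a split). Each
#' group's growth rate is the mean of its per-generation rates over its
#' recorded lifetime; "successful" groups are those with a positive mean
#' growth rate, and `growth_rate_successful` averages the rates of those
#' groups. The extinction rate is the number of extinction events divided by
#' the number of group-generations at risk.
#'
#' @param group_sizes data frame (generation, group, size) as produced by a
#'   run, or a `patriseg_run`.
#' @param events event data frame (uses rows with `type == "extinction"` and
#'   `type == "fission"`).
#' @return a `group_demography` list: `growth_rate_successful`,
#'   `extinction_rate` (per group per generation), `n_extinctions`,
#'   `n_fissions`, `group_generations`, `extinctions_per_100`,
#'   `fissions_per_100`, `group_growth_rates` (per-group mean rates) and
#'   `growth_rates` (all pooled group-generation rates).
#' @export
group_demography <- function(group_sizes, events = NULL) {
  if (inherits(group_sizes, "patriseg_run")) {
    events <- group_sizes$events
    group_sizes <- group_sizes$group_sizes
  }
  if (is.null(events)) events <- data.frame(type = character(0))
  if (!nrow(group_sizes)) {
    warning("empty group-size log: returning zero rates")
    return(empty_group_demography())
  }
  gs <- group_sizes[order(group_sizes$group, group_sizes$generation), ,
                    drop = FALSE]
  same <- c(FALSE, gs$group[-1L] == gs$group[-nrow(gs)])
  consec <- c(FALSE, diff(gs$generation) == 1L) & same
  prev_size <- c(NA_real_, gs$size[-nrow(gs)])
  rates <- (gs$size[consec] - prev_size[consec]) / prev_size[consec]
  per_group <- as.numeric(tapply(rates, gs$group[consec], mean))
  T_final <- max(gs$generation)
  span <- T_final - min(gs$generation)
  at_risk <- sum(gs$generation < T_final)
  n_ext <- sum(events$type == "extinction")
  n_fis <- sum(events$type == "fission")
  structure(list(
    growth_rate_successful = if (any(per_group > 0)) {
      mean(per_group[per_group > 0])
    } else NA_real_,
    extinction_rate = if (at_risk > 0L) n_ext / at_risk else 0,
    n_extinctions = n_ext,
    n_fissions = n_fis,
    group_generations = at_risk,
    extinctions_per_100 = if (span > 0) n_ext / span * 100 else 0,
    fissions_per_100 = if (span > 0) n_fis / span * 100 else 0,
    group_growth_rates = per_group,
    growth_rates = rates), class = "group_demography")
}

#' @export
print.group_demography <- function(x, ...) {
  cat("<group_demography>\n")
  cat(sprintf("  mean growth rate of successful groups: %.3f per generation\n",
              x$growth_rate_successful))
  cat(sprintf("  extinction rate: %.2f%% per group per generation\n",
              100 * x$extinction_rate))
  cat(sprintf("  %d fissions, %d extinctions over %d group-generations\n",
              x$n_fissions, x$n_extinctions, x$group_generations))
  invisible(x)
}

empty_group_demography <- function() {
  structure(list(growth_rate_successful = NA_real_,
                 extinction_rate = 0, n_extinctions = 0L,
                 n_fissions = 0L, group_generations = 0L,
                 extinctions_per_100 = 0, fissions_per_100 = 0,
                 group_growth_rates = numeric(0),
                 growth_rates = numeric(0)),
            class = "group_demography")
}

#' Pool group demography across replicates
#'
#' Pools all groups and group-generations of a list of runs before computing
#' the mean successful-group growth rate and the extinction rate.
#'
#' @param runs list of `patriseg_run` objects.
#' @return a `group_demography` list.
#' @export
pool_group_demography <- function(runs) {
  per_group <- unlist(lapply(runs,
                             function(r) r$demography$group_growth_rates))
  rates <- unlist(lapply(runs, function(r) r$demography$growth_rates))
  n_ext <- sum(vapply(runs, function(r) r$demography$n_extinctions,
                      numeric(1L)))
  n_fis <- sum(vapply(runs, function(r) r$demography$n_fissions,
                      numeric(1L)))
  at_risk <- sum(vapply(runs, function(r) r$demography$group_generations,
                        numeric(1L)))
  span <- sum(vapply(runs, function(r) {
    if (nrow(r$group_sizes)) diff(range(r$group_sizes$generation)) else 0
  }, numeric(1L)))
  structure(list(
    growth_rate_successful = if (any(per_group > 0)) {
      mean(per_group[per_group > 0])
    } else NA_real_,
    extinction_rate = if (at_risk > 0) n_ext / at_risk else 0,
    n_extinctions = n_ext, n_fissions = n_fis,
    group_generations = at_risk,
    extinctions_per_100 = if (span > 0) n_ext / span * 100 else 0,
    fissions_per_100 = if (span > 0) n_fis / span * 100 else 0,
    group_growth_rates = per_group,
    growth_rates = rates), class = "group_demography")
}
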