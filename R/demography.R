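# Stochastic demographic operators acting on the population state.
#
# The population state `pop` is a list with per-individual vectors `id`
# (pedigree ids), `sex` (1 = male, 2 = female), `village`, `group`
# (NA in bilateral phases), a `groups` registry data frame
# (id, village, fitness, last_fission) and bookkeeping accumulators.

#' Individual migration between villages
#'
#' Each female independently moves with probability `m_f` and each male with
#' probability `m_m`; the destination village is uniform among the other
#' villages. In patrilineal phases a migrant joins a uniformly chosen descent
#' group of the destination village.
#'
#' @param pop population state.
#' @param m_f,m_m per-individual migration rates in \[0, 1\].
#' @return the updated population state.
#' @export
migrate_individuals <- function(pop, m_f, m_m) {
  stopifnot(m_f >= 0, m_f <= 1, m_m >= 0, m_m <= 1)
  n <- length(pop$id)
  if (n == 0L || (m_f == 0 && m_m == 0)) return(pop)
  prob <- ifelse(pop$sex == 1L, m_m, m_f)
  mig <- which(stats::runif(n) < prob)
  if (!length(mig)) return(pop)
  V <- pop$n_villages
  # uniform choice among the V-1 other villages
  shift <- sample.int(V - 1L, length(mig), replace = TRUE)
  dest <- (pop$village[mig] - 1L + shift) %% V + 1L
  pop$village[mig] <- dest
  if (!all(is.na(pop$group))) {
    for (v in unique(dest)) {
      gv <- pop$groups$id[pop$groups$village == v]
      take <- mig[dest == v]
      if (!length(gv)) {
        stop("no descent group available in destination village ", v,
             call. = FALSE)
      }
      pop$group[take] <- gv[sample.int(length(gv), length(take),
                                       replace = TRUE)]
    }
  }
  pop
}

#' Form mating pairs within a village
#'
#' In patrilineal phases couples practice descent-group exogamy: males and
#' females from different groups are matched at random; individuals that can
#' only be matched within their own group are paired within-group, so the
#' number of singles is minimised. Bilateral phases pair uniformly at random.
#' Each individual appears in at most one couple (monogamy).
#'
#' @param males,females indices (into the population vectors) of the
#'   village's males and females.
#' @param group per-individual group ids (full population vector), or NULL
#'   for bilateral pairing.
#' @return list with `male` and `female` index vectors (the pairs) and
#'   `singles`, the indices left unpaired.
#' @export
form_mating_pairs <- function(males, females, group = NULL) {
  nm <- length(males)
  nf <- length(females)
  if (nm == 0L || nf == 0L) {
    return(list(male = integer(0), female = integer(0),
                singles = c(males, females)))
  }
  if (is.null(group)) {
    k <- min(nm, nf)
    pm <- if (nm > 1L) sample(males) else males
    pf <- if (nf > 1L) sample(females) else females
    return(list(male = pm[seq_len(k)], female = pf[seq_len(k)],
                singles = c(pm[-seq_len(k)], pf[-seq_len(k)])))
  }
  pm <- if (nm > 1L) sample(males) else males
  pf <- if (nf > 1L) sample(females) else females
  out_m <- integer(0)
  out_f <- integer(0)
  repeat {
    k <- min(length(pm), length(pf))
    if (k == 0L) break
    gm <- group[pm]
    gf <- group[pf]
    if (length(unique(c(gm, gf))) == 1L) break  # only same-group singles left
    ok <- gm[seq_len(k)] != gf[seq_len(k)]
    if (any(ok)) {
      take <- which(ok)
      out_m <- c(out_m, pm[take])
      out_f <- c(out_f, pf[take])
      pm <- pm[-take]
      pf <- pf[-take]
    } else {
      # a stalled shuffle: force one cross-group pair to guarantee progress
      fi <- which(gf != gm[1L])[1L]
      if (is.na(fi)) {  # male 1 matches every female's group; find another male
        mi <- which(gm != gf[1L])[1L]
        out_m <- c(out_m, pm[mi])
        out_f <- c(out_f, pf[1L])
        pm <- pm[-mi]
        pf <- pf[-1L]
      } else {
        out_m <- c(out_m, pm[1L])
        out_f <- c(out_f, pf[fi])
        pm <- pm[-1L]
        pf <- pf[-fi]
      }
    }
    if (length(pm) > 1L) pm <- sample(pm)
    if (length(pf) > 1L) pf <- sample(pf)
  }
  # within-group fallback
  k <- min(length(pm), length(pf))
  if (k > 0L) {
    out_m <- c(out_m, pm[seq_len(k)])
    out_f <- c(out_f, pf[seq_len(k)])
    pm <- pm[-seq_len(k)]
    pf <- pf[-seq_len(k)]
  }
  list(male = out_m, female = out_f, singles = c(pm, pf))
}

#' Assign offspring to mating pairs under group-weighted reproduction
#'
#' Each child independently draws a father descent group j with probability
#' proportional to `2 * M_j * exp(r_j)` (M_j the male count of group j in the
#' village, r_j its relative fitness), then a uniformly chosen couple whose
#' male belongs to that group; the child inherits the father's group. Groups
#' without any couple are excluded from the draw (the redraw rule). Sexes are
#' assigned alternately male, female, ... over a randomly permuted birth
#' order, keeping the village sex ratio balanced to within one.
#'
#' @param pairs pair list from [form_mating_pairs()].
#' @param pair_group group id of each pair's male (NULL for bilateral
#'   reproduction, where couples are drawn uniformly).
#' @param male_counts named vector: standing male count per group id.
#' @param fitness named vector: relative fitness per group id.
#' @param n_children number of children to produce.
#' @return list of vectors `father`, `mother` (indices into the population
#'   vectors), `group` (NA for bilateral) and `sex`.
#' @export
assign_offspring <- function(pairs, pair_group = NULL, male_counts = NULL,
                             fitness = NULL, n_children) {
  stopifnot(n_children >= 0)
  np <- length(pairs$male)
  if (n_children == 0L) {
    return(list(father = integer(0), mother = integer(0),
                group = integer(0), sex = integer(0)))
  }
  if (np == 0L) stop("cannot produce children without any couple",
                     call. = FALSE)
  if (is.null(pair_group)) {
    pick <- sample.int(np, n_children, replace = TRUE)
    group <- rep(NA_integer_, n_children)
  } else {
    gids <- unique(pair_group)
    w <- 2 * male_counts[as.character(gids)] *
      exp(fitness[as.character(gids)])
    counts <- as.vector(stats::rmultinom(1L, n_children, prob = w))
    pick <- integer(n_children)
    group <- integer(n_children)
    pos <- 0L
    for (i in seq_along(gids)) {
      ci <- counts[i]
      if (ci == 0L) next
      pg <- which(pair_group == gids[i])
      pick[pos + seq_len(ci)] <- pg[sample.int(length(pg), ci,
                                               replace = TRUE)]
      group[pos + seq_len(ci)] <- gids[i]
      pos <- pos + ci
    }
    ord <- sample.int(n_children)   # random birth order
    pick <- pick[ord]
    group <- group[ord]
  }
  sex <- rep_len(c(1L, 2L), n_children)
  list(father = pairs$male[pick], mother = pairs$female[pick],
       group = group, sex = sex)
}

#' Polygynous reproduction (Kipsigis-like)
#'
#' For each female a male partner is drawn with replacement with probability
#' `X_j / sum(X)`, where the per-male weights X are drawn from a geometric
#' distribution with parameter `p` (support 1, 2, ..., so every male has
#' positive weight). Children are then assigned uniformly to the resulting
#' couples; some males have several wives.
#'
#' @param males,females indices of the village's males and females.
#' @param n_children number of children to produce.
#' @param p geometric parameter of the mating weights.
#' @param weights optional fixed mating weights (one per male), overriding
#'   the geometric draws.
#' @return list as in [assign_offspring()] (group is NA).
#' @export
assign_offspring_polygynous <- function(males, females, n_children, p = 0.5,
                                        weights = NULL) {
  nm <- length(males)
  nf <- length(females)
  if (nm == 0L || nf == 0L) stop("cannot produce children without both sexes",
                                 call. = FALSE)
  X <- if (is.null(weights)) stats::rgeom(nm, prob = p) + 1 else weights
  stopifnot(length(X) == nm, all(X > 0))
  husband <- males[sample.int(nm, nf, replace = TRUE, prob = X)]
  pick <- sample.int(nf, n_children, replace = TRUE)
  sex <- rep_len(c(1L, 2L), n_children)
  list(father = husband[pick], mother = females[pick],
       group = rep(NA_integer_, n_children), sex = sex)
}

# Expected kill counts per group under the size-dependent violence model.
# Returns the Poisson rates lambda_j = rho * (sum_{i != j} N_i) * sqrt(N_j)
# with rho solved so that sum(lambda) = e * sum(N).
violence_rates <- function(male_counts, e) {
  total <- sum(male_counts)
  base <- (total - male_counts) * sqrt(male_counts)
  denom <- sum(base)
  if (denom == 0) return(rep(0, length(male_counts)))
  rho <- e * total / denom
  rho * base
}

#' Violent inter-group competition
#'
#' Kills a fraction `e` of the cohort's males in expectation. Per group j the
#' kill count is Poisson with rate `rho * (sum_{i != j} N_i) * sqrt(N_j)`
#' (N = group male counts pooled over all villages), rho being rescaled each
#' generation so the expected total equals `e` times the male population;
#' males of small groups therefore die at higher per-capita rates. Draws are
#' truncated at the group male count. With fewer than two groups the
#' size-dependent rates vanish, and a uniform kill of `round(e * males)` is
#' applied instead (logged as a fallback).
#'
#' @param sex,group cohort vectors (1 = male; group NA allowed).
#' @param e fraction of males killed per generation, in (0, 1\].
#' @return list with `killed` (cohort indices to remove), `kills_per_group`
#'   (named vector) and `fallback` flag.
#' @export
apply_violence <- function(sex, group, e) {
  stopifnot(e > 0, e <= 1)
  males <- which(sex == 1L)
  if (!length(males)) {
    return(list(killed = integer(0), kills_per_group = integer(0),
                fallback = FALSE))
  }
  mg <- group[males]
  gids <- unique(mg[!is.na(mg)])
  if (length(gids) < 2L) {
    n_kill <- round(e * length(males))
    killed <- if (n_kill > 0L) males[sample.int(length(males), n_kill)]
              else integer(0)
    kp <- stats::setNames(length(killed),
                          if (length(gids)) as.character(gids) else "none")
    return(list(killed = killed, kills_per_group = kp, fallback = TRUE))
  }
  N <- vapply(gids, function(g) sum(mg == g), integer(1L))
  lambda <- violence_rates(N, e)
  D <- pmin(stats::rpois(length(lambda), lambda), N)
  killed <- integer(0)
  for (i in seq_along(gids)) {
    if (D[i] == 0L) next
    cand <- males[mg == gids[i]]
    killed <- c(killed, cand[sample.int(length(cand), D[i])])
  }
  list(killed = killed,
       kills_per_group = stats::setNames(D, as.character(gids)),
       fallback = FALSE)
}

#' Remove empty descent groups
#'
#' A descent group is extinct when its membership reaches zero; extinct
#' groups are dropped from the registry and an extinction event is logged.
#'
#' @param pop population state.
#' @return updated population state.
#' @export
remove_extinct_groups <- function(pop) {
  if (!nrow(pop$groups)) return(pop)
  alive <- pop$groups$id %in% unique(pop$group[!is.na(pop$group)])
  if (all(alive)) return(pop)
  dead <- pop$groups[!alive, , drop = FALSE]
  for (i in seq_len(nrow(dead))) {
    pop$events[[length(pop$events) + 1L]] <- list(
      generation = pop$generation, type = "extinction",
      village = dead$village[i], group = dead$id[i])
  }
  pop$groups <- pop$groups[alive, , drop = FALSE]
  pop
}
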