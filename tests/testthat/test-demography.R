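test_that("migration respects rates, destinations and group adoption", {
  set.seed(1)
  # 4 villages x 10 individuals, alternating sexes, one group per village
  pop <- make_test_pop(sex = rep(c(1, 2), 20),
                       village = rep(1:4, each = 10),
                       group = rep(1:4, each = 10))
  same <- migrate_individuals(pop, 0, 0)
  expect_identical(same$village, pop$village)

  moved <- migrate_individuals(pop, 1, 0)
  females <- pop$sex == 2L
  expect_true(all(moved$village[females] != pop$village[females]))
  expect_identical(moved$village[!females], pop$village[!females])
  # migrants adopt a group of the destination village
  for (i in which(females)) {
    g <- moved$group[i]
    expect_equal(moved$groups$village[moved$groups$id == g],
                 moved$village[i])
  }
  expect_error(migrate_individuals(pop, 2, 0))
})

test_that("expected migrant counts follow the sex-specific rates", {
  set.seed(42)
  pop <- make_test_pop(sex = rep(c(1, 2), 500), village = rep(1:5, each = 200))
  n_mig <- replicate(40, {
    m <- migrate_individuals(pop, 0.1, 0.02)
    c(f = sum(m$village[pop$sex == 2L] != pop$village[pop$sex == 2L]),
      m = sum(m$village[pop$sex == 1L] != pop$village[pop$sex == 1L]))
  })
  expect_equal(mean(n_mig["f", ]) / 500, 0.1, tolerance = 0.15)
  expect_equal(mean(n_mig["m", ]) / 500, 0.02, tolerance = 0.3)
  # multilocal-style symmetric rates move both sexes equally on average
  sym <- replicate(40, {
    m <- migrate_individuals(pop, 0.05, 0.05)
    sum(m$village != pop$village)
  })
  expect_equal(mean(sym) / 1000, 0.05, tolerance = 0.15)
})

test_that("exogamous pairing avoids within-group couples until forced", {
  # two groups with balanced sexes: every pairing must be fully cross-group
  pop <- make_test_pop(sex = c(1, 1, 2, 2, 1, 1, 2, 2),
                       village = rep(1L, 8),
                       group = c(1, 1, 1, 1, 2, 2, 2, 2))
  for (s in 1:25) {
    set.seed(s)
    pr <- form_mating_pairs(which(pop$sex == 1L), which(pop$sex == 2L),
                            group = pop$group)
    expect_length(pr$male, 4L)
    expect_true(all(pop$group[pr$male] != pop$group[pr$female]))
  }
  # a single group still pairs everyone (within-group fallback)
  pop1 <- make_test_pop(sex = c(1, 1, 2, 2), village = rep(1L, 4),
                        group = rep(1L, 4))
  pr <- form_mating_pairs(c(1, 2), c(3, 4), group = pop1$group)
  expect_length(pr$male, 2L)
  # a village without females yields an empty pool
  pr0 <- form_mating_pairs(c(1, 2), integer(0), group = pop1$group)
  expect_length(pr0$male, 0L)
  expect_setequal(pr0$singles, c(1, 2))
})

test_that("unbalanced groups still minimise the number of singles", {
  # 3 males of group 1, 1 male of group 2; 4 females of group 1:
  # cross-group allows only the group-2 male; the rest must pair within
  pop <- make_test_pop(sex = c(1, 1, 1, 1, 2, 2, 2, 2),
                       village = rep(1L, 8),
                       group = c(1, 1, 1, 2, 1, 1, 1, 1))
  set.seed(3)
  pr <- form_mating_pairs(1:4, 5:8, group = pop$group)
  expect_length(pr$male, 4L)   # nobody single
  expect_length(pr$singles, 0L)
})

test_that("father-group probabilities follow the fitness-weighted law", {
  # two groups, equal male counts, fitness 0.1 vs 0: the expected share of
  # children fathered by group 1 is exp(0.1) / (exp(0.1) + 1)
  sex <- rep(c(1, 2), each = 20)
  group <- c(rep(1:2, each = 10), rep(1:2, each = 10))
  pop <- make_test_pop(sex = sex, village = rep(1L, 40), group = group,
                       fitness = c(0.1, 0))
  males <- which(pop$sex == 1L)
  females <- which(pop$sex == 2L)
  set.seed(9)
  share <- replicate(60, {
    pr <- form_mating_pairs(males, females, group = pop$group)
    mc <- c(`1` = 10L, `2` = 10L)
    kids <- assign_offspring(pr, pair_group = pop$group[pr$male],
                             male_counts = mc,
                             fitness = c(`1` = 0.1, `2` = 0),
                             n_children = 500L)
    mean(kids$group == 1L)
  })
  expect_equal(mean(share), exp(0.1) / (exp(0.1) + 1), tolerance = 0.02)
})

test_that("equal fitness and counts give symmetric paternity", {
  pop <- make_test_pop(sex = rep(c(1, 2), each = 20),
                       village = rep(1L, 40),
                       group = c(rep(1:2, each = 10), rep(1:2, each = 10)))
  set.seed(11)
  pr <- form_mating_pairs(which(pop$sex == 1L), which(pop$sex == 2L),
                          group = pop$group)
  kids <- assign_offspring(pr, pair_group = pop$group[pr$male],
                           male_counts = c(`1` = 10L, `2` = 10L),
                           fitness = c(`1` = 0.01, `2` = 0.01),
                           n_children = 4000L)
  expect_equal(mean(kids$group == 1L), 0.5, tolerance = 0.05)
  # children inherit the father's group
  expect_identical(kids$group, pop$group[kids$father])
  # mothers are the matched partners of the fathers
  pair_of <- match(kids$father, pr$male)
  expect_identical(kids$mother, pr$female[pair_of])
})

test_that("alternating sex assignment splits odd cohorts 152/151", {
  pop <- make_test_pop(sex = rep(c(1, 2), each = 5), village = rep(1L, 10))
  pr <- form_mating_pairs(1:5, 6:10, group = NULL)
  kids <- assign_offspring(pr, n_children = 303L)
  expect_equal(sum(kids$sex == 1L), 152L)
  expect_equal(sum(kids$sex == 2L), 151L)
})

test_that("polygynous mating weights concentrate paternity", {
  set.seed(5)
  # fixed weights (4,1,1,1,1): male 1 expects half of the couples
  share <- replicate(300, {
    kids <- assign_offspring_polygynous(1:5, 6:25, n_children = 40L,
                                        weights = c(4, 1, 1, 1, 1))
    mean(kids$father == 1L)
  })
  expect_equal(mean(share), 0.5, tolerance = 0.05)
  # geometric draws raise the male-to-female variance in offspring counts
  # relative to a monogamous control
  set.seed(6)
  males <- 1:50
  females <- 51:100
  var_ratio <- function(father, mother) {
    vf <- stats::var(tabulate(father, 50))
    vm <- stats::var(tabulate(mother - 50L, 50))
    vf / vm
  }
  poly <- replicate(60, {
    kids <- assign_offspring_polygynous(males, females, n_children = 200L)
    var_ratio(kids$father, kids$mother)
  })
  mono <- replicate(60, {
    pr <- form_mating_pairs(males, females, group = NULL)
    kids <- assign_offspring(pr, n_children = 200L)
    var_ratio(kids$father, kids$mother)
  })
  expect_gt(mean(poly), 2 * mean(mono))
})

test_that("violence rates solve the population-level kill quota", {
  # N = (400, 100), e = 0.15: rho = 0.0125, E[D] = (25, 50)
  lam <- patriseg:::violence_rates(c(400, 100), 0.15)
  expect_equal(lam, c(25, 50))
  expect_equal(patriseg:::violence_rates(c(100, 100), 0.15), c(15, 15))
  expect_equal(sum(patriseg:::violence_rates(c(37, 120, 260), 0.15)),
               0.15 * 417)
})

test_that("violence kills the expected fraction and spares females", {
  sex <- rep(c(1, 2), 300)
  group <- rep(1:3, each = 200)
  set.seed(7)
  kills <- replicate(60, {
    v <- apply_violence(sex, group, 0.15)
    expect_true(all(sex[v$killed] == 1L))
    length(v$killed)
  })
  expect_equal(mean(kills) / 300, 0.15, tolerance = 0.1)
})

test_that("violence with a single group falls back to uniform culling", {
  sex <- rep(c(1, 2), 100)
  v <- apply_violence(sex, rep(1L, 200), 0.15)
  expect_true(v$fallback)
  expect_equal(length(v$killed), round(0.15 * 100))
  expect_error(apply_violence(sex, rep(1L, 200), 0))
})

test_that("empty groups are removed and logged, others retained", {
  pop <- make_test_pop(sex = c(1, 2, 2), village = c(1, 1, 1),
                       group = c(1, 1, 2))
  # group 3 exists in the registry but has no members
  pop$groups <- rbind(pop$groups,
                      data.frame(id = 3L, village = 1L, fitness = 0.01,
                                 last_fission = -1000))
  out <- remove_extinct_groups(pop)
  expect_setequal(out$groups$id, c(1L, 2L))
  expect_equal(out$events[[1L]]$type, "extinction")
  expect_equal(out$events[[1L]]$group, 3L)
  # a group with only females survives the sweep
  expect_true(2L %in% out$groups$id)
  # idempotent on a clean registry
  expect_identical(remove_extinct_groups(out)$groups, out$groups)
})
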