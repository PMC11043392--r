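# Pedigree with one founder line branching into clades of 5, 3 and 2 males:
# founder (gen 0) -> three sons (gen 1) -> 5/3/2 grandsons (gen 2).
clade_532_ped <- function() {
  father <- c(0, 0,                 # 1 founder male, 1 founder female
              1, 1, 1,              # three sons (ids 3:5)
              rep(3, 5), rep(4, 3), rep(5, 2))  # grandsons (ids 6:15)
  mother <- c(0, 0, rep(2, 3), rep(2, 10))
  make_test_ped(father, mother, sex = rep(1L, 15))
}

test_that("lineal partition recovers exact founder patrilines", {
  # two founder patrilines of 6 and 4 males, target 0.6
  father <- c(0, 0, 0, rep(1, 6), rep(2, 4))
  ped <- make_test_ped(father, mother = c(0, 0, 0, rep(3, 10)),
                       sex = rep(1L, 13))
  males <- 4:13
  out <- lineal_partition(males, ped, n_generations = 1L,
                          target_proportion = 0.6)
  big <- if (length(out$set_a) == 6L) out$set_a else out$set_b
  expect_setequal(big, 4:9)
  expect_equal(sort(c(out$set_a, out$set_b)), males)
  expect_false(out$star)
})

test_that("greedy packing matches exhaustive enumeration on clades 5/3/2", {
  ped <- clade_532_ped()
  males <- 6:15
  out <- lineal_partition(males, ped, n_generations = 2L,
                          target_proportion = 0.5)
  # enumeration oracle over all clade bipartitions
  clades <- list(`5` = 6:10, `3` = 11:13, `2` = 14:15)
  sizes <- c(5, 3, 2)
  best <- Inf
  for (mask in 1:(2^3 - 2)) {
    inA <- as.logical(bitwAnd(mask, 2^(0:2)))
    best <- min(best, abs(sum(sizes[inA]) / 10 - 0.5))
  }
  expect_equal(abs(out$proportion - 0.5), best)
  expect_setequal(if (length(out$set_a) == 5L) out$set_a else out$set_b,
                  6:10)
})

test_that("partition sets are closed under paternal clades", {
  ped <- clade_532_ped()
  males <- 6:15
  for (target in c(0.2, 0.4, 0.7)) {
    out <- lineal_partition(males, ped, 2L, target)
    # brothers (same father) always end up on the same side
    fathers <- ped$father[males]
    side <- ifelse(males %in% out$set_a, "a", "b")
    expect_true(all(tapply(side, fathers, function(x) length(unique(x))) ==
                      1L))
  }
})

test_that("a star genealogy degenerates to a flagged random split", {
  father <- c(0, 0, rep(1, 6))
  ped <- make_test_ped(father, mother = c(0, 0, rep(2, 6)),
                       sex = rep(1L, 8))
  out <- lineal_partition(3:8, ped, 1L, 0.5)
  expect_true(out$star)
  expect_gt(length(out$set_a), 0L)
  expect_gt(length(out$set_b), 0L)
  expect_setequal(c(out$set_a, out$set_b), 3:8)
})

test_that("fission triggers on the male-count threshold and cooldown", {
  build <- function(n_males, last_fission, generation = 10L) {
    sex <- rep(c(1L, 2L), n_males)
    pop <- make_test_pop(sex = sex, village = rep(1L, 2 * n_males),
                         group = rep(1L, 2 * n_males),
                         last_fission = last_fission)
    pop$generation <- generation
    ped <- make_test_ped(rep(0L, 2 * n_males), rep(0L, 2 * n_males), sex)
    list(pop = pop, ped = ped)
  }
  params <- list(fission_threshold = 150L, fission_cooldown = 3L,
                 fission_type = "random", sigma2 = 0.1)
  # 2 * 76 = 152 > 150: fires
  set.seed(1)
  b <- build(76L, last_fission = -1000)
  out <- check_and_execute_fissions(b$pop, b$ped, params)
  expect_length(out$outcomes, 1L)
  # 2 * 75 = 150 is not > 150: boundary does not fire
  b <- build(75L, last_fission = -1000)
  out <- check_and_execute_fissions(b$pop, b$ped, params)
  expect_length(out$outcomes, 0L)
  # last fission 2 generations ago: suppressed; 4 generations ago: allowed
  b <- build(76L, last_fission = 8)
  expect_length(check_and_execute_fissions(b$pop, b$ped, params)$outcomes, 0L)
  b <- build(76L, last_fission = 6)
  expect_length(check_and_execute_fissions(b$pop, b$ped, params)$outcomes, 1L)
})

test_that("fission partitions conserve members and balance sexes", {
  set.seed(2)
  n <- 90L
  sex <- rep(c(1L, 2L), n)
  pop <- make_test_pop(sex = sex, village = rep(1L, 2 * n),
                       group = rep(1L, 2 * n), last_fission = -1000)
  pop$generation <- 5L
  ped <- make_test_ped(rep(0L, 2 * n), rep(0L, 2 * n), sex)
  params <- list(fission_threshold = 150L, fission_cooldown = 3L,
                 fission_type = "random", sigma2 = 0)
  out <- check_and_execute_fissions(pop, ped, params)
  expect_length(out$outcomes, 1L)
  newpop <- out$pop
  expect_setequal(unique(newpop$group), newpop$groups$id)
  expect_equal(length(newpop$groups$id), 2L)
  # membership conserved
  expect_equal(sum(!is.na(newpop$group)), 2L * n)
  # each daughter keeps a male fraction close to its female fraction
  for (g in newpop$groups$id) {
    gm <- sum(newpop$group == g & newpop$sex == 1L)
    gf <- sum(newpop$group == g & newpop$sex == 2L)
    expect_lt(abs(gm - gf), 3L)
  }
  # with sigma2 = 0 the daughters inherit the parent fitness exactly
  expect_equal(newpop$groups$fitness, rep(0.01, 2))
  expect_equal(newpop$groups$last_fission, rep(5L, 2))
})

test_that("post-fission migration relocates the smaller daughter", {
  set.seed(4)
  sex <- rep(c(1L, 2L), 50)
  pop <- make_test_pop(sex = sex, village = rep(1L, 100),
                       group = c(rep(1L, 60), rep(2L, 40)),
                       n_villages = 5L)
  outcome <- list(generation = 0L, type = "fission", village = 1L,
                  group = 99L, child1 = 1L, child2 = 2L, proportion = 0.6,
                  fission_type = "random", size1 = 60L, size2 = 40L)
  moved <- post_fission_migrate(pop, list(outcome))
  v2 <- unique(moved$village[moved$group == 2L])
  expect_length(v2, 1L)
  expect_false(v2 == 1L)
  expect_true(all(moved$village[moved$group == 1L] == 1L))
  expect_equal(moved$groups$village[moved$groups$id == 2L], v2)
  # simultaneous fissions in two villages exchange their movers
  pop2 <- make_test_pop(sex = rep(c(1L, 2L), 40), village = rep(1:2, each = 40),
                        group = rep(1:4, each = 20), n_villages = 5L)
  oc <- list(
    list(generation = 0L, type = "fission", village = 1L, group = 97L,
         child1 = 1L, child2 = 2L, proportion = 0.5, fission_type = "random",
         size1 = 30L, size2 = 20L),
    list(generation = 0L, type = "fission", village = 2L, group = 98L,
         child1 = 3L, child2 = 4L, proportion = 0.5, fission_type = "random",
         size1 = 30L, size2 = 20L))
  swapped <- post_fission_migrate(pop2, oc)
  expect_equal(unique(swapped$village[swapped$group == 2L]), 2L)
  expect_equal(unique(swapped$village[swapped$group == 4L]), 1L)
})
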