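test_that("single-record and two-record bookkeeping follows the half-open ages convention", {
  # one egg alive during [0, 3)
  coh <- cohort_table(lh_row("e1", "undetermined", death = 3))
  sched <- build_schedule(coh)
  expect_equal(unname(sched$l), c(1, 1, 1, 0))
  expect_equal(unname(sched$s[, "egg"]), c(1, 1, 1, 0))

  # one of two dies at age 1
  coh2 <- cohort_table(rbind(lh_row("e1", "undetermined", death = 1),
                             lh_row("e2", "undetermined", death = 3)))
  expect_equal(unname(build_schedule(coh2)$l[2]), 0.5)
})

test_that("row sums of s_xj equal the roll-call survival curve at every age", {
  for (seed in c(2, 9)) {
    coh <- simulate_cohort(cohort_preset("dsFoTPS-like"), seed = seed)
    sched <- build_schedule(coh)
    expect_equal(unname(sched$l * sched$N), roll_call_alive(coh),
                 tolerance = 1e-12)
    expect_equal(rowSums(sched$s), sched$l, tolerance = 1e-14,
                 ignore_attr = TRUE)
  }
})

test_that("R0 is the net-maternity sum and obeys the two-sex identity R0 = F Nf / N", {
  # no females -> 0
  males <- counts_cohort(n = 4, n_die = c(egg = 0, nymph = 0, pupa = 0),
                         n_female = 0, n_male = 4)
  expect_equal(net_reproductive_rate(build_schedule(males)), 0)

  # hand-listed eggs: 2 females lay 2 eggs on ages 18,19,20 plus one male
  coh <- counts_cohort(n = 3, n_die = c(egg = 0, nymph = 0, pupa = 0),
                       n_female = 2, n_male = 1)
  # phi_x = eggs at age x / N: ages 18..20 get 4/3 each
  expect_equal(net_reproductive_rate(build_schedule(coh)), 3 * 4 / 3,
               tolerance = 1e-12)

  coh2 <- fixture_cohort()
  p <- lifetable_params(coh2)
  expect_equal(p$R0, p$F * p$n_female / p$N, tolerance = 1e-12)
  expect_equal(p$R0, sum(build_schedule(coh2)$net_maternity), tolerance = 1e-12)
})

test_that("the Euler-Lotka solver matches closed forms, a grid scan, and its residual bound", {
  # all reproduction at age a: r = ln(R0)/(a+1)
  one <- cohort_table(lh_row("f1", "female", 0, 4, 11, 17, death = 30),
                      data.frame(id = "f1", age = 20, eggs = 50))
  sched <- build_schedule(one)
  r <- solve_intrinsic_rate(sched)
  expect_equal(r, log(50) / 21, tolerance = 1e-10)

  # R0 = 1 gives r = 0 exactly
  unit <- cohort_table(lh_row("f1", "female", 0, 4, 11, 17, death = 30),
                       data.frame(id = "f1", age = 20, eggs = 1))
  expect_identical(solve_intrinsic_rate(build_schedule(unit)), 0)

  # dense grid scan as independent root finder
  coh <- fixture_cohort()
  sched <- build_schedule(coh)
  r <- solve_intrinsic_rate(sched)
  phi <- sched$net_maternity
  ages1 <- seq_along(phi)
  resid <- function(rr) abs(sum(phi * exp(-rr * ages1)) - 1)
  grid <- seq(0.01, 0.5, by = 1e-6)
  r_grid <- grid[which.min(vapply(grid, resid, numeric(1)))]
  expect_equal(r, r_grid, tolerance = 1e-5)  # grid step limits the oracle
  expect_lt(resid(r), 1e-10)

  # lambda and T identities to machine precision
  p <- lifetable_params(coh, sched)
  expect_equal(p$lambda, exp(p$r), tolerance = 1e-15)
  expect_equal(p$T, log(p$R0) / p$r, tolerance = 1e-15)

  # no reproduction -> undefined marker
  males <- counts_cohort(n = 2, n_die = c(egg = 0, nymph = 0, pupa = 0),
                         n_female = 0, n_male = 2)
  expect_true(is.na(solve_intrinsic_rate(build_schedule(males))))
})

test_that("life expectancy equals observed mean longevity at birth and survives a Monte-Carlo check", {
  # certain death after one census day
  coh1 <- cohort_table(rbind(lh_row("a", "undetermined", death = 1),
                             lh_row("b", "undetermined", death = 1)))
  expect_equal(life_expectancy(build_schedule(coh1))[1, "egg"], 1,
               ignore_attr = TRUE)

  coh <- simulate_cohort(cohort_preset("dsFoTPS-like"), seed = 3)
  sched <- build_schedule(coh)
  e <- life_expectancy(sched)
  expect_equal(unname(e[1, "egg"]), mean(coh$life_history$death_age),
               tolerance = 1e-12)
  expect_true(all(e[sched$counts > 0] > 0))

  # Monte-Carlo walkers through the same kernel reproduce e at birth
  set.seed(99)
  nw <- 50000L
  A <- max(sched$ages)
  S <- length(sched$stages)
  state <- rep(1L, nw)
  days <- rep(1, nw)
  for (x in seq_len(A)) {
    u <- stats::runif(nw)
    newstate <- integer(nw)
    for (j in unique(state[state > 0L])) {
      sel <- state == j
      cum <- cumsum(sched$trans[x, j, ])
      k <- findInterval(u[sel], c(0, cum), left.open = TRUE)
      newstate[sel] <- ifelse(k > S, 0L, k)
    }
    state <- newstate
    days <- days + (state > 0L)
  }
  sem <- stats::sd(days) / sqrt(nw)
  expect_lt(abs(mean(days) - e[1, "egg"]), 3 * sem)
})

test_that("reproductive value equals lambda at birth, vanishes after reproduction, and matches the double sum", {
  coh <- fixture_cohort()
  sched <- build_schedule(coh)
  r <- solve_intrinsic_rate(sched)
  v <- reproductive_value(sched, r)
  expect_equal(unname(v[1, "egg"]), exp(r), tolerance = 1e-9)

  # beyond the last age with any future reproduction, v is zero
  toy <- counts_cohort()                       # females lay on ages 18..20, die at 40
  stoy <- build_schedule(toy)
  vtoy <- reproductive_value(stoy)
  expect_equal(unname(vtoy["30", "female"]), 0)
  expect_true(all(vtoy[stoy$counts[, "male"] > 0, "male"] == 0))

  # independent direct evaluation of the discounted double sum
  v_direct <- function(sched, age, j, r) {
    A <- max(sched$ages)
    sp <- matrix(0, A + 1L, length(sched$stages))
    sp[age + 1L, j] <- 1
    if (age < A) {
      for (ai in age:(A - 1L)) {
        sp[ai + 2L, ] <- sp[ai + 1L, ] %*% sched$trans[ai + 1L, , ]
      }
    }
    rows <- (age:A) + 1L
    disc <- exp(-r * (age:A + 1))
    exp(r * (age + 1)) *
      sum(disc * rowSums(sp[rows, , drop = FALSE] * sched$f[rows, , drop = FALSE]))
  }
  for (cell in list(c(0, 1), c(10, 2), c(25, 4))) {
    age <- cell[1]; j <- cell[2]
    if (sched$counts[age + 1, j] > 0) {
      expect_equal(unname(v[age + 1, j]), v_direct(sched, age, j, r),
                   tolerance = 1e-9)
    }
  }
})

test_that("mortality fractions come from entries minus completions over the original N", {
  tps <- counts_cohort(n_die = c(egg = 3, nymph = 9, pupa = 2),
                       n_female = 14, n_male = 12)
  expect_equal(mortality_distribution(tps),
               c(egg = 0.075, nymph = 0.225, pupa = 0.050))

  none <- counts_cohort(n = 4, n_die = c(egg = 0, nymph = 0, pupa = 0),
                        n_female = 2, n_male = 2)
  expect_equal(unname(mortality_distribution(none)), c(0, 0, 0))

  # fractions plus the fraction reaching adulthood account for everyone
  coh <- simulate_cohort(cohort_preset("dsFoTPS-like"), seed = 5)
  st <- twosexlt:::.ind_stats(coh)
  expect_equal(sum(mortality_distribution(coh)) +
                 sum(st$reached[, 4]) / st$n, 1, tolerance = 1e-12)
})

test_that("adding a death never increases any l_x", {
  coh <- counts_cohort()
  l1 <- build_schedule(coh)$l
  lh2 <- coh$life_history
  victim <- which(lh2$sex == "male")[1]
  lh2$death_age[victim] <- 20
  coh2 <- cohort_table(lh2, coh$fecundity, label = "toy")
  l2 <- build_schedule(coh2)$l
  expect_true(all(l2 <= l1[seq_along(l2)] + 1e-15))
})
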