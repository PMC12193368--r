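#' Build the age-stage survival and fecundity schedules
#'
#' Tabulates, from a daily-censused cohort, the matrices at the heart of the
#' age-stage two-sex framework: `s_xj`, the fraction of the original N alive at
#' age x in stage j (the adult stage split into female and male columns);
#' `f_xj`, the mean eggs laid at age x per female-stage individual then alive;
#' the age-specific survival `l_x = sum_j s_xj`, age-specific fecundity
#' `m_x = sum_j s_xj f_xj / l_x` and net maternity `l_x m_x`; and the daily
#' transition kernel giving, for each occupied (x, j), the observed
#' probabilities of staying in the stage, advancing to the next one (the
#' final preadult stage advancing to female or male), or dying. Age-stage
#' cells never visited by the cohort are treated as absorbing death. Eggs are
#' attributed to the mother's age on the day of laying, and `f_xj` divides by
#' female-stage individuals while `l_x m_x` spreads reproduction over the whole
#' cohort -- the convention that makes `R0 = F * Nf / N` an identity.
#'
#' @param cohort a validated [cohort_table()]
#' @return object of class `age_stage_schedule`: list with `ages` (0..A, A the
#'   maximum death age), `stages`, matrices `s` and `f`, vectors `l`, `m`,
#'   `net_maternity`, the transition array `trans` (dim A x S x S; slice x maps
#'   age x-1 to age x), raw `counts`, and cohort bookkeeping (`N`, `n_female`,
#'   `n_male`, `total_eggs`, `mean_longevity`).
#' @seealso [net_reproductive_rate()], [solve_intrinsic_rate()],
#'   [life_expectancy()], [reproductive_value()], [project_population()]
#' @export
build_schedule <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  st <- .ind_stats(cohort)
  if (st$n < 1L) stop("empty cohort")
  oc <- .occupancy(cohort, st)
  N <- st$n
  K <- length(cohort$stage_order)

  s <- oc$counts / N
  eggs_by_age <- colSums(oc$E)
  f <- matrix(0, nrow(s), ncol(s), dimnames = dimnames(s))
  cf <- oc$counts[, K]                     # female column
  f[, K] <- ifelse(cf > 0, eggs_by_age / cf, 0)
  l <- rowSums(s)
  phi <- eggs_by_age / N                   # net maternity l_x * m_x
  m <- ifelse(l > 0, phi / l, 0)

  structure(list(
    label = cohort$label, stages = oc$stages, ages = oc$ages,
    s = s, f = f, l = l, m = m, net_maternity = phi,
    trans = .transition_kernel(oc$occ, oc$S, oc$stages),
    counts = oc$counts, N = N,
    n_female = sum(st$sex == "female"), n_male = sum(st$sex == "male"),
    total_eggs = sum(eggs_by_age), mean_longevity = mean(st$death),
    stage_order = cohort$stage_order),
    class = "age_stage_schedule")
}

.transition_kernel <- function(occ, S, stages) {
  A <- ncol(occ) - 1L
  trans <- array(0, dim = c(A, S, S),
                 dimnames = list(NULL, stages, stages))
  for (x in seq_len(A)) {
    from <- occ[, x]
    to <- occ[, x + 1L]
    for (j in unique(from[from > 0L])) {
      sel <- from == j
      trans[x, j, ] <- tabulate(to[sel], nbins = S) / sum(sel)
    }
  }
  trans
}

#' @export
print.age_stage_schedule <- function(x, ...) {
  cat(sprintf("<age_stage_schedule> '%s': N = %d, ages 0..%d, stages %s\n",
              x$label, x$N, max(x$ages), paste(x$stages, collapse = ", ")))
  cat(sprintf("  R0 = %.3f, mean longevity = %.2f d\n",
              sum(x$net_maternity), x$mean_longevity))
  invisible(x)
}

#' Net reproductive rate
#'
#' `R0 = sum_x l_x m_x`, the expected lifetime offspring per newborn of the
#' cohort (both sexes in the denominator).
#'
#' @param schedule an [build_schedule()] result
#' @return a single number
#' @export
net_reproductive_rate <- function(schedule) {
  stopifnot(inherits(schedule, "age_stage_schedule"))
  sum(schedule$net_maternity)
}

# Vectorised bisection for the Euler-Lotka equation, one row of phi (= l_x m_x,
# ages 0..A) per problem: solves sum_x phi_x exp(-r (x+1)) = 1 on [lower, upper].
# Returns NA where R0 = 0 or no root lies in the bracket; exact 0 where R0 = 1.
.solve_r_many <- function(phi, lower = -1, upper = 2, iters = 80L) {
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1L)
  B <- nrow(phi)
  ages1 <- seq_len(ncol(phi))              # x + 1 for age x = 0..A
  R0 <- rowSums(phi)
  r <- rep(NA_real_, B)
  r[abs(R0 - 1) <= 1e-13] <- 0
  act <- which(R0 > 0 & abs(R0 - 1) > 1e-13)
  if (!length(act)) return(r)
  resid <- function(rv, rows) {
    rowSums(phi[rows, , drop = FALSE] * exp(-outer(rv, ages1))) - 1
  }
  ok <- resid(rep(lower, length(act)), act) > 0 &
        resid(rep(upper, length(act)), act) < 0
  act <- act[ok]
  if (!length(act)) return(r)
  lo <- rep(lower, length(act))
  hi <- rep(upper, length(act))
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos <- resid(mid, act) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  r[act] <- (lo + hi) / 2
  r
}

#' Solve the Euler-Lotka equation for the intrinsic rate of increase
#'
#' Finds the unique r with `sum_x exp(-r (x+1)) l_x m_x = 1` (ages indexed from
#' 0, so the discount exponent is x+1) by bisection on `[lower, upper]`, run to
#' an interval width far below 1e-12 so the residual at the returned r is below
#' 1e-10. Returns exactly 0 when R0 = 1 and `NA` when R0 = 0 (no reproduction;
#' the bootstrap counts such resamples as degenerate) or when no root lies in
#' the bracket.
#'
#' @param schedule an [build_schedule()] result
#' @param lower,upper bisection bracket (per day); the default bracket
#'   comfortably contains 0 and every biologically plausible daily rate
#' @return intrinsic rate of increase r (per day), or `NA`
#' @export
solve_intrinsic_rate <- function(schedule, lower = -1, upper = 2) {
  stopifnot(inherits(schedule, "age_stage_schedule"))
  .solve_r_many(matrix(schedule$net_maternity, nrow = 1L),
                lower = lower, upper = upper)[1]
}

#' Age-stage life expectancy
#'
#' `e_xj` is the expected number of remaining census days (including the
#' current one) of an individual now at age x in stage j, obtained by
#' propagating a virtual individual through the cohort's transition kernel:
#' `e_xj = 1 + sum_y P(x,j -> x+1,y) e_{x+1,y}`. Because the kernel is
#' estimated from the same cohort, `e` at age 0 in the first stage equals the
#' cohort's observed mean longevity exactly. Cells the cohort never occupied
#' are `NA`.
#'
#' @param schedule an [build_schedule()] result
#' @return matrix (ages x stages) of life expectancies, `NA` off the observed
#'   life path
#' @export
life_expectancy <- function(schedule) {
  stopifnot(inherits(schedule, "age_stage_schedule"))
  A <- length(schedule$ages) - 1L
  S <- length(schedule$stages)
  e <- matrix(0, A + 1L, S, dimnames = list(schedule$ages, schedule$stages))
  e[A + 1L, ] <- 1
  for (x in A:1) {
    e[x, ] <- 1 + schedule$trans[x, , ] %*% e[x + 1L, ]
  }
  e[schedule$counts == 0] <- NA_real_
  e
}

#' Age-stage reproductive value
#'
#' `v_xj` weighs an individual now at (x, j) by its expected future
#' contribution to population growth, discounted at the intrinsic rate:
#' `v_xj = exp(r (x+1)) sum_{i >= x} exp(-r (i+1)) sum_y s'_iy f_iy`, where s'
#' propagates the virtual individual started at (x, j) through the transition
#' kernel. Computed by the equivalent backward recursion. At age 0 in the first
#' stage the definition collapses to the Euler-Lotka sum, so
#' `v_{0,first} = exp(r) = lambda` -- a theorem of the framework used as a
#' self-check. Cells never occupied by the cohort are `NA`.
#'
#' @param schedule an [build_schedule()] result
#' @param r intrinsic rate of increase; solved from the schedule when missing
#' @return matrix (ages x stages) of reproductive values, `NA` off the observed
#'   life path
#' @export
reproductive_value <- function(schedule, r = NULL) {
  stopifnot(inherits(schedule, "age_stage_schedule"))
  if (is.null(r)) r <- solve_intrinsic_rate(schedule)
  A <- length(schedule$ages) - 1L
  S <- length(schedule$stages)
  if (is.na(r)) {
    v <- matrix(NA_real_, A + 1L, S,
                dimnames = list(schedule$ages, schedule$stages))
    return(v)
  }
  w <- matrix(0, A + 1L, S, dimnames = list(schedule$ages, schedule$stages))
  w[A + 1L, ] <- exp(-r * (A + 1)) * schedule$f[A + 1L, ]
  for (x in A:1) {
    w[x, ] <- exp(-r * x) * schedule$f[x, ] +
      schedule$trans[x, , ] %*% w[x + 1L, ]
  }
  v <- exp(r * seq_len(A + 1L)) * w        # row x is age x-1, prefactor e^{r x}
  v[schedule$counts == 0] <- NA_real_
  v
}

#' Preadult mortality distribution
#'
#' For each preadult stage, the fraction of the original cohort that died
#' during that stage: (number entering - number completing) / N, where
#' completing a stage means entering the next one. Together with the fraction
#' reaching adulthood these fractions sum to 1.
#'
#' @param cohort a [cohort_table()]
#' @return named numeric vector, one entry per preadult stage
#' @export
mortality_distribution <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  st <- .ind_stats(cohort)
  K <- length(cohort$stage_order)
  entered <- colSums(st$reached)
  out <- (entered[-K] - entered[-1]) / st$n
  names(out) <- cohort$stage_order[-K]
  out
}

#' All scalar demographic parameters of a cohort
#'
#' Point estimates of the full parameter set: intrinsic rate of increase r
#' (per day), finite rate `lambda = exp(r)`, net reproductive rate
#' `R0 = sum l_x m_x`, mean generation time `T = ln(R0)/r` (days), mean
#' fecundity per adult female `F` (so that `R0 = F * Nf / N` holds exactly),
#' sex counts, preadult mortality distribution, peak reproductive value and its
#' age, and mean longevity. Standard errors for all of these come from
#' [bootstrap_params()].
#'
#' @param cohort a [cohort_table()]
#' @param schedule optionally, a prebuilt [build_schedule()] result
#' @return object of class `life_table_params` (a named list)
#' @export
lifetable_params <- function(cohort, schedule = build_schedule(cohort)) {
  R0 <- net_reproductive_rate(schedule)
  r <- solve_intrinsic_rate(schedule)
  lambda <- if (is.na(r)) NA_real_ else exp(r)
  Tg <- if (!is.na(r) && r != 0 && R0 > 0) log(R0) / r else NA_real_
  Nf <- schedule$n_female
  Fm <- if (Nf > 0) schedule$total_eggs / Nf else NA_real_
  v <- reproductive_value(schedule, r)
  if (all(is.na(v))) {
    pk <- NA_real_
    pk_age <- NA_real_
  } else {
    pk <- max(v, na.rm = TRUE)
    pk_age <- schedule$ages[which(apply(v, 1, function(z) any(!is.na(z) & z == pk)))[1]]
  }
  structure(list(
    label = schedule$label, N = schedule$N, n_female = Nf,
    n_male = schedule$n_male,
    r = r, lambda = lambda, R0 = R0, T = Tg, F = Fm,
    mortality_distribution = mortality_distribution(cohort),
    peak_reproductive_value = pk, age_peak_reproductive_value = pk_age,
    mean_longevity = schedule$mean_longevity),
    class = "life_table_params")
}

#' @export
print.life_table_params <- function(x, digits = 4, ...) {
  cat(sprintf("<life_table_params> '%s' (N = %d: %d female, %d male)\n",
              x$label, x$N, x$n_female, x$n_male))
  cat(sprintf("  r = %.*f /d   lambda = %.*f /d   R0 = %.*f   T = %.*f d\n",
              digits, x$r, digits, x$lambda, digits, x$R0, digits, x$T))
  cat(sprintf("  F (eggs per adult female) = %.*f\n", digits, x$F))
  cat("  preadult mortality: ",
      paste(sprintf("%s %.3f", names(x$mortality_distribution),
                    x$mortality_distribution), collapse = ", "), "\n", sep = "")
  cat(sprintf("  peak reproductive value %.2f at age %s d\n",
              x$peak_reproductive_value,
              format(x$age_peak_reproductive_value)))
  invisible(x)
}

#' Internal-consistency identities of a life-table parameter set
#'
#' The scalar parameters of a two-sex life table are bound by exact identities:
#' `lambda = exp(r)`, `T = ln(R0)/r`, and `R0 = F * Nf / N`. Given any subset
#' of published values, this returns the values the identities imply, which is
#' how a reported parameter table can be cross-checked without the raw data.
#'
#' @param r intrinsic rate of increase (per day)
#' @param R0 net reproductive rate
#' @param F mean fecundity per adult female
#' @param Nf number of adult females
#' @param N cohort size
#' @return list with `lambda` (from `r`), `T` (from `R0` and `r`) and `R0`
#'   (from `F`, `Nf`, `N`); entries are `NA` when their inputs were not given
#' @examples
#' lifetable_identities(r = 0.1448, R0 = 94.1)
#' lifetable_identities(F = 209.2, Nf = 18, N = 40)
#' @export
lifetable_identities <- function(r = NA_real_, R0 = NA_real_, F = NA_real_,
                                 Nf = NA_real_, N = NA_real_) {
  list(lambda = exp(r),
       T = if (!is.na(r) && !is.na(R0) && r != 0) log(R0) / r else NA_real_,
       R0 = F * Nf / N)
}

#' Tidy data.frame view of an age-stage schedule
#'
#' One row per (age, stage) cell with the survival and fecundity schedules and,
#' optionally, life expectancy and reproductive value.
#'
#' @param schedule an [build_schedule()] result
#' @param e,v optional matrices from [life_expectancy()] /
#'   [reproductive_value()] to include as columns
#' @return data.frame with columns `age`, `stage`, `s`, `f` (and `e`, `v`)
#' @export
schedule_frame <- function(schedule, e = NULL, v = NULL) {
  stopifnot(inherits(schedule, "age_stage_schedule"))
  out <- data.frame(
    age = rep(schedule$ages, times = length(schedule$stages)),
    stage = rep(schedule$stages, each = length(schedule$ages)),
    s = as.vector(schedule$s),
    f = as.vector(schedule$f))
  if (!is.null(e)) out$e <- as.vector(e)
  if (!is.null(v)) out$v <- as.vector(v)
  out
}
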