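# Bootstrap machinery. The resampling unit is the individual: a resample of
# size N with replacement is a multinomial weight vector over individuals, so
# every statistic is computed from weighted per-individual summaries. One
# weight MATRIX (individuals x resamples) drives crossprod-based evaluation of
# all "ratio" statistics at once; the Euler-Lotka rate is solved for all
# resamples by vectorised bisection; only the peak reproductive value needs a
# per-resample backward recursion. Unit weights reproduce the point estimates
# exactly, which keeps the bootstrap and the point API on one code path.

.param_registry <- function(stage_order) {
  K <- length(stage_order)
  c(paste0("duration_", stage_order[-K]), "duration_preadult",
    "APOP", "TPOP", "oviposition_days", "fecundity",
    "female_longevity", "male_longevity", "age_50pct_survival",
    paste0("mortality_", stage_order[-K]),
    "R0", "r", "lambda", "T",
    "peak_reproductive_value", "age_peak_reproductive_value")
}

.boot_pre <- function(cohort) {
  st <- .ind_stats(cohort)
  oc <- .occupancy(cohort, st)
  so <- cohort$stage_order
  K <- length(so)
  n <- st$n

  num <- list()
  den <- list()
  ind01 <- function(x) as.numeric(x)
  for (k in seq_len(K - 1L)) {
    comp <- st$completed[, k]
    num[[paste0("duration_", so[k])]] <- ifelse(comp, st$dur[, k], 0)
    den[[paste0("duration_", so[k])]] <- ind01(comp)
  }
  adult <- st$reached[, K]
  num$duration_preadult <- ifelse(adult, st$preadult_dur, 0)
  den$duration_preadult <- ind01(adult)
  rf <- st$reproducing
  for (p in c("APOP", "TPOP", "oviposition_days", "fecundity")) {
    src <- switch(p, APOP = st$apop, TPOP = st$tpop,
                  oviposition_days = st$ovi_days, fecundity = st$total_eggs)
    num[[p]] <- ifelse(rf, src, 0)
    den[[p]] <- ind01(rf)
  }
  num$female_longevity <- ifelse(st$sex == "female", st$death, 0)
  den$female_longevity <- ind01(st$sex == "female")
  num$male_longevity <- ifelse(st$sex == "male", st$death, 0)
  den$male_longevity <- ind01(st$sex == "male")
  ones <- rep(1, n)
  for (k in seq_len(K - 1L)) {
    died_k <- st$reached[, k] & !st$reached[, k + 1L]
    num[[paste0("mortality_", so[k])]] <- ind01(died_k)
    den[[paste0("mortality_", so[k])]] <- ones
  }
  num$R0 <- st$total_eggs
  den$R0 <- ones

  # transition-pair indicators for the peak-reproductive-value path
  S <- oc$S
  pairs <- list()
  fromto <- function(j, jp) (oc$occ[, -ncol(oc$occ), drop = FALSE] == j) *
                            (oc$occ[, -1, drop = FALSE] == jp)
  for (j in seq_len(S)) {
    pairs[[paste(j, j)]] <- fromto(j, j)
    nxt <- if (j < K - 1L) j + 1L else if (j == K - 1L) c(K, K + 1L) else integer()
    for (jp in nxt) pairs[[paste(j, jp)]] <- fromto(j, jp)
  }

  list(n = n, K = K, S = S, A = oc$A, stages = oc$stages,
       registry = .param_registry(so),
       NUM = do.call(cbind, num), DEN = do.call(cbind, den),
       E = oc$E, alive = (oc$occ > 0) * 1, occ_ind = lapply(seq_len(S), function(j) (oc$occ == j) * 1),
       pairs = pairs,
       pair_idx = lapply(strsplit(names(pairs), " ", fixed = TRUE), as.integer),
       total_eggs = st$total_eggs)
}

# Evaluate the requested parameters for every column of the weight matrix W
# (n x B, non-negative integer resample multiplicities). Returns a B x P matrix.
.boot_stats <- function(pre, W, params) {
  B <- ncol(W)
  out <- matrix(NA_real_, B, length(params), dimnames = list(NULL, params))
  Wd <- if (is.double(W)) W else W + 0

  ratio <- intersect(params, colnames(pre$NUM))
  if (length(ratio)) {
    NUM <- crossprod(Wd, pre$NUM[, ratio, drop = FALSE])
    DEN <- crossprod(Wd, pre$DEN[, ratio, drop = FALSE])
    out[, ratio] <- ifelse(DEN > 0, NUM / DEN, NA_real_)
  }

  if ("age_50pct_survival" %in% params) {
    cnt <- crossprod(Wd, pre$alive)
    below <- cnt < pre$n / 2
    out[, "age_50pct_survival"] <- max.col(below, ties.method = "first") - 1
  }

  need_peak <- any(c("peak_reproductive_value", "age_peak_reproductive_value")
                   %in% params)
  need_r <- need_peak || any(c("r", "lambda", "T") %in% params)
  if (need_r) {
    Phi <- crossprod(Wd, pre$E) / pre$n
    R0v <- rowSums(Phi)
    rv <- .solve_r_many(Phi)
    if ("r" %in% params) out[, "r"] <- rv
    if ("lambda" %in% params) out[, "lambda"] <- exp(rv)
    if ("T" %in% params) {
      out[, "T"] <- ifelse(!is.na(rv) & rv != 0 & R0v > 0, log(R0v) / rv,
                           NA_real_)
    }
  }

  if (need_peak) {
    S <- pre$S
    A <- pre$A
    Cnt <- lapply(pre$occ_ind, function(M) crossprod(Wd, M))   # B x (A+1) each
    Pair <- lapply(pre$pairs, function(M) crossprod(Wd, M))    # B x A each
    EggA <- crossprod(Wd, pre$E)                               # B x (A+1)
    pk <- rep(NA_real_, B)
    pk_age <- rep(NA_real_, B)
    fcol <- pre$K
    pair_idx <- pre$pair_idx
    for (b in seq_len(B)) {
      r_b <- rv[b]
      if (is.na(r_b)) next
      cnts <- vapply(Cnt, function(M) M[b, ], numeric(A + 1L))  # (A+1) x S
      fb <- matrix(0, A + 1L, S)
      cf <- cnts[, fcol]
      fb[, fcol] <- ifelse(cf > 0, EggA[b, ] / cf, 0)
      w <- matrix(0, A + 1L, S)
      w[A + 1L, ] <- exp(-r_b * (A + 1)) * fb[A + 1L, ]
      for (x in A:1) {
        acc <- exp(-r_b * x) * fb[x, ]
        cx <- cnts[x, ]
        for (kk in seq_along(pair_idx)) {
          jj <- pair_idx[[kk]]
          if (cx[jj[1]] > 0) {
            p_move <- Pair[[kk]][b, x] / cx[jj[1]]
            if (p_move > 0) acc[jj[1]] <- acc[jj[1]] + p_move * w[x + 1L, jj[2]]
          }
        }
        w[x, ] <- acc
      }
      v <- exp(r_b * seq_len(A + 1L)) * w
      v[cnts == 0] <- NA_real_
      if (!all(is.na(v))) {
        pk[b] <- max(v, na.rm = TRUE)
        pk_age[b] <- which(apply(v, 1, function(z) any(!is.na(z) & z == pk[b])))[1] - 1
      }
    }
    if ("peak_reproductive_value" %in% params) {
      out[, "peak_reproductive_value"] <- pk
    }
    if ("age_peak_reproductive_value" %in% params) {
      out[, "age_peak_reproductive_value"] <- pk_age
    }
  }
  out
}

#' Bootstrap means and standard errors for all life-table parameters
#'
#' Each resample draws N individuals with replacement from the cohort
#' (preadult deaths included), rebuilds the age-stage schedules, and recomputes
#' every parameter in the registry: stage durations, APOP, TPOP, oviposition
#' days, fecundity, longevities, age of 50% survival, preadult mortality
#' fractions, R0, r, lambda, T, and the peak reproductive value with its age.
#' The bootstrap SE of a parameter is the standard deviation of its resample
#' estimates. Resamples with no reproduction (R0 = 0) are counted as degenerate
#' and excluded from the r / lambda / T summaries.
#'
#' @param cohort a [cohort_table()]
#' @param B number of resamples (>= 2). The study-scale default is 100000;
#'   a few thousand is ample for desk work.
#' @param seed integer seed for reproducibility (same seed, same call: bit
#'   identical results)
#' @param params character vector of parameter names to compute (default: the
#'   full registry, see `$parameters$parameter` of the result)
#' @param keep_resamples keep the B x P matrix of resample estimates (needed
#'   for percentile intervals; off for very large B if memory matters)
#' @return object of class `bootstrap_result`: list with `B`, `seed`,
#'   `parameters` (data.frame: parameter, estimate, boot_mean, boot_se,
#'   n_valid), `degenerate` (count of R0 = 0 resamples) and optionally
#'   `resamples`
#' @export
bootstrap_params <- function(cohort, B = 100000L, seed = NULL, params = NULL,
                             keep_resamples = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"), B >= 2)
  if (!is.null(seed)) set.seed(seed)
  pre <- .boot_pre(cohort)
  if (is.null(params)) params <- pre$registry
  W <- stats::rmultinom(B, pre$n, rep(1 / pre$n, pre$n))
  est <- .boot_stats(pre, matrix(1, pre$n, 1L), params)[1, ]
  sm <- .boot_stats(pre, W, params)
  degenerate <- sum(crossprod(W, pre$total_eggs) == 0)
  parameters <- data.frame(
    parameter = params,
    estimate = unname(est),
    boot_mean = apply(sm, 2, mean, na.rm = TRUE),
    boot_se = apply(sm, 2, stats::sd, na.rm = TRUE),
    n_valid = apply(sm, 2, function(z) sum(!is.na(z))),
    row.names = NULL)
  out <- list(B = B, seed = seed, parameters = parameters,
              degenerate = degenerate)
  if (keep_resamples) out$resamples <- sm
  structure(out, class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf("<bootstrap_result> B = %d resamples (%d degenerate, R0 = 0)%s\n",
              x$B, x$degenerate,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  print(format(x$parameters, digits = digits), row.names = FALSE)
  invisible(x)
}

.paired_boot <- function(cohortA, cohortB, B, seed, params) {
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  preA <- .boot_pre(cohortA)
  preB <- .boot_pre(cohortB)
  if (is.null(params)) params <- intersect(preA$registry, preB$registry)
  WA <- stats::rmultinom(B, preA$n, rep(1 / preA$n, preA$n))
  WB <- stats::rmultinom(B, preB$n, rep(1 / preB$n, preB$n))
  SA <- .boot_stats(preA, WA, params)
  SB <- .boot_stats(preB, WB, params)
  list(params = params, SA = SA, SB = SB,
       estA = .boot_stats(preA, matrix(1, preA$n, 1L), params)[1, ],
       estB = .boot_stats(preB, matrix(1, preB$n, 1L), params)[1, ])
}

#' Paired bootstrap test between two treatment cohorts
#'
#' Resample b of cohort A is paired with resample b of cohort B; the B
#' differences of the resample estimates form the bootstrap distribution of the
#' difference. The two-sided p-value is the percentile construction
#' `p = 2 min(frac(d <= 0), frac(d >= 0))`, clipped to `[2/B, 1]` -- with B
#' resamples no p-value below 2/B is resolvable. Pairs where either side is
#' degenerate (e.g. a resample with no reproducing female) are dropped from
#' that parameter's test.
#'
#' @param cohortA,cohortB two [cohort_table()]s
#' @inheritParams bootstrap_params
#' @return data.frame of class `paired_bootstrap_test`: one row per parameter
#'   with the group estimates, difference of bootstrap means, SE of the
#'   difference, p-value, and significance flag at 0.05
#' @export
paired_bootstrap_test <- function(cohortA, cohortB, B = 100000L, seed = NULL,
                                  params = NULL) {
  pb <- .paired_boot(cohortA, cohortB, B, seed, params)
  D <- pb$SA - pb$SB
  rows <- lapply(seq_along(pb$params), function(k) {
    d <- D[, k]
    d <- d[!is.na(d)]
    nb <- length(d)
    if (nb == 0) {
      return(data.frame(parameter = pb$params[k], estimate_A = pb$estA[k],
                        estimate_B = pb$estB[k], difference = NA_real_,
                        se_difference = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    p <- min(max(p, 2 / B), 1)
    data.frame(parameter = pb$params[k], estimate_A = unname(pb$estA[k]),
               estimate_B = unname(pb$estB[k]), difference = mean(d),
               se_difference = stats::sd(d), p_value = p,
               significant = p < 0.05)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("paired_bootstrap_test", "data.frame")
  out
}
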