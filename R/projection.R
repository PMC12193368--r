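#' Deterministic age-stage population projection under unlimited growth
#'
#' Propagates an initial age-stage composition day by day through the cohort's
#' transition kernel. Individuals at (x, j) split deterministically
#' (expected-value projection, fractional counts allowed) into (x+1, j),
#' (x+1, next stage) or death; female-stage individuals at age x contribute
#' `f_xj * count` newborns, which enter the first stage at age 0 on the NEXT
#' census day. Growth is density independent, so after the initial transient
#' the total grows at the finite rate lambda of the same schedule. Ages beyond
#' the cohort's maximum observed death age are absorbing death.
#'
#' @param schedule an [build_schedule()] result
#' @param initial named vector of starting counts per stage (e.g.
#'   `c(egg = 10)`); each stage's individuals start at the youngest age at
#'   which the cohort occupied that stage. Unknown stage names are an error.
#' @param days projection horizon in days (>= 1)
#' @return object of class `population_projection`: list with `days`, `stages`,
#'   `stage_totals` ((days+1) x stages matrix, day 0 first), `total`,
#'   `initial`, and the final age-stage state
#' @examples
#' coh <- simulate_cohort(cohort_preset("dsEGFP-like"), seed = 1)
#' proj <- project_population(build_schedule(coh), c(egg = 10), days = 100)
#' utils::tail(proj$total)
#' @export
project_population <- function(schedule, initial = c(egg = 10), days = 100) {
  stopifnot(inherits(schedule, "age_stage_schedule"), days >= 1)
  S <- length(schedule$stages)
  A <- length(schedule$ages) - 1L
  bad <- setdiff(names(initial), schedule$stages)
  if (length(bad)) {
    stop("unknown stage(s) in initial composition: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(names(initial)) || any(initial < 0)) {
    stop("initial must be a named vector of non-negative stage counts")
  }

  M <- matrix(0, A + 1L, S)
  for (stg in names(initial)) {
    j <- match(stg, schedule$stages)
    x0 <- which(schedule$counts[, j] > 0)[1]
    if (is.na(x0)) x0 <- 1L
    M[x0, j] <- M[x0, j] + initial[[stg]]
  }

  stage_totals <- matrix(0, days + 1L, S,
                         dimnames = list(0:days, schedule$stages))
  stage_totals[1L, ] <- colSums(M)
  for (t in seq_len(days)) {
    Mn <- matrix(0, A + 1L, S)
    for (x in seq_len(A)) {
      if (any(M[x, ] != 0)) {
        Mn[x + 1L, ] <- M[x, ] %*% schedule$trans[x, , ]
      }
    }
    Mn[1L, 1L] <- Mn[1L, 1L] + sum(M * schedule$f)
    M <- Mn
    stage_totals[t + 1L, ] <- colSums(M)
  }

  structure(list(days = days, stages = schedule$stages,
                 stage_totals = stage_totals, total = rowSums(stage_totals),
                 initial = initial, final_state = M,
                 label = schedule$label),
            class = "population_projection")
}

#' @export
print.population_projection <- function(x, ...) {
  cat(sprintf("<population_projection> '%s': %d days from %s\n", x$label,
              x$days,
              paste(sprintf("%s=%g", names(x$initial), x$initial),
                    collapse = ", ")))
  cat(sprintf("  final total %.4g (%s)\n", x$total[length(x$total)],
              paste(sprintf("%s %.4g", x$stages,
                            x$stage_totals[nrow(x$stage_totals), ]),
                    collapse = ", ")))
  invisible(x)
}

#' @describeIn project_population tidy (day, stage, count) view
#' @param x a `population_projection`
#' @param row.names,optional,... passed over from the generic (unused)
#' @export
as.data.frame.population_projection <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  data.frame(day = rep(0:x$days, times = length(x$stages)),
             stage = rep(x$stages, each = x$days + 1L),
             count = as.vector(x$stage_totals))
}
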