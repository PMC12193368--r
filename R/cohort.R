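#' Assemble a cohort life-history table
#'
#' A cohort table bundles one treatment group's per-individual life histories
#' (stage entry ages, sex, death age) with its long-format daily fecundity
#' records. Ages are integer days with age 0 the day the egg was laid; an
#' individual is alive during the half-open interval `[entry, death_age)`, so a
#' daily census at age x counts exactly the individuals with
#' `entry <= x < death_age`. An individual that dies on the day it molts is
#' attributed to the new stage (entry recorded, duration 0).
#'
#' @param life_history data.frame with columns `id`, `sex`
#'   (`"female"`, `"male"` or `"undetermined"` for individuals that died before
#'   adulthood), one `<stage>_entry` column per element of `stage_order`
#'   (`NA` = stage never reached), and `death_age` (first day the individual is
#'   no longer alive). An optional `treatment` column is used as the label.
#' @param fecundity data.frame with columns `id`, `age`, `eggs`: eggs laid by
#'   female `id` on the day it was age `age`. May be `NULL`/empty for cohorts
#'   without reproduction.
#' @param stage_order character vector of stage names in developmental order;
#'   the last element is the adult stage, which the age-stage schedule splits
#'   into female and male columns. The default pools first- and second-instar
#'   nymphs into `"nymph"` and prepupa plus pupa into `"pupa"`; record finer
#'   stages by passing a longer `stage_order`.
#' @param label cohort label (treatment name). Defaults to the `treatment`
#'   column when present.
#' @param validate if `TRUE` (default), stop with an informative error listing
#'   every invariant violation; set `FALSE` to build an object for inspection
#'   with [validate_cohort()].
#' @return An object of class `cohort_table`: a list with elements `label`,
#'   `stage_order`, `life_history`, `fecundity` and `census_interval` (fixed at
#'   one day).
#' @seealso [read_cohort()], [validate_cohort()], [stage_summaries()],
#'   [build_schedule()]
#' @examples
#' lh <- data.frame(id = "f1", sex = "female", egg_entry = 0, nymph_entry = 4,
#'                  pupa_entry = 11, adult_entry = 17, death_age = 60)
#' fec <- data.frame(id = "f1", age = 19:25, eggs = 3)
#' cohort_table(lh, fec)
#' @export
cohort_table <- function(life_history, fecundity = NULL,
                         stage_order = c("egg", "nymph", "pupa", "adult"),
                         label = NULL, validate = TRUE) {
  stopifnot(is.data.frame(life_history), length(stage_order) >= 2L)
  entry_cols <- paste0(stage_order, "_entry")
  needed <- c("id", "sex", entry_cols, "death_age")
  miss <- setdiff(needed, names(life_history))
  if (length(miss)) {
    stop("life_history is missing column(s): ", paste(miss, collapse = ", "))
  }
  lh <- life_history
  lh$id <- as.character(lh$id)
  lh$sex <- as.character(lh$sex)
  for (cl in c(entry_cols, "death_age")) lh[[cl]] <- as.numeric(lh[[cl]])
  if (is.null(label)) {
    label <- if ("treatment" %in% names(lh) && nrow(lh)) lh$treatment[1] else "cohort"
  }
  lh <- lh[needed]

  if (is.null(fecundity)) {
    fecundity <- data.frame(id = character(), age = numeric(), eggs = numeric())
  }
  miss <- setdiff(c("id", "age", "eggs"), names(fecundity))
  if (length(miss)) {
    stop("fecundity is missing column(s): ", paste(miss, collapse = ", "))
  }
  fec <- data.frame(id = as.character(fecundity$id),
                    age = as.numeric(fecundity$age),
                    eggs = as.numeric(fecundity$eggs))

  obj <- structure(
    list(label = label, stage_order = stage_order, life_history = lh,
         fecundity = fec, census_interval = 1L),
    class = "cohort_table")
  if (validate) {
    bad <- validate_cohort(obj)
    if (length(bad)) {
      stop("invalid cohort:\n  ", paste(bad, collapse = "\n  "))
    }
  }
  obj
}

#' Check every cohort invariant
#'
#' Reports (never throws) one message per violated rule, naming the individual
#' and the rule. An empty return value means the cohort is well formed.
#'
#' Rules checked per individual: the first stage is entered at age 0; entered
#' stages form a prefix of `stage_order`; entry ages strictly increase;
#' `death_age` exceeds the last entry; sex is `undetermined` exactly when the
#' adult stage was never reached. Fecundity rows must reference a known female,
#' carry non-negative egg counts, and fall inside the mother's adult lifespan
#' `[adult_entry, death_age)`.
#'
#' @param cohort a [cohort_table()]
#' @return character vector of violation descriptions (empty if none)
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  lh <- cohort$life_history
  fec <- cohort$fecundity
  so <- cohort$stage_order
  K <- length(so)
  entry_cols <- paste0(so, "_entry")
  out <- character()
  say <- function(id, msg) sprintf("individual '%s': %s", id, msg)

  if (nrow(lh) < 1L) {
    return("cohort must contain at least one individual")
  }
  dup <- unique(lh$id[duplicated(lh$id)])
  if (length(dup)) {
    out <- c(out, sprintf("duplicated id(s): %s", paste(dup, collapse = ", ")))
  }

  ent <- as.matrix(lh[entry_cols])
  for (i in seq_len(nrow(lh))) {
    id <- lh$id[i]
    e <- ent[i, ]
    reached <- !is.na(e)
    if (!reached[1] || e[1] != 0) {
      out <- c(out, say(id, sprintf("first stage (%s) entry must be age 0", so[1])))
    }
    if (any(reached) && !all(reached[seq_len(max(which(reached)))])) {
      out <- c(out, say(id, "entered stages must be a prefix of stage_order"))
    }
    ee <- e[reached]
    if (length(ee) > 1 && any(diff(ee) <= 0)) {
      out <- c(out, say(id, "stage entry ages must strictly increase"))
    }
    if (is.na(lh$death_age[i]) || (any(reached) && lh$death_age[i] <= max(ee))) {
      out <- c(out, say(id, "death_age must exceed the last stage entry age"))
    }
    if (!lh$sex[i] %in% c("female", "male", "undetermined")) {
      out <- c(out, say(id, sprintf("unknown sex '%s'", lh$sex[i])))
    } else if (lh$sex[i] == "undetermined" && reached[K]) {
      out <- c(out, say(id, "sex cannot be undetermined for an adult"))
    } else if (lh$sex[i] %in% c("female", "male") && !reached[K]) {
      out <- c(out, say(id, "sex is only observable at adult emergence; use 'undetermined' for preadult deaths"))
    }
  }

  if (nrow(fec)) {
    idx <- match(fec$id, lh$id)
    if (anyNA(idx)) {
      out <- c(out, sprintf("fecundity references unknown id(s): %s",
                            paste(unique(fec$id[is.na(idx)]), collapse = ", ")))
    }
    ok <- !is.na(idx)
    if (any(fec$eggs[ok] < 0)) {
      out <- c(out, sprintf("negative egg count for id(s): %s",
                            paste(unique(fec$id[ok & fec$eggs < 0]), collapse = ", ")))
    }
    nonf <- ok & lh$sex[idx] != "female"
    for (id in unique(fec$id[nonf])) {
      out <- c(out, say(id, "fecundity recorded for a non-female individual"))
    }
    isf <- ok & lh$sex[idx] == "female"
    if (any(isf)) {
      a0 <- ent[idx, K]
      bad <- isf & (fec$age < a0 | fec$age >= lh$death_age[idx])
      for (id in unique(fec$id[bad])) {
        out <- c(out, say(id, "fecundity age outside the adult lifespan [adult_entry, death_age)"))
      }
    }
  }
  out
}

#' Read a cohort from the two-CSV dialect
#'
#' `life_history.csv` holds one row per individual with columns
#' `id, treatment, sex, <stage>_entry..., death_age` (empty cell = stage never
#' reached); `fecundity.csv` is long format with columns `id, age, eggs`.
#' Both are UTF-8 with a header row. The cohort is validated on read.
#'
#' @param life_history_path path to the life-history CSV
#' @param fecundity_path path to the fecundity CSV
#' @inheritParams cohort_table
#' @return a validated [cohort_table()]
#' @export
read_cohort <- function(life_history_path, fecundity_path,
                        stage_order = c("egg", "nymph", "pupa", "adult"),
                        label = NULL) {
  lh <- utils::read.csv(life_history_path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  fec <- utils::read.csv(fecundity_path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  cohort_table(lh, fec, stage_order = stage_order, label = label)
}

#' Write a cohort in the two-CSV dialect
#'
#' Mirrors the format read by [read_cohort()]; `read_cohort()` of the written
#' files reproduces the cohort exactly. Only fecundity rows with at least one
#' egg are written.
#'
#' @param cohort a [cohort_table()]
#' @inheritParams read_cohort
#' @return invisibly, the two paths
#' @export
write_cohort <- function(cohort, life_history_path, fecundity_path) {
  stopifnot(inherits(cohort, "cohort_table"))
  lh <- cohort$life_history
  out <- cbind(lh["id"], treatment = cohort$label, lh[setdiff(names(lh), "id")])
  utils::write.csv(out, life_history_path, row.names = FALSE, na = "")
  fec <- cohort$fecundity
  fec <- fec[fec$eggs > 0, , drop = FALSE]
  utils::write.csv(fec, fecundity_path, row.names = FALSE)
  invisible(c(life_history_path, fecundity_path))
}

#' @export
print.cohort_table <- function(x, ...) {
  st <- .ind_stats(x)
  cat(sprintf("<cohort_table> '%s': %d individuals (%d female, %d male, %d preadult deaths)\n",
              x$label, st$n, sum(st$sex == "female"), sum(st$sex == "male"),
              sum(st$sex == "undetermined")))
  cat(sprintf("  stages: %s; daily census; max death age %d\n",
              paste(x$stage_order, collapse = " > "), max(st$death)))
  invisible(x)
}

# Per-individual derived quantities shared by the schedule and bootstrap code.
# entries: n x K matrix; completed[,k] == entered stage k+1 (adult col unused);
# fecundity rows with eggs == 0 are ignored throughout.
.ind_stats <- function(cohort) {
  lh <- cohort$life_history
  so <- cohort$stage_order
  K <- length(so)
  entries <- as.matrix(lh[paste0(so, "_entry")])
  n <- nrow(lh)
  reached <- !is.na(entries)
  completed <- cbind(reached[, -1, drop = FALSE], rep(FALSE, n))
  dur <- entries[, -1, drop = FALSE] - entries[, -K, drop = FALSE]

  fec <- cohort$fecundity
  fec <- fec[fec$eggs > 0, , drop = FALSE]
  total_eggs <- numeric(n)
  ovi_days <- numeric(n)
  first_egg <- rep(NA_real_, n)
  if (nrow(fec)) {
    idx <- match(fec$id, lh$id)
    te <- tapply(fec$eggs, idx, sum)
    total_eggs[as.integer(names(te))] <- te
    od <- tapply(fec$age, idx, function(a) length(unique(a)))
    ovi_days[as.integer(names(od))] <- od
    fe <- tapply(fec$age, idx, min)
    first_egg[as.integer(names(fe))] <- fe
  }
  sex <- lh$sex
  reproducing <- sex == "female" & total_eggs > 0
  apop <- ifelse(reproducing, first_egg - entries[, K], NA_real_)

  list(n = n, id = lh$id, sex = sex, death = lh$death_age,
       entries = entries, reached = reached, completed = completed, dur = dur,
       preadult_dur = entries[, K],
       total_eggs = total_eggs, ovi_days = ovi_days, first_egg = first_egg,
       reproducing = reproducing, apop = apop, tpop = first_egg)
}

# Day-by-day age-stage occupancy. occ[i, x+1] is the stage code of individual i
# at age x: 0 dead, 1..K-1 the preadult stages, K female adult, K+1 male adult.
# E[i, x+1] is the eggs individual i laid at age x.
.occupancy <- function(cohort, st = .ind_stats(cohort)) {
  so <- cohort$stage_order
  K <- length(so)
  stages <- c(so[-K], "female", "male")
  S <- K + 1L
  A <- as.integer(max(st$death))
  ages <- 0:A
  n <- st$n

  occ <- matrix(0L, n, A + 1L)
  for (i in seq_len(n)) {
    e <- st$entries[i, ]
    e <- e[!is.na(e)]
    stg <- findInterval(ages, e)        # first entry is 0, so >= 1 everywhere
    stg[ages >= st$death[i]] <- 0L
    if (st$sex[i] == "male") stg[stg == K] <- K + 1L
    occ[i, ] <- stg
  }

  E <- matrix(0, n, A + 1L)
  fec <- cohort$fecundity
  fec <- fec[fec$eggs > 0, , drop = FALSE]
  if (nrow(fec)) {
    ii <- match(fec$id, st$id)
    code <- (as.integer(fec$age)) * n + ii   # linear index into n x (A+1)
    sums <- rowsum(fec$eggs, code)
    E[as.integer(rownames(sums))] <- sums
  }

  counts <- vapply(seq_len(S), function(j) colSums(occ == j),
                   numeric(A + 1L))
  dimnames(counts) <- list(ages, stages)
  list(occ = occ, E = E, counts = counts, stages = stages, ages = ages,
       S = S, A = A)
}

#' Summary statistics of a cohort (durations, reproduction, longevity)
#'
#' Mean and standard error of each developmental-stage duration (over the
#' individuals that completed the stage, so sample sizes shrink down the
#' table), the preadult duration, APOP (adult emergence to first egg), TPOP
#' (age 0 to first egg), oviposition days and fecundity per reproducing female,
#' total longevity by sex, and the age at which fewer than half of the original
#' cohort is still alive (no interpolation; daily census granularity).
#' Statistics with no qualifying individuals are reported as `NA` with n = 0.
#'
#' @param cohort a [cohort_table()]
#' @return an object of class `stage_summary`: list with data.frames
#'   `durations`, `reproduction`, `longevity`, plus `age_50pct_survival` and `N`
#' @export
stage_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  st <- .ind_stats(cohort)
  so <- cohort$stage_order
  K <- length(so)

  msn <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    c(n = n,
      mean = if (n) mean(x) else NA_real_,
      se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_)
  }
  dur_rows <- lapply(seq_len(K - 1L), function(k) {
    msn(st$dur[st$completed[, k], k])
  })
  dur_rows <- c(dur_rows, list(msn(st$preadult_dur[st$reached[, K]])))
  durations <- data.frame(stage = c(so[-K], "preadult"),
                          do.call(rbind, dur_rows))

  rf <- st$reproducing
  reproduction <- data.frame(
    statistic = c("APOP", "TPOP", "oviposition_days", "fecundity"),
    rbind(msn(st$apop[rf]), msn(st$tpop[rf]),
          msn(st$ovi_days[rf]), msn(st$total_eggs[rf])))

  longevity <- data.frame(
    sex = c("female", "male"),
    rbind(msn(st$death[st$sex == "female"]),
          msn(st$death[st$sex == "male"])))

  ages <- 0:max(st$death)
  alive <- vapply(ages, function(x) sum(st$death > x), numeric(1))
  a50 <- ages[which(alive < st$n / 2)[1]]

  structure(list(durations = durations, reproduction = reproduction,
                 longevity = longevity, age_50pct_survival = a50,
                 N = st$n, label = cohort$label),
            class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<stage_summary> '%s' (N = %d)\n", x$label, x$N))
  cat("Stage durations (days, completers only):\n")
  print(format(x$durations, digits = digits), row.names = FALSE)
  cat("Reproduction (reproducing females):\n")
  print(format(x$reproduction, digits = digits), row.names = FALSE)
  cat("Total longevity by sex:\n")
  print(format(x$longevity, digits = digits), row.names = FALSE)
  cat(sprintf("Age of 50%% survival: %s days\n", format(x$age_50pct_survival)))
  invisible(x)
}
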