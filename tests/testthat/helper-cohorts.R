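# Deterministic toy-cohort builders used across the suite.

lh_row <- function(id, sex, egg = 0, nymph = NA, pupa = NA, adult = NA, death) {
  data.frame(id = id, sex = sex, egg_entry = egg, nymph_entry = nymph,
             pupa_entry = pupa, adult_entry = adult, death_age = death,
             stringsAsFactors = FALSE)
}

# One female that lays `eggs_per_day` on each age in `lay_ages`.
toy_female <- function(id = "f1", death = 60, lay_ages = 19:25,
                       eggs_per_day = 3) {
  list(lh = lh_row(id, "female", 0, 4, 11, 17, death),
       fec = data.frame(id = id, age = lay_ages, eggs = eggs_per_day))
}

# A cohort reproducing published per-stage sample sizes: n_die gives deaths in
# each preadult stage; survivors split into n_female/n_male adults. Durations
# are fixed (egg 4, nymph 7, pupa 5); adults die at age `adult_death`.
counts_cohort <- function(n = 40, n_die = c(egg = 0, nymph = 2, pupa = 4),
                          n_female = 18, n_male = 16, adult_death = 40,
                          lay = TRUE, label = "toy") {
  stopifnot(n - sum(n_die) == n_female + n_male)
  rows <- list(); fec <- list(); i <- 0
  nid <- function() sprintf("%s_%02d", label, i)
  for (k in seq_len(n_die[["egg"]])) {
    i <- i + 1; rows[[i]] <- lh_row(nid(), "undetermined", death = 2)
  }
  for (k in seq_len(n_die[["nymph"]])) {
    i <- i + 1; rows[[i]] <- lh_row(nid(), "undetermined", nymph = 4, death = 6)
  }
  for (k in seq_len(n_die[["pupa"]])) {
    i <- i + 1
    rows[[i]] <- lh_row(nid(), "undetermined", nymph = 4, pupa = 11, death = 13)
  }
  for (k in seq_len(n_female)) {
    i <- i + 1
    rows[[i]] <- lh_row(nid(), "female", nymph = 4, pupa = 11, adult = 16,
                        death = adult_death)
    if (lay) fec[[length(fec) + 1]] <-
      data.frame(id = rows[[i]]$id, age = 18:20, eggs = 2)
  }
  for (k in seq_len(n_male)) {
    i <- i + 1
    rows[[i]] <- lh_row(nid(), "male", nymph = 4, pupa = 11, adult = 16,
                        death = adult_death)
  }
  cohort_table(do.call(rbind, rows),
               if (length(fec)) do.call(rbind, fec) else NULL,
               label = label)
}

fixture_cohort <- function() {
  read_cohort(
    system.file("extdata", "dsEGFP_synthetic_cohort_life_history.csv",
                package = "twosexlt", mustWork = TRUE),
    system.file("extdata", "dsEGFP_synthetic_cohort_fecundity.csv",
                package = "twosexlt", mustWork = TRUE))
}

# Independent day-by-day roll call straight off the raw records: how many
# individuals are alive at age x (alive during [first entry, death)).
roll_call_alive <- function(cohort) {
  lh <- cohort$life_history
  ages <- 0:max(lh$death_age)
  vapply(ages, function(x) sum(lh$death_age > x), numeric(1))
}
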