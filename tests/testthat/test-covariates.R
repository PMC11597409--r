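# day-count oracle: days of `year` on which the female has an offspring
# younger than 365 days, stepped day by day
infant_days_oracle <- function(births, year) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  sum(vapply(days, function(d)
    any(births <= d & as.numeric(d - births) < 365), logical(1L)))
}

dem_with_infant <- function(birth) {
  demog_simple(fem = c("A", "B"),
               offspring = data.frame(mother_id = "A",
                                      birth_date = as.Date(birth)))
}

test_that("dependent-infant flag follows the more-than-6-months rule", {
  expect_true(flag_dependent_infant("A", 2015, dem_with_infant("2015-01-15")))
  # born 1 December: <= 31 qualifying days that year, flagged the next year
  dem <- dem_with_infant("2015-12-01")
  expect_false(flag_dependent_infant("A", 2015, dem))
  expect_true(flag_dependent_infant("A", 2016, dem))
  # born 2 July: exactly 183 qualifying days, not strictly more
  expect_false(flag_dependent_infant("A", 2015, dem_with_infant("2015-07-02")))
  expect_true(flag_dependent_infant("A", 2015, dem_with_infant("2015-07-01")))
  expect_false(flag_dependent_infant("B", 2015, dem_with_infant("2015-01-15")))
})

test_that("dependent-infant flag matches the day-count oracle on random births", {
  set.seed(21)
  for (i in 1:30) {
    birth <- as.Date("2014-01-01") + sample(0:730, 1)
    dem <- dem_with_infant(birth)
    for (year in 2014:2016) {
      expect_equal(flag_dependent_infant("A", year, dem),
                   infant_days_oracle(birth, year) > 183,
                   info = paste(birth, year))
    }
  }
})

dem_with_entry <- function(entry, type = "immigration") {
  individuals <- data.frame(id = c("A", "B"), sex = "F",
                            birth_date = as.Date("2000-01-01"))
  tenures <- data.frame(
    id = c("A", "B"), group_id = "G",
    entry_date = as.Date(c(entry, "2010-01-01")),
    entry_type = c(type, "natal"),
    exit_date = as.Date(NA), exit_type = NA_character_)
  demography_table(individuals, tenures)
}

test_that("new-immigrant flag honours the mid-year scoring rule", {
  dem <- dem_with_entry("2016-03-01")
  expect_true(flag_new_immigrant("A", 2016, dem))
  expect_false(flag_new_immigrant("A", 2017, dem))
  # entry after 1 July: first scored (and flagged) year is the next one
  dem <- dem_with_entry("2016-09-01")
  expect_false(flag_new_immigrant("A", 2016, dem))
  expect_true(flag_new_immigrant("A", 2017, dem))
  # natal females are never flagged
  dem <- dem_with_entry("2016-03-01", type = "natal")
  expect_false(flag_new_immigrant("A", 2016, dem))
})

test_that("last-year flag looks one year ahead at emigration only", {
  individuals <- data.frame(id = "A", sex = "F",
                            birth_date = as.Date("2000-01-01"))
  mk <- function(exit_type) {
    tenures <- data.frame(id = "A", group_id = "G",
                          entry_date = as.Date("2010-01-01"),
                          entry_type = "natal",
                          exit_date = as.Date("2018-05-10"),
                          exit_type = exit_type)
    demography_table(individuals, tenures)
  }
  expect_true(flag_last_year("A", 2017, mk("emigration")))
  expect_false(flag_last_year("A", 2016, mk("emigration")))
  expect_false(flag_last_year("A", 2017, mk("death")))
  open_dem <- demog_simple(fem = "A", males = "M1")
  expect_false(any(vapply(2014:2018, flag_last_year, logical(1L),
                          female = "A", demography = open_dem)))
})

test_that("new-alpha flag compares year-over-year identity", {
  alphas <- data.frame(group_id = "G", year = 2015:2017,
                       alpha_id = c("M1", "M1", "M2"))
  expect_false(flag_new_alpha("G", 2016, alphas))
  expect_true(flag_new_alpha("G", 2017, alphas))
  expect_true(is.na(flag_new_alpha("G", 2015, alphas)))  # no history
})

test_that("model tables join scores, ranks and flags coherently", {
  scen <- tiny_scenario(seed = 31)
  st <- simulate_study(scen)
  elo <- run_elo(st$agonistic, st$demography,
                 start_date = study_start(scen),
                 end_date = study_end(scen) - 1)
  ranks <- rank_table(elo, st$demography)
  nets <- yearly_networks(st$scans, st$demography)
  tabs <- suppressMessages(build_model_tables(nets, ranks, st$demography))
  ind <- tabs$individual; dy <- tabs$dyad

  # dyad rows per group-year = C(number of scored females, 2)
  for (gy in unique(paste(dy$group_id, dy$year))) {
    rows <- dy[paste(dy$group_id, dy$year) == gy, ]
    ids <- unique(c(rows$id1, rows$id2))
    expect_equal(nrow(rows), choose(length(ids), 2))
  }

  # dyad infant category consistent with the two individual flags
  for (r in seq_len(nrow(dy))) {
    fa <- flag_dependent_infant(dy$id1[r], dy$year[r], st$demography)
    fb <- flag_dependent_infant(dy$id2[r], dy$year[r], st$demography)
    expect_equal(dy$dependent_infant_cat[r],
                 if (fa && fb) "both" else if (fa || fb) "one" else "none")
  }

  # individual rows: brute-force join oracle over the node table
  nodes <- nets$nodes
  alphas <- ranks[ranks$sex == "M" & ranks$is_alpha %in% TRUE, ]
  alpha_tab <- data.frame(group_id = alphas$group_id, year = alphas$year,
                          alpha_id = alphas$id)
  expected <- 0L
  for (r in seq_len(nrow(nodes))) {
    if (nodes$n_focals[r] == 0) next
    g <- nodes$group_id[r]; y <- nodes$year[r]
    rk <- ranks$std_rank[ranks$group_id == g & ranks$year == y &
                           ranks$id == nodes$id[r]]
    if (length(rk) != 1 || is.na(rk)) next
    if (is.na(flag_new_alpha(g, y, alpha_tab))) next
    tt <- st$demography$tenures
    tt <- tt[tt$id == nodes$id[r] & tt$entry_type == "immigration", ]
    skip <- FALSE
    for (i in seq_len(nrow(tt))) {
      ey <- as.integer(format(tt$entry_date[i], "%Y"))
      if (y == ey && format(tt$entry_date[i], "%m-%d") > "07-01") skip <- TRUE
    }
    if (!skip) expected <- expected + 1L
  }
  expect_equal(nrow(ind), expected)

  # strengths carried through unchanged
  j <- match(paste(ind$group_id, ind$year, ind$id),
             paste(nodes$group_id, nodes$year, nodes$id))
  expect_equal(ind$strength, nodes$strength[j])
  expect_true(all(ind$dominance_rank >= 0 & ind$dominance_rank <= 1))
  expect_true(all(dy$rank_average >= 0 & dy$rank_average <= 1))
})

test_that("a mid-year immigrant's entry year is excluded from scoring", {
  scen <- tiny_scenario(seed = 32, immigration_rate = 0.4)
  st <- simulate_study(scen)
  imm <- st$demography$tenures
  imm <- imm[imm$entry_type == "immigration" &
               imm$entry_date >= study_start(scen) &
               format(imm$entry_date, "%m-%d") > "07-01", ]
  skip_if(nrow(imm) == 0, "no mid-year immigrant drawn")
  elo <- run_elo(st$agonistic, st$demography,
                 start_date = study_start(scen),
                 end_date = study_end(scen) - 1)
  ranks <- rank_table(elo, st$demography)
  nets <- yearly_networks(st$scans, st$demography)
  tabs <- suppressMessages(build_model_tables(nets, ranks, st$demography))
  for (i in seq_len(nrow(imm))) {
    ey <- as.integer(format(imm$entry_date[i], "%Y"))
    expect_false(any(tabs$individual$id == imm$id[i] &
                       tabs$individual$year == ey))
  }
})
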