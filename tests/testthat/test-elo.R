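# independent step-by-step oracle for a sequence of interactions
elo_oracle <- function(winners, losers, ids, start = 1000, k = 100) {
  r <- stats::setNames(rep(start, length(ids)), ids)
  for (i in seq_along(winners)) {
    w <- winners[i]; l <- losers[i]
    p <- 1 / (1 + 10^((r[l] - r[w]) / 400))
    r[w] <- r[w] + k * (1 - p)
    r[l] <- r[l] - k * (1 - p)
  }
  r
}

test_that("elo_update follows the classic update rule", {
  expect_equal(elo_update(1000, 1000, k = 100), c(1050, 950))
  # overwhelming favourite wins: ratings essentially unchanged
  upd <- elo_update(3000, 1000, k = 100)
  expect_lt(upd[1] - 3000, 0.01)
  # zero-sum for arbitrary ratings
  set.seed(1)
  for (i in 1:25) {
    rw <- runif(1, 500, 1500); rl <- runif(1, 500, 1500)
    upd <- elo_update(rw, rl, k = 100)
    expect_equal(sum(upd), rw + rl)
    expect_gte(upd[1], rw)  # winner never loses points
  }
})

test_that("run_elo reproduces a hand-stepped 10-event sequence", {
  dem <- demog_simple(fem = c("A", "B", "C"))
  winners <- c("A", "B", "A", "C", "A", "B", "A", "A", "C", "B")
  losers  <- c("B", "C", "C", "B", "B", "A", "C", "B", "A", "C")
  dates <- as.Date("2015-01-01") + seq(0, 27, by = 3)
  ev <- data.frame(date = dates, group_id = "G", winner_id = winners,
                   loser_id = losers, behaviour = "displacement",
                   sex_class = "female")
  elo <- run_elo(ev, dem, start_date = "2015-01-01", end_date = "2015-12-31")
  final <- elo[elo$date == as.Date("2015-12-31") & elo$sex == "F", ]
  expected <- elo_oracle(winners, losers, c("A", "B", "C"))
  expect_equal(stats::setNames(final$rating, final$id), expected[final$id])
  # single update visible on and after the event day
  day1 <- elo[elo$date == dates[1], ]
  expect_equal(day1$rating[day1$id == "A"], 1050)
  expect_equal(day1$rating[day1$id == "B"], 950)
  expect_equal(day1$rating[day1$id == "C"], 1000)
})

test_that("a newcomer enters the hierarchy at the active minimum", {
  individuals <- data.frame(id = c("A", "B", "C"), sex = "F",
                            birth_date = as.Date("2000-01-01"))
  tenures <- data.frame(
    id = c("A", "B", "C"), group_id = "G",
    entry_date = as.Date(c("2014-01-01", "2014-01-01", "2015-06-01")),
    entry_type = c("natal", "natal", "immigration"),
    exit_date = as.Date(NA), exit_type = NA_character_)
  dem <- demography_table(individuals, tenures)
  ev <- data.frame(date = as.Date(c("2015-02-01", "2015-03-01")),
                   group_id = "G", winner_id = "A", loser_id = "B",
                   behaviour = "displacement", sex_class = "female")
  elo <- run_elo(ev, dem, start_date = "2015-01-01", end_date = "2015-12-31")
  b_pre <- elo$rating[elo$id == "B" & elo$date == as.Date("2015-05-31")]
  c_entry <- elo$rating[elo$id == "C" & elo$date == as.Date("2015-06-01")]
  expect_equal(c_entry, b_pre)       # bottom entry = current active minimum
  expect_lt(c_entry, 1000)
  expect_false(any(elo$id == "C" & elo$date < as.Date("2015-06-01")))
})

test_that("event order in the input does not matter", {
  dem <- demog_simple(fem = c("A", "B", "C"))
  set.seed(4)
  n <- 40
  pairs <- t(sapply(1:n, function(i) sample(c("A", "B", "C"), 2)))
  ev <- data.frame(date = sort(sample(seq(as.Date("2015-01-01"),
                                          as.Date("2015-12-01"), by = "day"),
                                      n, replace = TRUE)),
                   group_id = "G", winner_id = pairs[, 1],
                   loser_id = pairs[, 2], behaviour = "avoidance",
                   sex_class = "female")
  shuffled <- ev[sample(n), ]
  e1 <- run_elo(ev, dem, start_date = "2015-01-01", end_date = "2015-12-31")
  e2 <- run_elo(shuffled, dem, start_date = "2015-01-01",
                end_date = "2015-12-31")
  expect_equal(e1, e2)
})

test_that("total rating of a closed hierarchy is conserved day by day", {
  dem <- demog_simple(fem = c("A", "B", "C", "D"))
  set.seed(5)
  n <- 60
  pairs <- t(sapply(1:n, function(i) sample(c("A", "B", "C", "D"), 2)))
  ev <- data.frame(date = sort(sample(seq(as.Date("2015-01-01"),
                                          as.Date("2015-12-01"), by = "day"),
                                      n, replace = TRUE)),
                   group_id = "G", winner_id = pairs[, 1],
                   loser_id = pairs[, 2], behaviour = "displacement",
                   sex_class = "female")
  elo <- run_elo(ev, dem, start_date = "2015-01-01", end_date = "2015-12-31")
  totals <- tapply(elo$rating[elo$sex == "F"], elo$date[elo$sex == "F"], sum)
  expect_true(all(abs(totals - 4000) < 1e-9))
})

test_that("events naming non-residents are rejected", {
  dem <- demog_simple(fem = c("A", "B"))
  ev <- data.frame(date = as.Date("2015-02-01"), group_id = "G",
                   winner_id = "A", loser_id = "ZZ",
                   behaviour = "displacement", sex_class = "female")
  expect_error(run_elo(ev, dem, start_date = "2015-01-01",
                       end_date = "2015-12-31"), "not resident")
})

test_that("yearly mean Elo averages over active days only", {
  # hand-built trajectory: 1050 for the first 100 days, 950 for the next 100
  traj <- data.frame(group_id = "G", sex = "F", id = "A",
                     date = as.Date("2015-01-01") + 0:199,
                     rating = rep(c(1050, 950), each = 100))
  class(traj) <- c("elo_daily", class(traj))
  ym <- yearly_mean_elo(traj, 2015)
  expect_equal(ym$mean_elo, 1000)
  expect_equal(ym$n_days, 200L)

  const <- data.frame(group_id = "G", sex = "F", id = "A",
                      date = seq(as.Date("2015-01-01"), as.Date("2015-12-31"),
                                 by = "day"),
                      rating = 1000)
  expect_equal(yearly_mean_elo(const, 2015)$mean_elo, 1000)

  # oracle: plain mean over a simulated trajectory's rows in the year
  dem <- demog_simple(fem = c("A", "B"))
  ev <- data.frame(date = as.Date(c("2015-03-01", "2015-08-15")),
                   group_id = "G", winner_id = c("A", "B"),
                   loser_id = c("B", "A"), behaviour = "displacement",
                   sex_class = "female")
  elo <- run_elo(ev, dem, start_date = "2015-01-01", end_date = "2015-12-31")
  ym <- yearly_mean_elo(elo, 2015)
  a_rows <- elo$rating[elo$id == "A"]
  expect_equal(ym$mean_elo[ym$id == "A"], mean(a_rows))
})

test_that("standardized ranks map linearly onto [0, 1]", {
  expect_equal(standardize_ranks(c(1200, 1000, 800)), c(1, 0.5, 0))
  expect_warning(r <- standardize_ranks(1000), "0.5")
  expect_equal(r, 0.5)
  expect_warning(standardize_ranks(c(1000, 1000)), "tied")
  set.seed(6)
  for (i in 1:50) {
    x <- rnorm(sample(2:8, 1), 1000, 150)
    r <- standardize_ranks(x)
    expect_equal(max(r), 1)
    expect_equal(min(r), 0)
    expect_equal(order(r), order(x))  # monotone in mean Elo
  }
})

test_that("dyad average rank is the symmetric midpoint", {
  expect_equal(dyad_average_rank(1, 0), 0.5)
  expect_equal(dyad_average_rank(1, 1), 1)
  set.seed(7)
  a <- runif(20); b <- runif(20)
  expect_equal(dyad_average_rank(a, b), dyad_average_rank(b, a))
  expect_error(dyad_average_rank(1.2, 0.5))
})

test_that("alpha male is the top yearly mean Elo, single male by default", {
  me <- data.frame(group_id = "G", sex = "M", id = c("M1", "M2"),
                   year = 2015, mean_elo = c(900, 1100), n_days = 365L)
  expect_equal(alpha_of_year(me, "G", 2015), "M2")
  expect_equal(alpha_of_year(me[1, ], "G", 2015), "M1")
  expect_error(alpha_of_year(me[0, ], "G", 2015), "no male")

  # simulated multimale group: alpha equals the argmax of oracle yearly means
  dem <- demog_simple(fem = c("A", "B"), males = c("M1", "M2", "M3"))
  set.seed(8)
  n <- 50
  pairs <- t(sapply(1:n, function(i) sample(c("M1", "M2", "M3"), 2)))
  ev <- data.frame(date = sort(sample(seq(as.Date("2015-01-01"),
                                          as.Date("2015-12-01"), by = "day"),
                                      n, replace = TRUE)),
                   group_id = "G", winner_id = pairs[, 1],
                   loser_id = pairs[, 2], behaviour = "displacement",
                   sex_class = "male")
  elo <- run_elo(ev, dem, start_date = "2015-01-01", end_date = "2015-12-31")
  ym <- yearly_mean_elo(elo, 2015)
  oracle <- ym$id[ym$sex == "M"][which.max(ym$mean_elo[ym$sex == "M"])]
  expect_equal(alpha_of_year(ym, "G", 2015, dem), oracle)
})

test_that("final Elo order recovers well-separated latent ranks", {
  fem <- c("F1", "F2", "F3", "F4", "F5")
  dem <- demog_simple(fem = fem)
  latents <- c(4, 2, 0, -2, -4)
  truth <- structure(list(
    females = data.frame(id = fem, group_id = "G", latent = latents,
                         std_latent = seq(1, 0, length.out = 5),
                         female_re = 0),
    males = NULL, dyads = NULL,
    years = data.frame(year = 2015, year_re = 0),
    effects = scenario_config()$effects), class = "truth")
  scen <- scenario_config(n_groups = 1, years = 1, start_year = 2015,
                          events_per_dyad_year = 30)
  set.seed(9)
  ev <- simulate_agonistic(dem, truth, scen)
  elo <- run_elo(ev[ev$sex_class == "female", ], dem,
                 start_date = "2015-01-01", end_date = "2015-12-31")
  final <- elo[elo$date == as.Date("2015-12-31"), ]
  rho <- stats::cor(final$rating[match(fem, final$id)], latents,
                    method = "spearman")
  expect_gte(rho, 0.9)
})
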