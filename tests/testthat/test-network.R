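test_that("single-scan and saturated networks tally correctly", {
  dem <- demog_simple(fem = c("A", "B"))
  w <- year_window("G", 2015)

  one <- mk_scans("A", "2015-05-01", list("B"))
  net <- build_network(one, dem, w)
  expect_equal(unname(net$focal_counts[c("A", "B")]), c(1L, 0L))
  expect_equal(net$dyads$N_ab, 1L)
  expect_equal(net$dyads$strength, 1)

  # always mutually within 5 m: N_ab = 100, strength = 1 (the upper bound)
  both <- mk_scans(rep(c("A", "B"), each = 50), rep("2015-05-01", 100),
                   c(replicate(50, "B", simplify = FALSE),
                     replicate(50, "A", simplify = FALSE)))
  net <- build_network(both, dem, w)
  expect_equal(net$dyads$N_ab, 100L)
  expect_equal(net$dyads$strength, 1)
})

test_that("dyadic strength is the simple ratio with its bounds", {
  expect_equal(dyadic_strength(0, 10, 10), 0)
  expect_equal(dyadic_strength(6, 10, 20), 0.2)
  expect_equal(dyadic_strength(100, 50, 50), 1)
  expect_warning(out <- dyadic_strength(0, 0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("node strength is the weighted degree over incident dyads", {
  dem <- demog_simple(fem = c("A", "B", "C"))
  w <- year_window("G", 2015)
  # craft counts: strengths AB = 4/20, AC = 6/20, BC = 0
  nb <- c(replicate(4, "B", simplify = FALSE),
          replicate(6, "C", simplify = FALSE))
  scans <- rbind(mk_scans(rep("A", 10), rep("2015-02-01", 10), nb),
                 mk_scans(rep("B", 10), rep("2015-02-02", 10),
                          replicate(10, character(0), simplify = FALSE)),
                 mk_scans(rep("C", 10), rep("2015-02-03", 10),
                          replicate(10, character(0), simplify = FALSE)))
  net <- build_network(scans, dem, w)
  expect_equal(net$dyads$strength[net$dyads$id1 == "A" & net$dyads$id2 == "B"], 0.2)
  expect_equal(net$dyads$strength[net$dyads$id1 == "A" & net$dyads$id2 == "C"], 0.3)
  expect_equal(node_strength(net, "A"), 0.5)
  expect_equal(node_strength(net, "B"), 0.2)
  expect_error(node_strength(net, "Z"), "not a node")

  # isolated female
  iso <- suppressWarnings(
    build_network(mk_scans(rep("A", 5), rep("2015-02-01", 5),
                           replicate(5, character(0), simplify = FALSE)),
                  dem, w))
  expect_equal(node_strength(iso, "A"), 0)
})

test_that("counts match the independent tally oracle on random scan sets", {
  fem <- c("A", "B", "C", "D", "E")
  dem <- demog_simple(fem = fem)
  w <- year_window("G", 2015)
  set.seed(11)
  for (rep in 1:5) {
    scans <- random_scans(200, fem)
    net <- build_network(scans, dem, w)
    oracle <- oracle_tally(scans, fem)
    expect_equal(net$focal_counts, oracle$N_a)
    key <- paste(net$dyads$id1, net$dyads$id2)
    expect_equal(stats::setNames(net$dyads$N_ab, key), oracle$N_ab[key])
    expect_equal(stats::setNames(net$dyads$strength, key), oracle$strength[key])
    expect_equal(net$node_strength, oracle$node_strength)
  }
})

test_that("node strength equals igraph weighted degree", {
  skip_if_not_installed("igraph")
  fem <- c("A", "B", "C", "D")
  dem <- demog_simple(fem = fem)
  set.seed(12)
  net <- build_network(random_scans(150, fem), dem, year_window("G", 2015))
  g <- igraph::graph_from_data_frame(
    net$dyads[net$dyads$strength > 0, c("id1", "id2", "strength")],
    directed = FALSE, vertices = fem)
  ig <- igraph::strength(g, weights = igraph::E(g)$strength)
  expect_equal(net$node_strength[fem], ig[fem])
})

test_that("strengths are bounded, symmetric and satisfy the sum rule", {
  fem <- c("A", "B", "C", "D")
  dem <- demog_simple(fem = fem)
  w <- year_window("G", 2015)
  set.seed(13)
  for (rep in 1:40) {
    net <- suppressWarnings(
      build_network(random_scans(sample(20:80, 1), fem,
                                 p = runif(1, 0.05, 0.6)), dem, w))
    s <- net$dyads$strength[!is.na(net$dyads$strength)]
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(net$dyads$N_ab <= net$dyads$N_a + net$dyads$N_b))
    expect_equal(sum(net$node_strength), 2 * sum(s))
    expect_true(all(net$node_strength <= length(fem) - 1))
    # symmetry: the tally does not depend on member order
    rev_key <- paste(net$dyads$id2, net$dyads$id1)
    expect_equal(anyDuplicated(c(paste(net$dyads$id1, net$dyads$id2), rev_key)), 0)
  }
})

test_that("counts are additive over a partition of the window", {
  fem <- c("A", "B", "C")
  dem <- demog_simple(fem = fem)
  set.seed(14)
  scans <- random_scans(120, fem)
  full <- build_network(scans, dem, year_window("G", 2015))
  h1 <- build_network(scans, dem,
                      window_spec("G", "2015-01-01", "2015-07-01"))
  h2 <- build_network(scans, dem,
                      window_spec("G", "2015-07-01", "2016-01-01"))
  key <- function(n) paste(n$dyads$id1, n$dyads$id2)
  expect_equal(full$dyads$N_ab,
               h1$dyads$N_ab[match(key(full), key(h1))] +
                 h2$dyads$N_ab[match(key(full), key(h2))])
  expect_equal(full$focal_counts, h1$focal_counts + h2$focal_counts)
})

test_that("empty windows warn and under-sampled females can be dropped", {
  dem <- demog_simple(fem = c("A", "B"))
  scans <- mk_scans("A", "2015-05-01", list("B"))
  w16 <- testthat::capture_warnings(
    net <- build_network(scans, dem, year_window("G", 2016)))
  expect_true(any(grepl("no scans", w16)))
  expect_equal(nrow(net$dyads), 1L)
  expect_equal(net$dyads$N_ab, 0L)

  net <- build_network(scans, dem, year_window("G", 2015), min_focals = 1)
  expect_equal(net$nodes, "A")
})

test_that("partial co-residency scales the dyad denominator, not the node count", {
  individuals <- data.frame(id = c("A", "B"), sex = "F",
                            birth_date = as.Date("2000-01-01"))
  tenures <- data.frame(
    id = c("A", "B"), group_id = "G",
    entry_date = as.Date(c("2014-01-01", "2015-07-01")),
    entry_type = c("natal", "immigration"),
    exit_date = as.Date(NA), exit_type = NA_character_)
  dem <- demography_table(individuals, tenures)
  # A focal 10x in spring (B absent), 10x in autumn (B present, 4 joint)
  nb <- c(replicate(10, character(0), simplify = FALSE),
          c(replicate(4, "B", simplify = FALSE),
            replicate(6, character(0), simplify = FALSE)))
  scans <- mk_scans(rep("A", 20),
                    c(rep("2015-03-01", 10), rep("2015-09-01", 10)), nb)
  net <- build_network(scans, dem, year_window("G", 2015))
  expect_equal(unname(net$focal_counts["A"]), 20L)     # node-level count
  expect_equal(net$dyads$N_a, 10L)                     # joint-exposure scans
  expect_equal(net$dyads$strength, 4 / 10)
})
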