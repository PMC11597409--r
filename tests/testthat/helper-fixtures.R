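# Shared fixture builders and independent oracles. Everything is generated in
# code; no stored data.

# A minimal hand-built group: adult females (natal, resident for the whole
# span) plus one adult male.
demog_simple <- function(fem = c("A", "B", "C"), group = "G",
                         entry = "2014-01-01", males = "M1",
                         offspring = NULL) {
  ids <- c(fem, males)
  individuals <- data.frame(
    id = ids, sex = c(rep("F", length(fem)), rep("M", length(males))),
    birth_date = as.Date("2000-01-01"))
  tenures <- data.frame(
    id = ids, group_id = group, entry_date = as.Date(entry),
    entry_type = "natal", exit_date = as.Date(NA), exit_type = NA_character_)
  demography_table(individuals, tenures, offspring = offspring)
}

# quick scan-table builder: neighbors given as list of character vectors
mk_scans <- function(focal, date, neighbors, group = "G") {
  data.frame(scan_id = sprintf("S%04d", seq_along(focal)),
             date = as.Date(date), time = "08:00", group_id = group,
             focal_id = focal, activity = "feeding",
             neighbors_5m = vapply(neighbors, paste, character(1),
                                   collapse = ";"))
}

# Independent row-by-row tally of N_a, N_ab and the simple-ratio strengths;
# deliberately written as an explicit loop, unlike the vectorised build.
oracle_tally <- function(scans, nodes) {
  N_a <- stats::setNames(rep(0L, length(nodes)), nodes)
  pairs <- t(utils::combn(sort(nodes), 2))
  N_ab <- stats::setNames(rep(0L, nrow(pairs)),
                          paste(pairs[, 1], pairs[, 2]))
  for (r in seq_len(nrow(scans))) {
    f <- scans$focal_id[r]
    if (!f %in% nodes) next
    N_a[f] <- N_a[f] + 1L
    nb <- strsplit(scans$neighbors_5m[r], ";", fixed = TRUE)[[1]]
    for (p in nb[nb %in% nodes]) {
      k <- paste(min(f, p), max(f, p))
      N_ab[k] <- N_ab[k] + 1L
    }
  }
  strength <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tot <- N_a[pairs[i, 1]] + N_a[pairs[i, 2]]
    strength[i] <- if (tot > 0) N_ab[i] / tot else NA_real_
  }
  node_strength <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in seq_len(nrow(pairs))) {
    if (is.na(strength[i])) next
    node_strength[pairs[i, 1]] <- node_strength[pairs[i, 1]] + strength[i]
    node_strength[pairs[i, 2]] <- node_strength[pairs[i, 2]] + strength[i]
  }
  list(N_a = N_a, N_ab = N_ab, strength = stats::setNames(strength, names(N_ab)),
       node_strength = node_strength)
}

# random scan table over a fixed female set (for property checks)
random_scans <- function(n, fem, date_range = c("2015-01-01", "2015-12-31"),
                         p = 0.3) {
  dates <- as.Date(date_range)
  focal <- sample(fem, n, replace = TRUE)
  neighbors <- lapply(focal, function(f) {
    others <- setdiff(fem, f)
    others[stats::runif(length(others)) < p]
  })
  mk_scans(focal, sample(seq(dates[1], dates[2], by = "day"), n, replace = TRUE),
           neighbors)
}

# tiny but fit-capable scenario for pipeline smoke tests
tiny_scenario <- function(...) {
  scenario_config(n_groups = 2, years = 3, females_per_group = c(4, 5),
                  focals_per_female_year = c(40, 10), ...)
}
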