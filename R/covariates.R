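#' Dependent-infant flag
#'
#' A female is deemed to have a dependent infant in a calendar year when she
#' has an offspring aged under 12 months (< 365 days) on strictly more than
#' 183 days of that year ("more than 6 months").
#'
#' @param female female id.
#' @param year calendar year.
#' @param demography a [demography_table()].
#' @return logical.
#' @export
flag_dependent_infant <- function(female, year, demography) {
  b <- demography$offspring$birth_date[demography$offspring$mother_id == female]
  if (!length(b)) return(FALSE)
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-01-01", year + 1))
  days <- 0
  for (bd in as.list(b)) {
    lo <- max(as.numeric(y0), as.numeric(bd))
    hi <- min(as.numeric(y1), as.numeric(bd) + 365)
    days <- days + max(hi - lo, 0)
  }
  days > 183
}

# first calendar year for which an immigration tenure is scored: the entry
# year when entry is on or before the cutoff (default 1 July), else the
# following year. NA for natal tenures.
first_scored_year <- function(entry_date, entry_type, cutoff_month_day = "07-01") {
  if (entry_type != "immigration") return(NA_integer_)
  y <- as.integer(format(entry_date, "%Y"))
  cutoff <- as.Date(sprintf("%d-%s", y, cutoff_month_day))
  if (entry_date <= cutoff) y else y + 1L
}

#' New-immigrant flag
#'
#' A female joining a group is termed an immigrant for her first scored year
#' there. Because association scores are yearly, a female joining in the
#' first half of the year is scored (and flagged) for that year; a female
#' joining after the mid-year cutoff gets her first score - and the flag -
#' the following year, and her entry year is excluded from scoring entirely.
#' Natal females are never flagged.
#'
#' @inheritParams flag_dependent_infant
#' @param cutoff_month_day mid-year cutoff as "MM-DD" (default "07-01").
#' @export
flag_new_immigrant <- function(female, year, demography,
                               cutoff_month_day = "07-01") {
  tt <- demography$tenures
  tt <- tt[tt$id == female & tt$entry_type == "immigration", , drop = FALSE]
  if (!nrow(tt)) return(FALSE)
  any(vapply(seq_len(nrow(tt)), function(i)
    identical(first_scored_year(tt$entry_date[i], "immigration",
                                cutoff_month_day), as.integer(year)),
    logical(1L)))
}

#' Last-year-in-group flag
#'
#' TRUE when the female emigrates (not dies, not censored) from the group in
#' the following calendar year.
#'
#' @inheritParams flag_dependent_infant
#' @param group_id group label.
#' @export
flag_last_year <- function(female, year, demography, group_id = NULL) {
  tt <- demography$tenures
  tt <- tt[tt$id == female & !is.na(tt$exit_type) &
             tt$exit_type == "emigration", , drop = FALSE]
  if (!is.null(group_id)) tt <- tt[tt$group_id == group_id, , drop = FALSE]
  if (!nrow(tt)) return(FALSE)
  any(as.integer(format(tt$exit_date, "%Y")) == year + 1L)
}

#' New-alpha-male flag
#'
#' Did the alpha male change in the previous 12 months? The default
#' comparison is year-over-year identity of the alpha: the flag for `year` is
#' TRUE when the alpha of `year` differs from the alpha of `year - 1`.
#' Undefined (NA) when either year's alpha is unknown; rows with an undefined
#' flag are dropped from the model tables.
#'
#' @param group_id group label.
#' @param year calendar year.
#' @param alpha_assignments data.frame with columns group_id, year, alpha_id
#'   (e.g. derived from [rank_table()]).
#' @export
flag_new_alpha <- function(group_id, year, alpha_assignments) {
  a <- alpha_assignments
  cur <- a$alpha_id[a$group_id == group_id & a$year == year]
  prev <- a$alpha_id[a$group_id == group_id & a$year == year - 1L]
  if (length(cur) != 1L || length(prev) != 1L) return(NA)
  cur != prev
}

# weaned individuals resident for the majority (> half the days) of the year.
# adults_only drops weaned immatures; simulated studies contain none, so the
# distinction only matters for field data.
majority_residents <- function(demography, group_id, year, sex = NULL,
                               adults_only = TRUE) {
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-01-01", year + 1))
  ids <- residents_in_window(demography, group_id, y0, y1, sex = sex)
  ndays <- as.numeric(y1 - y0)
  ids <- ids[vapply(ids, function(i)
    residency_days(demography, i, group_id, y0, y1) > ndays / 2, logical(1L))]
  if (adults_only && length(ids)) {
    bd <- demography$individuals$birth_date[match(ids, demography$individuals$id)]
    ids <- ids[as.numeric(y1 - bd) / 365.25 > 10]
  }
  ids
}

#' Assemble analysis-ready model tables
#'
#' Joins the yearly network scores, standardized ranks and demographic flags
#' into one individual-year table (response: node strength) and one dyad-year
#' table (response: dyadic strength). Group size is the number of weaned
#' adults (males and females) resident for the majority of the year; female
#' number counts the adult females. Rows are dropped, with a message, when a
#' predictor is undefined: no scans for the female that year, unknown alpha
#' history (the first observed year of each group), unknown rank, or an
#' immigrant's unscored entry year.
#'
#' @param networks output of [yearly_networks()].
#' @param ranks output of [rank_table()].
#' @param demography a [demography_table()].
#' @param alpha_assignments optional data.frame (group_id, year, alpha_id);
#'   derived from `ranks` when NULL.
#' @param cutoff_month_day mid-year cutoff for immigrant scoring.
#' @return list with data.frames `individual` and `dyad`.
#' @export
build_model_tables <- function(networks, ranks, demography,
                               alpha_assignments = NULL,
                               cutoff_month_day = "07-01") {
  if (is.null(alpha_assignments)) {
    m <- ranks[ranks$sex == "M" & !is.na(ranks$is_alpha) & ranks$is_alpha, ,
               drop = FALSE]
    alpha_assignments <- data.frame(group_id = m$group_id, year = m$year,
                                    alpha_id = m$id)
  }
  nodes <- networks$nodes
  dyads <- networks$dyads
  if (is.null(nodes) || !nrow(nodes)) stop("no network node scores supplied")

  scored <- function(id, year) {
    # is this female's year scored at all? (mid-year immigrants skip entry year)
    tt <- demography$tenures[demography$tenures$id == id, , drop = FALSE]
    ok <- TRUE
    for (i in seq_len(nrow(tt))) {
      if (tt$entry_type[i] != "immigration") next
      ey <- as.integer(format(tt$entry_date[i], "%Y"))
      fy <- first_scored_year(tt$entry_date[i], "immigration", cutoff_month_day)
      if (year == ey && fy > ey) ok <- FALSE
    }
    ok
  }

  ind <- list(); dropped_i <- 0L
  for (r in seq_len(nrow(nodes))) {
    g <- nodes$group_id[r]; y <- nodes$year[r]; id <- nodes$id[r]
    if (nodes$n_focals[r] == 0 || !scored(id, y)) { dropped_i <- dropped_i + 1L; next }
    rk <- ranks$std_rank[ranks$group_id == g & ranks$year == y & ranks$id == id]
    na_flag <- flag_new_alpha(g, y, alpha_assignments)
    if (length(rk) != 1L || is.na(rk) || is.na(na_flag)) {
      dropped_i <- dropped_i + 1L; next
    }
    tt <- demography$tenures
    tt <- tt[tt$id == id & tt$group_id == g, , drop = FALSE]
    entry <- min(tt$entry_date)
    ind[[length(ind) + 1L]] <- data.frame(
      group_id = g, year = y, id = id, strength = nodes$strength[r],
      dominance_rank = rk,
      dependent_infant = flag_dependent_infant(id, y, demography),
      new_immigrant = flag_new_immigrant(id, y, demography, cutoff_month_day),
      tenure = as.numeric(as.Date(sprintf("%d-12-31", y)) - entry) / 365.25,
      new_alpha_male = na_flag,
      last_year_in_group = flag_last_year(id, y, demography, g),
      female_number = length(majority_residents(demography, g, y, sex = "F")),
      group_size = length(majority_residents(demography, g, y)))
  }
  if (dropped_i) message(dropped_i, " individual-year row(s) dropped ",
                         "(no scans, undefined rank/alpha, or unscored entry year)")
  individual <- if (length(ind)) do.call(rbind, ind) else NULL

  dy <- list(); dropped_d <- 0L
  if (!is.null(dyads)) for (r in seq_len(nrow(dyads))) {
    g <- dyads$group_id[r]; y <- dyads$year[r]
    a <- dyads$id1[r]; b <- dyads$id2[r]
    if (is.na(dyads$strength[r]) || !scored(a, y) || !scored(b, y)) {
      dropped_d <- dropped_d + 1L; next
    }
    rka <- ranks$std_rank[ranks$group_id == g & ranks$year == y & ranks$id == a]
    rkb <- ranks$std_rank[ranks$group_id == g & ranks$year == y & ranks$id == b]
    na_flag <- flag_new_alpha(g, y, alpha_assignments)
    if (length(rka) != 1L || length(rkb) != 1L || is.na(rka) || is.na(rkb) ||
        is.na(na_flag)) {
      dropped_d <- dropped_d + 1L; next
    }
    ia <- flag_dependent_infant(a, y, demography)
    ib <- flag_dependent_infant(b, y, demography)
    dy[[length(dy) + 1L]] <- data.frame(
      group_id = g, year = y, id1 = a, id2 = b,
      dyad_id = paste(a, b, sep = "_"),
      strength = dyads$strength[r],
      rank_average = dyad_average_rank(rka, rkb),
      dependent_infant_cat = if (ia && ib) "both" else if (ia || ib) "one" else "none",
      new_immigrant = flag_new_immigrant(a, y, demography, cutoff_month_day) ||
        flag_new_immigrant(b, y, demography, cutoff_month_day),
      new_alpha_male = na_flag,
      female_number = length(majority_residents(demography, g, y, sex = "F")),
      group_size = length(majority_residents(demography, g, y)))
  }
  if (dropped_d) message(dropped_d, " dyad-year row(s) dropped")
  dyad <- if (length(dy)) do.call(rbind, dy) else NULL
  if (!is.null(individual)) rownames(individual) <- NULL
  if (!is.null(dyad)) rownames(dyad) <- NULL
  list(individual = individual, dyad = dyad)
}
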