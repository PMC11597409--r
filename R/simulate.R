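#' Scenario configuration for the synthetic study generator
#'
#' Describes a multi-year, multi-group observational study of adult female
#' gorillas: group sizes and focal-sampling effort on the scale of the study
#' populations (2-7 females per group, roughly 80-160 focal observations per
#' female per year, 2-6 ten-minute scans per focal), demographic turnover
#' (births, immigration, emigration, alpha-male change), and the latent social
#' structure whose effects the analysis is meant to recover.
#'
#' Proximity is generated focal-centrically: at each scan every co-resident
#' adult female is within 5 m of the focal with probability
#' `plogis(beta0 + dyad affinity + beta_rank_avg * mean standardized latent
#' rank + infant terms + beta_immigrant * either-recent-immigrant + both
#' females' random effects + year random effect)`. Symmetry of the dyadic
#' index is emergent, not imposed per scan.
#'
#' Default demographic rates are on the scale realized in long-term gorilla
#' study groups (roughly 0.15 births and 0.05 transfers per female-year, one
#' alpha change per group-decade); default
#' effect sizes are the generator's reference condition: a +1 logit boost when
#' both females have a dependent infant, a -1 logit penalty when either is a
#' recent immigrant, and a +0.5 logit rank-homophily slope.
#'
#' @param n_groups number of social groups.
#' @param years number of study years.
#' @param start_year first calendar year (January 1 is the study start).
#' @param females_per_group length-2 range; the initial number of adult
#'   females per group is drawn uniformly from it.
#' @param focals_per_female_year c(mean, sd) of the yearly number of focal
#'   observations per female (truncated below at 5, scaled by residency).
#' @param scans_per_focal length-2 integer range of 10-min scans per focal
#'   (must lie in 1..6, i.e. focal durations of 15-60 min).
#' @param males_per_group initial number of adult males per group (a single
#'   male is the alpha by default).
#' @param male_change_rate per-group-year probability that the subordinate
#'   male membership changes (a male joins, or a non-alpha male departs);
#'   gives the weaned-adult group size variation seen in real groups.
#' @param latent_rank_sd sd of the latent dominance scale.
#' @param birth_rate,immigration_rate,emigration_rate per-female-year event
#'   probabilities; `alpha_turnover_rate` is per-group-year.
#' @param events_per_dyad_year expected agonistic events per co-resident
#'   same-sex dyad per year.
#' @param effects named list of logit-scale generative parameters: `beta0`
#'   (baseline log-odds of being within 5 m), `beta_rank_avg`,
#'   `beta_both_infant`, `beta_one_infant`, `beta_immigrant`,
#'   `dyad_affinity_sd`, `female_re_sd`, `year_re_sd`.
#' @param seed integer seed applied by [simulate_study()].
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_groups = 3, years = 8, start_year = 2013,
                            females_per_group = c(2, 7),
                            focals_per_female_year = c(100, 50),
                            scans_per_focal = c(2, 6),
                            males_per_group = 2,
                            latent_rank_sd = 1,
                            birth_rate = 0.15,
                            immigration_rate = 0.06,
                            emigration_rate = 0.05,
                            alpha_turnover_rate = 0.10,
                            male_change_rate = 0.4,
                            events_per_dyad_year = 12,
                            effects = list(),
                            seed = NULL) {
  eff <- list(beta0 = stats::qlogis(0.08), beta_rank_avg = 0.5,
              beta_both_infant = 1.0, beta_one_infant = 0.0,
              beta_immigrant = -1.0, dyad_affinity_sd = 0.3,
              female_re_sd = 0.2, year_re_sd = 0.1)
  unknown <- setdiff(names(effects), names(eff))
  if (length(unknown)) stop("unknown effect(s): ", paste(unknown, collapse = ", "))
  eff[names(effects)] <- effects
  rates <- c(birth_rate = birth_rate, immigration_rate = immigration_rate,
             emigration_rate = emigration_rate,
             alpha_turnover_rate = alpha_turnover_rate,
             male_change_rate = male_change_rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (scans_per_focal[1] < 1 || scans_per_focal[2] > 6)
    stop("scans_per_focal must lie within 1..6")
  if (females_per_group[1] < 2)
    stop("females_per_group lower bound below 2: groups would be empty of dyads")
  # scenario error when the rates imply groups dwindling below 2 females
  n0 <- mean(females_per_group)
  if (n0 * (1 + immigration_rate - emigration_rate)^years < 2)
    stop("scenario implies expected female count below 2 by the final year")
  structure(list(n_groups = n_groups, years = years, start_year = start_year,
                 females_per_group = females_per_group,
                 focals_per_female_year = focals_per_female_year,
                 scans_per_focal = scans_per_focal,
                 males_per_group = males_per_group,
                 latent_rank_sd = latent_rank_sd,
                 birth_rate = birth_rate, immigration_rate = immigration_rate,
                 emigration_rate = emigration_rate,
                 alpha_turnover_rate = alpha_turnover_rate,
                 male_change_rate = male_change_rate,
                 events_per_dyad_year = events_per_dyad_year,
                 effects = eff, seed = seed),
            class = "scenario_config")
}

#' Study span of a scenario
#'
#' First day of the study (1 January of the start year) and the exclusive
#' end day (1 January after the final year).
#'
#' @param scenario a [scenario_config()].
#' @return a Date.
#' @export
study_start <- function(scenario) as.Date(sprintf("%d-01-01", scenario$start_year))

#' @rdname study_start
#' @export
study_end <- function(scenario)
  as.Date(sprintf("%d-01-01", scenario$start_year + scenario$years))

# size-safe uniform draw (sample() treats a length-1 vector as 1:n)
pick1 <- function(v) v[sample.int(length(v), 1L)]

runif_date <- function(n, from, to) {
  # uniform integer day in [from, to)
  from <- as.numeric(as.Date(from)); to <- as.numeric(as.Date(to))
  as.Date(from + floor(stats::runif(n) * (to - from)), origin = "1970-01-01")
}

#' Simulate the demography of a multi-group study
#'
#' Produces individuals, tenures, offspring births and alpha tenures. Each
#' group starts with a uniform draw of adult females from the configured
#' range. Year by year, resident females emigrate, give birth (never twice
#' within 365 days, and not in their arrival year) and new adult females
#' immigrate; the alpha male may be replaced. Groups are never allowed to
#' fall below two females through emigration. Offspring are never promoted to
#' adulthood within a study span, so mother-adult-daughter co-residence does
#' not arise (matching the study populations).
#'
#' @param scenario a [scenario_config()].
#' @return a [demography_table()].
#' @export
simulate_demography <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  start <- study_start(scenario); end <- study_end(scenario)
  individuals <- list(); tenures <- list(); offspring <- list(); alphas <- list()
  add_ind <- function(id, sex, birth) {
    individuals[[length(individuals) + 1L]] <<-
      data.frame(id = id, sex = sex, birth_date = birth)
  }
  add_ten <- function(id, g, entry, type) {
    tenures[[length(tenures) + 1L]] <<- data.frame(
      id = id, group_id = g, entry_date = entry, entry_type = type,
      exit_date = as.Date(NA), exit_type = NA_character_)
  }

  for (g in seq_len(scenario$n_groups)) {
    gid <- sprintf("G%d", g)
    n0 <- pick1(seq(scenario$females_per_group[1],
                    scenario$females_per_group[2]))
    counter <- 0L
    new_fid <- function() {
      counter <<- counter + 1L
      sprintf("%sF%02d", gid, counter)
    }
    for (k in seq_len(n0)) {
      id <- new_fid()
      add_ind(id, "F", start - round(stats::runif(1, 10 * 365.25, 30 * 365.25)))
      add_ten(id, gid, start - sample(365:3650, 1L),
              sample(c("natal", "immigration"), 1L, prob = c(0.3, 0.7)))
    }
    # males: one alpha (plus subordinates in the multimale setting)
    mcount <- 0L
    new_mid <- function() {
      mcount <<- mcount + 1L
      sprintf("%sM%02d", gid, mcount)
    }
    for (k in seq_len(max(1L, scenario$males_per_group))) {
      id <- new_mid()
      add_ind(id, "M", start - round(stats::runif(1, 12 * 365.25, 30 * 365.25)))
      add_ten(id, gid, start - sample(365:3650, 1L), "natal")
    }
    alpha_id <- sprintf("%sM01", gid)
    alpha_since <- start - 365

    last_birth <- list()  # per mother, most recent offspring date
    open_exit <- function(id) {
      for (j in seq_along(tenures))
        if (tenures[[j]]$id == id && is.na(tenures[[j]]$exit_date)) return(j)
      NA_integer_
    }
    n_open_females <- function() {
      sum(vapply(tenures, function(t)
        t$group_id == gid && is.na(t$exit_date) && grepl("F\\d+$", t$id),
        logical(1L)))
    }
    for (y in seq_len(scenario$years)) {
      y0 <- as.Date(sprintf("%d-01-01", scenario$start_year + y - 1L))
      y1 <- as.Date(sprintf("%d-01-01", scenario$start_year + y))
      fem_jan1 <- sort(unlist(lapply(tenures, function(t)
        if (t$group_id == gid && grepl("F\\d+$", t$id) &&
            t$entry_date <= y0 && is.na(t$exit_date)) t$id)))
      # emigrations first so that later draws respect the exit date
      for (f in fem_jan1) {
        if (stats::runif(1) < scenario$emigration_rate && n_open_females() > 2L) {
          j <- open_exit(f)
          tenures[[j]]$exit_date <- runif_date(1, y0 + 1, y1)
          tenures[[j]]$exit_type <- "emigration"
        }
      }
      # births within residency, spaced >= 365 days, not in arrival year
      for (f in fem_jan1) {
        if (stats::runif(1) < scenario$birth_rate) {
          j <- open_exit(f)
          ex <- if (is.na(j)) {
            jj <- which(vapply(tenures, function(t)
              t$id == f && t$group_id == gid, logical(1L)))
            tenures[[utils::tail(jj, 1L)]]$exit_date
          } else NA
          hi <- min(y1, if (is.na(ex)) y1 else ex)
          if (hi > y0) {
            b <- runif_date(1, y0, hi)
            prev <- last_birth[[f]]
            if (is.null(prev) || abs(as.numeric(b - prev)) >= 365) {
              offspring[[length(offspring) + 1L]] <-
                data.frame(mother_id = f, birth_date = b)
              last_birth[[f]] <- b
            }
          }
        }
      }
      # immigrations: binomial on the Jan-1 female count
      k_imm <- stats::rbinom(1L, length(fem_jan1), scenario$immigration_rate)
      for (k in seq_len(k_imm)) {
        id <- new_fid()
        entry <- runif_date(1, y0, y1)
        add_ind(id, "F", entry - round(stats::runif(1, 10 * 365.25, 20 * 365.25)))
        add_ten(id, gid, entry, "immigration")
      }
      # subordinate male membership change (join or departure)
      if (stats::runif(1) < scenario$male_change_rate) {
        mdate <- runif_date(1, y0, y1)
        males_now <- unlist(lapply(tenures, function(t)
          if (t$group_id == gid && grepl("M\\d+$", t$id) &&
              t$entry_date <= mdate && is.na(t$exit_date)) t$id))
        subs <- setdiff(males_now, alpha_id)
        if (stats::runif(1) < 0.5 || !length(subs)) {
          id <- new_mid()
          add_ind(id, "M", mdate - round(stats::runif(1, 12 * 365.25, 25 * 365.25)))
          add_ten(id, gid, mdate, "immigration")
        } else {
          j <- open_exit(pick1(subs))
          tenures[[j]]$exit_date <- mdate
          tenures[[j]]$exit_type <- "emigration"
        }
      }
      # alpha-male turnover: sitting alpha dies/disappears, successor recorded
      if (stats::runif(1) < scenario$alpha_turnover_rate) {
        tdate <- runif_date(1, y0, y1)
        j <- open_exit(alpha_id)
        if (!is.na(j)) {
          tenures[[j]]$exit_date <- tdate
          tenures[[j]]$exit_type <- "death"
        }
        alphas[[length(alphas) + 1L]] <- data.frame(
          id = alpha_id, group_id = gid, start_date = alpha_since,
          end_date = tdate)
        # succession: longest-tenured remaining male, else a new male
        males_now <- unlist(lapply(tenures, function(t)
          if (t$group_id == gid && grepl("M\\d+$", t$id) &&
              t$entry_date <= tdate && is.na(t$exit_date)) t$id))
        if (length(males_now)) {
          alpha_id <- sort(males_now)[1L]
        } else {
          alpha_id <- new_mid()
          add_ind(alpha_id, "M",
                  tdate - round(stats::runif(1, 12 * 365.25, 25 * 365.25)))
          add_ten(alpha_id, gid, tdate, "immigration")
        }
        alpha_since <- tdate
      }
    }
    alphas[[length(alphas) + 1L]] <- data.frame(
      id = alpha_id, group_id = gid, start_date = alpha_since,
      end_date = as.Date(NA))
  }
  demography_table(do.call(rbind, individuals), do.call(rbind, tenures),
                   if (length(offspring)) do.call(rbind, offspring),
                   do.call(rbind, alphas))
}

#' Draw the latent social structure underlying a simulated study
#'
#' Latent dominance values are drawn once per individual (female rank order
#' rarely changes in these populations, so ranks are static within tenure);
#' females immigrating during the study enter below the current group minimum,
#' mirroring bottom entry into the hierarchy. Dyad affinities and female/year
#' random effects are the residual social structure of the proximity process.
#'
#' @param demography output of [simulate_demography()].
#' @param scenario the same [scenario_config()].
#' @return a list of class `truth` with elements `females` (id, group_id,
#'   latent, std_latent, female_re), `males`, `dyads` (id1, id2, group_id,
#'   affinity), `years` (year, year_re) and `effects`.
#' @export
simulate_truth <- function(demography, scenario) {
  eff <- scenario$effects
  start <- study_start(scenario)
  ten <- demography$tenures
  fem <- list(); mal <- list(); dy <- list()
  for (gid in sort(unique(ten$group_id))) {
    tg <- ten[ten$group_id == gid, , drop = FALSE]
    sex <- demography$individuals$sex[match(tg$id, demography$individuals$id)]
    fids <- unique(tg$id[sex == "F"][order(tg$entry_date[sex == "F"])])
    lat <- numeric(0)
    for (i in seq_along(fids)) {
      row <- tg[tg$id == fids[i], , drop = FALSE][1L, ]
      if (row$entry_type == "immigration" && row$entry_date >= start &&
          length(lat)) {
        l <- min(lat) - abs(stats::rnorm(1, 0, scenario$latent_rank_sd / 2))
      } else {
        l <- stats::rnorm(1, 0, scenario$latent_rank_sd)
      }
      lat <- c(lat, l)
    }
    std <- if (length(lat) > 1 && diff(range(lat)) > 0)
      (lat - min(lat)) / diff(range(lat)) else rep(0.5, length(lat))
    fem[[gid]] <- data.frame(id = fids, group_id = gid, latent = lat,
                             std_latent = std,
                             female_re = stats::rnorm(length(fids), 0,
                                                      eff$female_re_sd))
    mids <- sort(unique(tg$id[sex == "M"]))
    if (length(mids)) {
      # male dominance follows entry seniority (queue-like succession), so
      # the Elo-derived alpha agrees with the recorded alpha tenures
      entry <- vapply(mids, function(i)
        min(as.numeric(tg$entry_date[tg$id == i])), numeric(1))
      sen <- rank(entry, ties.method = "first")
      mal[[gid]] <- data.frame(id = mids, group_id = gid,
                               latent = scenario$latent_rank_sd *
                                 (length(mids) - sen))
    }
    if (length(fids) > 1) {
      cmb <- utils::combn(sort(fids), 2)
      dy[[gid]] <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ], group_id = gid,
                              affinity = stats::rnorm(ncol(cmb), 0,
                                                      eff$dyad_affinity_sd))
    }
  }
  yrs <- seq(scenario$start_year, scenario$start_year + scenario$years - 1L)
  structure(list(females = do.call(rbind, fem), males = do.call(rbind, mal),
                 dyads = do.call(rbind, dy),
                 years = data.frame(year = yrs,
                                    year_re = stats::rnorm(length(yrs), 0,
                                                           eff$year_re_sd)),
                 effects = eff),
            class = "truth")
}

#' Simulate agonistic events from latent dominance values
#'
#' For every co-resident same-sex dyad and year, a Poisson number of dated
#' displacement/avoidance events is drawn (expectation `events_per_dyad_year`
#' scaled by co-residency); in each event the first member wins with
#' probability `plogis(latent_1 - latent_2)`.
#'
#' @inheritParams simulate_truth
#' @param truth output of [simulate_truth()].
#' @return data.frame of agonistic events (may have zero rows).
#' @export
simulate_agonistic <- function(demography, truth, scenario) {
  start <- study_start(scenario); end <- study_end(scenario)
  lat_tab <- rbind(truth$females[c("id", "group_id", "latent")],
                   if (!is.null(truth$males)) truth$males)
  ten <- demography$tenures
  out <- list()
  for (gid in sort(unique(ten$group_id))) {
    for (sx in c("F", "M")) {
      ids <- residents_in_window(demography, gid, start, end, sex = sx)
      if (length(ids) < 2) next
      cmb <- utils::combn(sort(ids), 2)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        iv <- coresidency(demography, a, b, gid, start, end)
        if (is.null(iv)) next
        days <- as.numeric(iv[2] - iv[1])
        n <- stats::rpois(1, scenario$events_per_dyad_year * days / 365)
        if (!n) next
        dates <- sort(runif_date(n, iv[1], iv[2]))
        la <- lat_tab$latent[lat_tab$id == a & lat_tab$group_id == gid]
        lb <- lat_tab$latent[lat_tab$id == b & lat_tab$group_id == gid]
        a_wins <- stats::runif(n) < stats::plogis(la - lb)
        out[[length(out) + 1L]] <- data.frame(
          date = dates, group_id = gid,
          winner_id = ifelse(a_wins, a, b), loser_id = ifelse(a_wins, b, a),
          behaviour = sample(c("displacement", "avoidance"), n, replace = TRUE),
          sex_class = if (sx == "F") "female" else "male")
      }
    }
  }
  if (!length(out))
    return(data.frame(date = as.Date(character()), group_id = character(),
                      winner_id = character(), loser_id = character(),
                      behaviour = character(), sex_class = character()))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$date, ev$group_id, ev$winner_id, ev$loser_id), ]
  rownames(ev) <- NULL
  ev
}

# overlap of two individuals' residency in a group, clipped to [start, end);
# NULL if they never co-reside
coresidency <- function(demography, a, b, gid, start, end) {
  tt <- demography$tenures
  iv <- function(id) {
    ti <- tt[tt$id == id & tt$group_id == gid, , drop = FALSE]
    cbind(as.numeric(ti$entry_date),
          ifelse(is.na(ti$exit_date), Inf, as.numeric(ti$exit_date)))
  }
  ia <- iv(a); ib <- iv(b)
  lo <- as.numeric(as.Date(start)); hi <- as.numeric(as.Date(end))
  best <- NULL
  for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
    s <- max(ia[i, 1], ib[j, 1], lo); e <- min(ia[i, 2], ib[j, 2], hi)
    if (e > s) best <- c(s, e)  # simulated histories have one tenure each
  }
  if (is.null(best)) return(NULL)
  as.Date(best, origin = "1970-01-01")
}

#' Simulate focal scan records
#'
#' Focal observation follows the field protocol: each resident female receives
#' a yearly number of focal follows (Gaussian around the configured mean,
#' scaled by her residency fraction), each focal comprises 2-6 instantaneous
#' scans at 10-minute intervals, and at every scan each co-resident adult
#' female independently falls within 5 m of the focal with the logistic
#' probability described in [scenario_config()].
#'
#' @inheritParams simulate_agonistic
#' @return data.frame of scan records (columns of [read_scans()]).
#' @export
simulate_scans <- function(demography, truth, scenario) {
  eff <- truth$effects
  start <- study_start(scenario)
  ten <- demography$tenures
  off <- demography$offspring
  groups <- sort(unique(truth$females$group_id))
  out <- list()
  counter <- 0L
  for (gid in groups) {
    ft <- truth$females[truth$females$group_id == gid, , drop = FALSE]
    for (y in seq_len(scenario$years)) {
      yr <- scenario$start_year + y - 1L
      y0 <- as.Date(sprintf("%d-01-01", yr))
      y1 <- as.Date(sprintf("%d-01-01", yr + 1L))
      fids <- residents_in_window(demography, gid, y0, y1, sex = "F",
                                  adult_only = TRUE)
      if (length(fids) < 2) next
      # one scan row per (focal, scan)
      rows <- list()
      for (f in fids) {
        frac <- residency_days(demography, f, gid, y0, y1) / 365
        if (frac <= 0) next
        nf <- round(max(5, stats::rnorm(1, scenario$focals_per_female_year[1],
                                        scenario$focals_per_female_year[2])) * frac)
        if (nf < 1) next
        tt <- ten[ten$id == f & ten$group_id == gid, , drop = FALSE][1L, ]
        lo <- max(y0, tt$entry_date)
        hi <- min(y1, if (is.na(tt$exit_date)) y1 else tt$exit_date)
        fdates <- runif_date(nf, lo, hi)
        nsc <- sample(seq(scenario$scans_per_focal[1],
                          scenario$scans_per_focal[2]), nf, replace = TRUE)
        hrs <- sample(7:14, nf, replace = TRUE)
        rows[[f]] <- data.frame(
          date = rep(fdates, nsc), focal_id = f,
          time = sprintf("%02d:%02d", rep(hrs, nsc),
                         unlist(lapply(nsc, function(k) (seq_len(k) - 1L) * 10))))
      }
      if (!length(rows)) next
      sc <- do.call(rbind, rows)
      sc$row <- seq_len(nrow(sc))
      # candidate partners: cross join scans x resident females
      cand <- merge(sc[c("row", "date", "focal_id")],
                    data.frame(partner = fids), by = NULL)
      cand <- cand[cand$partner != cand$focal_id, , drop = FALSE]
      dnum <- as.numeric(cand$date)
      keep <- logical(nrow(cand))
      # residency, infant and immigrant status per (female, date) combo
      combo <- unique(data.frame(id = c(cand$focal_id, cand$partner),
                                 d = c(dnum, dnum)))
      combo$res <- FALSE; combo$inf <- FALSE; combo$imm <- FALSE
      for (f in fids) {
        m <- combo$id == f
        tt <- ten[ten$id == f & ten$group_id == gid, , drop = FALSE][1L, ]
        e0 <- as.numeric(tt$entry_date)
        e1 <- if (is.na(tt$exit_date)) Inf else as.numeric(tt$exit_date)
        combo$res[m] <- combo$d[m] >= e0 & combo$d[m] < e1
        b <- as.numeric(off$birth_date[off$mother_id == f])
        if (length(b))
          combo$inf[m] <- vapply(combo$d[m], function(d)
            any(d >= b & d - b < 365), logical(1L))
        if (tt$entry_type == "immigration")
          combo$imm[m] <- combo$d[m] - e0 < 365 & combo$d[m] >= e0
      }
      key <- function(id, d) paste(id, d)
      ck <- key(combo$id, combo$d)
      i_f <- match(key(cand$focal_id, dnum), ck)
      i_p <- match(key(cand$partner, dnum), ck)
      ok <- combo$res[i_f] & combo$res[i_p]
      inf_f <- combo$inf[i_f]; inf_p <- combo$inf[i_p]
      both_inf <- inf_f & inf_p
      one_inf <- xor(inf_f, inf_p)
      any_imm <- combo$imm[i_f] | combo$imm[i_p]
      std <- ft$std_latent[match(cand$focal_id, ft$id)]
      stdp <- ft$std_latent[match(cand$partner, ft$id)]
      re_f <- ft$female_re[match(cand$focal_id, ft$id)]
      re_p <- ft$female_re[match(cand$partner, ft$id)]
      dk <- paste(pmin(cand$focal_id, cand$partner),
                  pmax(cand$focal_id, cand$partner))
      dtr <- truth$dyads[truth$dyads$group_id == gid, , drop = FALSE]
      aff <- dtr$affinity[match(dk, paste(dtr$id1, dtr$id2))]
      aff[is.na(aff)] <- 0
      yre <- truth$years$year_re[truth$years$year == yr]
      eta <- eff$beta0 + aff + eff$beta_rank_avg * (std + stdp) / 2 +
        eff$beta_both_infant * both_inf + eff$beta_one_infant * one_inf +
        eff$beta_immigrant * any_imm + re_f + re_p + yre
      hit <- ok & stats::runif(nrow(cand)) < stats::plogis(eta)
      nb <- rep("", nrow(sc))
      if (any(hit)) {
        agg <- tapply(cand$partner[hit], cand$row[hit],
                      function(v) paste(sort(v), collapse = ";"))
        nb[as.integer(names(agg))] <- unname(agg)
      }
      out[[length(out) + 1L]] <- data.frame(
        scan_id = sprintf("%s-%07d", gid, counter + sc$row),
        date = sc$date, time = sc$time, group_id = gid,
        focal_id = sc$focal_id,
        activity = sample(ACTIVITIES, nrow(sc), replace = TRUE,
                          prob = c(0.45, 0.3, 0.2, 0.05)),
        neighbors_5m = nb)
      counter <- counter + nrow(sc)
    }
  }
  sc <- do.call(rbind, out)
  sc <- sc[order(sc$group_id, sc$date, sc$scan_id), SCAN_COLS]
  rownames(sc) <- NULL
  sc
}

#' Simulate a complete study
#'
#' Runs [simulate_demography()], [simulate_truth()], [simulate_agonistic()]
#' and [simulate_scans()] under the scenario's seed. Identical scenario and
#' seed give identical output.
#'
#' @param scenario a [scenario_config()].
#' @return list with elements `demography`, `truth`, `agonistic`, `scans`,
#'   `scenario`.
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  demography <- simulate_demography(scenario)
  truth <- simulate_truth(demography, scenario)
  agonistic <- simulate_agonistic(demography, truth, scenario)
  scans <- simulate_scans(demography, truth, scenario)
  list(demography = demography, truth = truth, agonistic = agonistic,
       scans = scans, scenario = scenario)
}

#' Flatten the truth record to a long table
#'
#' One row per realized latent quantity (female latent ranks and random
#' effects, dyad affinities, year effects, generative betas), suitable for
#' `truth.csv`.
#'
#' @param truth output of [simulate_truth()].
#' @export
truth_long <- function(truth) {
  f <- truth$females
  rbind(
    data.frame(component = "female_latent", group_id = f$group_id,
               id1 = f$id, id2 = "", year = NA, value = f$latent),
    data.frame(component = "female_re", group_id = f$group_id,
               id1 = f$id, id2 = "", year = NA, value = f$female_re),
    if (!is.null(truth$dyads))
      data.frame(component = "dyad_affinity", group_id = truth$dyads$group_id,
                 id1 = truth$dyads$id1, id2 = truth$dyads$id2, year = NA,
                 value = truth$dyads$affinity),
    data.frame(component = "year_re", group_id = "", id1 = "", id2 = "",
               year = truth$years$year, value = truth$years$year_re),
    data.frame(component = "effect", group_id = "",
               id1 = names(truth$effects), id2 = "", year = NA,
               value = unlist(truth$effects)))
}
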