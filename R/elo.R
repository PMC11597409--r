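#' Elo rating update for one agonistic interaction
#'
#' Classic Elo with a base-10 logistic expectation curve of scale 400: the
#' winner's expected score is `p = 1 / (1 + 10^((loser - winner)/400))`; the
#' winner gains `k * (1 - p)` points and the loser loses the same amount, so
#' every update is zero-sum.
#'
#' @param rating_winner,rating_loser current ratings.
#' @param k update constant (> 0); hierarchies here use k = 100 with a
#'   starting value of 1000.
#' @return numeric vector `c(winner, loser)` of updated ratings.
#' @export
#' @examples
#' elo_update(1000, 1000)  # c(1050, 950)
elo_update <- function(rating_winner, rating_loser, k = 100) {
  stopifnot(k > 0)
  p <- 1 / (1 + 10^((rating_loser - rating_winner) / 400))
  d <- k * (1 - p)
  c(rating_winner + d, rating_loser - d)
}

#' Run Elo hierarchies and extract daily scores
#'
#' Hierarchies are constructed separately per group and sex from dated
#' winner/loser records. Individuals present when their hierarchy starts are
#' initialized at the starting value; an individual entering an
#' already-rated hierarchy enters at the bottom, i.e. at the current minimum
#' rating among active same-sex group members. Ratings change only at
#' interactions, are carried forward on days without interactions, and are
#' defined from group entry (or the trajectory start) until exit. Events are
#' sorted internally by date (ties broken by winner then loser id), so input
#' order does not matter.
#'
#' @param events agonistic events (columns of [read_agonistic()]).
#' @param demography a [demography_table()] giving tenures.
#' @param start starting rating.
#' @param k Elo update constant.
#' @param start_date,end_date span of the daily trajectories; default to the
#'   calendar years covering the events.
#' @return data.frame of class `elo_daily` with columns group_id, sex, id,
#'   date, rating — one row per individual per active day.
#' @export
run_elo <- function(events, demography, start = 1000, k = 100,
                    start_date = NULL, end_date = NULL) {
  if (is.null(start_date)) {
    yr <- if (nrow(events)) min(format(events$date, "%Y")) else
      format(min(demography$tenures$entry_date), "%Y")
    start_date <- as.Date(paste0(yr, "-01-01"))
  }
  if (is.null(end_date)) {
    yr <- if (nrow(events)) max(format(events$date, "%Y")) else
      format(Sys.Date(), "%Y")
    end_date <- as.Date(paste0(yr, "-12-31"))
  }
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  sexes <- demography$individuals$sex
  names(sexes) <- demography$individuals$id
  out <- list()
  for (gid in sort(unique(demography$tenures$group_id))) {
    for (sx in c("F", "M")) {
      ids <- residents_in_window(demography, gid, start_date, end_date + 1,
                                 sex = sx)
      if (!length(ids)) next
      tt <- demography$tenures
      tt <- tt[tt$group_id == gid & tt$id %in% ids, , drop = FALSE]
      from <- pmax(tt$entry_date, start_date)
      # residency is half-open: the exit day itself is not active
      to <- pmin(ifelse(is.na(tt$exit_date), as.numeric(end_date),
                        as.numeric(tt$exit_date) - 1), as.numeric(end_date))
      to <- as.Date(to, origin = "1970-01-01")
      names(from) <- names(to) <- tt$id

      sx_class <- if (sx == "F") "female" else "male"
      ev <- events[events$group_id == gid & events$sex_class == sx_class, ,
                   drop = FALSE]
      bad <- !(ev$winner_id %in% tt$id) | !(ev$loser_id %in% tt$id)
      if (any(bad))
        stop("agonistic event involves id not resident in ", gid, ": ",
             paste(unique(c(ev$winner_id[bad], ev$loser_id[bad])), collapse = ", "))
      ev <- ev[order(ev$date, ev$winner_id, ev$loser_id), , drop = FALSE]

      rating <- numeric(0)
      chg <- lapply(stats::setNames(tt$id, tt$id), function(i) list())
      note <- function(i, d) {
        chg[[i]][[length(chg[[i]]) + 1L]] <<- c(as.numeric(d), rating[[i]])
      }
      moments <- rbind(
        data.frame(date = unname(from), type = 1L, a = tt$id, b = ""),
        if (nrow(ev)) data.frame(date = ev$date, type = 2L,
                                 a = ev$winner_id, b = ev$loser_id))
      moments <- moments[order(moments$date, moments$type, moments$a), ,
                         drop = FALSE]
      for (m in seq_len(nrow(moments))) {
        d <- moments$date[m]
        if (moments$type[m] == 1L) {
          i <- moments$a[m]
          others <- names(rating)[from[names(rating)] <= d &
                                    to[names(rating)] >= d]
          others <- setdiff(others, i)
          rating[[i]] <- if (length(others)) min(rating[others]) else start
          note(i, d)
        } else {
          w <- moments$a[m]; l <- moments$b[m]
          if (!(w %in% names(rating)) || !(l %in% names(rating)) ||
              d < from[w] || d > to[w] || d < from[l] || d > to[l])
            stop("event on ", d, " involves an individual not active in ",
                 gid, "/", sx)
          upd <- elo_update(rating[[w]], rating[[l]], k)
          rating[[w]] <- upd[1]; rating[[l]] <- upd[2]
          note(w, d); note(l, d)
        }
      }
      for (i in tt$id) {
        if (from[[i]] > to[[i]]) next
        days <- seq(from[[i]], to[[i]], by = "day")
        cp <- do.call(rbind, chg[[i]])
        r <- cp[findInterval(as.numeric(days), cp[, 1]), 2]
        out[[length(out) + 1L]] <- data.frame(
          group_id = gid, sex = sx, id = i, date = days, rating = r)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("elo_daily", class(res))
  res
}

#' Yearly mean Elo scores
#'
#' Arithmetic mean of the daily ratings over each individual's active days in
#' the calendar year (1 January to 31 December); days before entry or after
#' exit are not imputed. Individuals with no active day in the year are
#' omitted.
#'
#' @param elo_daily output of [run_elo()].
#' @param year calendar year (integer); NULL for all years present.
#' @return data.frame with columns group_id, sex, id, year, mean_elo, n_days.
#' @export
yearly_mean_elo <- function(elo_daily, year = NULL) {
  yr <- as.integer(format(elo_daily$date, "%Y"))
  keep <- if (is.null(year)) rep(TRUE, nrow(elo_daily)) else yr %in% year
  x <- elo_daily[keep, , drop = FALSE]
  if (!nrow(x))
    return(data.frame(group_id = character(), sex = character(),
                      id = character(), year = integer(),
                      mean_elo = numeric(), n_days = integer()))
  key <- paste(x$group_id, x$sex, x$id, yr[keep], sep = "\r")
  agg <- tapply(x$rating, key, mean)
  nn <- tapply(x$rating, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  res <- data.frame(group_id = parts[, 1], sex = parts[, 2], id = parts[, 3],
                    year = as.integer(parts[, 4]),
                    mean_elo = unname(agg), n_days = unname(as.integer(nn)))
  res <- res[order(res$group_id, res$sex, res$year, res$id), ]
  rownames(res) <- NULL
  res
}

#' Standardize Elo scores within one group-year
#'
#' Min-max rescaling to `[0, 1]`: 1 is the highest-ranked, 0 the
#' lowest-ranked female of that group and year, making ranks comparable
#' across groups of different size and interaction rate. With a single
#' female, or when all scores are equal, the standardized rank is 0.5 (with a
#' warning), since no ordering information exists.
#'
#' @param mean_elos numeric vector of yearly mean Elo scores for the females
#'   of one group-year.
#' @return numeric vector of standardized ranks in `[0, 1]`.
#' @export
standardize_ranks <- function(mean_elos) {
  if (!length(mean_elos)) stop("no Elo scores to standardize")
  rng <- range(mean_elos)
  if (length(mean_elos) == 1L || diff(rng) == 0) {
    warning("single individual or tied scores: standardized rank set to 0.5")
    return(rep(0.5, length(mean_elos)))
  }
  (mean_elos - rng[1]) / diff(rng)
}

#' Dyadic average rank
#'
#' The two members' standardized ranks summed and divided by two.
#'
#' @param std_rank_a,std_rank_b standardized ranks in `[0, 1]`.
#' @export
dyad_average_rank <- function(std_rank_a, std_rank_b) {
  stopifnot(all(std_rank_a >= 0 & std_rank_a <= 1),
            all(std_rank_b >= 0 & std_rank_b <= 1))
  (std_rank_a + std_rank_b) / 2
}

#' Alpha male of a group-year
#'
#' The male with the highest yearly mean Elo; a single male is the alpha by
#' default. Ties are broken by earlier group entry, then id.
#'
#' @param mean_elos data.frame from [yearly_mean_elo()] (male rows).
#' @param group_id,year which group-year.
#' @param demography optional; supplies entry dates for tie-breaking.
#' @return the alpha male's id.
#' @export
alpha_of_year <- function(mean_elos, group_id, year, demography = NULL) {
  m <- mean_elos[mean_elos$group_id == group_id & mean_elos$year == year &
                   mean_elos$sex == "M", , drop = FALSE]
  if (!nrow(m)) stop("no male resident in ", group_id, " in ", year)
  entry <- if (!is.null(demography)) {
    vapply(m$id, function(i) {
      tt <- demography$tenures
      min(as.numeric(tt$entry_date[tt$id == i & tt$group_id == group_id]))
    }, numeric(1))
  } else rep(0, nrow(m))
  m$id[order(-m$mean_elo, entry, m$id)][1L]
}

#' Build the yearly rank table
#'
#' Joins yearly mean Elo scores with within-group-year standardization for
#' females and alpha identification for males.
#'
#' @param elo_daily output of [run_elo()].
#' @param demography a [demography_table()] (for alpha tie-breaking).
#' @return data.frame with columns group_id, year, id, sex, mean_elo,
#'   std_rank (females; NA for males), is_alpha (males; NA for females).
#' @export
rank_table <- function(elo_daily, demography = NULL) {
  ym <- yearly_mean_elo(elo_daily)
  ym$std_rank <- NA_real_
  ym$is_alpha <- NA
  for (gy in unique(paste(ym$group_id, ym$year, sep = "\r"))) {
    p <- strsplit(gy, "\r", fixed = TRUE)[[1]]
    f <- which(ym$group_id == p[1] & ym$year == as.integer(p[2]) & ym$sex == "F")
    if (length(f))
      ym$std_rank[f] <- suppressWarnings(standardize_ranks(ym$mean_elo[f]))
    m <- which(ym$group_id == p[1] & ym$year == as.integer(p[2]) & ym$sex == "M")
    if (length(m)) {
      a <- alpha_of_year(ym, p[1], as.integer(p[2]), demography)
      ym$is_alpha[m] <- ym$id[m] == a
    }
  }
  ym[, c("group_id", "year", "id", "sex", "mean_elo", "n_days",
         "std_rank", "is_alpha")]
}
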