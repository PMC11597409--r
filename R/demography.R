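#' Assemble a demography table
#'
#' The demography table is the life-history backbone of the pipeline: every
#' residency check, covariate flag and event anchor is derived from it. It is
#' stored as four flat data frames.
#'
#' @param individuals data.frame with columns `id`, `sex` ("F"/"M"),
#'   `birth_date` (Date).
#' @param tenures data.frame with columns `id`, `group_id`, `entry_date`,
#'   `entry_type` ("natal"/"immigration"), `exit_date` (Date, NA if open),
#'   `exit_type` ("emigration"/"death"/"censored", NA if open).
#' @param offspring data.frame with columns `mother_id`, `birth_date`
#'   (one row per infant born to a study female), or NULL.
#' @param alpha_tenures data.frame with columns `id`, `group_id`,
#'   `start_date`, `end_date` (NA if open), or NULL. Males only.
#'
#' @return An object of class `demography` (a list of the four validated
#'   data frames, tenures sorted by individual and entry date).
#' @export
demography_table <- function(individuals, tenures, offspring = NULL,
                             alpha_tenures = NULL) {
  individuals <- as.data.frame(individuals)
  tenures <- as.data.frame(tenures)
  need_ind <- c("id", "sex", "birth_date")
  need_ten <- c("id", "group_id", "entry_date", "entry_type",
                "exit_date", "exit_type")
  if (!all(need_ind %in% names(individuals)))
    stop("individuals must have columns: ", paste(need_ind, collapse = ", "))
  if (!all(need_ten %in% names(tenures)))
    stop("tenures must have columns: ", paste(need_ten, collapse = ", "))
  individuals$birth_date <- as.Date(individuals$birth_date)
  tenures$entry_date <- as.Date(tenures$entry_date)
  tenures$exit_date <- as.Date(tenures$exit_date)
  if (anyDuplicated(individuals$id))
    stop("duplicate individual ids: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  bad <- setdiff(tenures$id, individuals$id)
  if (length(bad))
    stop("tenure rows for unknown ids: ", paste(bad, collapse = ", "))
  tenures <- tenures[order(tenures$id, tenures$entry_date), , drop = FALSE]
  rownames(tenures) <- NULL

  # tenures of one individual must not overlap in time
  for (ind in unique(tenures$id)) {
    tt <- tenures[tenures$id == ind, , drop = FALSE]
    if (nrow(tt) > 1L) {
      ends <- tt$exit_date[-nrow(tt)]
      if (anyNA(ends))
        stop("individual ", ind, ": open tenure followed by a later tenure")
      if (any(ends > tt$entry_date[-1L]))
        stop("individual ", ind, ": overlapping tenures")
    }
  }

  if (is.null(offspring)) {
    offspring <- data.frame(mother_id = character(), birth_date = as.Date(character()))
  } else {
    offspring <- as.data.frame(offspring)
    offspring$birth_date <- as.Date(offspring$birth_date)
    bad <- setdiff(offspring$mother_id, individuals$id)
    if (length(bad))
      stop("offspring rows for unknown mothers: ", paste(bad, collapse = ", "))
    mb <- individuals$birth_date[match(offspring$mother_id, individuals$id)]
    if (any(offspring$birth_date <= mb))
      stop("offspring birth precedes mother's birth")
  }
  if (is.null(alpha_tenures)) {
    alpha_tenures <- data.frame(id = character(), group_id = character(),
                                start_date = as.Date(character()),
                                end_date = as.Date(character()))
  } else {
    alpha_tenures <- as.data.frame(alpha_tenures)
    alpha_tenures$start_date <- as.Date(alpha_tenures$start_date)
    alpha_tenures$end_date <- as.Date(alpha_tenures$end_date)
  }
  structure(list(individuals = individuals, tenures = tenures,
                 offspring = offspring, alpha_tenures = alpha_tenures),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("<demography> ", nrow(x$individuals), " individuals (",
      sum(x$individuals$sex == "F"), " F), ",
      nrow(x$tenures), " tenures, ",
      nrow(x$offspring), " offspring births, ",
      length(unique(x$tenures$group_id)), " groups\n", sep = "")
  invisible(x)
}

# days alive at `date` (0 on the birth date)
age_days <- function(demography, ids, date) {
  bd <- demography$individuals$birth_date[match(ids, demography$individuals$id)]
  as.numeric(as.Date(date) - bd)
}

#' Is each individual resident in a group on a date?
#'
#' Residency is the half-open interval `[entry_date, exit_date)`; an open
#' tenure (NA exit) extends indefinitely.
#'
#' @param demography a [demography_table()] object
#' @param ids character vector of individual ids
#' @param group_id group label
#' @param date calendar date
#' @return logical vector along `ids`
#' @export
is_resident <- function(demography, ids, group_id, date) {
  date <- as.Date(date)
  tt <- demography$tenures
  tt <- tt[tt$group_id == group_id, , drop = FALSE]
  vapply(ids, function(i) {
    ti <- tt[tt$id == i, , drop = FALSE]
    any(ti$entry_date <= date & (is.na(ti$exit_date) | ti$exit_date > date))
  }, logical(1L), USE.NAMES = FALSE)
}

#' Individuals resident in a group during a window
#'
#' @inheritParams is_resident
#' @param start,end window bounds, half-open `[start, end)`
#' @param sex optional filter ("F" or "M")
#' @param adult_only if TRUE keep only individuals aged >= 10 years for at
#'   least one day of the window (females are considered adult from age 10)
#' @return character vector of ids
#' @export
residents_in_window <- function(demography, group_id, start, end,
                                sex = NULL, adult_only = FALSE) {
  start <- as.Date(start); end <- as.Date(end)
  tt <- demography$tenures
  tt <- tt[tt$group_id == group_id, , drop = FALSE]
  ex <- ifelse(is.na(tt$exit_date), as.numeric(end) + 1, as.numeric(tt$exit_date))
  keep <- tt$entry_date < end & ex > as.numeric(start)
  ids <- unique(tt$id[keep])
  if (!is.null(sex)) {
    sx <- demography$individuals$sex[match(ids, demography$individuals$id)]
    ids <- ids[sx == sex]
  }
  if (adult_only && length(ids)) {
    bd <- demography$individuals$birth_date[match(ids, demography$individuals$id)]
    # adult for >= 1 day of the window: 10th birthday falls before window end
    ids <- ids[as.numeric(end - bd) / 365.25 > 10]
  }
  ids
}

# residency intervals of `id` in a group clipped to [start, end), as a
# numeric matrix of [from, to) day numbers (possibly zero rows)
res_intervals <- function(demography, id, group_id, start, end) {
  tt <- demography$tenures
  tt <- tt[tt$id == id & tt$group_id == group_id, , drop = FALSE]
  lo <- as.numeric(as.Date(start)); hi <- as.numeric(as.Date(end))
  if (!nrow(tt)) return(matrix(numeric(0), 0, 2))
  s <- pmax(as.numeric(tt$entry_date), lo)
  e <- pmin(ifelse(is.na(tt$exit_date), hi, as.numeric(tt$exit_date)), hi)
  m <- cbind(s, e)[e > s, , drop = FALSE]
  m
}

# number of days of [start, end) during which `id` is resident in group
residency_days <- function(demography, id, group_id, start, end) {
  tt <- demography$tenures
  tt <- tt[tt$id == id & tt$group_id == group_id, , drop = FALSE]
  if (!nrow(tt)) return(0)
  s <- pmax(as.numeric(tt$entry_date), as.numeric(as.Date(start)))
  e <- pmin(ifelse(is.na(tt$exit_date), Inf, as.numeric(tt$exit_date)),
            as.numeric(as.Date(end)))
  sum(pmax(e - s, 0))
}

# mother has an infant aged < 365 days on `date`? (vectorised over mothers)
has_dependent_infant_on <- function(demography, mothers, date) {
  off <- demography$offspring
  date <- as.Date(date)
  vapply(mothers, function(m) {
    b <- off$birth_date[off$mother_id == m]
    any(b <= date & as.numeric(date - b) < 365)
  }, logical(1L), USE.NAMES = FALSE)
}

# is `id` within the first 365 days of an immigration tenure on `date`?
is_recent_immigrant_on <- function(demography, ids, date) {
  tt <- demography$tenures
  date <- as.Date(date)
  vapply(ids, function(i) {
    ti <- tt[tt$id == i & tt$entry_type == "immigration", , drop = FALSE]
    any(ti$entry_date <= date & as.numeric(date - ti$entry_date) < 365)
  }, logical(1L), USE.NAMES = FALSE)
}
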