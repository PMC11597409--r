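#' @title Reading and writing the study tables
#'
#' @description All tables are plain comma-separated UTF-8 text with ISO-8601
#' dates. A scan record holds the focal female's activity and the set of adult
#' females within 5 m of her, serialized as a semicolon-joined field; an
#' agonistic record is one dated displacement/avoidance with a winner and a
#' loser; the demography file is one row per individual with tenures,
#' offspring births and alpha tenures packed into delimited sub-fields.
#'
#' @name gorassoc-io
NULL

SCAN_COLS <- c("scan_id", "date", "time", "group_id", "focal_id",
               "activity", "neighbors_5m")
AGON_COLS <- c("date", "group_id", "winner_id", "loser_id",
               "behaviour", "sex_class")
ACTIVITIES <- c("feeding", "resting", "travelling", "other")

split_ids <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}

join_ids <- function(lst) vapply(lst, paste, character(1L), collapse = ";")

#' Read scan records
#'
#' @param path CSV file with columns scan_id, date, time, group_id, focal_id,
#'   activity, neighbors_5m (semicolon-joined ids, may be empty).
#' @param demography optional [demography_table()]; when given, every focal
#'   and neighbour is checked to be an adult female resident in the scan's
#'   group on the scan's date.
#' @param lax downgrade referential errors (unknown/non-resident ids) to
#'   warnings and keep the rows; structural errors (focal listed as its own
#'   neighbour) always fail.
#' @return data.frame of validated scan records; `neighbors_5m` stays a
#'   semicolon-joined character column.
#' @export
read_scans <- function(path, demography = NULL, lax = FALSE) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  x <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(SCAN_COLS, names(x))
  if (length(missing))
    stop("scan file missing column(s): ", paste(missing, collapse = ", "))
  x <- x[SCAN_COLS]
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable date at line(s) ",
                          paste(which(is.na(x$date)) + 1L, collapse = ", "))
  bad_act <- !x$activity %in% ACTIVITIES
  if (any(bad_act))
    stop("unknown activity at line(s) ",
         paste(which(bad_act) + 1L, collapse = ", "))
  validate_scans(x, demography, lax = lax)
}

validate_scans <- function(x, demography = NULL, lax = FALSE) {
  nb <- split_ids(x$neighbors_5m)
  self <- mapply(function(f, n) f %in% n, x$focal_id, nb)
  if (any(self))
    stop("focal listed among its own neighbours at line(s) ",
         paste(which(self) + 1L, collapse = ", "))
  if (!is.null(demography)) {
    report <- function(msg, rows) {
      msg <- paste0(msg, " at line(s) ", paste(rows + 1L, collapse = ", "))
      if (lax) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
    }
    ids <- demography$individuals$id
    unknown <- vapply(seq_len(nrow(x)), function(i)
      !(x$focal_id[i] %in% ids) || !all(nb[[i]] %in% ids), logical(1L))
    if (any(unknown)) report("id absent from demography", which(unknown))
    ok <- vapply(seq_len(nrow(x)), function(i) {
      all_ids <- unique(c(x$focal_id[i], nb[[i]]))
      all_ids <- all_ids[all_ids %in% ids]
      all(is_resident(demography, all_ids, x$group_id[i], x$date[i]))
    }, logical(1L))
    if (any(!ok)) report("id not resident in group on scan date", which(!ok))
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_scans
#' @param scans data.frame of scan records
#' @export
write_scans <- function(scans, path) {
  utils::write.csv(scans[SCAN_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read agonistic (displacement/avoidance) events
#'
#' @inheritParams read_scans
#' @export
read_agonistic <- function(path, demography = NULL, lax = FALSE) {
  if (!file.exists(path)) stop("agonistic file not found: ", path)
  x <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(AGON_COLS, names(x))
  if (length(missing))
    stop("agonistic file missing column(s): ", paste(missing, collapse = ", "))
  x <- x[AGON_COLS]
  x$date <- as.Date(x$date)
  if (any(x$winner_id == x$loser_id))
    stop("winner equals loser at line(s) ",
         paste(which(x$winner_id == x$loser_id) + 1L, collapse = ", "))
  if (!is.null(demography)) {
    ids <- demography$individuals$id
    bad <- !(x$winner_id %in% ids) | !(x$loser_id %in% ids)
    res <- vapply(seq_len(nrow(x)), function(i) {
      w <- c(x$winner_id[i], x$loser_id[i]); w <- w[w %in% ids]
      all(is_resident(demography, w, x$group_id[i], x$date[i]))
    }, logical(1L))
    bad <- bad | !res
    if (any(bad)) {
      msg <- paste0("unknown or non-resident contestant at line(s) ",
                    paste(which(bad) + 1L, collapse = ", "))
      if (lax) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
    }
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_agonistic
#' @param events data.frame of agonistic events
#' @export
write_agonistic <- function(events, path) {
  utils::write.csv(events[AGON_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))

#' Read or write a demography table
#'
#' On disk the demography is one CSV row per individual: `id,sex,birth_date`
#' plus three packed fields. `tenures` is
#' `group|entry|entry_type|exit|exit_type` records joined by `;` (open fields
#' empty), `offspring_births` is `;`-joined dates, `alpha_tenures` is
#' `group|start|end` records joined by `;`.
#'
#' @param path CSV file path
#' @return a [demography_table()] object (invariants re-checked on read)
#' @export
read_demography <- function(path) {
  if (!file.exists(path)) stop("demography file not found: ", path)
  x <- utils::read.csv(path, colClasses = "character")
  need <- c("id", "sex", "birth_date", "tenures", "offspring_births",
            "alpha_tenures")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("demography file missing column(s): ", paste(missing, collapse = ", "))
  individuals <- data.frame(id = x$id, sex = x$sex,
                            birth_date = as.Date(x$birth_date))
  unpack <- function(field, ids, cols) {
    recs <- split_ids(field)
    out <- do.call(rbind, lapply(seq_along(recs), function(i) {
      if (!length(recs[[i]])) return(NULL)
      parts <- strsplit(recs[[i]], "|", fixed = TRUE)
      m <- do.call(rbind, lapply(parts, function(p) {
        length(p) <- length(cols); p
      }))
      data.frame(id = ids[i], m)
    }))
    if (is.null(out)) return(NULL)
    names(out) <- c("id", cols)
    out
  }
  ten <- unpack(x$tenures, x$id,
                c("group_id", "entry_date", "entry_type", "exit_date", "exit_type"))
  if (is.null(ten)) stop("demography file has no tenures")
  ten$entry_date <- as.Date(ten$entry_date)
  ten$exit_date <- as.Date(ifelse(nzchar(ten$exit_date) & !is.na(ten$exit_date),
                                  ten$exit_date, NA))
  ten$exit_type[!nzchar(ten$exit_type) | is.na(ten$exit_type)] <- NA
  off_l <- split_ids(x$offspring_births)
  offspring <- do.call(rbind, lapply(seq_along(off_l), function(i) {
    if (!length(off_l[[i]])) return(NULL)
    data.frame(mother_id = x$id[i], birth_date = as.Date(off_l[[i]]))
  }))
  alf <- unpack(x$alpha_tenures, x$id, c("group_id", "start_date", "end_date"))
  if (!is.null(alf)) {
    names(alf)[1] <- "id"
    alf$start_date <- as.Date(alf$start_date)
    alf$end_date <- as.Date(ifelse(nzchar(alf$end_date) & !is.na(alf$end_date),
                                   alf$end_date, NA))
  }
  demography_table(individuals, ten, offspring, alf)
}

#' @rdname read_demography
#' @param demography a [demography_table()] object
#' @export
write_demography <- function(demography, path) {
  ind <- demography$individuals
  pack <- function(id, df, fmt) {
    rows <- df[df[[1L]] == id, , drop = FALSE]
    if (!nrow(rows)) return("")
    paste(vapply(seq_len(nrow(rows)), function(i) fmt(rows[i, ]),
                 character(1L)), collapse = ";")
  }
  ten <- demography$tenures[, c("id", "group_id", "entry_date", "entry_type",
                                "exit_date", "exit_type")]
  out <- data.frame(
    id = ind$id, sex = ind$sex, birth_date = fmt_date(ind$birth_date),
    tenures = vapply(ind$id, pack, character(1L), df = ten, fmt = function(r)
      paste(r$group_id, fmt_date(r$entry_date), r$entry_type,
            fmt_date(r$exit_date),
            ifelse(is.na(r$exit_type), "", r$exit_type), sep = "|")),
    offspring_births = vapply(ind$id, function(i) {
      b <- demography$offspring$birth_date[demography$offspring$mother_id == i]
      paste(fmt_date(sort(b)), collapse = ";")
    }, character(1L)),
    alpha_tenures = vapply(ind$id, pack, character(1L),
                           df = demography$alpha_tenures, fmt = function(r)
      paste(r$group_id, fmt_date(r$start_date), fmt_date(r$end_date), sep = "|"))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
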