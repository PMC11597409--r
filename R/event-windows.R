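#' Find birth and immigration event anchors
#'
#' Two kinds of events re-anchor the association windows. A *second-birth*
#' event arises for each dyad whose two members have dependent-infant periods
#' that overlap (births less than 365 days apart while co-resident); its
#' anchor is the birth date of the later infant and its focal dyad is the
#' pair. An *immigration* event arises for each immigration tenure; its
#' anchor is the group-entry date, and every dyad containing the immigrant is
#' treated as experiencing the event.
#'
#' @param demography a [demography_table()].
#' @param start_date,end_date restrict anchors to this span (optional).
#' @return data.frame with columns event_id, event_type ("second_birth" /
#'   "immigration"), group_id, anchor_date, id1, id2 (id2 NA for
#'   immigration events).
#' @export
find_events <- function(demography, start_date = NULL, end_date = NULL) {
  out <- list()
  off <- demography$offspring
  ten <- demography$tenures
  for (gid in sort(unique(ten$group_id))) {
    fem <- unique(ten$id[ten$group_id == gid])
    fem <- fem[demography$individuals$sex[match(fem, demography$individuals$id)] == "F"]
    mothers <- intersect(fem, off$mother_id)
    if (length(mothers) > 1) {
      cmb <- utils::combn(sort(mothers), 2)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        ba <- off$birth_date[off$mother_id == a]
        bb <- off$birth_date[off$mother_id == b]
        anchors <- as.Date(character())
        for (x in as.list(ba)) for (y in as.list(bb)) {
          if (abs(as.numeric(x - y)) >= 365) next  # dependency periods disjoint
          anchor <- max(x, y)
          if (!all(is_resident(demography, c(a, b), gid, anchor))) next
          anchors <- c(anchors, anchor)
        }
        # one event per dyad per overlap episode: several birth pairings with
        # anchors inside one 365-day span are the same joint-dependency spell
        anchors <- sort(unique(anchors))
        kept <- as.Date(character())
        for (anchor in as.list(anchors)) {
          if (length(kept) && as.numeric(anchor - max(kept)) < 365) next
          kept <- c(kept, anchor)
          out[[length(out) + 1L]] <- data.frame(
            event_type = "second_birth", group_id = gid,
            anchor_date = anchor, id1 = a, id2 = b)
        }
      }
    }
    imm <- ten[ten$group_id == gid & ten$entry_type == "immigration" &
                 ten$id %in% fem, , drop = FALSE]
    for (j in seq_len(nrow(imm)))
      out[[length(out) + 1L]] <- data.frame(
        event_type = "immigration", group_id = gid,
        anchor_date = imm$entry_date[j], id1 = imm$id[j], id2 = NA_character_)
  }
  if (!length(out))
    return(data.frame(event_id = character(), event_type = character(),
                      group_id = character(),
                      anchor_date = as.Date(character()),
                      id1 = character(), id2 = character()))
  ev <- do.call(rbind, out)
  if (!is.null(start_date)) ev <- ev[ev$anchor_date >= as.Date(start_date), ]
  if (!is.null(end_date)) ev <- ev[ev$anchor_date < as.Date(end_date), ]
  ev <- ev[order(ev$event_type, ev$group_id, ev$anchor_date, ev$id1), ]
  ev <- cbind(event_id = sprintf("E%03d", seq_len(nrow(ev))), ev)
  rownames(ev) <- NULL
  ev
}

event_offsets <- function(event_type) {
  switch(event_type,
         second_birth = -2:2,
         immigration = 0:4,
         stop("unknown event type: ", event_type))
}

#' Time-matched strength series around one event
#'
#' Replaces the 31 December window boundary with the event date: for each
#' offset `k` the association network is rebuilt over the 365-day window
#' `[anchor + 365k, anchor + 365(k + 1))` (offset 0 starting at the anchor,
#' leap days ignored), for *all* dyads resident in that window. Second-birth
#' events use offsets -2..+2; immigration events 0..+4. Windows with no
#' scans, and dyads without focal scans, yield missing strengths (logged),
#' so series at the edge of the observation period stay partial rather than
#' being dropped.
#'
#' @param scans scan records.
#' @param demography a [demography_table()].
#' @param event one row of [find_events()].
#' @param ... passed to [build_network()] (e.g. `node_strength_mode`).
#' @return data.frame: event_id, event_type, group_id, dyad_id, id1, id2,
#'   offset, strength, condition ("yes"/"no"), is_focal_dyad.
#' @export
event_strength_series <- function(scans, demography, event, ...) {
  anchor <- as.Date(event$anchor_date)
  gid <- event$group_id
  offs <- event_offsets(event$event_type)
  rows <- list()
  n_missing <- 0L
  for (k in offs) {
    w <- window_spec(gid, anchor + 365 * k, anchor + 365 * (k + 1),
                     anchor = "event_offset", offset_label = k)
    net <- suppressWarnings(build_network(scans, demography, w, ...))
    d <- net$dyads
    if (!nrow(d)) next
    n_missing <- n_missing + sum(is.na(d$strength))
    cond <- vapply(seq_len(nrow(d)), function(i)
      event_condition(demography, event, d$id1[i], d$id2[i]), logical(1L))
    focal <- if (event$event_type == "second_birth") {
      (d$id1 == min(event$id1, event$id2) & d$id2 == max(event$id1, event$id2))
    } else {
      d$id1 == event$id1 | d$id2 == event$id1
    }
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = event$event_id, event_type = event$event_type,
      group_id = gid, dyad_id = paste(d$id1, d$id2, sep = "_"),
      id1 = d$id1, id2 = d$id2, offset = k, strength = d$strength,
      condition = ifelse(cond, "yes", "no"), is_focal_dyad = focal)
  }
  if (n_missing)
    message(event$event_id, ": ", n_missing,
            " dyad-offset row(s) missing (no focal scans in window)")
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(event_id = character(), event_type = character(),
                      group_id = character(), dyad_id = character(),
                      id1 = character(), id2 = character(), offset = integer(),
                      strength = numeric(), condition = character(),
                      is_focal_dyad = logical()))
  rownames(res) <- NULL
  res
}

# does this dyad satisfy the event's condition (both-infant overlap spanning
# the offset-0 window for births; containing a member newly immigrated in the
# offset-0 window for immigrations)?
event_condition <- function(demography, event, a, b) {
  anchor <- as.Date(event$anchor_date)
  w0 <- c(anchor, anchor + 365)
  if (event$event_type == "second_birth") {
    dep <- function(id) {
      bd <- demography$offspring$birth_date[demography$offspring$mother_id == id]
      any(bd < w0[2] & bd + 365 > w0[1])
    }
    dep(a) && dep(b)
  } else {
    rec <- function(id) {
      tt <- demography$tenures
      tt <- tt[tt$id == id & tt$entry_type == "immigration", , drop = FALSE]
      any(tt$entry_date < w0[2] & tt$entry_date + 365 > w0[1])
    }
    rec(a) || rec(b)
  }
}

#' Compile time-matched event tables for the additive models
#'
#' Stacks per-event series into the two long tables consumed by
#' [fit_event_gam()]: one for second-birth events, one for immigration
#' events, each with columns event_id, dyad_id, offset, condition, strength.
#' Rows with missing strength are excluded (count reported).
#'
#' @param series data.frame from [event_strength_series()] (rows of several
#'   events bound together).
#' @return list with data.frames `infant` and `immigrant` (NULL when no
#'   events of that type).
#' @export
compile_event_tables <- function(series) {
  n_na <- sum(is.na(series$strength))
  if (n_na) message(n_na, " row(s) with missing strength excluded")
  s <- series[!is.na(series$strength), , drop = FALSE]
  pick <- function(type) {
    x <- s[s$event_type == type,
           c("event_id", "dyad_id", "offset", "condition", "strength"),
           drop = FALSE]
    if (!nrow(x)) return(NULL)
    rownames(x) <- NULL
    x
  }
  list(infant = pick("second_birth"), immigrant = pick("immigration"))
}
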