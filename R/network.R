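#' Window specification for a network
#'
#' A half-open interval `[start, end)` over which one group's proximity
#' network is tallied: either a calendar year (1 January to 31 December) or a
#' 365-day window anchored on an event date.
#'
#' @param group_id group label.
#' @param start,end window bounds (end exclusive).
#' @param anchor "calendar_year" or "event_offset".
#' @param offset_label integer offset label for event windows.
#' @export
window_spec <- function(group_id, start, end, anchor = "calendar_year",
                        offset_label = NA_integer_) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(end > start, anchor %in% c("calendar_year", "event_offset"))
  if (anchor == "event_offset" && as.numeric(end - start) != 365)
    stop("event windows must be exactly 365 days")
  structure(list(group_id = group_id, start = start, end = end,
                 anchor = anchor, offset_label = offset_label),
            class = "window_spec")
}

#' Calendar-year window
#' @param group_id group label.
#' @param year calendar year.
#' @export
year_window <- function(group_id, year) {
  window_spec(group_id, sprintf("%d-01-01", year), sprintf("%d-01-01", year + 1))
}

#' Dyadic strength (simple-ratio proximity index)
#'
#' `Strength = N_ab / (N_a + N_b)`: the number of scans in which the two
#' females were within 5 m of each other (counted from either member's
#' focals) divided by the total number of scans in which each was the focal
#' animal.
#'
#' @param N_ab joint within-5 m scan count.
#' @param N_a,N_b each member's focal scan count.
#' @return strength in `[0, 1]`; NA with a warning when `N_a + N_b = 0`.
#' @export
dyadic_strength <- function(N_ab, N_a, N_b) {
  tot <- N_a + N_b
  if (any(tot == 0)) {
    warning("dyad with no focal scans: strength undefined, dropped")
    return(ifelse(tot == 0, NA_real_, N_ab / tot))
  }
  N_ab / tot
}

#' Build a proximity association network for one window
#'
#' Tallies the 5 m proximity scans of one group over a window. Nodes are the
#' adult females resident for at least one day of the window; `N_a` is the
#' number of scans with female `a` as focal; `N_ab` the number of scans, from
#' either member's focals, in which the pair was within 5 m. Dyadic strengths
#' are the simple ratio [dyadic_strength()]; node strength is by default the
#' weighted degree (sum of incident dyadic strengths), with the per-capita
#' neighbour rate (`raw_rate`: total neighbour sightings over own focal
#' scans) available as an alternative reading of the individual score.
#'
#' The focal-scan denominators of a dyad count each member's focal scans
#' taken while the other member was resident, so a dyad that co-resides for
#' only part of the window (a mid-year immigration or emigration) is scored
#' over its joint exposure rather than being mechanically deflated by scans
#' on which the pair could not possibly have been together.
#'
#' @param scans scan records ([read_scans()]).
#' @param demography a [demography_table()].
#' @param window a [window_spec()].
#' @param node_strength_mode "weighted_degree" (default) or "raw_rate".
#' @param min_focals drop females with fewer focal scans than this in the
#'   window (default 0: the analysis states no threshold).
#' @return object of class `association_network`: list with `window`,
#'   `nodes`, `focal_counts` (named N_a), `dyads` (data.frame id1 < id2,
#'   N_ab, N_a, N_b, strength) and `node_strength` (named).
#' @export
build_network <- function(scans, demography, window,
                          node_strength_mode = c("weighted_degree", "raw_rate"),
                          min_focals = 0) {
  node_strength_mode <- match.arg(node_strength_mode)
  nodes <- sort(residents_in_window(demography, window$group_id,
                                    window$start, window$end,
                                    sex = "F", adult_only = TRUE))
  s <- scans[scans$group_id == window$group_id &
               scans$date >= window$start & scans$date < window$end, ,
             drop = FALSE]
  if (!nrow(s))
    warning("no scans in window [", window$start, ", ", window$end, ") for ",
            window$group_id)
  s <- s[s$focal_id %in% nodes, , drop = FALSE]
  N_a <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(s$focal_id)
  N_a[names(tab)] <- as.integer(tab)
  if (min_focals > 0) {
    nodes <- nodes[N_a[nodes] >= min_focals]
    N_a <- N_a[nodes]
    s <- s[s$focal_id %in% nodes, , drop = FALSE]
  }
  # long pair tally: one row per (scan, neighbour in node set)
  nb <- split_ids(s$neighbors_5m)
  reps <- lengths(nb)
  foc <- rep(s$focal_id, reps)
  par <- unlist(nb)
  keep <- par %in% nodes
  foc <- foc[keep]; par <- par[keep]
  raw_seen <- stats::setNames(numeric(length(nodes)), nodes)
  dyads <- if (length(nodes) > 1) {
    cmb <- utils::combn(nodes, 2)
    d <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ], N_ab = 0L)
    if (length(foc)) {
      k <- paste(pmin(foc, par), pmax(foc, par), sep = "\r")
      tb <- table(k)
      idx <- match(paste(d$id1, d$id2, sep = "\r"), names(tb))
      d$N_ab <- ifelse(is.na(idx), 0L, as.integer(tb[idx]))
      seen <- table(par)  # times each female was seen as a neighbour
      raw_seen[names(seen)] <- as.numeric(seen)
      # plus times she was focal with >= 1 neighbour counted per neighbour
      seen_f <- table(foc)
      raw_seen[names(seen_f)] <- raw_seen[names(seen_f)] + as.numeric(seen_f)
    }
    # denominators count each member's focal scans only while the other
    # member is resident: partial co-residency (mid-year immigration or
    # emigration) must not deflate the index mechanically
    scan_dates <- split(as.numeric(s$date), s$focal_id)
    iv <- lapply(stats::setNames(nodes, nodes), function(i)
      res_intervals(demography, i, window$group_id, window$start, window$end))
    w0 <- as.numeric(window$start); w1 <- as.numeric(window$end)
    n_in <- function(focal, other) {
      dts <- scan_dates[[focal]]
      if (is.null(dts)) return(0L)
      m <- iv[[other]]
      if (!nrow(m)) return(0L)
      if (nrow(m) == 1L && m[1, 1] <= w0 && m[1, 2] >= w1)
        return(length(dts))  # other member resident throughout
      sum(vapply(dts, function(x) any(x >= m[, 1] & x < m[, 2]), logical(1L)))
    }
    d$N_a <- vapply(seq_len(nrow(d)), function(i)
      n_in(d$id1[i], d$id2[i]), integer(1L))
    d$N_b <- vapply(seq_len(nrow(d)), function(i)
      n_in(d$id2[i], d$id1[i]), integer(1L))
    tot <- d$N_a + d$N_b
    d$strength <- ifelse(tot > 0, d$N_ab / tot, NA_real_)
    if (any(tot == 0))
      warning("dyad(s) with no focal scans dropped from strengths")
    rownames(d) <- NULL
    d
  } else {
    data.frame(id1 = character(), id2 = character(), N_ab = integer(),
               N_a = integer(), N_b = integer(), strength = numeric())
  }
  ns <- stats::setNames(numeric(length(nodes)), nodes)
  if (node_strength_mode == "weighted_degree") {
    for (i in seq_len(nrow(dyads))) {
      w <- dyads$strength[i]
      if (is.na(w)) next
      ns[dyads$id1[i]] <- ns[dyads$id1[i]] + w
      ns[dyads$id2[i]] <- ns[dyads$id2[i]] + w
    }
  } else {
    ns <- ifelse(N_a > 0, raw_seen / N_a, NA_real_)
    names(ns) <- nodes
  }
  structure(list(window = window, nodes = nodes, focal_counts = N_a,
                 dyads = dyads, node_strength = ns,
                 node_strength_mode = node_strength_mode),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat("<association_network> ", x$window$group_id, " [",
      format(x$window$start), ", ", format(x$window$end), "): ",
      length(x$nodes), " females, ", nrow(x$dyads), " dyads, ",
      sum(x$focal_counts), " focal scans\n", sep = "")
  invisible(x)
}

#' Node strength of one female
#'
#' @param network an [build_network()] result.
#' @param id female id (must be a node).
#' @export
node_strength <- function(network, id) {
  if (!id %in% network$nodes) stop(id, " is not a node of this network")
  unname(network$node_strength[id])
}

#' Build calendar-year networks for all groups
#'
#' @inheritParams build_network
#' @param years integer vector of calendar years; defaults to the years
#'   spanned by the scans.
#' @return list with `networks` (list of association_network), `dyads` (long
#'   data.frame: group_id, year, id1, id2, N_ab, N_a, N_b, strength) and
#'   `nodes` (group_id, year, id, n_focals, strength).
#' @export
yearly_networks <- function(scans, demography, years = NULL,
                            node_strength_mode = "weighted_degree",
                            min_focals = 0) {
  if (is.null(years))
    years <- sort(unique(as.integer(format(scans$date, "%Y"))))
  groups <- sort(unique(scans$group_id))
  nets <- list(); dy <- list(); no <- list()
  for (g in groups) for (y in years) {
    w <- year_window(g, y)
    net <- suppressWarnings(build_network(scans, demography, w,
                                          node_strength_mode = node_strength_mode,
                                          min_focals = min_focals))
    nets[[paste(g, y)]] <- net
    if (nrow(net$dyads))
      dy[[paste(g, y)]] <- cbind(group_id = g, year = y, net$dyads)
    if (length(net$nodes))
      no[[paste(g, y)]] <- data.frame(
        group_id = g, year = y, id = net$nodes,
        n_focals = unname(net$focal_counts[net$nodes]),
        strength = unname(net$node_strength[net$nodes]))
  }
  list(networks = nets,
       dyads = if (length(dy)) do.call(rbind, dy) else NULL,
       nodes = if (length(no)) do.call(rbind, no) else NULL)
}
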