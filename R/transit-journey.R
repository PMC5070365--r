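# Minimum-duration journey search and round trips.
#
# A journey departs home no earlier than the window start, walks to one of
# the candidate boarding stops (boarding is timed exactly, so no waiting at
# the first stop is ever counted), rides/waits/transfers through the event
# graph, and walks from the alighting stop to the destination, arriving no
# later than the window end.  The objective is minimum duration
# (arrival - departure); ties prefer the latest departure, then the fewest
# boardings.  A direct walk within its cap may compete as a fallback.

#' Search the minimum-duration journey between stop sets
#'
#' Low-level search over an [build_event_graph()] graph: `access` lists the
#' boarding stops with their origin walks, `egress` the alighting stops
#' with their destination walks.  Returns the best journey within the
#' window or `NULL` when no connection exists.
#'
#' @param graph An `event_graph`.
#' @param access Data frame `stop_id`, `walk_min` (and optionally `dist_m`)
#'   of boarding candidates.
#' @param egress Data frame `stop_id`, `walk_min` (optionally `dist_m`) of
#'   alighting candidates.
#' @param window Two clock times (seconds or `"HH:MM"`): earliest
#'   departure, latest arrival.
#' @param params A [transit_params()] object.
#' @param walk_only_min Optional duration of a direct walk; when given it
#'   competes with the transit journeys.
#' @param latest_departure_objective If `TRUE`, prefer the latest feasible
#'   departure instead of the shortest duration (used when waiting at the
#'   destination counts as travel time).
#' @return A `journey` object (legs, departure, arrival, duration) or
#'   `NULL`.
#' @export
journey_search <- function(graph, access, egress, window, params,
                           walk_only_min = NULL,
                           latest_departure_objective = FALSE) {
  w0 <- parse_clock(window[1])
  w1 <- parse_clock(window[2])
  cands <- list()

  if (!is.null(access) && nrow(access) && !is.null(egress) && nrow(egress) &&
      length(graph$times)) {
    eg_code <- match(egress$stop_id, graph$stop_ids)
    keep <- !is.na(eg_code)
    eg_code <- eg_code[keep]
    eg_walk <- egress$walk_min[keep] * 60
    for (a in seq_len(nrow(access))) {
      code <- match(access$stop_id[a], graph$stop_ids)
      if (is.na(code)) next
      evs <- graph$stop_events[[code]]
      if (!length(evs)) next
      tb <- graph$times[evs]
      wa <- access$walk_min[a] * 60
      sel <- which(tb - wa >= w0 & tb <= w1)
      for (k in sel) {
        e <- evs[k]
        reach <- .scan_layers(graph, e, w1)
        arr_stop <- .scan_stop_arrivals(graph, reach$A, w1)
        if (!length(eg_code)) next
        arr_opts <- arr_stop[eg_code] + eg_walk
        arr_opts[arr_stop[eg_code] > w1] <- Inf
        arr_opts[arr_opts > w1] <- Inf
        if (all(is.infinite(arr_opts))) next
        j <- which.min(arr_opts)
        dep <- tb[k] - wa
        cands[[length(cands) + 1L]] <- list(
          kind = "transit", access_row = a, board_event = e,
          egress_row = which(keep)[j],
          departure = dep, arrival = arr_opts[j],
          duration = arr_opts[j] - dep)
      }
    }
  }

  if (!is.null(walk_only_min) && length(walk_only_min) &&
      is.finite(walk_only_min) && walk_only_min * 60 <= w1 - w0) {
    cands[[length(cands) + 1L]] <- list(
      kind = "walk", departure = w1 - walk_only_min * 60, arrival = w1,
      duration = walk_only_min * 60)
  }

  if (!length(cands)) return(NULL)

  dur <- vapply(cands, `[[`, numeric(1), "duration")
  dep <- vapply(cands, `[[`, numeric(1), "departure")
  score <- if (latest_departure_objective) -dep else dur
  best_score <- min(score)
  tied <- which(score <= best_score + 1e-9)
  # among objective ties prefer latest departure, then fewest boardings
  tied <- tied[order(-dep[tied])]
  tied <- tied[dep[tied] >= max(dep[tied]) - 1e-9]
  if (length(tied) > 1L) {
    built <- lapply(tied, function(i) .build_journey(graph, cands[[i]],
                                                     access, egress, params))
    nr <- vapply(built, `[[`, numeric(1), "n_rides")
    built[[which.min(nr)]]
  } else {
    .build_journey(graph, cands[[tied]], access, egress, params)
  }
}

.build_journey <- function(graph, cand, access, egress, params) {
  leg <- function(type, from, to, start_s, end_s, trip_id = NA_character_,
                  dist_m = NA_real_) {
    data.frame(type = type, from = from, to = to, start_s = start_s,
               end_s = end_s, trip_id = trip_id, dist_m = dist_m,
               stringsAsFactors = FALSE)
  }
  dist_of <- function(df, row) {
    if ("dist_m" %in% names(df)) df$dist_m[row] else
      df$walk_min[row] / 60 * params$walk_speed_kmh * 1000
  }

  if (cand$kind == "walk") {
    legs <- leg("WALK", "origin", "destination", cand$departure,
                cand$arrival,
                dist_m = cand$duration / 60 * params$walk_speed_kmh * 1000)
    out <- list(legs = legs, departure_s = cand$departure,
                arrival_s = cand$arrival,
                duration_min = cand$duration / 60, n_rides = 0,
                status = "OK")
    class(out) <- "journey"
    return(out)
  }

  sc <- .scan_full(graph, cand$board_event, cand$arrival)
  # final event: earliest reachable ride arrival at the chosen egress stop
  code <- match(egress$stop_id[cand$egress_row], graph$stop_ids)
  evs <- graph$stop_events[[code]]
  evs <- evs[is.finite(sc$ridesA[evs])]
  target <- evs[which.min(graph$times[evs])]

  path_edges <- integer()
  cur <- target
  layer <- "A"
  while (!(layer == "B" && cur == cand$board_event)) {
    if (layer == "A") {
      pe <- sc$parA[cur]
      if (pe == 0L) break
      path_edges <- c(pe, path_edges)
      cur <- graph$edges$from[pe]
      layer <- "B"
    } else {
      pb <- sc$parB[cur]
      if (pb == -1L) {
        layer <- "A"
      } else {
        if (pb == 0L) break
        path_edges <- c(pb, path_edges)
        cur <- graph$edges$from[pb]
        layer <- if (graph$edges$type[pb] == "transfer") "A" else "B"
      }
    }
  }

  ev <- graph$events
  legs <- list()
  wa <- access$walk_min[cand$access_row] * 60
  legs[[1]] <- leg("WALK", "origin", access$stop_id[cand$access_row],
                   cand$departure, cand$departure + wa,
                   dist_m = dist_of(access, cand$access_row))
  n_rides <- 0L
  i <- 1L
  while (i <= length(path_edges)) {
    e <- path_edges[i]
    type <- graph$edges$type[e]
    if (type == "ride") {
      trip <- graph$edges$trip_id[e]
      j <- i
      while (j < length(path_edges) &&
             graph$edges$type[path_edges[j + 1L]] == "ride" &&
             graph$edges$trip_id[path_edges[j + 1L]] == trip) {
        j <- j + 1L
      }
      from_ev <- graph$edges$from[path_edges[i]]
      to_ev <- graph$edges$to[path_edges[j]]
      legs[[length(legs) + 1L]] <- leg("RIDE", ev$stop_id[from_ev],
                                       ev$stop_id[to_ev],
                                       ev$time_s[from_ev], ev$time_s[to_ev],
                                       trip_id = trip)
      n_rides <- n_rides + 1L
      i <- j + 1L
    } else if (type == "wait") {
      from_ev <- graph$edges$from[e]
      to_ev <- graph$edges$to[e]
      prev <- legs[[length(legs)]]
      if (prev$type == "WAIT" && prev$to == ev$stop_id[to_ev]) {
        legs[[length(legs)]]$end_s <- ev$time_s[to_ev]
      } else {
        legs[[length(legs) + 1L]] <- leg("WAIT", ev$stop_id[from_ev],
                                         ev$stop_id[to_ev],
                                         ev$time_s[from_ev],
                                         ev$time_s[to_ev])
      }
      i <- i + 1L
    } else {  # transfer
      from_ev <- graph$edges$from[e]
      to_ev <- graph$edges$to[e]
      legs[[length(legs) + 1L]] <- leg("WALK", ev$stop_id[from_ev],
                                       ev$stop_id[to_ev],
                                       ev$time_s[from_ev],
                                       ev$time_s[to_ev])
      i <- i + 1L
    }
  }
  we <- egress$walk_min[cand$egress_row] * 60
  legs[[length(legs) + 1L]] <- leg("WALK",
                                   egress$stop_id[cand$egress_row],
                                   "destination",
                                   graph$times[target],
                                   graph$times[target] + we,
                                   dist_m = dist_of(egress, cand$egress_row))
  legs <- do.call(rbind, legs)
  rownames(legs) <- NULL
  out <- list(legs = legs, departure_s = cand$departure,
              arrival_s = cand$arrival,
              duration_min = (cand$arrival - cand$departure) / 60,
              n_rides = n_rides, status = "OK")
  class(out) <- "journey"
  out
}

#' @export
print.journey <- function(x, ...) {
  cat(sprintf("Journey %s -> %s, %.1f min, %d ride(s)\n",
              format_clock(x$departure_s), format_clock(x$arrival_s),
              x$duration_min, x$n_rides))
  for (i in seq_len(nrow(x$legs))) {
    l <- x$legs[i, ]
    cat(sprintf("  %-5s %s -> %s  %s-%s%s\n", l$type, l$from, l$to,
                format_clock(l$start_s), format_clock(l$end_s),
                if (!is.na(l$trip_id)) paste0("  [", l$trip_id, "]") else ""))
  }
  invisible(x)
}

#' Minimum-duration journey from a district to a practice
#'
#' Boards via one of the district's (at most) `k_access_stops` candidate
#' stops, alights within the stop-to-practice cap, and may fall back on a
#' direct walk when allowed; returns the shortest journey inside the
#' window, or `NULL` when none is feasible (no connection).
#'
#' @param district District id.
#' @param practice Practice id.
#' @param window Two clock times: earliest departure, latest arrival.
#' @param graph An [build_event_graph()] graph.
#' @param fp A [footpaths()] set.
#' @param params A [transit_params()] object.
#' @return A `journey` or `NULL`.
#' @export
min_duration_journey <- function(district, practice, window, graph, fp,
                                 params) {
  access <- candidate_access_stops(fp, district, params$k_access_stops)
  egress <- fp$stop_practice[fp$stop_practice$practice_id == practice, ,
                             drop = FALSE]
  walk_only <- NULL
  if (params$allow_walk_only) {
    op <- fp$origin_practice[fp$origin_practice$origin_id == district &
                               fp$origin_practice$practice_id == practice, ]
    if (nrow(op)) walk_only <- op$walk_min[1]
  }
  journey_search(graph, access, egress, window, params,
                 walk_only_min = walk_only,
                 latest_departure_objective = params$count_practice_wait)
}

#' Round trip from a district to a practice and back
#'
#' Outbound within `[earliest_departure, appointment_time]`, return within
#' `[return_earliest, latest_home_arrival]` (the hour at the practice is
#' never part of travel time); the total is the sum of both durations and
#' the trip is a connection only if both legs are feasible.
#'
#' @inheritParams min_duration_journey
#' @return One-row data frame: `district_id`, `practice_id`,
#'   `outbound_min`, `return_min`, `total_min`, `status`
#'   (`"OK"`/`"NO_CONNECTION"`).
#' @export
round_trip <- function(district, practice, graph, fp, params) {
  outb <- min_duration_journey(
    district, practice,
    c(params$earliest_departure_s, params$appointment_time_s),
    graph, fp, params)

  ret <- NULL
  if (!is.null(outb)) {
    access_r <- fp$stop_practice[fp$stop_practice$practice_id == practice, ,
                                 drop = FALSE]
    names(access_r)[names(access_r) == "stop_id"] <- "stop_id"
    egress_r <- candidate_access_stops(fp, district, params$k_access_stops)
    walk_only <- NULL
    if (params$allow_walk_only) {
      op <- fp$origin_practice[fp$origin_practice$origin_id == district &
                                 fp$origin_practice$practice_id == practice, ]
      if (nrow(op)) walk_only <- op$walk_min[1]
    }
    ret <- journey_search(
      graph, access_r, egress_r,
      c(params$return_earliest_s, params$latest_home_arrival_s),
      params, walk_only_min = walk_only)
  }

  if (is.null(outb) || is.null(ret)) {
    return(data.frame(district_id = district, practice_id = practice,
                      outbound_min = NA_real_, return_min = NA_real_,
                      total_min = NA_real_, status = "NO_CONNECTION",
                      stringsAsFactors = FALSE))
  }
  out_min <- if (params$count_practice_wait) {
    (params$appointment_time_s - outb$departure_s) / 60
  } else {
    outb$duration_min
  }
  data.frame(district_id = district, practice_id = practice,
             outbound_min = out_min, return_min = ret$duration_min,
             total_min = out_min + ret$duration_min, status = "OK",
             stringsAsFactors = FALSE)
}

#' Nearest reachable practice of a group by public transport
#'
#' Minimises the round-trip total over all practices of the group (core
#' and buffer); `NO_CONNECTION` only when every practice is infeasible.
#'
#' @param district District id.
#' @param group One of [physician_groups()].
#' @param graph An [build_event_graph()] graph.
#' @param fp A [footpaths()] set.
#' @param practices Practice table (`id`, `group`).
#' @param params A [transit_params()] object.
#' @return One-row data frame as [round_trip()], with the winning
#'   `practice_id`.
#' @export
nearest_reachable_practice <- function(district, group, graph, fp,
                                       practices, params) {
  pid <- sort(practices$id[practices$group == group])
  if (!length(pid)) stop("no practices of group '", group, "'",
                         call. = FALSE)
  best <- NULL
  for (p in pid) {
    rt <- round_trip(district, p, graph, fp, params)
    if (rt$status == "OK" &&
        (is.null(best) || rt$total_min < best$total_min)) {
      best <- rt
    }
  }
  if (is.null(best)) {
    return(data.frame(district_id = district, practice_id = NA_character_,
                      outbound_min = NA_real_, return_min = NA_real_,
                      total_min = NA_real_, status = "NO_CONNECTION",
                      stringsAsFactors = FALSE))
  }
  best
}

#' Validate a journey against the timetable and walking caps
#'
#' Checks leg-by-leg consistency: contiguous times and places, ride legs
#' that exist in the timetable (correct board/alight stops and times), and
#' walking legs within their caps.
#'
#' @param journey A `journey` object.
#' @param timetable The timetable it was computed from.
#' @param params The [transit_params()] used.
#' @param direction `"outbound"` (origin is the district) or `"return"`
#'   (origin is the practice); decides which walking caps apply at the two
#'   ends.
#' @return `TRUE` invisibly; errors on the first violation.
#' @export
validate_journey <- function(journey, timetable, params,
                             direction = c("outbound", "return")) {
  direction <- match.arg(direction)
  start_cap <- if (direction == "outbound") {
    params$max_walk_origin_to_stop_m
  } else {
    params$max_walk_stop_to_practice_m
  }
  end_cap <- if (direction == "outbound") {
    params$max_walk_stop_to_practice_m
  } else {
    params$max_walk_origin_to_stop_m
  }
  legs <- journey$legs
  stopifnot(nrow(legs) >= 1)
  if (any(diff(c(legs$start_s[1], legs$end_s)) < -1e-6)) {
    stop("journey legs are not contiguous in time", call. = FALSE)
  }
  for (i in seq_len(nrow(legs))) {
    l <- legs[i, ]
    if (l$end_s < l$start_s - 1e-9) stop("leg ", i, " ends before it starts")
    if (l$type == "RIDE") {
      st <- timetable$stop_times[timetable$stop_times$trip_id == l$trip_id, ]
      if (!nrow(st)) stop("ride leg uses unknown trip ", l$trip_id)
      bi <- which(st$stop_id == l$from & st$departure_s == l$start_s)
      ai <- which(st$stop_id == l$to & st$arrival_s == l$end_s)
      ok <- length(bi) && length(ai) &&
        any(outer(st$stop_sequence[bi], st$stop_sequence[ai], `<`))
      if (!ok) {
        stop("ride leg not consistent with timetable: trip ", l$trip_id,
             call. = FALSE)
      }
    }
    if (l$type == "WALK" && !is.na(l$dist_m)) {
      cap <- if (l$from == "origin" && l$to == "destination") {
        params$max_walk_origin_to_practice_m
      } else if (l$from == "origin") {
        start_cap
      } else if (l$to == "destination") {
        end_cap
      } else {
        params$max_walk_transfer_m
      }
      if (l$dist_m > cap + 1e-6) {
        stop("walk leg ", i, " exceeds its cap (", round(l$dist_m), " > ",
             cap, " m)", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
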