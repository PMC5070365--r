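# Time-expanded transit graph.
#
# Nodes are (stop, scheduled time) events.  Three edge kinds connect them:
# ride edges between consecutive stop events of a trip, wait edges chaining
# the events of one stop in time order, and transfer-walk edges from an
# event to the first event at a neighbouring stop (within the transfer
# cap) reachable after the walk.  Every edge strictly advances the clock,
# so any path from a boarding event ends at an event whose time IS the
# arrival time; a single forward pass in chronological order answers
# earliest-arrival queries.
#
# Queries distinguish two passenger states per event: "alighted" (just got
# off a vehicle: may leave for the destination, wait to re-board, or take
# ONE transfer walk) and "boarding" (standing at the stop after the access
# or a transfer walk: may wait and board).  This enforces the footpath
# structure of the model -- one access walk, at most one walk per vehicle
# change, one egress walk after the final ride -- and rules out chained
# stop-to-stop walking as a travel mode of its own.

#' Build the time-expanded event graph of a timetable
#'
#' @param timetable A `timetable` object.
#' @param fp A [footpaths()] result (its `stop_stop` pairs, already capped
#'   at the transfer distance, become transfer-walk edges).
#' @param params A [transit_params()] object.
#' @param service Service-day tag to include (e.g. `"school"`).
#' @return Object of class `event_graph`: `events` (stop_id, time_s, in
#'   chronological order), `edges` (from, to, type in ride/wait/transfer,
#'   trip_id), adjacency indexed by event, and per-stop event lists.
#' @export
build_event_graph <- function(timetable, fp, params, service = "school") {
  trips <- timetable$trips[timetable$trips$service == service, , drop = FALSE]
  st <- timetable$stop_times[
    timetable$stop_times$trip_id %in% trips$trip_id, , drop = FALSE]
  stop_ids <- sort(unique(timetable$stops$stop_id))

  if (nrow(st) == 0L) {
    eg <- list(
      events = data.frame(stop_id = character(), time_s = numeric()),
      edges = data.frame(from = integer(), to = integer(),
                         type = character(), trip_id = character()),
      adj_ride = list(), adj_wait = list(), adj_transfer = list(),
      adj_ride_e = list(), adj_wait_e = list(), adj_transfer_e = list(),
      stop_ids = stop_ids,
      stop_code = integer(),
      stop_events = rep(list(integer()), length(stop_ids)),
      times = numeric())
    class(eg) <- "event_graph"
    return(eg)
  }

  st <- st[order(st$trip_id, st$stop_sequence), ]
  ev_key_all <- unique(data.frame(
    stop_id = rep(st$stop_id, 2L),
    time_s = c(st$arrival_s, st$departure_s),
    stringsAsFactors = FALSE))
  ev <- ev_key_all[order(ev_key_all$time_s, ev_key_all$stop_id), ,
                   drop = FALSE]
  rownames(ev) <- NULL
  n <- nrow(ev)
  key <- paste(ev$stop_id, ev$time_s)
  ev_index <- function(stop, time) match(paste(stop, time), key)

  # ride edges: consecutive stop events within a trip
  same_trip <- st$trip_id[-nrow(st)] == st$trip_id[-1]
  i1 <- which(same_trip)
  ride <- data.frame(
    from = ev_index(st$stop_id[i1], st$departure_s[i1]),
    to = ev_index(st$stop_id[i1 + 1L], st$arrival_s[i1 + 1L]),
    type = "ride", trip_id = st$trip_id[i1],
    stringsAsFactors = FALSE)
  # dwell at a stop (arrival precedes departure) rides the wait chain below

  # wait edges: consecutive events of one stop
  stop_code <- match(ev$stop_id, stop_ids)
  stop_events <- rep(list(integer()), length(stop_ids))
  spl <- split(seq_len(n), stop_code)
  stop_events[as.integer(names(spl))] <- spl  # already time-ordered
  wait <- do.call(rbind, lapply(spl, function(ix) {
    if (length(ix) < 2L) return(NULL)
    data.frame(from = ix[-length(ix)], to = ix[-1L], type = "wait",
               trip_id = NA_character_, stringsAsFactors = FALSE)
  }))

  # transfer-walk edges: to the first boardable event after the walk
  transfer <- NULL
  if (nrow(fp$stop_stop)) {
    tr <- fp$stop_stop[fp$stop_stop$from_stop %in% stop_ids &
                         fp$stop_stop$to_stop %in% stop_ids, , drop = FALSE]
    pieces <- vector("list", nrow(tr))
    for (r in seq_len(nrow(tr))) {
      ca <- match(tr$from_stop[r], stop_ids)
      cb <- match(tr$to_stop[r], stop_ids)
      ia <- stop_events[[ca]]
      ib <- stop_events[[cb]]
      if (!length(ia) || !length(ib)) next
      tb <- ev$time_s[ib]
      pos <- findInterval(ev$time_s[ia] + tr$walk_min[r] * 60 - 1e-9, tb) + 1L
      keep <- pos <= length(ib)
      # a forward scan needs strictly time-ordered edges; drop the
      # degenerate zero-length-walk case that would point sideways
      keep <- keep & ifelse(keep, ib[pmin(pos, length(ib))] > ia, FALSE)
      if (!any(keep)) next
      pieces[[r]] <- data.frame(from = ia[keep], to = ib[pos[keep]],
                                type = "transfer", trip_id = NA_character_,
                                stringsAsFactors = FALSE)
    }
    transfer <- do.call(rbind, pieces)
  }

  edges <- rbind(ride, wait, transfer)
  rownames(edges) <- NULL
  stopifnot(all(ev$time_s[edges$to] >= ev$time_s[edges$from]))

  adj_of <- function(type) {
    keep <- which(edges$type == type)
    to_l <- rep(list(integer()), n)
    e_l <- rep(list(integer()), n)
    se <- split(keep, edges$from[keep])
    e_l[as.integer(names(se))] <- se
    to_l[as.integer(names(se))] <- lapply(se, function(ix) edges$to[ix])
    list(to = to_l, e = e_l)
  }
  ar <- adj_of("ride")
  aw <- adj_of("wait")
  at <- adj_of("transfer")

  eg <- list(events = ev, edges = edges,
             adj_ride = ar$to, adj_wait = aw$to, adj_transfer = at$to,
             adj_ride_e = ar$e, adj_wait_e = aw$e, adj_transfer_e = at$e,
             stop_ids = stop_ids, stop_code = stop_code,
             stop_events = stop_events, times = ev$time_s)
  class(eg) <- "event_graph"
  eg
}

# two-layer forward reachability from a boarding event, bounded by t_max.
# A = alighted from a ride (may egress / transfer / re-board);
# B = at the stop ready to board (after the access or a transfer walk).
.scan_layers <- function(eg, src, t_max = Inf) {
  n <- length(eg$times)
  A <- logical(n)
  B <- logical(n)
  if (!n) return(list(A = A, B = B))
  B[src] <- TRUE
  tm <- eg$times
  for (i in src:n) {
    if (tm[i] > t_max) break
    if (A[i]) {
      B[i] <- TRUE  # alight and wait at the same stop
      nb <- eg$adj_transfer[[i]]
      if (length(nb)) B[nb] <- TRUE
    }
    if (B[i]) {
      nb <- eg$adj_wait[[i]]
      if (length(nb)) B[nb] <- TRUE
      nb <- eg$adj_ride[[i]]
      if (length(nb)) A[nb] <- TRUE
    }
  }
  list(A = A, B = B)
}

# earliest ride-arrival time per stop code (Inf if unreached); egress is
# only possible from the alighted layer
.scan_stop_arrivals <- function(eg, reachA, t_max = Inf) {
  arr <- rep(Inf, length(eg$stop_ids))
  r <- which(reachA & eg$times <= t_max)
  if (!length(r)) return(arr)
  s <- eg$stop_code[r]
  first <- !duplicated(s)  # events are in chronological order
  arr[s[first]] <- eg$times[r[first]]
  arr
}

# layered scan with minimum-boarding labels and parent edges for journey
# reconstruction.  parB == -1L marks "alighted here" (layer switch A -> B
# at the same event).
.scan_full <- function(eg, src, t_max = Inf) {
  n <- length(eg$times)
  ridesA <- rep(Inf, n)
  ridesB <- rep(Inf, n)
  parA <- integer(n)
  parB <- integer(n)
  if (!n) {
    return(list(ridesA = ridesA, ridesB = ridesB, parA = parA, parB = parB))
  }
  ridesB[src] <- 0
  tm <- eg$times
  for (i in src:n) {
    if (tm[i] > t_max) break
    if (is.finite(ridesA[i])) {
      if (ridesA[i] < ridesB[i]) {
        ridesB[i] <- ridesA[i]
        parB[i] <- -1L
      }
      to <- eg$adj_transfer[[i]]
      es <- eg$adj_transfer_e[[i]]
      for (k in seq_along(to)) {
        if (ridesA[i] < ridesB[to[k]]) {
          ridesB[to[k]] <- ridesA[i]
          parB[to[k]] <- es[k]
        }
      }
    }
    if (is.finite(ridesB[i])) {
      to <- eg$adj_wait[[i]]
      es <- eg$adj_wait_e[[i]]
      for (k in seq_along(to)) {
        if (ridesB[i] < ridesB[to[k]]) {
          ridesB[to[k]] <- ridesB[i]
          parB[to[k]] <- es[k]
        }
      }
      to <- eg$adj_ride[[i]]
      es <- eg$adj_ride_e[[i]]
      for (k in seq_along(to)) {
        if (ridesB[i] + 1 < ridesA[to[k]]) {
          ridesA[to[k]] <- ridesB[i] + 1
          parA[to[k]] <- es[k]
        }
      }
    }
  }
  list(ridesA = ridesA, ridesB = ridesB, parA = parA, parB = parB)
}
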