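# Public-transport model parameters and street-network footpaths.

#' Parameters of the public-transport accessibility model
#'
#' Encodes the behavioural assumptions of the round-trip model for an
#' elderly patient with a late-morning appointment: a reduced walking speed
#' of 1.8 km/h (half the commonly assumed 1 m/s), walking caps of 1,000 m
#' from the district centre to a boarding stop (with the three nearest
#' stops considered as boarding candidates, since the nearest stop need not
#' give the fastest connection), 500 m from the alighting stop to the
#' practice, 250 m between stops at a transfer, and 1,000 m for a direct
#' centre-to-practice walk; travel starts no earlier than 07:00, the
#' appointment is at 11:00 on a school-day Tuesday and lasts 60 minutes
#' (excluded from travel time), the return trip starts no earlier than
#' 12:00, and the patient must be home by midnight.
#'
#' @param walk_speed_kmh Pedestrian speed in km/h.
#' @param max_walk_origin_to_stop_m Cap on the district-centre-to-stop walk.
#' @param max_walk_stop_to_practice_m Cap on the stop-to-practice walk.
#' @param max_walk_transfer_m Cap on each stop-to-stop transfer walk.
#' @param max_walk_origin_to_practice_m Cap on a direct walk to the
#'   practice.
#' @param k_access_stops Number of nearest boarding stops considered.
#' @param earliest_departure,appointment_time,return_earliest,latest_home_arrival
#'   Clock times (`"HH:MM"` or seconds since midnight).
#' @param appointment_duration_min Appointment length, minutes (never part
#'   of travel time).
#' @param weekday Service weekday (informational; the school-day Tuesday
#'   timetable is the modelled day).
#' @param service Service-day tag of the timetable to use.
#' @param count_practice_wait If `TRUE`, waiting at the practice before the
#'   appointment counts into the outbound travel time (the outbound
#'   objective becomes "latest feasible departure" instead of minimum
#'   journey duration).
#' @param allow_walk_only If `TRUE` (default), a direct walking round trip
#'   within `max_walk_origin_to_practice_m` is admitted as a fallback and
#'   the minimum of walking and transit durations is reported; `FALSE`
#'   restores a strict always-transit reading.
#' @return An object of class `transit_params`; clock fields are also
#'   available pre-parsed as `*_s` seconds.
#' @export
transit_params <- function(walk_speed_kmh = 1.8,
                           max_walk_origin_to_stop_m = 1000,
                           max_walk_stop_to_practice_m = 500,
                           max_walk_transfer_m = 250,
                           max_walk_origin_to_practice_m = 1000,
                           k_access_stops = 3,
                           earliest_departure = "07:00",
                           appointment_time = "11:00",
                           appointment_duration_min = 60,
                           return_earliest = "12:00",
                           latest_home_arrival = "24:00",
                           weekday = "tuesday",
                           service = "school",
                           count_practice_wait = FALSE,
                           allow_walk_only = TRUE) {
  p <- list(
    walk_speed_kmh = walk_speed_kmh,
    max_walk_origin_to_stop_m = max_walk_origin_to_stop_m,
    max_walk_stop_to_practice_m = max_walk_stop_to_practice_m,
    max_walk_transfer_m = max_walk_transfer_m,
    max_walk_origin_to_practice_m = max_walk_origin_to_practice_m,
    k_access_stops = as.integer(k_access_stops),
    earliest_departure = earliest_departure,
    appointment_time = appointment_time,
    appointment_duration_min = appointment_duration_min,
    return_earliest = return_earliest,
    latest_home_arrival = latest_home_arrival,
    weekday = weekday,
    service = service,
    count_practice_wait = isTRUE(count_practice_wait),
    allow_walk_only = isTRUE(allow_walk_only)
  )
  p$earliest_departure_s <- parse_clock(earliest_departure)
  p$appointment_time_s <- parse_clock(appointment_time)
  p$return_earliest_s <- parse_clock(return_earliest)
  p$latest_home_arrival_s <- parse_clock(latest_home_arrival)

  caps <- c(p$walk_speed_kmh, p$max_walk_origin_to_stop_m,
            p$max_walk_stop_to_practice_m, p$max_walk_transfer_m,
            p$max_walk_origin_to_practice_m)
  if (any(!is.finite(caps)) || any(caps <= 0)) {
    stop("walking speed and caps must be positive", call. = FALSE)
  }
  if (p$k_access_stops < 1L) stop("k_access_stops must be >= 1", call. = FALSE)
  if (!(p$earliest_departure_s < p$appointment_time_s &&
        p$appointment_time_s < p$return_earliest_s &&
        p$return_earliest_s <= p$latest_home_arrival_s)) {
    stop("time windows must satisfy earliest_departure < appointment_time ",
         "< return_earliest <= latest_home_arrival", call. = FALSE)
  }
  class(p) <- "transit_params"
  p
}

#' Walking time for a distance at a given speed
#'
#' `minutes = 0.06 * distance_m / speed_kmh`; at the commonly assumed
#' 1 m/s (3.6 km/h) a kilometre takes 16.67 minutes, at the reduced elderly
#' speed of 1.8 km/h it takes 33.33 minutes.
#'
#' @param distance_m Distance in metres (>= 0).
#' @param walk_speed_kmh Speed in km/h (> 0).
#' @return Minutes.
#' @export
#' @examples
#' walking_time(1000, 3.6)  # 16.67 min, i.e. 1 m/s
#' walking_time(1000, 1.8)  # 33.33 min
walking_time <- function(distance_m, walk_speed_kmh) {
  if (any(!is.finite(walk_speed_kmh)) || any(walk_speed_kmh <= 0)) {
    stop("walking speed must be > 0", call. = FALSE)
  }
  stopifnot(all(distance_m >= 0))
  0.06 * distance_m / walk_speed_kmh
}

#' Street-network walking distances within the model's caps
#'
#' Computes shortest walking distances over the street network (one-way
#' flags ignored: every edge is traversable on foot) between district
#' centres and stops, stop pairs (transfers), stops and practices, and
#' district centres and practices, keeping only pairs within the
#' respective [transit_params()] caps.  Points are snapped to their nearest
#' street node; the straight-line snap offset is added to the network
#' distance.
#'
#' @param network A `street_network`.
#' @param districts Data frame `id`, `x`, `y` (district centroids).
#' @param stops Data frame `stop_id`, `x`, `y`.
#' @param practices Data frame `id`, `x`, `y`.
#' @param params A [transit_params()] object.
#' @return Object of class `footpath_set`: data frames `origin_stop`
#'   (origin_id, stop_id, dist_m, walk_min), `stop_stop` (both directions),
#'   `stop_practice`, `origin_practice`.
#' @export
footpaths <- function(network, districts, stops, practices, params) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes)
  wts <- network$edges$length_m
  vx <- igraph::V(g)$x
  vy <- igraph::V(g)$y
  vn <- igraph::V(g)$name

  snap <- function(df, idcol) {
    if (nrow(df) == 0L) {
      return(data.frame(id = character(), node = character(),
                        off = numeric(), stringsAsFactors = FALSE))
    }
    np <- nearest_point(df$x, df$y, vx, vy)
    data.frame(id = df[[idcol]], node = vn[np$index], off = np$dist,
               stringsAsFactors = FALSE)
  }
  so <- snap(districts, "id")
  ss <- snap(stops, "stop_id")
  sp_ <- snap(practices, "id")

  pair_dist <- function(a, b, cap) {
    if (nrow(a) == 0L || nrow(b) == 0L) {
      return(data.frame(from = character(), to = character(),
                        dist_m = numeric(), stringsAsFactors = FALSE))
    }
    na <- unique(a$node)
    nb <- unique(b$node)
    dm <- igraph::distances(g, v = na, to = nb, weights = wts)
    d <- dm[match(a$node, na), match(b$node, nb), drop = FALSE]
    tot <- sweep(sweep(d, 1, a$off, "+"), 2, b$off, "+")
    idx <- which(tot <= cap, arr.ind = TRUE)
    data.frame(from = a$id[idx[, 1]], to = b$id[idx[, 2]],
               dist_m = tot[idx], stringsAsFactors = FALSE)
  }

  os <- pair_dist(so, ss, params$max_walk_origin_to_stop_m)
  names(os) <- c("origin_id", "stop_id", "dist_m")
  tt <- pair_dist(ss, ss, params$max_walk_transfer_m)
  names(tt) <- c("from_stop", "to_stop", "dist_m")
  tt <- tt[tt$from_stop != tt$to_stop, , drop = FALSE]
  sp2 <- pair_dist(ss, sp_, params$max_walk_stop_to_practice_m)
  names(sp2) <- c("stop_id", "practice_id", "dist_m")
  op <- pair_dist(so, sp_, params$max_walk_origin_to_practice_m)
  names(op) <- c("origin_id", "practice_id", "dist_m")

  for (nm in c("os", "tt", "sp2", "op")) {
    df <- get(nm)
    df$walk_min <- walking_time(df$dist_m, params$walk_speed_kmh)
    rownames(df) <- NULL
    assign(nm, df)
  }
  structure(list(origin_stop = os, stop_stop = tt, stop_practice = sp2,
                 origin_practice = op,
                 walk_speed_kmh = params$walk_speed_kmh),
            class = "footpath_set")
}

#' Candidate boarding stops of a district
#'
#' The `k` nearest stops within the origin-to-stop walking cap (ties broken
#' by stop id); fewer or none may exist.
#'
#' @param fp A [footpaths()] result.
#' @param district_id District id.
#' @param k Maximum number of stops.
#' @return Data frame `stop_id`, `dist_m`, `walk_min`, at most `k` rows.
#' @export
candidate_access_stops <- function(fp, district_id, k = 3) {
  sub <- fp$origin_stop[fp$origin_stop$origin_id == district_id, ,
                        drop = FALSE]
  sub <- sub[order(sub$dist_m, sub$stop_id), , drop = FALSE]
  out <- utils::head(sub[, c("stop_id", "dist_m", "walk_min")], k)
  rownames(out) <- NULL
  out
}
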