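# Independent brute-force oracles used to check the routing cores.
# These deliberately share no code with the implementation: the car oracle
# enumerates all simple paths, the transit oracle recursively enumerates
# event sequences over the raw stop_times table.

# ---- car: exhaustive simple-path enumeration -------------------------------
# edges: data.frame(from, to, weight_s, length_m), directed
# returns per node: minimum time and the set of path lengths attaining it
bf_car_times <- function(node_ids, edges, src) {
  best_t <- setNames(rep(Inf, length(node_ids)), node_ids)
  opt_len <- setNames(vector("list", length(node_ids)), node_ids)
  best_t[src] <- 0
  opt_len[[src]] <- 0
  out_edges <- split(seq_len(nrow(edges)), edges$from)

  rec <- function(cur, t, len, visited) {
    es <- out_edges[[cur]]
    for (e in es) {
      nxt <- edges$to[e]
      if (nxt %in% visited) next
      t2 <- t + edges$weight_s[e]
      l2 <- len + edges$length_m[e]
      if (t2 < best_t[nxt] - 1e-9) {
        best_t[nxt] <<- t2
        opt_len[[nxt]] <<- l2
      } else if (t2 <= best_t[nxt] + 1e-9) {
        opt_len[[nxt]] <<- c(opt_len[[nxt]], l2)
      }
      rec(nxt, t2, l2, c(visited, nxt))
    }
  }
  rec(src, 0, 0, src)
  list(time = best_t, opt_lengths = opt_len)
}

# a random sparse directed street network on n nodes (as oneway edges so
# build_car_graph() reproduces exactly the drawn directed edge set)
random_car_network <- function(n) {
  ids <- sprintf("v%d", seq_len(n))
  nodes <- data.frame(id = ids, x = runif(n, 0, 5000), y = runif(n, 0, 5000),
                      stringsAsFactors = FALSE)
  pairs <- expand.grid(a = seq_len(n), b = seq_len(n))
  pairs <- pairs[pairs$a != pairs$b, ]
  pairs <- pairs[runif(nrow(pairs)) < 0.25, , drop = FALSE]
  if (!nrow(pairs)) pairs <- data.frame(a = 1, b = 2)
  edges <- data.frame(
    from = ids[pairs$a], to = ids[pairs$b],
    length_m = runif(nrow(pairs), 100, 3000),
    speed_kmh = sample(c(30, 70, 100), nrow(pairs), replace = TRUE),
    oneway = TRUE, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "street_network")
}

# ---- transit: exhaustive journey enumeration -------------------------------
# st: stop_times data.frame; access/egress: stop_id + walk_min;
# transfers: from_stop, to_stop, walk_min.  Journeys have the footpath
# structure of the model: access walk, ride, (one transfer walk, ride)*,
# egress walk from the last alighting stop.  Returns the minimum duration
# in seconds over all feasible journeys (Inf if none).
bf_best_duration <- function(st, access, egress, transfers, window,
                             walk_only_min = NULL) {
  w0 <- window[1]
  w1 <- window[2]
  best <- Inf

  # board at `stop` no earlier than `time`: try every later stop of every
  # departing trip
  explore_board <- function(stop, time, dep, seen) {
    key <- paste0("B|", stop)
    prev <- seen[[key]]
    if (!is.null(prev) && time >= prev - 1e-9) return()
    seen[[key]] <- time
    here <- st[st$stop_id == stop & st$departure_s >= time - 1e-9, ,
               drop = FALSE]
    for (r in seq_len(nrow(here))) {
      later <- st[st$trip_id == here$trip_id[r] &
                    st$stop_sequence > here$stop_sequence[r], , drop = FALSE]
      for (q in seq_len(nrow(later))) {
        if (later$arrival_s[q] <= w1) {
          explore_alight(later$stop_id[q], later$arrival_s[q], dep, seen)
        }
      }
    }
  }

  # just alighted at `stop`: egress, wait to re-board, or one transfer walk
  explore_alight <- function(stop, time, dep, seen) {
    key <- paste0("A|", stop)
    prev <- seen[[key]]
    if (!is.null(prev) && time >= prev - 1e-9) return()
    seen[[key]] <- time
    er <- egress[egress$stop_id == stop, , drop = FALSE]
    if (nrow(er)) {
      arr <- time + min(er$walk_min) * 60
      if (arr <= w1) best <<- min(best, arr - dep)
    }
    explore_board(stop, time, dep, seen)
    tr <- transfers[transfers$from_stop == stop, , drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      nt <- time + tr$walk_min[r] * 60
      if (nt <= w1) explore_board(tr$to_stop[r], nt, dep, seen)
    }
  }

  for (a in seq_len(nrow(access))) {
    s <- access$stop_id[a]
    wa <- access$walk_min[a] * 60
    ev <- sort(unique(c(st$arrival_s[st$stop_id == s],
                        st$departure_s[st$stop_id == s])))
    for (t in ev) {
      if (t - wa >= w0 && t <= w1) {
        explore_board(s, t, t - wa, new.env(parent = emptyenv()))
      }
    }
  }
  if (!is.null(walk_only_min) && walk_only_min * 60 <= w1 - w0) {
    best <- min(best, walk_only_min * 60)
  }
  best
}

# a random tiny timetable (<= 30 stop events) plus walk tables
random_transit_instance <- function() {
  n_stops <- sample(3:6, 1)
  stops <- sprintf("S%d", seq_len(n_stops))
  n_trips <- sample(2:4, 1)
  st <- list()
  for (tr in seq_len(n_trips)) {
    k <- sample(2:min(4, n_stops), 1)
    route <- sample(stops, k)
    t0 <- sample(seq(7 * 3600, 10 * 3600, by = 300), 1)
    times <- t0 + cumsum(c(0, sample(180:900, k - 1, replace = TRUE)))
    st[[tr]] <- data.frame(
      trip_id = sprintf("t%d", tr), stop_sequence = seq_len(k),
      stop_id = route, arrival_s = times, departure_s = times,
      stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, st)
  timetable <- structure(list(
    stops = data.frame(stop_id = stops, x = runif(n_stops, 0, 3000),
                       y = runif(n_stops, 0, 3000), node = NA_character_,
                       stringsAsFactors = FALSE),
    trips = data.frame(trip_id = sprintf("t%d", seq_len(n_trips)),
                       route_id = "r", direction = "out", service = "school",
                       stringsAsFactors = FALSE),
    stop_times = st), class = "timetable")

  # a few random transfer pairs (symmetric), short walks
  transfers <- NULL
  if (n_stops >= 2) {
    cmb <- utils::combn(stops, 2)
    pick <- which(runif(ncol(cmb)) < 0.3)
    if (length(pick)) {
      wmin <- runif(length(pick), 2, 8)
      transfers <- data.frame(
        from_stop = c(cmb[1, pick], cmb[2, pick]),
        to_stop = c(cmb[2, pick], cmb[1, pick]),
        dist_m = rep(wmin, 2) / 60 * 1800, walk_min = rep(wmin, 2),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(transfers)) {
    transfers <- data.frame(from_stop = character(), to_stop = character(),
                            dist_m = numeric(), walk_min = numeric(),
                            stringsAsFactors = FALSE)
  }

  acc_n <- sample(1:2, 1)
  egr_n <- sample(1:2, 1)
  access <- data.frame(stop_id = sample(stops, acc_n),
                       walk_min = runif(acc_n, 3, 20),
                       stringsAsFactors = FALSE)
  access$dist_m <- access$walk_min / 60 * 1800
  egress <- data.frame(stop_id = sample(stops, egr_n),
                       walk_min = runif(egr_n, 2, 15),
                       stringsAsFactors = FALSE)
  egress$dist_m <- egress$walk_min / 60 * 1800
  list(timetable = timetable, transfers = transfers, access = access,
       egress = egress)
}
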