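# Car accessibility: weighted street graph, shortest paths, OD cost matrix,
# nearest practice per physician group, travel-time bands and group summaries.

#' Build the directed car routing graph
#'
#' Every street edge becomes a directed edge weighted by free-flow travel
#' time in seconds, `3.6 * length_m / speed_kmh`; two-way edges get both
#' directions, one-way edges only the stored one.  No congestion, turn
#' restrictions or parking-search time are modelled.
#'
#' @param network A `street_network` (nodes: id/x/y; edges: from/to/
#'   length_m/speed_kmh/oneway).
#' @return An igraph directed graph with edge attributes `weight_s` and
#'   `length_m` and vertex attributes `x`, `y`.
#' @export
#' @examples
#' net <- structure(list(
#'   nodes = data.frame(id = c("a", "b"), x = c(0, 1000), y = c(0, 0)),
#'   edges = data.frame(from = "a", to = "b", length_m = 1000,
#'                      speed_kmh = 100, oneway = FALSE)),
#'   class = "street_network")
#' g <- build_car_graph(net)  # edge weight 36 s
build_car_graph <- function(network) {
  ed <- network$edges
  if (nrow(ed) == 0L) stop("street network has no edges", call. = FALSE)
  if (any(!is.finite(ed$speed_kmh)) || any(ed$speed_kmh <= 0)) {
    stop("edge speeds must be positive", call. = FALSE)
  }
  if (any(!is.finite(ed$length_m)) || any(ed$length_m <= 0)) {
    stop("edge lengths must be positive", call. = FALSE)
  }
  w <- 3.6 * ed$length_m / ed$speed_kmh
  fwd <- data.frame(from = ed$from, to = ed$to,
                    weight_s = w, length_m = ed$length_m,
                    stringsAsFactors = FALSE)
  bwd <- fwd[!ed$oneway, , drop = FALSE]
  if (nrow(bwd)) {
    tmp <- bwd$from; bwd$from <- bwd$to; bwd$to <- tmp
  }
  igraph::graph_from_data_frame(rbind(fwd, bwd), directed = TRUE,
                                vertices = network$nodes)
}

#' Single-source car travel times and distances
#'
#' Time-optimal shortest paths (Dijkstra, non-negative weights) from one
#' node to every node, with the metre length measured along the
#' time-optimal path.
#'
#' @param graph Car graph from [build_car_graph()].
#' @param source Node id.
#' @return Data frame `node`, `time_s`, `dist_m`, `reachable`; unreachable
#'   nodes carry `NA` times/distances and `reachable = FALSE`.
#' @export
car_travel_times <- function(graph, source) {
  vn <- igraph::V(graph)$name
  if (!source %in% vn) stop("source node '", source, "' not in graph",
                            call. = FALSE)
  d <- igraph::distances(graph, v = source, mode = "out",
                         weights = igraph::E(graph)$weight_s)[1, ]
  reach <- is.finite(d)
  dist_m <- rep(NA_real_, length(vn))
  targets <- which(reach)
  if (length(targets)) {
    sp <- suppressWarnings(igraph::shortest_paths(
      graph, from = source, to = vn[targets], mode = "out",
      weights = igraph::E(graph)$weight_s, output = "epath"))
    len <- igraph::E(graph)$length_m
    dist_m[targets] <- vapply(sp$epath,
                              function(e) sum(len[as.integer(e)]),
                              numeric(1))
  }
  data.frame(node = vn,
             time_s = ifelse(reach, d, NA_real_),
             dist_m = dist_m,
             reachable = reach,
             stringsAsFactors = FALSE)
}

# snap points to the nearest graph vertex within a tolerance
.snap_to_graph <- function(graph, pts, tolerance_m, what = "point") {
  vx <- igraph::V(graph)$x
  vy <- igraph::V(graph)$y
  vn <- igraph::V(graph)$name
  np <- nearest_point(pts$x, pts$y, vx, vy)
  ok <- np$dist <= tolerance_m
  if (any(!ok)) {
    warning(sum(!ok), " ", what, "(s) beyond ", tolerance_m,
            " m of the street network excluded: ",
            paste(utils::head(pts$id[!ok], 5), collapse = ", "),
            call. = FALSE)
  }
  data.frame(id = pts$id, node = vn[np$index], snap_m = np$dist,
             ok = ok, stringsAsFactors = FALSE)
}

#' Origin-destination car cost matrix
#'
#' Travel time (minutes) and distance (km, along the time-optimal route)
#' from every origin to every destination, after snapping both to the
#' nearest street node within `snap_m` metres.  Unsnappable points are
#' excluded with a warning and listed in the `excluded` attribute;
#' unreachable pairs carry `NA` and `reachable = FALSE`.
#'
#' @param graph Car graph from [build_car_graph()].
#' @param origins,destinations Data frames with `id`, `x`, `y`.
#' @param snap_m Snapping tolerance in metres.
#' @return Long data frame `origin_id`, `dest_id`, `minutes`, `km`,
#'   `reachable`, of class `od_matrix`.
#' @export
od_cost_matrix <- function(graph, origins, destinations, snap_m = 500) {
  so <- .snap_to_graph(graph, origins, snap_m, "origin")
  sd_ <- .snap_to_graph(graph, destinations, snap_m, "destination")
  excluded <- c(so$id[!so$ok], sd_$id[!sd_$ok])
  so <- so[so$ok, , drop = FALSE]
  sd_ <- sd_[sd_$ok, , drop = FALSE]

  out <- vector("list", nrow(so))
  wts <- igraph::E(graph)$weight_s
  lens <- igraph::E(graph)$length_m
  dnodes <- unique(sd_$node)
  for (i in seq_len(nrow(so))) {
    d <- igraph::distances(graph, v = so$node[i], to = dnodes,
                           mode = "out", weights = wts)[1, ]
    reach <- is.finite(d)
    dist_m <- rep(NA_real_, length(dnodes))
    if (any(reach)) {
      sp <- suppressWarnings(igraph::shortest_paths(
        graph, from = so$node[i], to = dnodes[reach], mode = "out",
        weights = wts, output = "epath"))
      dist_m[reach] <- vapply(sp$epath,
                              function(e) sum(lens[as.integer(e)]),
                              numeric(1))
    }
    j <- match(sd_$node, dnodes)
    out[[i]] <- data.frame(
      origin_id = so$id[i],
      dest_id = sd_$id,
      minutes = ifelse(reach[j], d[j] / 60, NA_real_),
      km = dist_m[j] / 1000,
      reachable = reach[j],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(origin_id = character(), dest_id = character(),
                      minutes = numeric(), km = numeric(),
                      reachable = logical(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  class(res) <- c("od_matrix", "data.frame")
  res
}

#' Nearest practice of a physician group per origin
#'
#' Picks, for every origin in the OD matrix, the practice of `group` with
#' the smallest travel time; ties go to the smaller distance, then the
#' lexicographically smallest practice id.  Buffer-ring practices compete
#' on equal terms with core practices.
#'
#' @param odm An [od_cost_matrix()] result whose destinations are practices.
#' @param practices Practice table with `id` and `group`.
#' @param group One of [physician_groups()].
#' @return Data frame `district_id`, `group`, `minutes`, `km`,
#'   `practice_id`, `reachable` (one row per origin; unreachable origins
#'   carry `NA`).
#' @export
nearest_practice <- function(odm, practices, group) {
  pid <- practices$id[practices$group == group]
  if (!length(pid)) stop("no practices of group '", group, "'", call. = FALSE)
  sub <- odm[odm$dest_id %in% pid & odm$reachable, , drop = FALSE]
  origins <- unique(odm$origin_id)
  out <- data.frame(district_id = origins, group = group,
                    minutes = NA_real_, km = NA_real_,
                    practice_id = NA_character_, reachable = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(sub)) {
    sub <- sub[order(sub$origin_id, sub$minutes, sub$km, sub$dest_id), ]
    best <- sub[!duplicated(sub$origin_id), ]
    i <- match(best$origin_id, out$district_id)
    out$minutes[i] <- best$minutes
    out$km[i] <- best$km
    out$practice_id[i] <- best$dest_id
    out$reachable[i] <- TRUE
  }
  out
}

#' Band labels for travel-time breaks
#'
#' @param breaks Strictly increasing positive thresholds, e.g.
#'   `c(5, 10, 15, 20)`.
#' @return Character labels `"<5"`, `"5 to <10"`, ..., `">=20"`.
#' @export
band_labels <- function(breaks) {
  stopifnot(length(breaks) >= 1, all(breaks > 0), !is.unsorted(breaks,
    strictly = TRUE))
  n <- length(breaks)
  c(paste0("<", breaks[1]),
    if (n > 1) paste0(breaks[-n], " to <", breaks[-1]),
    paste0(">=", breaks[n]))
}

#' Assign travel times to half-open bands
#'
#' Bands are half-open on the right: `[0, b1)`, `[b1, b2)`, ..., plus a
#' terminal `>= b_last` band, so a value exactly on a break belongs to the
#' upper band (a 5.0-minute ride is "5 to <10").
#'
#' @param x Non-negative travel times (NA allowed, propagated).
#' @param breaks Strictly increasing positive thresholds.
#' @return Factor with [band_labels()] levels.
#' @export
#' @examples
#' band_assign(c(4.99, 5, 22.9), c(5, 10, 15, 20))
band_assign <- function(x, breaks) {
  labs <- band_labels(breaks)
  stopifnot(all(x >= 0, na.rm = TRUE))
  idx <- findInterval(x, c(0, breaks))
  factor(labs[idx], levels = labs)
}

#' Mean, sample standard deviation and maximum of travel costs
#'
#' @param minutes Per-district travel times in minutes.
#' @param km Optional per-district distances in km.
#' @return One-row data frame with `mean_min`, `sd_min`, `max_min` and,
#'   when `km` is given, `mean_km`, `sd_km`, `max_km`.
#' @export
summarize_group <- function(minutes, km = NULL) {
  minutes <- minutes[!is.na(minutes)]
  if (!length(minutes)) stop("no travel times to summarise", call. = FALSE)
  out <- data.frame(mean_min = mean(minutes),
                    sd_min = stats::sd(minutes),
                    max_min = max(minutes))
  if (!is.null(km)) {
    km <- km[!is.na(km)]
    out$mean_km <- mean(km)
    out$sd_km <- stats::sd(km)
    out$max_km <- max(km)
  }
  out
}

#' Car accessibility pipeline for a region
#'
#' Runs the full car analysis: builds the routing graph, computes the OD
#' cost matrix from district centroids to all practices (core and buffer),
#' selects the nearest practice per district and physician group, assigns
#' service-area time bands, and summarises each group.
#'
#' @param region A `region` bundle from [generate_region()].
#' @param groups Physician groups to analyse.
#' @param breaks Travel-time band breaks in minutes.
#' @param snap_m Snapping tolerance for centroids/practices, metres.
#' @return List of class `car_accessibility` with `per_district` (long data
#'   frame: district_id, group, minutes, km, practice_id, band) and
#'   `summary` (per-group mean/sd/max in minutes and km).
#' @export
accessibility_by_car <- function(region, groups = physician_groups(),
                                 breaks = c(5, 10, 15, 20), snap_m = 500) {
  stopifnot(inherits(region, "region"))
  graph <- build_car_graph(region$network)
  origins <- region$districts[, c("id", "x", "y")]
  dests <- region$practices[, c("id", "x", "y")]
  odm <- od_cost_matrix(graph, origins, dests, snap_m = snap_m)

  per <- list()
  summ <- list()
  for (g in groups) {
    np <- nearest_practice(odm, region$practices, g)
    np$band <- band_assign(np$minutes, breaks)
    per[[g]] <- np
    s <- summarize_group(np$minutes, np$km)
    summ[[g]] <- cbind(data.frame(group = g, stringsAsFactors = FALSE), s)
  }
  out <- list(per_district = do.call(rbind, per),
              summary = do.call(rbind, summ),
              breaks = breaks)
  rownames(out$per_district) <- NULL
  rownames(out$summary) <- NULL
  class(out) <- "car_accessibility"
  out
}

#' @export
print.car_accessibility <- function(x, ...) {
  cat("Car accessibility (", length(unique(x$per_district$group)),
      " groups, ", length(unique(x$per_district$district_id)),
      " districts)\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
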