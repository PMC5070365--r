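# Synthetic study-region generator.
#
# The generator stands in for the proprietary inputs a real accessibility
# study of this kind consumes: routable commercial street data, a population
# register at district level, practice addresses and heterogeneous company
# timetables.  It reproduces their structural properties (skewed district
# sizes, local/rural/trunk road mix with one-way sections, specialists
# clustered in towns, a buffer ring of extra providers, school-day-oriented
# bus service with stops every 400-800 m along street paths) without any
# real geography.

#' Generate a synthetic study region
#'
#' Deterministically builds a complete region bundle from a
#' [region_config()]: population districts anchored to street nodes, a
#' routable street network (perturbed lattice, three speed classes, one-way
#' flags, pruned but connected), physician practices of the four groups
#' (GPs dispersed across districts and guaranteed in every
#' specialist-hosting town, specialists concentrated in the
#' highest-population districts, extra practices in the buffer ring), and a
#' public-transport timetable whose routes follow street shortest paths
#' through chains of districts with stops every 400--800 m (street edges are
#' subdivided so every stop sits exactly on a network node).
#'
#' The same configuration (including its `seed`) always yields an identical
#' bundle.  District populations are drawn log-normally and
#' largest-remainder rounded so that they sum exactly to
#' `total_population`.
#'
#' @param config A [region_config()] object.
#' @return An object of class `region`: a list with elements `config`,
#'   `extent` (core and buffer rectangles, metres), `districts`
#'   (id, x, y, population, anchor node), `network` (nodes and edges of the
#'   street graph), `practices` (id, group, x, y, in_buffer) and
#'   `timetable` (stops, trips, stop_times).
#' @seealso [region_config()], [write_gtfs()], [accessibility_by_car()],
#'   [accessibility_by_transit()]
#' @export
#' @examples
#' reg <- generate_region(region_config(
#'   extent_km = c(20, 15), n_districts = 25, total_population = 8000,
#'   n_gp = 8, n_ophthalmologist = 2, n_internist = 2, n_urologist = 1,
#'   buffer_km = 3, n_routes = 3, headway_min = 60, seed = 42))
#' sum(reg$districts$population)
generate_region <- function(config) {
  validate_region_config(config)
  set.seed(config$seed)

  W <- config$extent_km[1] * 1000
  H <- config$extent_km[2] * 1000
  buf <- config$buffer_km * 1000
  sp <- 1000  # lattice spacing, m

  lat <- .make_lattice_network(W, H, buf, sp)
  network <- lat$network
  grid <- lat$grid

  districts <- .make_districts(network, grid, config, W, H, sp)
  tr <- .make_transit(network, districts, config)
  network <- tr$network
  timetable <- tr$timetable
  practices <- .make_practices(network, grid, districts, config, W, H, sp)

  stopifnot(sum(districts$population) == config$total_population)

  region <- list(
    config = config,
    extent = list(
      core = c(xmin = 0, ymin = 0, xmax = W, ymax = H),
      buffer = c(xmin = -buf, ymin = -buf, xmax = W + buf, ymax = H + buf)
    ),
    districts = districts,
    network = network,
    practices = practices,
    timetable = timetable
  )
  class(region) <- "region"
  region
}

#' @export
print.region <- function(x, ...) {
  cat("Synthetic study region\n")
  cat(sprintf("  core extent : %.0f x %.0f km, buffer %.0f km\n",
              diff(x$extent$core[c(1, 3)]) / 1000,
              diff(x$extent$core[c(2, 4)]) / 1000,
              x$config$buffer_km))
  cat(sprintf("  districts   : %d (%s inhabitants)\n",
              nrow(x$districts),
              format(sum(x$districts$population), big.mark = ",")))
  cat(sprintf("  street net  : %d nodes, %d edges\n",
              nrow(x$network$nodes), nrow(x$network$edges)))
  tab <- table(x$practices$group)
  cat(sprintf("  practices   : %s\n",
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("  transit     : %d stops, %d trips\n",
              nrow(x$timetable$stops), nrow(x$timetable$trips)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# street network: jittered lattice, MST-guaranteed connectivity, three speed
# classes (30 local / 70 rural / 100 trunk), one-way flags on redundant edges
.make_lattice_network <- function(W, H, buf, sp) {
  gx <- seq(-buf, W + buf, by = sp)
  gy <- seq(-buf, H + buf, by = sp)
  nx <- length(gx)
  ny <- length(gy)
  n <- nx * ny
  x0 <- rep(gx, times = ny)
  y0 <- rep(gy, each = nx)
  x <- x0 + runif(n, -0.25 * sp, 0.25 * sp)
  y <- y0 + runif(n, -0.25 * sp, 0.25 * sp)
  ids <- sprintf("n%d", seq_len(n))

  idx <- matrix(seq_len(n), nrow = nx)
  ha <- as.vector(idx[-nx, , drop = FALSE])   # horizontal edges
  hb <- as.vector(idx[-1, , drop = FALSE])
  va <- as.vector(idx[, -ny, drop = FALSE])   # vertical edges
  vb <- as.vector(idx[, -1, drop = FALSE])
  ea <- c(ha, va)
  eb <- c(hb, vb)
  horiz <- c(rep(TRUE, length(ha)), rep(FALSE, length(va)))
  m <- length(ea)

  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[ea], to = ids[eb]),
    directed = FALSE, vertices = ids)
  igraph::E(g)$eid <- seq_len(m)
  mt <- igraph::mst(g, weights = runif(m))
  in_mst <- logical(m)
  in_mst[igraph::E(mt)$eid] <- TRUE

  keep <- in_mst | runif(m) < 0.8

  # trunk lines: two full grid rows and columns carry the motorway-like class
  trunk_rows <- sample(seq(2, max(2, ny - 1)), min(2, ny - 2))
  trunk_cols <- sample(seq(2, max(2, nx - 1)), min(2, nx - 2))
  row_of <- ((ea - 1) %/% nx) + 1
  col_of <- ((ea - 1) %% nx) + 1
  trunk <- (horiz & row_of %in% trunk_rows) | (!horiz & col_of %in% trunk_cols)
  speed <- ifelse(trunk, 100, ifelse(runif(m) < 0.3, 70, 30))
  oneway <- !in_mst & !trunk & runif(m) < 0.05

  ea <- ea[keep]; eb <- eb[keep]
  length_m <- euclid(x[ea], y[ea], x[eb], y[eb])
  edges <- data.frame(
    from = ids[ea], to = ids[eb],
    length_m = length_m, speed_kmh = speed[keep], oneway = oneway[keep],
    stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, x = x, y = y, stringsAsFactors = FALSE)

  network <- structure(list(nodes = nodes, edges = edges),
                       class = "street_network")
  list(network = network,
       grid = data.frame(id = ids, x0 = x0, y0 = y0, stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
.make_districts <- function(network, grid, config, W, H, sp) {
  n <- config$n_districts
  core <- grid$x0 >= sp / 2 & grid$x0 <= W - sp / 2 &
    grid$y0 >= sp / 2 & grid$y0 <= H - sp / 2
  core_ids <- grid$id[core]
  if (length(core_ids) < n) {
    stop("configuration error: extent too small for ", n, " districts",
         call. = FALSE)
  }
  sel <- sample(core_ids, n)
  ni <- match(sel, network$nodes$id)
  cx <- network$nodes$x[ni] + runif(n, -150, 150)
  cy <- network$nodes$y[ni] + runif(n, -150, 150)

  w <- rlnorm(n, meanlog = 0, sdlog = config$population_skew)
  pop <- .largest_remainder(config$total_population * w / sum(w),
                            config$total_population)

  data.frame(
    id = sprintf("d%04d", seq_len(n)),
    x = cx, y = cy,
    population = pop,
    node = sel,
    stringsAsFactors = FALSE)
}

# round non-negative reals to integers preserving the exact total
.largest_remainder <- function(p, total) {
  fl <- floor(p)
  k <- as.integer(round(total - sum(fl)))
  if (k > 0) {
    ord <- order(p - fl, decreasing = TRUE)
    fl[ord[seq_len(k)]] <- fl[ord[seq_len(k)]] + 1
  }
  as.integer(fl)
}

# ---------------------------------------------------------------------------
# transit: routes as chains of districts (population-seeded, greedy nearest
# unserved), paths along two-way street shortest paths, stops every
# 400-800 m with street edges subdivided so stops are network nodes
.make_transit <- function(network, districts, config) {
  empty_tt <- structure(list(
    stops = data.frame(stop_id = character(), x = numeric(), y = numeric(),
                       node = character(), stringsAsFactors = FALSE),
    trips = data.frame(trip_id = character(), route_id = character(),
                       direction = character(), service = character(),
                       stringsAsFactors = FALSE),
    stop_times = data.frame(trip_id = character(), stop_sequence = integer(),
                            stop_id = character(), arrival_s = integer(),
                            departure_s = integer(), stringsAsFactors = FALSE)),
    class = "timetable")
  if (config$n_routes == 0L) {
    return(list(network = network, timetable = empty_tt))
  }

  nd <- nrow(districts)
  two_way <- network$edges[!network$edges$oneway, , drop = FALSE]
  gp <- igraph::graph_from_data_frame(
    two_way[, c("from", "to")], directed = FALSE,
    vertices = network$nodes$id)
  wts <- two_way$length_m

  # mutable state shared across routes (edge splitting)
  st <- new.env(parent = emptyenv())
  st$nodes <- network$nodes
  st$edges <- network$edges
  st$e2row <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(network$edges))) {
    assign(.ekey(network$edges$from[r], network$edges$to[r]), r,
           envir = st$e2row)
  }
  st$emap <- new.env(parent = emptyenv())
  st$mcount <- 0L
  st$stop_of_node <- new.env(parent = emptyenv())
  st$stop_nodes <- character()

  served <- logical(nd)
  pop <- districts$population
  chain_len <- min(25L, max(4L, ceiling(1.3 * nd / config$n_routes)))
  route_stops <- vector("list", config$n_routes)

  for (r in seq_len(config$n_routes)) {
    cand <- if (any(!served)) which(!served) else seq_len(nd)
    start <- if (length(cand) == 1L) cand else
      sample(cand, 1, prob = pop[cand] + 1)
    chain <- start
    served[start] <- TRUE
    while (length(chain) < chain_len) {
      cur <- chain[length(chain)]
      cand <- which(!served)
      if (!length(cand)) cand <- setdiff(seq_len(nd), chain)
      if (!length(cand)) break
      dd <- euclid(districts$x[cur], districts$y[cur],
                   districts$x[cand], districts$y[cand])
      j <- cand[which.min(dd)]
      if (min(dd) > 12000 && length(chain) >= 4L) break
      chain <- c(chain, j)
      served[j] <- TRUE
    }

    # concatenated shortest paths between consecutive chain districts
    path <- districts$node[chain[1]]
    ok <- TRUE
    for (k in seq_len(length(chain) - 1)) {
      sp_k <- igraph::shortest_paths(
        gp, from = districts$node[chain[k]],
        to = districts$node[chain[k + 1]], weights = wts,
        output = "vpath")$vpath[[1]]
      vp <- names(sp_k)
      if (length(vp) < 2L) { ok <- FALSE; break }
      path <- c(path, vp[-1])
    }
    if (!ok || length(path) < 2L) next
    # drop immediate backtracks (chain may revisit a junction)
    path <- path[c(TRUE, path[-1] != path[-length(path)])]
    route_stops[[r]] <- .place_route_stops(st, path,
                                           districts$node[chain])
  }

  # stop table in creation order
  if (!length(st$stop_nodes)) {
    return(list(
      network = structure(list(nodes = st$nodes, edges = st$edges),
                          class = "street_network"),
      timetable = empty_tt))
  }
  stop_ids <- vapply(st$stop_nodes, function(nid) get(nid, st$stop_of_node),
                     character(1), USE.NAMES = FALSE)
  ni <- match(st$stop_nodes, st$nodes$id)
  stops <- data.frame(stop_id = stop_ids,
                      x = st$nodes$x[ni], y = st$nodes$y[ni],
                      node = st$stop_nodes, stringsAsFactors = FALSE)

  trips <- list()
  stop_times <- list()
  dep_sets <- list(
    school = seq(6 * 3600 + 1800, 19 * 3600, by = config$headway_min * 60),
    vacation = seq(8 * 3600, 16 * 3600, by = 2 * config$headway_min * 60))
  for (r in seq_len(config$n_routes)) {
    rs <- route_stops[[r]]
    if (is.null(rs) || length(rs$stop_id) < 2L) next
    route_id <- sprintf("r%02d", r)
    seqs <- list(
      out = list(ids = rs$stop_id, off = rs$cum_s - rs$cum_s[1]),
      inb = list(ids = rev(rs$stop_id),
                 off = rs$cum_s[length(rs$cum_s)] - rev(rs$cum_s)))
    for (svc in names(dep_sets)) {
      for (dep in dep_sets[[svc]]) {
        for (dir in names(seqs)) {
          sq <- seqs[[dir]]
          trip_id <- sprintf("%s_%s_%s_%05d", route_id, dir, svc, dep)
          tt <- as.integer(round(dep + sq$off))
          trips[[length(trips) + 1L]] <- data.frame(
            trip_id = trip_id, route_id = route_id, direction = dir,
            service = svc, stringsAsFactors = FALSE)
          stop_times[[length(stop_times) + 1L]] <- data.frame(
            trip_id = trip_id, stop_sequence = seq_along(sq$ids),
            stop_id = sq$ids, arrival_s = tt, departure_s = tt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  timetable <- structure(list(
    stops = stops,
    trips = do.call(rbind, trips),
    stop_times = do.call(rbind, stop_times)), class = "timetable")
  rownames(timetable$trips) <- NULL
  rownames(timetable$stop_times) <- NULL
  validate_timetable(timetable)

  list(network = structure(list(nodes = st$nodes, edges = st$edges),
                           class = "street_network"),
       timetable = timetable)
}

.ekey <- function(a, b) if (a < b) paste0(a, "|", b) else paste0(b, "|", a)

# walk a node path placing stops; splits street edges at mid-edge stops
.place_route_stops <- function(st, path, district_nodes) {
  out_nodes <- character()
  out_t <- numeric()
  add_stop <- function(node, t) {
    if (length(out_nodes) && out_nodes[length(out_nodes)] == node) return()
    if (!exists(node, st$stop_of_node)) {
      sid <- sprintf("s%04d", length(st$stop_nodes) + 1L)
      assign(node, sid, envir = st$stop_of_node)
      st$stop_nodes <- c(st$stop_nodes, node)
    }
    out_nodes[length(out_nodes) + 1L] <<- node
    out_t[length(out_t) + 1L] <<- t
  }

  cumt <- 0
  add_stop(path[1], 0)
  gap <- runif(1, 400, 800)
  since <- 0

  for (k in seq_len(length(path) - 1)) {
    u <- path[k]; v <- path[k + 1]
    key <- .ekey(u, v)
    chain <- if (exists(key, st$emap)) get(key, st$emap) else c(u, v)
    if (chain[1] != u) chain <- rev(chain)
    s <- 1L
    while (s < length(chain)) {
      a <- chain[s]; b <- chain[s + 1L]
      repeat {
        row <- get(.ekey(a, b), st$e2row)
        len <- st$edges$length_m[row]
        spd <- min(st$edges$speed_kmh[row], 60)  # bus speed cap
        tt <- 3.6 * len / spd
        if (since + len < gap - 50) {
          since <- since + len
          cumt <- cumt + tt
          break
        }
        d_in <- gap - since
        if (d_in <= 50) {
          add_stop(a, cumt)
          since <- 0
          gap <- runif(1, 400, 800)
        } else if (d_in >= len - 50) {
          cumt <- cumt + tt
          add_stop(b, cumt)
          since <- 0
          gap <- runif(1, 400, 800)
          break
        } else {
          m <- .split_edge(st, a, b, row, d_in, key)
          cumt <- cumt + tt * d_in / len
          add_stop(m, cumt)
          since <- 0
          gap <- runif(1, 400, 800)
          a <- m
          # chain gained a node; refresh local copy and stay on (m, b)
          chain <- append(chain, m, after = s)
          s <- s + 1L
        }
      }
      s <- s + 1L
    }
    if (v %in% district_nodes) {
      add_stop(v, cumt)
      since <- 0
      gap <- runif(1, 400, 800)
    }
  }
  add_stop(path[length(path)], cumt)

  sid <- vapply(out_nodes, function(nid) get(nid, st$stop_of_node),
                character(1), USE.NAMES = FALSE)
  list(stop_id = sid, cum_s = out_t)
}

.split_edge <- function(st, a, b, row, d_in, orig_key) {
  len <- st$edges$length_m[row]
  frac <- d_in / len
  ia <- match(a, st$nodes$id)
  ib <- match(b, st$nodes$id)
  st$mcount <- st$mcount + 1L
  m <- sprintf("ms%05d", st$mcount)
  mx <- st$nodes$x[ia] + frac * (st$nodes$x[ib] - st$nodes$x[ia])
  my <- st$nodes$y[ia] + frac * (st$nodes$y[ib] - st$nodes$y[ia])
  st$nodes <- rbind(st$nodes,
                    data.frame(id = m, x = mx, y = my,
                               stringsAsFactors = FALSE))

  spd <- st$edges$speed_kmh[row]
  ow <- st$edges$oneway[row]
  # keep stored orientation consistent with the original from->to direction
  if (st$edges$from[row] == a) {
    st$edges$to[row] <- m
    newe <- data.frame(from = m, to = b, length_m = len - d_in,
                       speed_kmh = spd, oneway = ow, stringsAsFactors = FALSE)
  } else {
    st$edges$from[row] <- m
    newe <- data.frame(from = b, to = m, length_m = len - d_in,
                       speed_kmh = spd, oneway = ow, stringsAsFactors = FALSE)
  }
  st$edges$length_m[row] <- d_in
  st$edges <- rbind(st$edges, newe)
  rm(list = .ekey(a, b), envir = st$e2row)
  assign(.ekey(a, m), row, envir = st$e2row)
  assign(.ekey(m, b), nrow(st$edges), envir = st$e2row)

  # record the subdivision under the original lattice pair
  ch <- if (exists(orig_key, st$emap)) get(orig_key, st$emap) else
    strsplit(orig_key, "|", fixed = TRUE)[[1]]
  pos <- which((ch[-length(ch)] == a & ch[-1] == b) |
                 (ch[-length(ch)] == b & ch[-1] == a))[1]
  ch <- append(ch, m, after = pos)
  assign(orig_key, ch, envir = st$emap)
  m
}

# ---------------------------------------------------------------------------
.make_practices <- function(network, grid, districts, config, W, H, sp) {
  nd <- nrow(districts)
  pop <- districts$population
  ord <- order(pop, decreasing = TRUE)
  towns <- ord[seq_len(max(3L, min(nd, ceiling(0.05 * nd))))]

  spec_counts <- c(OPHTHALMOLOGIST = config$n_ophthalmologist,
                   INTERNIST = config$n_internist,
                   UROLOGIST = config$n_urologist)
  host <- list()
  for (g in names(spec_counts)) {
    host[[g]] <- if (length(towns) == 1L) rep(towns, spec_counts[[g]]) else
      sample(towns, spec_counts[[g]], replace = TRUE, prob = pop[towns] + 1)
  }
  # every specialist town gets a GP; remaining GPs spread over the villages
  spec_districts <- unique(unlist(host))
  gp_hosts <- spec_districts[seq_len(min(config$n_gp, length(spec_districts)))]
  remaining <- config$n_gp - length(gp_hosts)
  if (remaining > 0L) {
    pool <- setdiff(seq_len(nd), gp_hosts)
    gp_hosts <- c(gp_hosts,
                  if (length(pool) == 1L) pool else
                    sample(pool, remaining, prob = (pop[pool] + 1)^0.3))
  }
  host[["GP"]] <- gp_hosts

  rows <- list()
  for (g in physician_groups()) {
    h <- host[[g]]
    if (is.null(h) || !length(h)) next
    rows[[g]] <- data.frame(
      id = sprintf("%s_%03d", g, seq_along(h)),
      group = g,
      x = districts$x[h] + runif(length(h), -100, 100),
      y = districts$y[h] + runif(length(h), -100, 100),
      in_buffer = FALSE,
      stringsAsFactors = FALSE)
  }

  # buffer ring providers: outside the core, inside core + buffer
  nb <- config$buffer_practices_per_group
  if (nb > 0L && config$buffer_km * 1000 >= sp) {
    outside <- grid$x0 <= -sp | grid$x0 >= W + sp |
      grid$y0 <= -sp | grid$y0 >= H + sp
    bnodes <- grid$id[outside]
    bnodes <- bnodes[bnodes %in% network$nodes$id]
    if (length(bnodes)) {
      for (g in physician_groups()) {
        pick <- if (length(bnodes) == 1L) rep(bnodes, nb) else
          sample(bnodes, nb, replace = length(bnodes) < nb)
        ni <- match(pick, network$nodes$id)
        rows[[paste0(g, "_buf")]] <- data.frame(
          id = sprintf("%s_B%02d", g, seq_len(nb)),
          group = g,
          x = network$nodes$x[ni] + runif(nb, -100, 100),
          y = network$nodes$y[ni] + runif(nb, -100, 100),
          in_buffer = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate a timetable object
#'
#' Checks referential integrity (every stop_time refers to an existing trip
#' and stop), that event times strictly increase along each trip, and that
#' arrivals never follow departures at a stop.
#'
#' @param timetable A `timetable` object.
#' @return The timetable, invisibly; errors describe the first violation.
#' @export
validate_timetable <- function(timetable) {
  stopifnot(inherits(timetable, "timetable") || is.list(timetable))
  st <- timetable$stop_times
  if (nrow(st)) {
    missing_stop <- !(st$stop_id %in% timetable$stops$stop_id)
    if (any(missing_stop)) {
      stop("stop_times references unknown stop '",
           st$stop_id[which(missing_stop)[1]], "' (row ",
           which(missing_stop)[1], ")", call. = FALSE)
    }
    missing_trip <- !(st$trip_id %in% timetable$trips$trip_id)
    if (any(missing_trip)) {
      stop("stop_times references unknown trip '",
           st$trip_id[which(missing_trip)[1]], "' (row ",
           which(missing_trip)[1], ")", call. = FALSE)
    }
    if (any(st$arrival_s > st$departure_s)) {
      stop("arrival after departure at stop_times row ",
           which(st$arrival_s > st$departure_s)[1], call. = FALSE)
    }
    for (tid in unique(st$trip_id)) {
      rows <- st[st$trip_id == tid, ]
      rows <- rows[order(rows$stop_sequence), ]
      # consecutive stops must strictly advance; dwell may be zero
      if (any(rows$arrival_s[-1] <= rows$departure_s[-nrow(rows)])) {
        stop("non-increasing event times in trip '", tid, "'", call. = FALSE)
      }
    }
  }
  invisible(timetable)
}
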