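# Property-style suites: monotonicity of the accessibility measures,
# closed-form checks, and leg-level validation of returned journeys.

test_that("adding a street edge never increases any car OD time", {
  set.seed(611)
  for (i in 1:12) {
    net <- random_car_network(8)
    g1 <- build_car_graph(net)
    ids <- net$nodes$id
    origins <- data.frame(id = ids[1:3], x = net$nodes$x[1:3],
                          y = net$nodes$y[1:3])
    dests <- data.frame(id = ids[6:8], x = net$nodes$x[6:8],
                        y = net$nodes$y[6:8])
    od1 <- od_cost_matrix(g1, origins, dests, snap_m = 1e9)
    # add one random edge
    ab <- sample(seq_along(ids), 2)
    net$edges <- rbind(net$edges, data.frame(
      from = ids[ab[1]], to = ids[ab[2]], length_m = runif(1, 100, 2000),
      speed_kmh = 100, oneway = TRUE, stringsAsFactors = FALSE))
    od2 <- od_cost_matrix(build_car_graph(net), origins, dests,
                          snap_m = 1e9)
    t1 <- ifelse(od1$reachable, od1$minutes, Inf)
    t2 <- ifelse(od2$reachable, od2$minutes, Inf)
    expect_true(all(t2 <= t1 + 1e-9))
  }
})

test_that("removing a practice never decreases a nearest-practice time", {
  set.seed(612)
  for (i in 1:10) {
    np <- 5
    odm <- data.frame(
      origin_id = rep(sprintf("d%d", 1:4), each = np),
      dest_id = rep(sprintf("p%d", 1:np), 4),
      minutes = runif(4 * np, 1, 60), km = runif(4 * np, 1, 50),
      reachable = TRUE, stringsAsFactors = FALSE)
    class(odm) <- c("od_matrix", "data.frame")
    pr <- data.frame(id = sprintf("p%d", 1:np), group = "GP",
                     stringsAsFactors = FALSE)
    full <- nearest_practice(odm, pr, "GP")
    drop <- sample(np, 1)
    reduced <- nearest_practice(
      odm[odm$dest_id != pr$id[drop], ], pr[-drop, ], "GP")
    m <- merge(full, reduced, by = "district_id")
    expect_true(all(m$minutes.y >= m$minutes.x - 1e-9))
  }
})

test_that("adding a trip never worsens a journey; fewer stops never help", {
  set.seed(613)
  p <- transit_params()
  window <- c(7 * 3600, 12 * 3600)
  for (i in 1:15) {
    inst <- random_transit_instance()
    eg1 <- build_event_graph(inst$timetable,
                             mk_fp(stop_stop = inst$transfers), p)
    j1 <- journey_search(eg1, inst$access, inst$egress, window, p)

    # extra trip over two random stops
    tt2 <- inst$timetable
    s2 <- sample(tt2$stops$stop_id, 2)
    t0 <- sample(seq(8 * 3600, 11 * 3600, by = 600), 1)
    extra <- mk_stop_times("extra", s2, c(t0, t0 + 600))
    tt2$stop_times <- rbind(tt2$stop_times, extra)
    tt2$trips <- rbind(tt2$trips,
                       data.frame(trip_id = "extra", route_id = "x",
                                  direction = "out", service = "school",
                                  stringsAsFactors = FALSE))
    eg2 <- build_event_graph(tt2, mk_fp(stop_stop = inst$transfers), p)
    j2 <- journey_search(eg2, inst$access, inst$egress, window, p)
    if (!is.null(j1)) {
      expect_false(is.null(j2))  # an OK pair never turns unconnected
      expect_lte(j2$duration_min, j1$duration_min + 1e-9)
    }

    # shrinking the candidate stop set (cap effect) never helps
    if (nrow(inst$access) > 1) {
      j3 <- journey_search(eg1, inst$access[-1, , drop = FALSE],
                           inst$egress, window, p)
      if (!is.null(j3)) {
        expect_false(is.null(j1))
        expect_gte(j3$duration_min, j1$duration_min - 1e-9)
      }
    }
  }
})

test_that("single-line closed form: duration within one headway of optimum", {
  p <- transit_params()
  v <- 1200  # in-vehicle seconds
  walks <- (10 + 6) * 60  # access 10 min, egress 6 min
  for (h in c(600, 900, 1800, 3600)) {
    deps <- seq(7 * 3600 + 300, 10 * 3600, by = h)
    st <- do.call(rbind, lapply(seq_along(deps), function(k)
      mk_stop_times(sprintf("t%d", k), c("A", "B"),
                    c(deps[k], deps[k] + v))))
    tt <- mk_timetable(st)
    eg <- build_event_graph(tt, mk_fp(), p)
    j <- journey_search(eg,
                        data.frame(stop_id = "A", walk_min = 10,
                                   dist_m = 300),
                        data.frame(stop_id = "B", walk_min = 6,
                                   dist_m = 180),
                        c(7 * 3600, 11 * 3600), p)
    dur <- j$duration_min * 60
    expect_gte(dur, v + walks - 1e-9)
    expect_lt(dur, v + walks + h)
  }
})

test_that("returned journeys validate leg by leg against the timetable", {
  set.seed(614)
  p <- transit_params()
  window <- c(7 * 3600, 12 * 3600)
  n_ok <- 0
  for (i in 1:20) {
    inst <- random_transit_instance()
    eg <- build_event_graph(inst$timetable,
                            mk_fp(stop_stop = inst$transfers), p)
    j <- journey_search(eg, inst$access, inst$egress, window, p)
    if (!is.null(j)) {
      expect_silent(validate_journey(j, inst$timetable, p))
      # duration is never less than the sum of its leg durations
      expect_gte(j$duration_min * 60 + 1e-6,
                 sum(j$legs$end_s - j$legs$start_s))
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 3)
})

test_that("shrinking the access cap never improves regional accessibility", {
  res <- demo_results()
  pd1 <- res$pt$per_district
  pt2 <- accessibility_by_transit(res$region,
                                  transit_params(max_walk_origin_to_stop_m = 500))
  pd2 <- pt2$per_district
  m <- merge(pd1, pd2, by = c("district_id", "group"))
  expect_gte(sum(pd2$status == "NO_CONNECTION"),
             sum(pd1$status == "NO_CONNECTION"))
  both <- m$status.x == "OK" & m$status.y == "OK"
  expect_true(all(m$total_min.y[both] >= m$total_min.x[both] - 1e-9))
  # no district connected under the tight cap is unconnected under the wide
  expect_false(any(m$status.x == "NO_CONNECTION" & m$status.y == "OK"))
})

test_that("band nesting: cumulative counts non-decreasing up to the total", {
  res <- demo_results()
  pd <- res$car$per_district
  gp <- pd[pd$group == "GP", ]
  pops <- res$region$districts$population[
    match(gp$district_id, res$region$districts$id)]
  zt <- zone_table(gp$minutes, c(5, 10, 15, 20), pops)
  body <- zt[zt$band != "Total", ]
  cum <- cumsum(body$n_inhabitants)
  expect_true(all(diff(cum) >= 0))
  expect_identical(cum[length(cum)], sum(pops))
})

test_that("co-located GPs dominate specialists in both travel modes", {
  # constructed fixture: every urologist location also hosts a GP, plus
  # extra GPs elsewhere -> per district nearest-GP <= nearest-urologist
  reg <- generate_region(region_config(
    extent_km = c(20, 15), n_districts = 25, total_population = 10000,
    n_gp = 8, n_ophthalmologist = 2, n_internist = 2, n_urologist = 2,
    buffer_km = 2, n_routes = 4, headway_min = 60, seed = 21))
  uro <- reg$practices[reg$practices$group == "UROLOGIST" &
                         !reg$practices$in_buffer, ]
  extra_gp <- reg$practices[reg$practices$group == "GP" &
                              !reg$practices$in_buffer, ][1:4, ]
  gp_at_uro <- uro
  gp_at_uro$group <- "GP"
  gp_at_uro$id <- sprintf("GP_%03d", 900 + seq_len(nrow(uro)))
  reg$practices <- rbind(uro, gp_at_uro, extra_gp)

  car <- accessibility_by_car(reg, groups = c("GP", "UROLOGIST"))
  w <- reshape(car$per_district[, c("district_id", "group", "minutes")],
               direction = "wide", idvar = "district_id",
               timevar = "group")
  expect_true(all(w$minutes.GP <= w$minutes.UROLOGIST + 1e-9, na.rm = TRUE))
  expect_lte(mean(w$minutes.GP, na.rm = TRUE),
             mean(w$minutes.UROLOGIST, na.rm = TRUE))

  pt <- accessibility_by_transit(reg, groups = c("GP", "UROLOGIST"))
  pd <- pt$per_district
  wide_tot <- reshape(pd[, c("district_id", "group", "total_min")],
                      direction = "wide", idvar = "district_id",
                      timevar = "group")
  ok <- !is.na(wide_tot$total_min.UROLOGIST)
  expect_true(all(!is.na(wide_tot$total_min.GP[ok])))  # GP at least as reachable
  expect_true(all(wide_tot$total_min.GP[ok] <=
                    wide_tot$total_min.UROLOGIST[ok] + 1e-9))
})
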