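test_that("walking time follows the closed-form conversion", {
  expect_equal(walking_time(1000, 3.6), 100 / 6, tolerance = 1e-12)  # 1 m/s
  expect_equal(round(walking_time(1000, 3.6), 2), 16.67)
  expect_equal(round(walking_time(1000, 1.8), 2), 33.33)
  expect_equal(walking_time(0, 1.8), 0)
  expect_error(walking_time(100, 0), "speed must be > 0")
  expect_error(walking_time(100, -2), "speed must be > 0")
})

test_that("footpaths respect caps and use street distances", {
  # straight street: o --900m-- s1 --400m-- s2, practice at s2
  net <- structure(list(
    nodes = data.frame(id = c("o", "s1", "s2"),
                       x = c(0, 900, 1300), y = 0, stringsAsFactors = FALSE),
    edges = data.frame(from = c("o", "s1"), to = c("s1", "s2"),
                       length_m = c(900, 400), speed_kmh = 30,
                       oneway = c(TRUE, FALSE),  # walking ignores one-way
                       stringsAsFactors = FALSE)),
    class = "street_network")
  p <- transit_params()
  fp <- footpaths(net,
                  districts = data.frame(id = "d1", x = 0, y = 0),
                  stops = data.frame(stop_id = c("s1", "s2"),
                                     x = c(900, 1300), y = 0),
                  practices = data.frame(id = "p1", x = 1300, y = 0),
                  params = p)
  os <- fp$origin_stop
  expect_identical(os$stop_id, "s1")          # s2 is 1300 m away: over cap
  expect_equal(os$dist_m, 900)
  expect_equal(os$walk_min, 30)               # at 1.8 km/h
  sp <- fp$stop_practice[order(fp$stop_practice$stop_id), ]
  expect_identical(sp$stop_id, c("s1", "s2"))   # both within 500 m
  expect_equal(sp$dist_m, c(400, 0))
  # transfer pairs within 250 m only; symmetric
  expect_identical(nrow(fp$stop_stop), 0L)    # 400 m apart
  expect_identical(nrow(fp$origin_practice), 0L)  # 1300 m > 1000 m cap
})

test_that("candidate stops are the k nearest within the cap", {
  os <- data.frame(origin_id = "d1",
                   stop_id = c("s5", "s2", "s3", "s1", "s4"),
                   dist_m = c(900, 300, 500, 300, 700),
                   walk_min = c(30, 10, 50 / 3, 10, 70 / 3),
                   stringsAsFactors = FALSE)
  fp <- mk_fp(origin_stop = os)
  cs <- candidate_access_stops(fp, "d1", 3)
  expect_identical(cs$stop_id, c("s1", "s2", "s3"))  # tie s1/s2 by id
  expect_identical(candidate_access_stops(fp, "d1", 2)$stop_id,
                   c("s1", "s2"))
  expect_identical(nrow(candidate_access_stops(fp, "nowhere", 3)), 0L)
})

test_that("event graph has the expected ride, wait and transfer edges", {
  st <- mk_stop_times("t1", c("A", "B", "C"), c(100, 200, 300))
  tt <- mk_timetable(st)
  eg <- build_event_graph(tt, mk_fp(), transit_params())
  expect_identical(sum(eg$edges$type == "ride"), 2L)
  expect_identical(sum(eg$edges$type == "wait"), 0L)
  expect_identical(sum(eg$edges$type == "transfer"), 0L)

  # second trip at stop A creates a wait edge chain
  st2 <- rbind(st, mk_stop_times("t2", c("A", "B"), c(400, 500)))
  tt2 <- mk_timetable(st2)
  eg2 <- build_event_graph(tt2, mk_fp(), transit_params())
  expect_identical(sum(eg2$edges$type == "wait"), 2L)  # A:100->400, B:200->500

  # transfer edges appear in both directions within 250 m, none at 300 m
  ss_near <- rbind(
    setNames(walk_row("A", "B", 200), c("from_stop", "to_stop", "dist_m",
                                        "walk_min")))
  eg3 <- build_event_graph(tt2, mk_fp(stop_stop = rbind(
    ss_near, setNames(walk_row("B", "A", 200),
                      c("from_stop", "to_stop", "dist_m", "walk_min")))),
    transit_params())
  tr <- eg3$edges[eg3$edges$type == "transfer", ]
  # the 200 m walk takes 400 s: only A@100 -> B@500 has a boardable target,
  # but candidate edges were generated for both directions
  expect_identical(eg3$events$stop_id[tr$from], "A")
  expect_identical(eg3$events$stop_id[tr$to], "B")
  walk_s <- 200 / 1800 * 3600
  expect_gte(eg3$events$time_s[tr$to],
             eg3$events$time_s[tr$from] + walk_s - 1e-9)
  # with a shorter walk both directions materialise
  ss_fast <- rbind(
    setNames(walk_row("A", "B", 30), c("from_stop", "to_stop", "dist_m",
                                       "walk_min")),
    setNames(walk_row("B", "A", 30), c("from_stop", "to_stop", "dist_m",
                                       "walk_min")))
  eg4 <- build_event_graph(tt2, mk_fp(stop_stop = ss_fast), transit_params())
  tr4 <- eg4$edges[eg4$edges$type == "transfer", ]
  expect_setequal(unique(eg4$events$stop_id[tr4$from]), c("A", "B"))

  fp300 <- mk_fp()  # 300 m pairs are already excluded by footpaths' cap
  expect_identical(sum(build_event_graph(tt2, fp300,
                                         transit_params())$edges$type ==
                         "transfer"), 0L)
})

test_that("single feasible journey: walks plus ride give duration 50", {
  # bus departs origin stop at 10:00, arrives practice stop at 10:30;
  # 10-minute walks on both sides -> depart 09:50, arrive 10:40
  st <- mk_stop_times("bus", c("S1", "S2"), c(36000, 37800))
  tt <- mk_timetable(st)
  eg <- build_event_graph(tt, mk_fp(), transit_params())
  p <- transit_params()
  access <- data.frame(stop_id = "S1", walk_min = 10, dist_m = 300)
  egress <- data.frame(stop_id = "S2", walk_min = 10, dist_m = 300)
  j <- journey_search(eg, access, egress, c("07:00", "11:00"), p)
  expect_equal(j$duration_min, 50)
  expect_equal(j$departure_s, 35400)  # 09:50
  expect_equal(j$arrival_s, 38400)    # 10:40
  expect_identical(j$legs$type, c("WALK", "RIDE", "WALK"))
  expect_identical(j$n_rides, 1L)
  expect_silent(validate_journey(j, tt, p))
})

test_that("the shorter-duration journey wins even departing later", {
  # slow early bus (08:00 -> 10:00) vs fast late bus (10:00 -> 10:30)
  st <- rbind(mk_stop_times("slow", c("S1", "S2"), c(28800, 36000)),
              mk_stop_times("fast", c("S1", "S2"), c(36000, 37800)))
  tt <- mk_timetable(st)
  eg <- build_event_graph(tt, mk_fp(), transit_params())
  p <- transit_params()
  access <- data.frame(stop_id = "S1", walk_min = 5, dist_m = 150)
  egress <- data.frame(stop_id = "S2", walk_min = 5, dist_m = 150)
  j <- journey_search(eg, access, egress, c("07:00", "11:00"), p)
  expect_equal(j$duration_min, 40)
  expect_identical(j$legs$trip_id[j$legs$type == "RIDE"], "fast")

  # with waiting at the practice counted, the latest departure wins too
  j2 <- journey_search(eg, access, egress, c("07:00", "11:00"), p,
                       latest_departure_objective = TRUE)
  expect_identical(j2$legs$trip_id[j2$legs$type == "RIDE"], "fast")
})

test_that("transfers chain rides with timetable waiting", {
  st <- rbind(mk_stop_times("t1", c("A", "B"), c(28800, 30600)),
              mk_stop_times("t2", c("C", "D"), c(31800, 33600)))
  tt <- mk_timetable(st, coords = data.frame(
    stop_id = c("A", "B", "C", "D"), x = c(0, 5000, 5200, 9000), y = 0))
  ss <- rbind(
    setNames(walk_row("B", "C", 200), c("from_stop", "to_stop", "dist_m",
                                        "walk_min")),
    setNames(walk_row("C", "B", 200), c("from_stop", "to_stop", "dist_m",
                                        "walk_min")))
  eg <- build_event_graph(mk_timetable(st), mk_fp(stop_stop = ss),
                          transit_params())
  p <- transit_params()
  access <- data.frame(stop_id = "A", walk_min = 5, dist_m = 150)
  egress <- data.frame(stop_id = "D", walk_min = 5, dist_m = 150)
  j <- journey_search(eg, access, egress, c("07:00", "11:00"), p)
  # 07:55 depart, ride to B 08:30, walk 200 m (6.67 min), wait, ride 08:50->09:20, walk
  expect_identical(j$legs$type[j$legs$type %in% c("RIDE")], c("RIDE", "RIDE"))
  expect_identical(j$n_rides, 2L)
  expect_equal(j$arrival_s, 33600 + 300)
  expect_silent(validate_journey(j, tt, p))
})

test_that("round trips sum both legs and detect missing return service", {
  # symmetric service: out 09:00->09:30, back 13:00->13:30
  st <- rbind(mk_stop_times("out", c("H", "P"), c(32400, 34200)),
              mk_stop_times("back", c("P", "H"), c(46800, 48600)))
  tt <- mk_timetable(st)
  p <- transit_params()
  fp <- mk_fp(
    origin_stop = setNames(walk_row("d1", "H", 300),
                           c("origin_id", "stop_id", "dist_m", "walk_min")),
    stop_practice = setNames(walk_row("P", "p1", 300),
                             c("stop_id", "practice_id", "dist_m",
                               "walk_min")))
  eg <- build_event_graph(tt, fp, p)
  rt <- round_trip("d1", "p1", eg, fp, p)
  expect_identical(rt$status, "OK")
  expect_equal(rt$outbound_min, rt$return_min)  # symmetric timetable
  expect_equal(rt$total_min, 2 * rt$outbound_min)

  # outbound feasible but no service after 12:00 -> NO_CONNECTION
  st2 <- mk_stop_times("out", c("H", "P"), c(32400, 34200))
  tt2 <- mk_timetable(st2)
  eg2 <- build_event_graph(tt2, fp, p)
  rt2 <- round_trip("d1", "p1", eg2, fp, p)
  expect_identical(rt2$status, "NO_CONNECTION")
  expect_true(is.na(rt2$total_min))
})

test_that("nearest reachable practice minimises the round-trip total", {
  # p_far: 40-min rides; p_near: 20-min rides
  st <- rbind(
    mk_stop_times("o1", c("H", "F"), c(32400, 34800)),
    mk_stop_times("b1", c("F", "H"), c(46800, 49200)),
    mk_stop_times("o2", c("H", "N"), c(32400, 33600)),
    mk_stop_times("b2", c("N", "H"), c(46800, 48000)))
  tt <- mk_timetable(st)
  p <- transit_params()
  fp <- mk_fp(
    origin_stop = setNames(walk_row("d1", "H", 300),
                           c("origin_id", "stop_id", "dist_m", "walk_min")),
    stop_practice = rbind(
      setNames(walk_row("F", "p_far", 300),
               c("stop_id", "practice_id", "dist_m", "walk_min")),
      setNames(walk_row("N", "p_near", 300),
               c("stop_id", "practice_id", "dist_m", "walk_min"))))
  eg <- build_event_graph(tt, fp, p)
  pr <- data.frame(id = c("p_far", "p_near"), group = "GP",
                   stringsAsFactors = FALSE)
  best <- nearest_reachable_practice("d1", "GP", eg, fp, pr, p)
  expect_identical(best$practice_id, "p_near")
  tot_far <- round_trip("d1", "p_far", eg, fp, p)$total_min
  expect_lt(best$total_min, tot_far)

  # all infeasible -> NO_CONNECTION
  fp0 <- mk_fp(origin_stop = setNames(
    walk_row("d1", "H", 300),
    c("origin_id", "stop_id", "dist_m", "walk_min")))
  eg0 <- build_event_graph(tt, fp0, p)
  none <- nearest_reachable_practice("d1", "GP", eg0, fp0, pr, p)
  expect_identical(none$status, "NO_CONNECTION")
})

test_that("direct walking fallback competes when allowed", {
  p <- transit_params()
  fp <- mk_fp(origin_practice = setNames(
    walk_row("d1", "p1", 600),
    c("origin_id", "practice_id", "dist_m", "walk_min")))
  eg <- build_event_graph(mk_timetable(
    mk_stop_times("t", c("X", "Y"), c(100, 200))), fp, p)
  rt <- round_trip("d1", "p1", eg, fp, p)
  expect_identical(rt$status, "OK")
  expect_equal(rt$outbound_min, 20)  # 600 m at 1.8 km/h
  expect_equal(rt$total_min, 40)

  p_strict <- transit_params(allow_walk_only = FALSE)
  rt2 <- round_trip("d1", "p1", eg, fp, p_strict)
  expect_identical(rt2$status, "NO_CONNECTION")
})

test_that("journeys match exhaustive enumeration on random timetables", {
  set.seed(777)
  p <- transit_params()
  window <- c(7 * 3600, 12 * 3600)
  checked <- 0
  for (i in 1:40) {
    inst <- random_transit_instance()
    eg <- build_event_graph(inst$timetable, mk_fp(stop_stop = inst$transfers),
                            p)
    j <- journey_search(eg, inst$access, inst$egress, window, p)
    bf <- bf_best_duration(inst$timetable$stop_times, inst$access,
                           inst$egress, inst$transfers, window)
    if (is.null(j)) {
      expect_true(is.infinite(bf))
    } else {
      expect_equal(j$duration_min * 60, bf, tolerance = 1e-6)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)  # enough non-trivial instances exercised
})
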