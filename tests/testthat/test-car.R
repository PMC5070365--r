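line_network <- function() {
  structure(list(
    nodes = data.frame(id = c("a", "b", "c"),
                       x = c(0, 1000, 2000), y = c(0, 0, 0),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                       length_m = c(1000, 1000), speed_kmh = c(100, 50),
                       oneway = c(FALSE, FALSE), stringsAsFactors = FALSE)),
    class = "street_network")
}

test_that("edge weights are seconds from length and speed", {
  g <- build_car_graph(line_network())
  w <- igraph::E(g)$weight_s[igraph::get_edge_ids(g, c("a", "b"))]
  expect_equal(w, 36)  # 1000 m at 100 km/h
  # closed form for arbitrary (length, speed)
  for (i in 1:10) {
    len <- runif(1, 10, 5000)
    spd <- runif(1, 5, 130)
    net <- line_network()
    net$edges$length_m[1] <- len
    net$edges$speed_kmh[1] <- spd
    g2 <- build_car_graph(net)
    expect_equal(igraph::E(g2)$weight_s[igraph::get_edge_ids(g2, c("a", "b"))],
                 3.6 * len / spd)
  }
  net <- line_network()
  net$edges$speed_kmh[1] <- 0
  expect_error(build_car_graph(net), "speeds must be positive")
})

test_that("one-way edges cannot be traversed in reverse", {
  net <- line_network()
  net$edges$oneway[1] <- TRUE
  g <- build_car_graph(net)
  tt <- car_travel_times(g, "c")
  expect_false(tt$reachable[tt$node == "a"])
  expect_true(is.na(tt$time_s[tt$node == "a"]))
  fwd <- car_travel_times(g, "a")
  expect_true(fwd$reachable[fwd$node == "c"])
})

test_that("triangle shortest path goes via the cheaper two-hop route", {
  net <- structure(list(
    nodes = data.frame(id = c("A", "B", "C"), x = c(0, 1, 2), y = c(0, 1, 0),
                       stringsAsFactors = FALSE),
    # weights 10, 10 and 25 seconds via length at fixed speed
    edges = data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                       length_m = c(100, 100, 250), speed_kmh = 36,
                       oneway = FALSE, stringsAsFactors = FALSE)),
    class = "street_network")
  g <- build_car_graph(net)
  tt <- car_travel_times(g, "A")
  expect_equal(tt$time_s[tt$node == "C"], 20)
  expect_equal(tt$dist_m[tt$node == "C"], 200)  # along the time-optimal path
  expect_error(car_travel_times(g, "nope"), "not in graph")
})

test_that("shortest paths match exhaustive enumeration on random graphs", {
  set.seed(401)
  for (i in 1:25) {
    net <- random_car_network(sample(5:9, 1))
    g <- build_car_graph(net)
    src <- net$nodes$id[1]
    tt <- car_travel_times(g, src)
    ed <- net$edges
    ed$weight_s <- 3.6 * ed$length_m / ed$speed_kmh
    bf <- bf_car_times(net$nodes$id, ed, src)
    for (v in net$nodes$id) {
      if (is.finite(bf$time[v])) {
        expect_equal(tt$time_s[tt$node == v], unname(bf$time[v]),
                     tolerance = 1e-9)
        expect_true(any(abs(tt$dist_m[tt$node == v] -
                              bf$opt_lengths[[v]]) < 1e-6))
      } else {
        expect_false(tt$reachable[tt$node == v])
      }
    }
  }
})

test_that("OD matrix is consistent with single-source searches", {
  net <- line_network()
  g <- build_car_graph(net)
  origins <- data.frame(id = "o1", x = 10, y = 5)
  dests <- data.frame(id = c("p1", "p2"), x = c(1010, 1990), y = c(0, 0))
  odm <- od_cost_matrix(g, origins, dests)
  expect_equal(odm$minutes[odm$dest_id == "p1"], 36 / 60)
  expect_equal(odm$km[odm$dest_id == "p2"], 2)
  # identical origin and destination node
  odm2 <- od_cost_matrix(g, data.frame(id = "x", x = 0, y = 0),
                         data.frame(id = "y", x = 0, y = 0))
  expect_equal(odm2$minutes, 0)
  expect_equal(odm2$km, 0)
  # unsnappable points are excluded with a warning
  expect_warning(
    odm3 <- od_cost_matrix(g, data.frame(id = "far", x = 99999, y = 99999),
                           dests),
    "excluded")
  expect_identical(nrow(odm3), 0L)
  expect_identical(attr(odm3, "excluded"), "far")
})

test_that("nearest practice minimises minutes with km and id tie-breaks", {
  odm <- data.frame(
    origin_id = "d1", dest_id = c("GP_2", "GP_1", "GP_3", "URO_1"),
    minutes = c(4, 9, 4, 2), km = c(3, 1, 2.5, 1),
    reachable = TRUE, stringsAsFactors = FALSE)
  class(odm) <- c("od_matrix", "data.frame")
  pr <- data.frame(id = odm$dest_id,
                   group = c("GP", "GP", "GP", "UROLOGIST"),
                   stringsAsFactors = FALSE)
  np <- nearest_practice(odm, pr, "GP")
  expect_equal(np$minutes, 4)
  expect_identical(np$practice_id, "GP_3")  # km tie-break
  odm$km[odm$dest_id == "GP_3"] <- 3
  np2 <- nearest_practice(odm, pr, "GP")
  expect_identical(np2$practice_id, "GP_2")  # id tie-break at equal km
  expect_error(nearest_practice(odm, pr, "INTERNIST"), "no practices")
})

test_that("a nearer buffer practice beats all core practices", {
  odm <- data.frame(origin_id = "d1", dest_id = c("GP_1", "GP_B01"),
                    minutes = c(9, 4), km = c(8, 3), reachable = TRUE,
                    stringsAsFactors = FALSE)
  class(odm) <- c("od_matrix", "data.frame")
  pr <- data.frame(id = c("GP_1", "GP_B01"), group = "GP",
                   stringsAsFactors = FALSE)
  np <- nearest_practice(odm, pr, "GP")
  expect_identical(np$practice_id, "GP_B01")
})

test_that("band assignment uses half-open intervals with terminal band", {
  br <- c(5, 10, 15, 20)
  expect_identical(as.character(band_assign(4.99, br)), "<5")
  expect_identical(as.character(band_assign(5, br)), "5 to <10")
  expect_identical(as.character(band_assign(22.9, br)), ">=20")
  expect_identical(as.character(band_assign(0, br)), "<5")
  expect_identical(levels(band_assign(0, br)),
                   c("<5", "5 to <10", "10 to <15", "15 to <20", ">=20"))
  expect_true(is.na(band_assign(NA, br)))
})

test_that("group summaries are mean, sample sd and max", {
  s <- summarize_group(c(6, 6, 6))
  expect_equal(unlist(s), c(mean_min = 6, sd_min = 0, max_min = 6))
  s2 <- summarize_group(c(2, 4, 6), km = c(1, 2, 3))
  expect_equal(s2$mean_min, 4)
  expect_equal(s2$sd_min, 2)
  expect_equal(s2$max_min, 6)
  expect_equal(s2$mean_km, 2)
  # against an independent two-pass computation
  for (i in 1:10) {
    x <- runif(sample(2:40, 1), 0, 60)
    s3 <- summarize_group(x)
    expect_equal(s3$sd_min, sqrt(sum((x - sum(x) / length(x))^2) /
                                   (length(x) - 1)))
  }
  expect_error(summarize_group(numeric()), "no travel times")
})
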