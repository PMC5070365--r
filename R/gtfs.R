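# GTFS text-file reading and writing.
#
# The timetable container maps 1:1 onto the standard GTFS text files
# (stops.txt, trips.txt, stop_times.txt, calendar.txt).  Coordinates are
# planar metres of the synthetic frame and are stored in the stop_lat /
# stop_lon columns (stop_lat = y, stop_lon = x); service-day tags
# ("school", "vacation") become service_ids in calendar.txt.

#' Write a timetable as GTFS text files
#'
#' Writes `stops.txt`, `routes.txt`, `trips.txt`, `stop_times.txt` and
#' `calendar.txt` into `directory` (created if needed).  Event times are
#' written as `HH:MM:SS`; [read_gtfs()] restores the original timetable
#' exactly on all fields used.
#'
#' @param timetable A `timetable` object (see [generate_region()]).
#' @param directory Output directory.
#' @return `directory`, invisibly.
#' @export
write_gtfs <- function(timetable, directory) {
  validate_timetable(timetable)
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)

  stops <- data.frame(
    stop_id = timetable$stops$stop_id,
    stop_name = timetable$stops$stop_id,
    stop_lat = timetable$stops$y,
    stop_lon = timetable$stops$x,
    stringsAsFactors = FALSE)
  write.csv(stops, file.path(directory, "stops.txt"),
            row.names = FALSE, quote = FALSE)

  routes <- unique(data.frame(
    route_id = timetable$trips$route_id,
    route_short_name = timetable$trips$route_id,
    route_type = 3L, stringsAsFactors = FALSE))
  write.csv(routes, file.path(directory, "routes.txt"),
            row.names = FALSE, quote = FALSE)

  trips <- data.frame(
    route_id = timetable$trips$route_id,
    service_id = timetable$trips$service,
    trip_id = timetable$trips$trip_id,
    direction_id = ifelse(timetable$trips$direction == "out", 0L, 1L),
    stringsAsFactors = FALSE)
  write.csv(trips, file.path(directory, "trips.txt"),
            row.names = FALSE, quote = FALSE)

  st <- data.frame(
    trip_id = timetable$stop_times$trip_id,
    arrival_time = format_clock(timetable$stop_times$arrival_s),
    departure_time = format_clock(timetable$stop_times$departure_s),
    stop_id = timetable$stop_times$stop_id,
    stop_sequence = timetable$stop_times$stop_sequence,
    stringsAsFactors = FALSE)
  write.csv(st, file.path(directory, "stop_times.txt"),
            row.names = FALSE, quote = FALSE)

  services <- unique(timetable$trips$service)
  if (!length(services)) services <- "school"
  cal <- data.frame(
    service_id = services,
    monday = 1L, tuesday = 1L, wednesday = 1L, thursday = 1L, friday = 1L,
    saturday = 0L, sunday = 0L,
    start_date = ifelse(services == "vacation", "20120625", "20120901"),
    end_date = ifelse(services == "vacation", "20120803", "20121220"),
    stringsAsFactors = FALSE)
  write.csv(cal, file.path(directory, "calendar.txt"),
            row.names = FALSE, quote = FALSE)

  invisible(directory)
}

#' Read a GTFS directory into a timetable
#'
#' Parses the GTFS text files written by [write_gtfs()] (or any GTFS feed
#' restricted to the fields used here).  Malformed times and dangling
#' references raise errors naming the offending file and line.
#'
#' @param directory Directory containing `stops.txt`, `trips.txt`,
#'   `stop_times.txt` and `calendar.txt`.
#' @return A `timetable` object.
#' @export
read_gtfs <- function(directory) {
  need <- c("stops.txt", "trips.txt", "stop_times.txt", "calendar.txt")
  for (f in need) {
    if (!file.exists(file.path(directory, f))) {
      stop("missing GTFS file: ", f, call. = FALSE)
    }
  }
  stops_raw <- read.csv(file.path(directory, "stops.txt"),
                        stringsAsFactors = FALSE)
  trips_raw <- read.csv(file.path(directory, "trips.txt"),
                        stringsAsFactors = FALSE)
  st_raw <- read.csv(file.path(directory, "stop_times.txt"),
                     stringsAsFactors = FALSE)
  .require_cols(stops_raw, c("stop_id", "stop_lat", "stop_lon"), "stops.txt")
  .require_cols(trips_raw, c("trip_id", "route_id", "service_id"), "trips.txt")
  .require_cols(st_raw, c("trip_id", "arrival_time", "departure_time",
                          "stop_id", "stop_sequence"), "stop_times.txt")

  arr <- .parse_gtfs_times(st_raw$arrival_time, "stop_times.txt")
  dep <- .parse_gtfs_times(st_raw$departure_time, "stop_times.txt")

  bad <- !(st_raw$stop_id %in% stops_raw$stop_id)
  if (any(bad)) {
    stop("stop_times.txt line ", which(bad)[1] + 1L,
         ": unknown stop_id '", st_raw$stop_id[which(bad)[1]], "'",
         call. = FALSE)
  }
  bad <- !(st_raw$trip_id %in% trips_raw$trip_id)
  if (any(bad)) {
    stop("stop_times.txt line ", which(bad)[1] + 1L,
         ": unknown trip_id '", st_raw$trip_id[which(bad)[1]], "'",
         call. = FALSE)
  }

  direction <- if ("direction_id" %in% names(trips_raw)) {
    ifelse(trips_raw$direction_id == 0, "out", "inb")
  } else rep("out", nrow(trips_raw))

  timetable <- structure(list(
    stops = data.frame(stop_id = as.character(stops_raw$stop_id),
                       x = stops_raw$stop_lon, y = stops_raw$stop_lat,
                       node = if ("node" %in% names(stops_raw))
                         stops_raw$node else NA_character_,
                       stringsAsFactors = FALSE),
    trips = data.frame(trip_id = as.character(trips_raw$trip_id),
                       route_id = as.character(trips_raw$route_id),
                       direction = direction,
                       service = as.character(trips_raw$service_id),
                       stringsAsFactors = FALSE),
    stop_times = data.frame(trip_id = as.character(st_raw$trip_id),
                            stop_sequence = as.integer(st_raw$stop_sequence),
                            stop_id = as.character(st_raw$stop_id),
                            arrival_s = arr, departure_s = dep,
                            stringsAsFactors = FALSE)),
    class = "timetable")
  validate_timetable(timetable)
  timetable
}

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(file, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

.parse_gtfs_times <- function(x, file) {
  ok <- grepl("^[0-9]{1,2}:[0-9]{2}(:[0-9]{2})?$", x)
  if (any(!ok)) {
    stop(file, " line ", which(!ok)[1] + 1L, ": malformed time '",
         x[which(!ok)[1]], "'", call. = FALSE)
  }
  parse_clock(x)
}
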