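# Travel-time zone tabulation with district and inhabitant shares.

#' Tabulate per-district travel times into zone bands
#'
#' Counts districts and inhabitants per half-open travel-time band (plus a
#' terminal open band and, where flagged, a NO_CONNECTION row) and reports
#' the shares both as half-up-rounded integers — the style of published
#' zone tables, whose columns may then sum to 99--101 — and exactly to one
#' decimal.
#'
#' @param values Per-district travel times (minutes or hours, matching
#'   `breaks`); `NA` allowed only where `no_connection` is `TRUE`.
#' @param breaks Strictly increasing band breaks.
#' @param populations Per-district inhabitant counts (no missing values).
#' @param no_connection Logical per district; these districts fill the
#'   NO_CONNECTION row. `NULL` for car-type tables without that row.
#' @return Data frame of class `zone_table`: `band`, `n_districts`,
#'   `n_inhabitants`, `pct_districts`, `pct_inhabitants` (integers),
#'   `pct_districts_exact`, `pct_inhabitants_exact` (one decimal), with a
#'   Total row last.
#' @export
#' @examples
#' zone_table(c(3, 7, 12), c(5, 10, 15, 20), c(100, 200, 700))
zone_table <- function(values, breaks, populations, no_connection = NULL) {
  n <- length(values)
  if (length(populations) != n || anyNA(populations)) {
    stop("populations must be known for every district", call. = FALSE)
  }
  populations <- as.integer(round(populations))
  if (is.null(no_connection)) no_connection <- rep(FALSE, n)
  stopifnot(length(no_connection) == n)
  if (anyNA(values[!no_connection])) {
    stop("travel time missing for a connected district", call. = FALSE)
  }

  labs <- band_labels(breaks)
  bands <- band_assign(ifelse(no_connection, NA, values), breaks)
  nd <- as.integer(table(bands))
  ni <- as.integer(vapply(labs, function(l)
    sum(populations[!is.na(bands) & bands == l]), numeric(1)))

  rows <- data.frame(band = labs, n_districts = nd, n_inhabitants = ni,
                     stringsAsFactors = FALSE)
  if (any(no_connection)) {
    rows <- rbind(rows, data.frame(
      band = "NO_CONNECTION",
      n_districts = sum(no_connection),
      n_inhabitants = sum(populations[no_connection]),
      stringsAsFactors = FALSE))
  }
  .finish_zone_table(rows, n, sum(populations))
}

#' Build a zone table from published band counts
#'
#' For recomputing the share arithmetic of an existing (printed) zone
#' table whose per-band district and inhabitant counts are known but whose
#' underlying per-district values are not.
#'
#' @param band Band labels, in display order (may include
#'   `"NO_CONNECTION"`).
#' @param n_districts,n_inhabitants Per-band counts.
#' @param total_districts,total_inhabitants Denominators; default to the
#'   column sums.
#' @return A `zone_table` data frame (see [zone_table()]).
#' @export
zone_table_from_counts <- function(band, n_districts, n_inhabitants,
                                   total_districts = sum(n_districts),
                                   total_inhabitants = sum(n_inhabitants)) {
  rows <- data.frame(band = band, n_districts = as.integer(n_districts),
                     n_inhabitants = as.integer(n_inhabitants),
                     stringsAsFactors = FALSE)
  .finish_zone_table(rows, total_districts, total_inhabitants)
}

.finish_zone_table <- function(rows, total_d, total_i) {
  total_d <- as.integer(total_d)
  total_i <- as.integer(total_i)
  rows$n_districts <- as.integer(rows$n_districts)
  rows$n_inhabitants <- as.integer(rows$n_inhabitants)
  rows$pct_districts <- as.integer(round_half_up(100 * rows$n_districts /
                                                   total_d))
  rows$pct_inhabitants <- as.integer(round_half_up(100 * rows$n_inhabitants /
                                                     total_i))
  rows$pct_districts_exact <- round_half_up(100 * rows$n_districts / total_d,
                                            1)
  rows$pct_inhabitants_exact <- round_half_up(100 * rows$n_inhabitants /
                                                total_i, 1)
  total <- data.frame(band = "Total", n_districts = total_d,
                      n_inhabitants = total_i,
                      pct_districts = sum(rows$pct_districts),
                      pct_inhabitants = sum(rows$pct_inhabitants),
                      pct_districts_exact = NA_real_,
                      pct_inhabitants_exact = NA_real_,
                      stringsAsFactors = FALSE)
  out <- rbind(rows, total)
  rownames(out) <- NULL
  class(out) <- c("zone_table", "data.frame")
  out
}

#' Cumulative inhabitant share through a band
#'
#' Share of inhabitants in all bands up to and including `up_to_band`
#' (bands are ordered as in the table; `"NO_CONNECTION"`, if present, comes
#' last, so accumulating through it returns 100).
#'
#' @param zt A `zone_table`.
#' @param up_to_band Band label to accumulate through.
#' @param what `"inhabitants"` or `"districts"`.
#' @return Exact cumulative percentage (unrounded).
#' @export
cumulative_share <- function(zt, up_to_band, what = "inhabitants") {
  stopifnot(inherits(zt, "zone_table"))
  body <- zt[zt$band != "Total", , drop = FALSE]
  i <- match(up_to_band, body$band)
  if (is.na(i)) stop("unknown band: '", up_to_band, "'", call. = FALSE)
  col <- if (what == "inhabitants") "n_inhabitants" else "n_districts"
  total <- zt[[col]][zt$band == "Total"]
  100 * sum(body[[col]][seq_len(i)]) / total
}
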