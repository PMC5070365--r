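# Region-wide public-transport accessibility.
#
# The per-pair search in round_trip() is exact but would repeat the same
# event-graph scans for every district x practice pair.  The pipeline
# instead scans once per distinct boarding event (memoised), derives
# earliest arrivals per stop, and evaluates all districts/practices from
# those tables; results are identical to the per-pair operations.

#' Public-transport accessibility pipeline for a region
#'
#' Computes, for every district and physician group, the round trip to the
#' nearest reachable practice under the model in [transit_params()]:
#' outbound within `[earliest_departure, appointment_time]`, return within
#' `[return_earliest, latest_home_arrival]`, walking caps applied at every
#' leg, `NO_CONNECTION` where no practice of the group is reachable on
#' both legs.
#'
#' @param region A `region` bundle.
#' @param params A [transit_params()] object.
#' @param groups Physician groups to analyse.
#' @return Object of class `transit_accessibility`: data frame
#'   `per_district` (district_id, group, outbound_min, return_min,
#'   total_min, status, practice_id) plus the `footpaths` and `event_graph`
#'   used.
#' @export
accessibility_by_transit <- function(region, params = transit_params(),
                                     groups = physician_groups()) {
  stopifnot(inherits(region, "region"))
  fp <- footpaths(region$network, region$districts, region$timetable$stops,
                  region$practices, params)
  eg <- build_event_graph(region$timetable, fp, params,
                          service = params$service)

  dist_ids <- region$districts$id
  prac <- region$practices[order(region$practices$id), , drop = FALSE]
  n_d <- length(dist_ids)
  n_p <- nrow(prac)

  w0o <- params$earliest_departure_s
  w1o <- params$appointment_time_s
  w0r <- params$return_earliest_s
  w1r <- params$latest_home_arrival_s

  # per-district candidate stops (<= k nearest within the access cap)
  cand <- lapply(dist_ids, function(d)
    candidate_access_stops(fp, d, params$k_access_stops))
  # per-practice egress stops
  pe <- lapply(prac$id, function(p) {
    sub <- fp$stop_practice[fp$stop_practice$practice_id == p, , drop = FALSE]
    list(code = match(sub$stop_id, eg$stop_ids), walk_s = sub$walk_min * 60)
  })

  outb <- matrix(Inf, n_d, n_p)
  retn <- matrix(Inf, n_d, n_p)

  if (length(eg$times)) {
    # ---- outbound: scan once per distinct boarding event
    memo_o <- new.env(parent = emptyenv())
    practice_arrivals <- function(e) {
      k <- as.character(e)
      if (!is.null(memo_o[[k]])) return(memo_o[[k]])
      arr <- .scan_stop_arrivals(eg, .scan_layers(eg, e, w1o)$A, w1o)
      pa <- vapply(pe, function(x) {
        if (!length(x$code)) return(Inf)
        v <- arr[x$code] + x$walk_s
        v[arr[x$code] > w1o] <- Inf
        min(c(v[v <= w1o], Inf))
      }, numeric(1))
      memo_o[[k]] <- pa
      pa
    }
    for (d in seq_len(n_d)) {
      cs <- cand[[d]]
      for (a in seq_len(nrow(cs))) {
        code <- match(cs$stop_id[a], eg$stop_ids)
        evs <- eg$stop_events[[code]]
        if (!length(evs)) next
        tb <- eg$times[evs]
        wa <- cs$walk_min[a] * 60
        sel <- which(tb - wa >= w0o & tb <= w1o)
        for (kk in sel) {
          pa <- practice_arrivals(evs[kk])
          dep <- tb[kk] - wa
          dur <- if (params$count_practice_wait) {
            ifelse(is.finite(pa), w1o - dep, Inf)
          } else {
            pa - dep
          }
          outb[d, ] <- pmin(outb[d, ], dur)
        }
      }
    }

    # ---- return: scan once per distinct practice-side boarding event
    cs_long <- do.call(rbind, lapply(seq_len(n_d), function(d) {
      cs <- cand[[d]]
      if (!nrow(cs)) return(NULL)
      data.frame(d = d, code = match(cs$stop_id, eg$stop_ids),
                 walk_s = cs$walk_min * 60)
    }))
    memo_r <- new.env(parent = emptyenv())
    district_arrivals <- function(e) {
      k <- as.character(e)
      if (!is.null(memo_r[[k]])) return(memo_r[[k]])
      da <- rep(Inf, n_d)
      if (!is.null(cs_long)) {
        arr <- .scan_stop_arrivals(eg, .scan_layers(eg, e, w1r)$A, w1r)
        v <- arr[cs_long$code] + cs_long$walk_s
        v[arr[cs_long$code] > w1r | v > w1r] <- Inf
        for (r in which(is.finite(v))) {
          if (v[r] < da[cs_long$d[r]]) da[cs_long$d[r]] <- v[r]
        }
      }
      memo_r[[k]] <- da
      da
    }
    for (p in seq_len(n_p)) {
      x <- pe[[p]]
      if (!length(x$code)) next
      for (a in seq_along(x$code)) {
        if (is.na(x$code[a])) next
        evs <- eg$stop_events[[x$code[a]]]
        if (!length(evs)) next
        tb <- eg$times[evs]
        wb <- x$walk_s[a]
        sel <- which(tb - wb >= w0r & tb <= w1r)
        for (kk in sel) {
          da <- district_arrivals(evs[kk])
          dep <- tb[kk] - wb
          retn[, p] <- pmin(retn[, p], da - dep)
        }
      }
    }
  }

  # ---- direct-walk fallback
  if (params$allow_walk_only && nrow(fp$origin_practice)) {
    op <- fp$origin_practice
    di <- match(op$origin_id, dist_ids)
    pi_ <- match(op$practice_id, prac$id)
    ws <- op$walk_min * 60
    ok_o <- ws <= (w1o - w0o)
    ok_r <- ws <= (w1r - w0r)
    for (r in seq_len(nrow(op))) {
      if (is.na(di[r]) || is.na(pi_[r])) next
      if (ok_o[r]) outb[di[r], pi_[r]] <- min(outb[di[r], pi_[r]], ws[r])
      if (ok_r[r]) retn[di[r], pi_[r]] <- min(retn[di[r], pi_[r]], ws[r])
    }
  }

  total <- outb + retn

  rows <- list()
  for (g in groups) {
    cols <- which(prac$group == g)  # prac sorted by id: ties -> smaller id
    if (!length(cols)) stop("no practices of group '", g, "'", call. = FALSE)
    for (d in seq_len(n_d)) {
      tt <- total[d, cols]
      if (all(is.infinite(tt))) {
        rows[[length(rows) + 1L]] <- data.frame(
          district_id = dist_ids[d], group = g,
          outbound_min = NA_real_, return_min = NA_real_,
          total_min = NA_real_, status = "NO_CONNECTION",
          practice_id = NA_character_, stringsAsFactors = FALSE)
      } else {
        j <- cols[which.min(tt)]
        rows[[length(rows) + 1L]] <- data.frame(
          district_id = dist_ids[d], group = g,
          outbound_min = outb[d, j] / 60, return_min = retn[d, j] / 60,
          total_min = total[d, j] / 60, status = "OK",
          practice_id = prac$id[j], stringsAsFactors = FALSE)
      }
    }
  }
  per_district <- do.call(rbind, rows)
  rownames(per_district) <- NULL
  out <- list(per_district = per_district, footpaths = fp, event_graph = eg,
              params = params)
  class(out) <- "transit_accessibility"
  out
}

#' @export
print.transit_accessibility <- function(x, ...) {
  pd <- x$per_district
  cat("Public-transport accessibility (",
      length(unique(pd$district_id)), " districts)\n", sep = "")
  for (g in unique(pd$group)) {
    sub <- pd[pd$group == g, ]
    ok <- sub$status == "OK"
    cat(sprintf("  %-15s mean total %6.1f min, no connection %d/%d\n", g,
                mean(sub$total_min[ok]), sum(!ok), nrow(sub)))
  }
  invisible(x)
}
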