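# Report bundle: zone-table CSVs, comparison JSON, Thiessen GeoJSON layer
# and a Markdown summary, with deterministic ordering throughout.

#' Write an accessibility report bundle
#'
#' Emits, into `out_dir`: one CSV per zone table (published column order:
#' band, district count, inhabitant count, integer shares, exact shares),
#' one JSON per group comparison, a GeoJSON polygon layer with each
#' district's band and a categorical fill colour, and a `summary.md`
#' overview.  Inputs are written in name order so re-runs are
#' byte-stable.
#'
#' @param out_dir Output directory (created if needed).
#' @param zone_tables Named list of `zone_table` objects.
#' @param comparisons Named list of `group_comparison` objects.
#' @param polygons Optional `thiessen_tessellation`.
#' @param polygon_bands Optional data frame `id`, `band` matching the
#'   tessellation seeds (e.g. the per-district band of one group).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(out_dir, zone_tables = list(),
                          comparisons = list(), polygons = NULL,
                          polygon_bands = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()

  for (nm in sort(names(zone_tables))) {
    path <- file.path(out_dir, paste0("zone_", nm, ".csv"))
    write.csv(as.data.frame(zone_tables[[nm]]), path, row.names = FALSE)
    written <- c(written, path)
  }

  for (nm in sort(names(comparisons))) {
    cm <- comparisons[[nm]]
    path <- file.path(out_dir, paste0("comparison_", nm, ".json"))
    jsonlite::write_json(
      list(H = cm$H, df = cm$df, p_value = cm$p_value, method = cm$method,
           alpha = cm$alpha, pairwise = cm$pairwise),
      path, auto_unbox = TRUE, digits = NA)
    written <- c(written, path)
  }

  if (!is.null(polygons)) {
    props <- data.frame(seed = names(polygons$polygons),
                        stringsAsFactors = FALSE)
    if (!is.null(polygon_bands)) {
      i <- match(props$seed, polygon_bands$id)
      props$band <- as.character(polygon_bands$band[i])
      bands <- sort(unique(props$band))
      pal <- grDevices::hcl.colors(max(length(bands), 2L), "YlOrRd",
                                   rev = TRUE)
      props$fill <- pal[match(props$band, bands)]
    }
    path <- file.path(out_dir, "districts_thiessen.geojson")
    write_geojson_polygons(polygons$polygons, path, properties = props)
    written <- c(written, path)
  }

  md <- c("# Accessibility report", "")
  for (nm in sort(names(zone_tables))) {
    zt <- zone_tables[[nm]]
    md <- c(md, paste0("## Zone table: ", nm), "",
            paste(names(zt), collapse = " | "),
            paste(rep("---", ncol(zt)), collapse = " | "),
            vapply(seq_len(nrow(zt)), function(i)
              paste(vapply(zt[i, ], function(v)
                ifelse(is.na(v), "", format(v)), character(1)),
                collapse = " | "), character(1)),
            "")
  }
  for (nm in sort(names(comparisons))) {
    cm <- comparisons[[nm]]
    md <- c(md, paste0("## Group comparison: ", nm), "",
            sprintf("Kruskal-Wallis H = %.4f (df = %d), p = %.4g; %s",
                    cm$H, cm$df, cm$p_value,
                    paste0(sum(cm$pairwise$significant), "/",
                           nrow(cm$pairwise),
                           " pairs significant at alpha = ", cm$alpha)),
            "")
  }
  path <- file.path(out_dir, "summary.md")
  writeLines(md, path)
  written <- c(written, path)
  invisible(written)
}
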