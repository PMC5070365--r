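#' Configuration of a synthetic study region
#'
#' Describes the shape and contents of a generated region: a rectangular core
#' study area with a surrounding buffer ring, population districts with
#' log-normally skewed sizes, four groups of physician practices, and a
#' school-day-oriented bus/train timetable.  The defaults emulate the scale
#' of a sparsely populated north-east German county: about 3,900 km2,
#' 464 districts and 239,102 inhabitants, with specialists concentrated in a
#' handful of towns and a 15 km buffer ring of additional providers around
#' the core region.
#'
#' @param extent_km Width and height of the core study rectangle in km.
#' @param n_districts Number of population districts.
#' @param total_population Total inhabitants; district populations sum to
#'   this exactly.
#' @param population_skew Log-normal sigma of district sizes (larger means a
#'   few dominant towns and many small villages).
#' @param n_gp,n_ophthalmologist,n_internist,n_urologist Practice counts per
#'   physician group inside the core region.
#' @param buffer_km Width of the buffer ring around the core; providers in
#'   the ring are eligible destinations (edge-effect correction).
#' @param buffer_practices_per_group Extra practices of each group placed
#'   inside the buffer ring.
#' @param n_routes Number of public-transport routes.
#' @param headway_min Base service interval on a school day, in minutes;
#'   vacation service runs at twice this interval.
#' @param seed Integer RNG seed; the whole bundle is a deterministic
#'   function of the configuration including this seed.
#' @return An object of class `region_config`.
#' @seealso [generate_region()], [read_region_config()], [demo_region_config()]
#' @export
#' @examples
#' cfg <- region_config(n_districts = 50, total_population = 20000,
#'                      extent_km = c(30, 20), n_gp = 12, seed = 7)
region_config <- function(extent_km = c(84, 47),
                          n_districts = 464,
                          total_population = 239102,
                          population_skew = 1.6,
                          n_gp = 140,
                          n_ophthalmologist = 12,
                          n_internist = 15,
                          n_urologist = 6,
                          buffer_km = 15,
                          buffer_practices_per_group = 2,
                          n_routes = 17,
                          headway_min = 120,
                          seed = 1L) {
  cfg <- list(
    extent_km = as.numeric(extent_km),
    n_districts = as.integer(n_districts),
    total_population = as.integer(total_population),
    population_skew = as.numeric(population_skew),
    n_gp = as.integer(n_gp),
    n_ophthalmologist = as.integer(n_ophthalmologist),
    n_internist = as.integer(n_internist),
    n_urologist = as.integer(n_urologist),
    buffer_km = as.numeric(buffer_km),
    buffer_practices_per_group = as.integer(buffer_practices_per_group),
    n_routes = as.integer(n_routes),
    headway_min = as.numeric(headway_min),
    seed = as.integer(seed)
  )
  class(cfg) <- "region_config"
  validate_region_config(cfg)
  cfg
}

validate_region_config <- function(cfg) {
  stopifnot(inherits(cfg, "region_config"))
  if (length(cfg$extent_km) != 2L || any(!is.finite(cfg$extent_km)) ||
      any(cfg$extent_km <= 0)) {
    stop("extent_km must be two positive numbers (width, height in km)",
         call. = FALSE)
  }
  counts <- c(n_districts = cfg$n_districts, total_population = cfg$total_population,
              n_gp = cfg$n_gp, n_ophthalmologist = cfg$n_ophthalmologist,
              n_internist = cfg$n_internist, n_urologist = cfg$n_urologist)
  bad <- counts < 1L | is.na(counts)
  if (any(bad)) {
    stop("configuration error: ", paste(names(counts)[bad], collapse = ", "),
         " must be >= 1", call. = FALSE)
  }
  if (is.na(cfg$buffer_km) || cfg$buffer_km < 0) {
    stop("configuration error: buffer_km must be >= 0", call. = FALSE)
  }
  if (cfg$n_routes < 0L) {
    stop("configuration error: n_routes must be >= 0", call. = FALSE)
  }
  if (cfg$headway_min <= 0) {
    stop("configuration error: headway_min must be > 0", call. = FALSE)
  }
  grp <- c(cfg$n_gp, cfg$n_ophthalmologist, cfg$n_internist, cfg$n_urologist)
  if (any(grp > cfg$n_districts)) {
    stop("configuration error: more practices of a group (",
         max(grp), ") than districts (", cfg$n_districts, ")", call. = FALSE)
  }
  if (cfg$population_skew < 0 || !is.finite(cfg$population_skew)) {
    stop("configuration error: population_skew must be finite and >= 0",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a region configuration from a YAML file
#'
#' The file holds a flat mapping whose keys mirror the arguments of
#' [region_config()]; missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `region_config` object.
#' @export
read_region_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(region_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(region_config, vals)
}

#' Write a region configuration to a YAML file
#'
#' @param config A `region_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_config <- function(config, path) {
  validate_region_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Scaled-down demonstration region configuration
#'
#' A compact region used by the worked examples: 100 districts and 50,000
#' inhabitants on a 40 x 25 km core with a 6 km buffer, 30 GPs spread over
#' the villages, a few specialists clustered in the towns, and 10 bus routes
#' at an hourly school-day headway.  Small enough that the full car and
#' public-transport pipelines complete in a few minutes on one CPU while
#' preserving the structural contrasts of the full-scale configuration
#' (dispersed GPs versus clustered specialists, skewed populations,
#' school-oriented service).
#'
#' @param seed Integer RNG seed.
#' @return A `region_config` object.
#' @export
demo_region_config <- function(seed = 1L) {
  region_config(
    extent_km = c(40, 25),
    n_districts = 100,
    total_population = 50000,
    population_skew = 1.6,
    n_gp = 30,
    n_ophthalmologist = 4,
    n_internist = 5,
    n_urologist = 2,
    buffer_km = 6,
    buffer_practices_per_group = 1,
    n_routes = 10,
    headway_min = 60,
    seed = seed
  )
}
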