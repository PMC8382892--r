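#' Population map
#'
#' Links individuals to populations and populations to habitat
#' (`"mine"` or `"coast"`), region and geographic coordinates.
#'
#' @param individuals A data frame with columns `individual`, `population`.
#' @param populations A data frame with column `population` and optional
#'   `habitat`, `region`, `lat`, `lon`. Habitat tokens are case-folded;
#'   only `mine`/`coast` are accepted.
#' @return An object of class `pop_map`: a list of two tibbles,
#'   `individuals` and `populations`.
#' @export
#'
#' @examples
#' pm <- pop_map(data.frame(individual = c("i1", "i2"),
#'                          population = c("A", "A")),
#'               data.frame(population = "A", habitat = "Mine",
#'                          region = "R1", lat = 52.3, lon = -3.9))
#' pm$populations$habitat
pop_map <- function(individuals, populations = NULL) {
  individuals <- as_tibble(individuals)
  stopifnot(all(c("individual", "population") %in% names(individuals)))
  individuals <- dplyr::distinct(individuals,
                                 .data$individual, .data$population)
  dup <- duplicated(individuals$individual)
  if (any(dup))
    stop("individual(s) assigned to more than one population: ",
         paste(unique(individuals$individual[dup]), collapse = ", "),
         call. = FALSE)
  if (is.null(populations)) {
    populations <- tibble(population = unique(individuals$population))
  }
  populations <- as_tibble(populations)
  stopifnot("population" %in% names(populations))
  if (anyDuplicated(populations$population))
    stop("each population must appear once in the population table",
         call. = FALSE)
  for (col in c("habitat", "region")) {
    if (!col %in% names(populations)) populations[[col]] <- NA_character_
  }
  for (col in c("lat", "lon")) {
    if (!col %in% names(populations)) populations[[col]] <- NA_real_
  }
  hab <- tolower(trimws(as.character(populations$habitat)))
  bad <- !is.na(hab) & !hab %in% c("mine", "coast")
  if (any(bad))
    stop("unknown habitat token(s): ",
         paste(unique(populations$habitat[bad]), collapse = ", "),
         call. = FALSE)
  populations$habitat <- hab
  ok_lat <- is.na(populations$lat) | abs(populations$lat) <= 90
  ok_lon <- is.na(populations$lon) | abs(populations$lon) <= 180
  if (!all(ok_lat) || !all(ok_lon))
    stop("coordinates out of range (|lat| <= 90, |lon| <= 180)",
         call. = FALSE)
  extra <- setdiff(individuals$population, populations$population)
  if (length(extra))
    stop("individuals reference unknown population(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  structure(list(individuals = individuals,
                 populations = populations[, c("population", "habitat",
                                               "region", "lat", "lon")]),
            class = "pop_map")
}

as_pop_map <- function(x) {
  if (inherits(x, "pop_map")) return(x)
  if (is.data.frame(x)) {
    popcols <- intersect(c("population", "habitat", "region", "lat", "lon"),
                         names(x))
    pops <- dplyr::distinct(as_tibble(x)[popcols])
    return(pop_map(x[, c("individual", "population")], pops))
  }
  stop("cannot interpret object as a pop_map", call. = FALSE)
}

#' @exportS3Method base::print
print.pop_map <- function(x, ...) {
  cat(sprintf("<pop_map> %d individuals in %d populations\n",
              nrow(x$individuals), nrow(x$populations)))
  print(x$populations)
  invisible(x)
}

#' Individuals belonging to a population
#' @param pm A [pop_map()].
#' @param pop Population label.
#' @return Character vector of individual ids.
#' @export
pop_individuals <- function(pm, pop) {
  pm <- as_pop_map(pm)
  if (!pop %in% pm$populations$population)
    stop("population not in map: ", pop, call. = FALSE)
  pm$individuals$individual[pm$individuals$population == pop]
}

#' Mine-coast pairs by region
#'
#' Returns the within-region (mine, coast) population pairs defined by a
#' population map, the comparisons used by the outlier scan and the
#' observed IBD analysis.
#'
#' @param pm A [pop_map()].
#' @return A tibble with columns `region`, `mine`, `coast`.
#' @export
region_pairs <- function(pm) {
  pm <- as_pop_map(pm)
  pops <- pm$populations
  if (any(is.na(pops$habitat)) || any(is.na(pops$region)))
    stop("habitat and region must be defined for all populations",
         call. = FALSE)
  pops |>
    dplyr::select("population", "habitat", "region") |>
    tidyr::pivot_wider(names_from = "habitat",
                       values_from = "population") |>
    dplyr::select("region", "mine", "coast")
}
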