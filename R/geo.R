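#' Great-circle distance between two coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Coordinates are
#' `c(lat, lon)` in decimal degrees.
#'
#' @param coord_a,coord_b Numeric length-2 vectors `c(lat, lon)`.
#' @return Distance in km.
#' @export
#'
#' @examples
#' haversine_km(c(51.5, -0.12), c(48.85, 2.35))  # London-Paris, ~343 km
haversine_km <- function(coord_a, coord_b) {
  check_coord <- function(x, nm) {
    if (length(x) != 2 || anyNA(x) || !is.numeric(x))
      stop(nm, " must be numeric c(lat, lon)", call. = FALSE)
    if (abs(x[1]) > 90 || abs(x[2]) > 180)
      stop(nm, " out of range (|lat| <= 90, |lon| <= 180)", call. = FALSE)
  }
  check_coord(coord_a, "coord_a")
  check_coord(coord_b, "coord_b")
  # geosphere expects (lon, lat); r in km gives km out
  geosphere::distHaversine(c(coord_a[2], coord_a[1]),
                           c(coord_b[2], coord_b[1]),
                           r = 6371.0088)
}

#' Pairwise geographic distances between populations
#'
#' @param pm A [pop_map()] with coordinates.
#' @param pops Populations (default all with coordinates).
#' @return A tibble `pop_a`, `pop_b`, `km`.
#' @export
pop_distances <- function(pm, pops = NULL) {
  pm <- as_pop_map(pm)
  tab <- pm$populations
  if (is.null(pops)) pops <- tab$population
  tab <- tab[match(pops, tab$population), ]
  if (anyNA(tab$lat) || anyNA(tab$lon))
    stop("missing coordinates for: ",
         paste(tab$population[is.na(tab$lat) | is.na(tab$lon)],
               collapse = ", "), call. = FALSE)
  prs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(prs)), function(i) {
    a <- tab[tab$population == prs[1, i], ]
    b <- tab[tab$population == prs[2, i], ]
    tibble(pop_a = prs[1, i], pop_b = prs[2, i],
           km = haversine_km(c(a$lat, a$lon), c(b$lat, b$lon)))
  })
}
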