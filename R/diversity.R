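#' Nucleotide diversity per variant site
#'
#' Mean pairwise difference per variant site within one population:
#' for each site with at least two genotyped individuals and
#' `0 < p < 1`, the unbiased per-site value `(n/(n-1)) * 2*p*(1-p)` with
#' `n` the number of non-missing alleles, averaged over contributing
#' variant sites. Reported per variant site, not per bp.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param pop Population label.
#' @return An object of class `diversity_result`: list with `population`,
#'   `pi` (mean over variant sites), `n_variant_sites` and `per_site`
#'   tibble.
#' @export
nucleotide_diversity <- function(gm, pm, pop) {
  stopifnot(inherits(gm, "geno_matrix"))
  pm <- as_pop_map(pm)
  ids <- intersect(pop_individuals(pm, pop), sample_ids(gm))
  if (!length(ids)) stop("no genotyped individuals in ", pop,
                         call. = FALSE)
  d <- gm$dosages[ids, , drop = FALSE]
  n_ind <- colSums(!is.na(d))
  n_al <- 2 * n_ind
  p <- ifelse(n_al > 0, colSums(d, na.rm = TRUE) / n_al, NA_real_)
  variant <- n_ind >= 2 & !is.na(p) & p > 0 & p < 1
  if (!any(variant))
    stop("no variant sites in population ", pop, call. = FALSE)
  pi_site <- ifelse(variant, (n_al / (n_al - 1)) * 2 * p * (1 - p),
                    NA_real_)
  structure(list(population = pop,
                 pi = mean(pi_site[variant]),
                 n_variant_sites = sum(variant),
                 per_site = dplyr::bind_cols(
                   gm$sites,
                   tibble(n_alleles = n_al, p = p, pi = pi_site,
                          variant = variant))),
            class = "diversity_result")
}

#' @exportS3Method base::print
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> %s: pi = %.4f per variant site (%d sites)\n",
              x$population, x$pi, x$n_variant_sites))
  invisible(x)
}

#' @export
tidy.diversity_result <- function(x, ...) x$per_site

#' @export
glance.diversity_result <- function(x, ...) {
  tibble(population = x$population, pi = x$pi,
         n_variant_sites = x$n_variant_sites)
}

# Tajima constants for sample size n (number of alleles)
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Tajima's D in non-overlapping windows of `window_bp` bp anchored at
#' position 1 on each scaffold (half-open `[start, start + window_bp)`
#' intervals). Within a window, the mean pairwise difference uses each
#' site's own unbiased `2*p*(1-p)*n/(n-1)` term; the `a1..e2` constants
#' use the modal number of non-missing alleles across segregating sites
#' in the window (with complete data this is the standard statistic).
#' Windows with `S = 0`, fewer than 4 alleles, or a non-positive variance
#' denominator are flagged undefined rather than erroring.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param pop Population label.
#' @param window_bp Window width in bp (default 20000).
#' @return An object of class `tajima_result`: list with `population`,
#'   `mean_d` (mean over defined windows), and `windows` tibble
#'   (scaffold, start, end, S, n, pi, D, defined).
#' @export
tajimas_d <- function(gm, pm, pop, window_bp = 20000) {
  stopifnot(inherits(gm, "geno_matrix"))
  pm <- as_pop_map(pm)
  ids <- intersect(pop_individuals(pm, pop), sample_ids(gm))
  if (!length(ids)) stop("no genotyped individuals in ", pop,
                         call. = FALSE)
  d <- gm$dosages[ids, , drop = FALSE]
  n_al <- 2 * colSums(!is.na(d))
  p <- ifelse(n_al > 0, colSums(d, na.rm = TRUE) / n_al, NA_real_)
  seg <- n_al >= 2 & !is.na(p) & p > 0 & p < 1
  win <- ((gm$sites$pos - 1L) %/% as.integer(window_bp)) *
    as.integer(window_bp) + 1L
  key <- tibble(scaffold = gm$sites$scaffold, start = win,
                seg = seg, n_al = n_al,
                pi_term = ifelse(seg, 2 * p * (1 - p) * n_al / (n_al - 1),
                                 0))
  windows <- key |>
    dplyr::group_by(.data$scaffold, .data$start) |>
    dplyr::summarise(
      S = sum(.data$seg),
      n = if (any(.data$seg))
        modal_value(.data$n_al[.data$seg]) else NA_integer_,
      pi = sum(.data$pi_term),
      .groups = "drop") |>
    dplyr::mutate(end = .data$start + as.integer(window_bp))
  dvals <- purrr::pmap_dbl(windows[c("S", "n", "pi")], function(S, n, pi) {
    if (S < 1 || is.na(n) || n < 4) return(NA_real_)
    k <- tajima_constants(n)
    denom <- k$e1 * S + k$e2 * S * (S - 1)
    if (denom <= 0) return(NA_real_)
    (pi - S / k$a1) / sqrt(denom)
  })
  windows$D <- dvals
  windows$defined <- is.finite(dvals)
  windows <- windows[, c("scaffold", "start", "end", "S", "n", "pi",
                         "D", "defined")]
  structure(list(population = pop,
                 mean_d = if (any(windows$defined))
                   mean(windows$D[windows$defined]) else NA_real_,
                 windows = windows,
                 window_bp = window_bp),
            class = "tajima_result")
}

modal_value <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' @exportS3Method base::print
print.tajima_result <- function(x, ...) {
  cat(sprintf("<tajima_result> %s: mean D = %.3f over %d defined window(s)\n",
              x$population, x$mean_d, sum(x$windows$defined)))
  invisible(x)
}

#' @export
tidy.tajima_result <- function(x, ...) x$windows

#' Cross-population mean Tajima's D
#'
#' Per-population windowed Tajima's D restricted to the windows where D
#' is defined in every requested population, then averaged per
#' population.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param pops Populations (default all in the map).
#' @param window_bp Window width in bp.
#' @return A tibble with columns `population`, `mean_d`,
#'   `n_shared_windows`.
#' @export
mean_tajimas_d <- function(gm, pm, pops = NULL, window_bp = 20000) {
  pm <- as_pop_map(pm)
  if (is.null(pops)) pops <- pm$populations$population
  res <- purrr::map(pops, ~ tajimas_d(gm, pm, .x, window_bp))
  tabs <- purrr::map2_dfr(res, pops, function(r, pp)
    dplyr::mutate(r$windows, population = pp))
  shared <- tabs |>
    dplyr::group_by(.data$scaffold, .data$start) |>
    dplyr::filter(all(.data$defined), dplyr::n() == length(pops)) |>
    dplyr::ungroup()
  if (!nrow(shared))
    stop("no window has defined D in all populations", call. = FALSE)
  shared |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(mean_d = mean(.data$D),
                     n_shared_windows = dplyr::n(), .groups = "drop")
}
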