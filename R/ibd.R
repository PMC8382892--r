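#' Isolation-by-distance regression
#'
#' Ordinary least-squares fit of pairwise FST on pairwise distance for
#' one pair class. Raw FST is regressed (no FST/(1-FST) linearization).
#'
#' @param fst_pairs Numeric vector of pairwise FST values.
#' @param distances Numeric vector of matching distances (chain steps
#'   for simulated demes, km for observed populations).
#' @param pair_class One of `"mine-mine"`, `"coast-coast"`,
#'   `"mine-coast"`.
#' @param distance_metric Label recorded with the fit
#'   (`"chain_steps"` or `"km"`).
#' @return A one-row tibble of class `ibd_fit`: `pair_class`, `slope`,
#'   `intercept`, `r2`, `n_pairs`, `distance_metric`.
#' @export
ibd_regression <- function(fst_pairs, distances,
                           pair_class = c("mine-mine", "coast-coast",
                                          "mine-coast"),
                           distance_metric = "chain_steps") {
  pair_class <- match.arg(pair_class)
  ok <- is.finite(fst_pairs) & is.finite(distances)
  fst_pairs <- fst_pairs[ok]
  distances <- distances[ok]
  if (length(fst_pairs) != length(distances))
    stop("fst_pairs and distances must have equal length", call. = FALSE)
  if (length(fst_pairs) < 3)
    stop("need at least 3 pairs for an IBD fit", call. = FALSE)
  if (length(unique(distances)) < 2)
    stop("all distances identical: slope undefined", call. = FALSE)
  fit <- lm(fst_pairs ~ distances)
  # summary.lm warns on an exactly perfect fit; r2 is still valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out <- tibble(pair_class = pair_class,
                slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r2 = r2, n_pairs = length(fst_pairs),
                distance_metric = distance_metric)
  class(out) <- c("ibd_fit", class(out))
  out
}

# chain position of a simulated deme (mines inherit the position of the
# matched coastal deme)
chain_position <- function(pop) as.integer(substring(pop, 2))

#' Per-replicate IBD fits from simulation summaries
#'
#' For each replicate, regresses pairwise FST on distance within the
#' mine-mine and coast-coast classes. The default distance is the
#' chain-step count between deme positions on the p1-p4 line (mines
#' inherit their matched coastal deme's position); alternatively
#' `-log10` of the effective migration rate along the chain.
#'
#' @param replicates A stacked [run_experiment()] tibble.
#' @param cfg The [sim_config()] (needed for
#'   `metric = "neg_log_migration"`).
#' @param metric `"chain_steps"` (default) or `"neg_log_migration"`.
#' @return A tibble with one row per replicate x class, columns of
#'   [ibd_regression()] plus `replicate`, `scenario`.
#' @export
replicate_ibd <- function(replicates, cfg = NULL,
                          metric = c("chain_steps",
                                     "neg_log_migration")) {
  metric <- match.arg(metric)
  within <- replicates[replicates$class %in% c("mine-mine",
                                               "coast-coast"), ]
  pos_a <- chain_position(within$pop_a)
  pos_b <- chain_position(within$pop_b)
  if (metric == "chain_steps") {
    within$distance <- abs(pos_a - pos_b)
  } else {
    if (is.null(cfg)) stop("cfg required for neg_log_migration",
                           call. = FALSE)
    edges <- c(cfg$m12, cfg$m23, cfg$m34)
    chain <- purrr::map2_dbl(pmin(pos_a, pos_b), pmax(pos_a, pos_b),
                             function(a, b)
                               if (a == b) 0
                               else sum(-log10(edges[a:(b - 1)])))
    within$distance <- chain +
      ifelse(within$class == "mine-mine",
             2 * -log10(cfg$m_mine_coast), 0)
  }
  within |>
    dplyr::group_by(.data$replicate, .data$scenario, .data$class) |>
    dplyr::group_modify(function(df, key)
      ibd_regression(df$fst, df$distance, key$class,
                     distance_metric = metric) |>
        dplyr::select(-"pair_class")) |>
    dplyr::ungroup() |>
    dplyr::rename(pair_class = "class")
}

#' Paired mine-vs-coast contrast of IBD strength across replicates
#'
#' The discriminating statistic for colonization origins: per replicate,
#' the mine-mine and coast-coast IBD slopes (and intercepts) are
#' compared with a paired two-sided t-test across replicates. Under a
#' multiple-origin scenario mine IBD is steeper; under a single-origin
#' scenario the contrast reverses.
#'
#' @param replicates A stacked [run_experiment()] tibble, or a
#'   pre-computed [replicate_ibd()] table.
#' @param cfg,metric Passed to [replicate_ibd()] when `replicates` is a
#'   raw summary table.
#' @return An object of class `scenario_contrast`: list with `scenario`,
#'   `fits` (per-replicate wide table), `t_slope` and `t_intercept`
#'   ([paired_t()] rows, mine minus coast).
#' @export
scenario_contrast <- function(replicates, cfg = NULL,
                              metric = "chain_steps") {
  fits <- if ("pair_class" %in% names(replicates)) replicates
          else replicate_ibd(replicates, cfg, metric)
  wide <- fits |>
    dplyr::select("replicate", "scenario", "pair_class", "slope",
                  "intercept") |>
    tidyr::pivot_wider(names_from = "pair_class",
                       values_from = c("slope", "intercept"))
  need <- c("slope_mine-mine", "slope_coast-coast",
            "intercept_mine-mine", "intercept_coast-coast")
  if (!all(need %in% names(wide)) || anyNA(wide[need]))
    stop("every replicate must yield both a mine-mine and a ",
         "coast-coast fit", call. = FALSE)
  if (nrow(wide) < 2) stop("need at least 2 replicates", call. = FALSE)
  structure(
    list(scenario = unique(wide$scenario),
         fits = wide,
         t_slope = paired_t(wide$`slope_mine-mine`,
                            wide$`slope_coast-coast`),
         t_intercept = paired_t(wide$`intercept_mine-mine`,
                                wide$`intercept_coast-coast`)),
    class = "scenario_contrast")
}

#' @exportS3Method base::print
print.scenario_contrast <- function(x, ...) {
  cat(sprintf("<scenario_contrast> %s, %d replicates\n",
              paste(x$scenario, collapse = "/"), nrow(x$fits)))
  cat(sprintf("  slope (mine - coast): mean = %+.4g, paired t = %.2f, p = %.3g\n",
              mean(x$fits$`slope_mine-mine` -
                     x$fits$`slope_coast-coast`),
              x$t_slope$t, x$t_slope$p))
  cat(sprintf("  intercept (mine - coast): mean = %+.4g, p = %.3g\n",
              mean(x$fits$`intercept_mine-mine` -
                     x$fits$`intercept_coast-coast`),
              x$t_intercept$p))
  invisible(x)
}

#' @export
tidy.scenario_contrast <- function(x, ...) x$fits

#' @export
glance.scenario_contrast <- function(x, ...) {
  tibble(scenario = paste(x$scenario, collapse = "/"),
         n_replicates = nrow(x$fits),
         mean_slope_diff = mean(x$fits$`slope_mine-mine` -
                                  x$fits$`slope_coast-coast`),
         t_slope = x$t_slope$t, p_slope = x$t_slope$p,
         t_intercept = x$t_intercept$t, p_intercept = x$t_intercept$p)
}

#' Observed isolation by distance from genotypes and coordinates
#'
#' Pairwise Weir-Cockerham FST for all populations, haversine distances
#' from the map coordinates, and one IBD fit per pair class.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()] with habitat and coordinates.
#' @return A list with `pairs` (tibble: pop_a, pop_b, class, fst, km)
#'   and `fits` (stacked [ibd_regression()] rows per class).
#' @export
observed_ibd <- function(gm, pm) {
  pm <- as_pop_map(pm)
  pops <- pm$populations
  if (anyNA(pops$habitat))
    stop("habitat must be defined for all populations", call. = FALSE)
  fst <- pairwise_fst(gm, pm)
  km <- pop_distances(pm)
  hab <- setNames(pops$habitat, pops$population)
  pairs <- dplyr::left_join(fst, km, by = c("pop_a", "pop_b")) |>
    dplyr::mutate(class = dplyr::case_when(
      hab[.data$pop_a] == "mine" & hab[.data$pop_b] == "mine" ~
        "mine-mine",
      hab[.data$pop_a] == "coast" & hab[.data$pop_b] == "coast" ~
        "coast-coast",
      TRUE ~ "mine-coast"))
  fits <- pairs |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(df, key)
      ibd_regression(df$fst, df$km, key$class,
                     distance_metric = "km") |>
        dplyr::select(-"pair_class")) |>
    dplyr::ungroup() |>
    dplyr::rename(pair_class = "class")
  list(pairs = pairs, fits = fits)
}
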