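#' Simulation configuration for the colonization scenarios
#'
#' Full demographic parameterization of the two colonization scenarios:
#' a burn-in ancestral population, stepwise stepping-stone colonization
#' of four coastal demes (p1 -> p2 -> p3 -> p4), then founding of four
#' mine demes either independently from the matched coastal deme
#' (multiple origin) or all from one randomly chosen coastal deme
#' (single origin).
#'
#' `rescale_Q` applies standard population-genetic rescaling: sizes and
#' durations are divided by Q and per-generation rates (mutation,
#' recombination, migration) multiplied by Q, which preserves
#' `4*N*mu`, `4*N*r`, `N*m` and `t/N` exactly. Every size and duration
#' must be divisible by Q.
#'
#' @param L Chromosome length in bp.
#' @param mu Per-bp per-generation mutation rate.
#' @param rec Per-bp per-generation recombination rate.
#' @param N_anc Ancestral population size (diploid individuals).
#' @param burn_in Burn-in duration in generations.
#' @param coastal_founders Founding size of each coastal deme.
#' @param coastal_size Post-growth size of each coastal deme.
#' @param growth_delay Generations between coastal founding and growth.
#' @param colonization_interval Generations between successive coastal
#'   colonizations.
#' @param m12 Backward migration rate between p1 and p2.
#' @param m23,m34 Backward migration rates between p2-p3 and p3-p4.
#' @param mine_founders Founding (and permanent) size of each mine deme.
#' @param mine_coast_gap Generations between the founding of the last
#'   coastal deme and the founding of the mines.
#' @param m_mine_coast Backward migration rate between each mine and its
#'   matched coastal deme.
#' @param post_mine_generations Generations of evolution after mine
#'   founding before sampling.
#' @param extra_generations Additional generations appended before
#'   sampling (default 0).
#' @param n_replicates Number of independent replicates for
#'   [run_experiment()].
#' @param rescale_Q Rescaling factor Q >= 1 (default 10, desk scale).
#' @param sample_n Individuals sampled per deme at the end (0 = all).
#' @param seed Integer seed for [run_experiment()].
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(L = 50000, mu = 7.5e-9, rec = 4.0e-9,
                       N_anc = 10000, burn_in = 100000,
                       coastal_founders = 500, coastal_size = 1000,
                       growth_delay = 10, colonization_interval = 20,
                       m12 = 1e-5, m23 = 1e-4, m34 = 1e-4,
                       mine_founders = 100, mine_coast_gap = 10000,
                       m_mine_coast = 2e-4, post_mine_generations = 100,
                       extra_generations = 0, n_replicates = 100,
                       rescale_Q = 10, sample_n = 0, seed = 1L) {
  cfg <- list(L = as.integer(L), mu = mu, rec = rec,
              N_anc = as.integer(N_anc), burn_in = as.integer(burn_in),
              coastal_founders = as.integer(coastal_founders),
              coastal_size = as.integer(coastal_size),
              growth_delay = as.integer(growth_delay),
              colonization_interval = as.integer(colonization_interval),
              m12 = m12, m23 = m23, m34 = m34,
              mine_founders = as.integer(mine_founders),
              mine_coast_gap = as.integer(mine_coast_gap),
              m_mine_coast = m_mine_coast,
              post_mine_generations = as.integer(post_mine_generations),
              extra_generations = as.integer(extra_generations),
              n_replicates = as.integer(n_replicates),
              rescale_Q = as.integer(rescale_Q),
              sample_n = as.integer(sample_n),
              seed = as.integer(seed))
  rates <- c(cfg$mu * cfg$rescale_Q, cfg$rec * cfg$rescale_Q,
             cfg$m12, cfg$m23, cfg$m34, cfg$m_mine_coast)
  if (any(rates < 0) || any(rates * cfg$rescale_Q > 1))
    stop("rates must stay within [0, 1] after rescaling", call. = FALSE)
  sizes <- c(cfg$N_anc, cfg$coastal_founders, cfg$coastal_size,
             cfg$mine_founders)
  durs <- c(cfg$burn_in, cfg$growth_delay, cfg$colonization_interval,
            cfg$mine_coast_gap, cfg$post_mine_generations)
  if (any(sizes <= 0) || any(durs <= 0))
    stop("sizes and durations must be positive", call. = FALSE)
  if (cfg$rescale_Q < 1) stop("rescale_Q must be >= 1", call. = FALSE)
  if (any(c(sizes, durs, cfg$extra_generations) %% cfg$rescale_Q != 0))
    stop("all sizes and durations must be divisible by rescale_Q ",
         "(rescaling must preserve t/N exactly)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# rescaled (engine-unit) view of a config
scaled_config <- function(cfg) {
  q <- cfg$rescale_Q
  within_list <- cfg
  for (f in c("N_anc", "burn_in", "coastal_founders", "coastal_size",
              "growth_delay", "colonization_interval", "mine_founders",
              "mine_coast_gap", "post_mine_generations",
              "extra_generations"))
    within_list[[f]] <- cfg[[f]] %/% q
  for (f in c("mu", "rec", "m12", "m23", "m34", "m_mine_coast"))
    within_list[[f]] <- cfg[[f]] * q
  within_list
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  s <- scaled_config(x)
  cat(sprintf("<sim_config> L=%d bp, theta/site=%.2e, Q=%d\n",
              x$L, 4 * s$N_anc * s$mu, x$rescale_Q))
  cat(sprintf("  engine units: N_anc=%d, burn-in=%d gen, %d replicates\n",
              s$N_anc, s$burn_in, x$n_replicates))
  invisible(x)
}

# deme index layout used by the engine
.demes <- c(anc = 0L, p1 = 1L, p2 = 2L, p3 = 3L, p4 = 4L,
            m1 = 5L, m2 = 6L, m3 = 7L, m4 = 8L)

#' Build the demographic event schedule for a scenario
#'
#' Encodes, in engine (rescaled) generations: burn-in of one ancestral
#' deme; founding of p1 and p2 from it (and its removal); stepwise
#' founding of p3 from p2 and p4 from p3 every `colonization_interval`
#' generations; coastal growth `growth_delay` generations after each
#' founding; stepping-stone migration p1-p2, p2-p3, p3-p4 activated as
#' soon as both demes exist; founding of the four mine demes
#' `mine_coast_gap` generations after p4 (multiple origin: mk from pk;
#' single origin: all four from one coastal deme); mine-coast migration
#' mk-pk thereafter; sampling `post_mine_generations` (+
#' `extra_generations`) later.
#'
#' @param cfg A [sim_config()].
#' @param kind `"multiple_origin"` or `"single_origin"`.
#' @param founder For `single_origin`, the founding coastal deme index
#'   (1-4) or `NA` to draw uniformly at random per replicate (default).
#' @return An `event_schedule`: a tibble (generation, event, deme,
#'   source, n, rate) with the config, kind and founder as attributes.
#'   Generations are in rescaled units.
#' @export
build_scenario <- function(cfg, kind = c("multiple_origin",
                                         "single_origin"),
                           founder = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "sim_config"))
  s <- scaled_config(cfg)
  ev <- function(generation, event, deme, source = NA_character_,
                 n = NA_integer_, rate = NA_real_)
    tibble(generation = as.integer(generation), event = event,
           deme = deme, source = source, n = as.integer(n), rate = rate)
  b <- s$burn_in
  ci <- s$colonization_interval
  gd <- s$growth_delay
  mine_gen <- b + 2L * ci + s$mine_coast_gap
  stop_gen <- mine_gen + s$post_mine_generations + s$extra_generations
  mines <- paste0("m", 1:4)
  coasts <- paste0("p", 1:4)
  if (kind == "multiple_origin") {
    mine_src <- coasts
  } else {
    mine_src <- rep(if (is.na(founder)) NA_character_
                    else coasts[founder], 4)
  }
  sched <- dplyr::bind_rows(
    ev(0L, "found", "anc", NA, s$N_anc),
    ev(b, "found", "p1", "anc", s$coastal_founders),
    ev(b, "found", "p2", "anc", s$coastal_founders),
    ev(b, "set_migration", "p1", "p2", rate = s$m12),
    ev(b, "remove", "anc"),
    ev(b + gd, "resize", "p1", n = s$coastal_size),
    ev(b + gd, "resize", "p2", n = s$coastal_size),
    ev(b + ci, "found", "p3", "p2", s$coastal_founders),
    ev(b + ci, "set_migration", "p2", "p3", rate = s$m23),
    ev(b + ci + gd, "resize", "p3", n = s$coastal_size),
    ev(b + 2L * ci, "found", "p4", "p3", s$coastal_founders),
    ev(b + 2L * ci, "set_migration", "p3", "p4", rate = s$m34),
    ev(b + 2L * ci + gd, "resize", "p4", n = s$coastal_size),
    purrr::map2_dfr(mines, mine_src,
                    ~ ev(mine_gen, "found", .x, .y, s$mine_founders)),
    purrr::map2_dfr(mines, coasts,
                    ~ ev(mine_gen, "set_migration", .x, .y,
                         rate = s$m_mine_coast)),
    ev(stop_gen, "sample_and_stop", NA_character_)
  )
  sched <- dplyr::arrange(sched, .data$generation,
                          match(.data$event, c("found", "resize",
                                               "set_migration", "remove",
                                               "sample_and_stop")))
  structure(sched, class = c("event_schedule", class(sched)),
            cfg = cfg, kind = kind, founder = founder)
}

# translate a schedule into the engine's integer encoding
encode_schedule <- function(sched) {
  codes <- c(found = 0L, resize = 1L, set_migration = 2L, remove = 3L,
             sample_and_stop = 4L)
  list(gen = sched$generation,
       type = unname(codes[sched$event]),
       deme = ifelse(is.na(sched$deme), -1L,
                     unname(.demes[sched$deme])),
       other = ifelse(is.na(sched$source), -1L,
                      unname(.demes[sched$source])),
       n = ifelse(is.na(sched$n), -1L, sched$n),
       rate = ifelse(is.na(sched$rate), 0, sched$rate))
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
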