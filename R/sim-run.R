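#' Run one simulation replicate
#'
#' Executes the Wright-Fisher engine on a scenario schedule and returns
#' the pairwise Weir-Cockerham FST summary among the eight final demes:
#' 6 coastal pairs, 6 mine pairs and 16 mine-coast pairs. FST is computed
#' with the same estimator as the empirical module ([wc_fst()]) on all
#' sampled individuals (or `cfg$sample_n` per deme).
#'
#' For a `single_origin` schedule built with `founder = NA`, the founding
#' coastal deme is drawn uniformly from p1-p4 using `rng_seed`.
#'
#' @param schedule An `event_schedule` from [build_scenario()].
#' @param cfg The [sim_config()] the schedule was built from (defaults to
#'   the one stored in the schedule).
#' @param rng_seed Integer seed for this replicate.
#' @return A tibble with one row per deme pair: `scenario`, `seed`,
#'   `founder_choice`, `pop_a`, `pop_b`, `class` (coast-coast, mine-mine,
#'   mine-coast), `fst`.
#' @export
run_replicate <- function(schedule, cfg = attr(schedule, "cfg"),
                          rng_seed = 1L) {
  stopifnot(inherits(schedule, "event_schedule"))
  kind <- attr(schedule, "kind")
  founder <- attr(schedule, "founder")
  engine_seed <- rng_seed
  if (kind == "single_origin" && any(is.na(schedule$source) &
                                     schedule$event == "found" &
                                     schedule$deme != "anc")) {
    draws <- with_seed(rng_seed, list(f = sample.int(4, 1),
                                      s = sample.int(.Machine$integer.max, 1)))
    founder <- draws$f
    engine_seed <- draws$s
    mine_rows <- schedule$event == "found" & schedule$deme %in%
      paste0("m", 1:4)
    schedule$source[mine_rows] <- paste0("p", founder)
  }
  s <- scaled_config(cfg)
  enc <- encode_schedule(schedule)
  out <- wf_engine(n_demes = length(.demes), L = cfg$L, mu = s$mu,
                   rec = s$rec, ev_gen = enc$gen, ev_type = enc$type,
                   ev_deme = enc$deme, ev_other = enc$other,
                   ev_n = enc$n, ev_rate = enc$rate,
                   seed = as.double(engine_seed),
                   sample_n = cfg$sample_n)
  sim_pair_fst(out, kind, rng_seed, founder)
}

# engine output -> pairwise FST tibble over the final demes
sim_pair_fst <- function(out, kind, rng_seed, founder) {
  deme_names <- names(.demes)[match(out$deme, .demes)]
  ids <- paste0("ind", seq_along(deme_names))
  gm <- geno_matrix(out$dosages,
                    rep("chr1", length(out$positions)),
                    out$positions, ids)
  pm <- pop_map(data.frame(individual = ids, population = deme_names))
  pops <- unique(deme_names)
  prs <- utils::combn(sort(pops), 2)
  purrr::map_dfr(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    cls <- pair_class(a, b)
    f <- tryCatch(wc_fst(gm, pm, a, b)$multilocus_fst,
                  error = function(e) NA_real_)
    tibble(scenario = kind, seed = rng_seed,
           founder_choice = if (identical(kind, "single_origin"))
             as.integer(founder) else NA_integer_,
           pop_a = a, pop_b = b, class = cls, fst = f)
  })
}

pair_class <- function(a, b) {
  am <- startsWith(a, "m"); bm <- startsWith(b, "m")
  dplyr::case_when(am & bm ~ "mine-mine",
                   !am & !bm ~ "coast-coast",
                   TRUE ~ "mine-coast")
}

#' Run a replicated simulation experiment
#'
#' Runs `cfg$n_replicates` independent replicates of a colonization
#' scenario with per-replicate seeds derived reproducibly from
#' `cfg$seed`. The same `cfg$seed` yields bit-identical summary tables.
#'
#' @param cfg A [sim_config()].
#' @param kind `"multiple_origin"` or `"single_origin"`.
#' @param out_tsv Optional path: replicate summaries are appended to this
#'   TSV as they complete.
#' @return A tibble of stacked [run_replicate()] summaries with a
#'   `replicate` column.
#' @export
run_experiment <- function(cfg, kind = c("multiple_origin",
                                         "single_origin"),
                           out_tsv = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "sim_config"), cfg$n_replicates >= 2)
  schedule <- build_scenario(cfg, kind)
  seeds <- with_seed(cfg$seed,
                     sample.int(.Machine$integer.max, cfg$n_replicates))
  res <- purrr::map_dfr(seq_len(cfg$n_replicates), function(i) {
    rep_tab <- run_replicate(schedule, cfg, rng_seed = seeds[i])
    rep_tab <- dplyr::mutate(rep_tab, replicate = i,
                             .before = "scenario")
    if (!is.null(out_tsv))
      utils::write.table(rep_tab, out_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = !file.exists(out_tsv),
                         append = file.exists(out_tsv))
    rep_tab
  })
  res
}
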