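# helper: encode a hand-built schedule for the engine
raw_engine <- function(events, L = 50000, mu = 7.5e-8, rec = 4e-8,
                       seed = 1, sample_n = 0) {
  e <- minepop:::encode_schedule(events)
  minepop:::wf_engine(9L, L, mu, rec, e$gen, e$type, e$deme, e$other,
                      e$n, e$rate, seed = seed, sample_n = sample_n)
}

ev <- function(generation, event, deme, source = NA, n = NA, rate = NA)
  tibble::tibble(generation = as.integer(generation), event = event,
                 deme = deme, source = source, n = as.integer(n),
                 rate = as.numeric(rate))

test_that("scenario schedule reproduces the printed colonization timeline", {
  cfg <- sim_config(rescale_Q = 1)
  sch <- build_scenario(cfg, "multiple_origin")
  found <- sch[sch$event == "found", ]
  expect_equal(found$generation[found$deme == "p1"], 100000L)
  expect_equal(found$generation[found$deme == "p3"], 100020L)
  expect_equal(found$generation[found$deme == "p4"], 100040L)
  expect_equal(unique(found$generation[grepl("^m", found$deme)]),
               110040L)
  expect_equal(sch$generation[sch$event == "sample_and_stop"], 110140L)
  expect_equal(found$source[found$deme == "m2"], "p2")
  # coastal growth 10 generations after each founding
  rs <- sch[sch$event == "resize", ]
  expect_equal(rs$generation[rs$deme == "p1"], 100010L)
  expect_equal(rs$generation[rs$deme == "p4"], 100050L)
  # single origin with explicit founder
  s2 <- build_scenario(cfg, "single_origin", founder = 3)
  f2 <- s2[s2$event == "found" & grepl("^m", s2$deme), ]
  expect_equal(unique(f2$source), "p3")
  expect_error(build_scenario(cfg, "weird"), "arg")
})

test_that("rescaling divides sizes/durations and multiplies rates by Q,
           preserving theta", {
  cfg <- sim_config(rescale_Q = 10)
  s <- minepop:::scaled_config(cfg)
  expect_equal(s$N_anc, 1000L)
  expect_equal(s$burn_in, 10000L)
  expect_equal(s$mine_founders, 10L)
  expect_equal(s$mu, 7.5e-8)
  expect_equal(s$m23, 1e-3)
  expect_equal(4 * s$N_anc * s$mu, 4 * 10000 * 7.5e-9)  # theta/site
  expect_equal(s$burn_in / s$N_anc, 100000 / 10000)     # t/N
  expect_error(sim_config(rescale_Q = 7), "divisible")
})

test_that("zero mutation rate yields zero segregating sites", {
  events <- dplyr::bind_rows(ev(0, "found", "anc", NA, 50),
                             ev(100, "sample_and_stop", NA))
  out <- raw_engine(events, mu = 0)
  expect_equal(length(out$positions), 0L)
  expect_equal(ncol(out$dosages), 0L)
})

test_that("founding more individuals than the source holds is an error", {
  events <- dplyr::bind_rows(ev(0, "found", "anc", NA, 20),
                             ev(10, "found", "p1", "anc", 50),
                             ev(20, "sample_and_stop", NA))
  expect_error(raw_engine(events), "underflow")
})

test_that("identical seeds give bit-identical replicate summaries", {
  cfg <- sim_config(N_anc = 200, burn_in = 400, coastal_founders = 50,
                    coastal_size = 100, mine_founders = 10,
                    mine_coast_gap = 100, post_mine_generations = 20,
                    growth_delay = 10, colonization_interval = 20,
                    n_replicates = 2, rescale_Q = 1, seed = 9)
  a <- run_experiment(cfg, "multiple_origin")
  b <- run_experiment(cfg, "multiple_origin")
  expect_identical(a, b)
  expect_equal(dplyr::n_distinct(a$replicate), 2L)
  expect_equal(nrow(a), 2 * 28)  # 6 + 6 + 16 pairs per replicate
})

test_that("single-origin founder choice is uniform over the coastal demes", {
  cfg <- sim_config(N_anc = 100, burn_in = 100, coastal_founders = 20,
                    coastal_size = 40, mine_founders = 5,
                    mine_coast_gap = 50, post_mine_generations = 10,
                    growth_delay = 5, colonization_interval = 10,
                    rescale_Q = 1, seed = 2)
  sch <- build_scenario(cfg, "single_origin")
  founders <- sapply(1:60, function(s) {
    rep_tab <- run_replicate(sch, cfg, rng_seed = 5000 + s)
    unique(rep_tab$founder_choice)
  })
  expect_true(all(founders %in% 1:4))
  tab <- tabulate(founders, 4)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("neutral diversity at equilibrium matches 4*N*mu", {
  N <- 500; mu <- 7.5e-8; L <- 50000
  events <- dplyr::bind_rows(ev(0, "found", "anc", NA, N),
                             ev(5000, "sample_and_stop", NA))
  pis <- sapply(1:30, function(s) {
    out <- raw_engine(events, mu = mu, seed = s, sample_n = 50)
    d <- out$dosages
    n_al <- 2 * nrow(d)
    p <- colSums(d) / n_al
    sum(2 * p * (1 - p) * n_al / (n_al - 1)) / L
  })
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 4 * N * mu), 3 * se)
})

test_that("post-split FST matches the drift expectation 1 - exp(-t/2N)", {
  N <- 500; t_split <- N / 2
  events <- dplyr::bind_rows(
    ev(0, "found", "anc", NA, N),
    ev(3000, "found", "p1", "anc", N),
    ev(3000, "found", "p2", "anc", N),
    ev(3000, "remove", "anc"),
    ev(3000 + t_split, "sample_and_stop", NA))
  fst <- sapply(1:30, function(s) {
    out <- raw_engine(events, mu = 1.5e-8, seed = 1000 + s,
                      sample_n = 50)
    deme <- names(minepop:::.demes)[match(out$deme, minepop:::.demes)]
    ids <- paste0("i", seq_along(deme))
    gm <- geno_matrix(out$dosages, rep("c", length(out$positions)),
                      out$positions, ids)
    pm <- pop_map(data.frame(individual = ids, population = deme))
    wc_fst(gm, pm, "p1", "p2")$multilocus_fst
  })
  se <- sd(fst) / sqrt(length(fst))
  expect_lt(abs(mean(fst) - (1 - exp(-t_split / (2 * N)))), 3 * se)
})

test_that("simulated mine demes are less diverse than coastal demes", {
  cfg <- sim_config(N_anc = 400, burn_in = 2000, coastal_founders = 50,
                    coastal_size = 100, mine_founders = 10,
                    mine_coast_gap = 500, post_mine_generations = 20,
                    growth_delay = 10, colonization_interval = 20,
                    mu = 7.5e-8, rec = 4e-8,
                    n_replicates = 2, rescale_Q = 1, seed = 4)
  sch <- build_scenario(cfg, "multiple_origin")
  e <- minepop:::encode_schedule(sch)
  out <- minepop:::wf_engine(9L, cfg$L, cfg$mu, cfg$rec, e$gen, e$type,
                             e$deme, e$other, e$n, e$rate, seed = 77,
                             sample_n = 0L)
  deme <- names(minepop:::.demes)[match(out$deme, minepop:::.demes)]
  ids <- paste0("i", seq_along(deme))
  gm <- geno_matrix(out$dosages, rep("c", length(out$positions)),
                    out$positions, ids)
  pm <- pop_map(data.frame(individual = ids, population = deme))
  # per-bp diversity (summed over variant sites): the bottleneck must
  # depress total diversity in the mine demes
  pi_of <- function(pops) mean(sapply(pops, function(pp) {
    tab <- tidy(nucleotide_diversity(gm, pm, pp))
    sum(tab$pi[tab$variant]) / cfg$L
  }))
  expect_lt(pi_of(paste0("m", 1:4)), pi_of(paste0("p", 1:4)))
})
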