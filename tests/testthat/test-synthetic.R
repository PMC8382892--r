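test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_snps = 200, n_scaffolds = 20, n_per_pop = 5,
                          seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  a <- gen_dataset(cfg, dir = d1)
  b <- gen_dataset(cfg, dir = d2)
  expect_identical(a$gm, b$gm)
  expect_identical(readLines(a$paths$vcf), readLines(b$paths$vcf))
  # and a different seed changes the data
  c_ <- gen_dataset(generator_config(n_snps = 200, n_scaffolds = 20,
                                     n_per_pop = 5, seed = 43))
  expect_false(identical(a$gm$dosages, c_$gm$dosages))
})

test_that("degenerate frequencies give degenerate genotypes", {
  cfg <- generator_config(n_snps = 50, n_scaffolds = 5, n_per_pop = 4,
                          seed = 1)
  freqs <- gen_frequencies(cfg)
  freqs$p[] <- 0
  ds <- gen_genotypes(freqs, cfg)
  expect_true(all(ds$gm$dosages == 0L))
})

test_that("sample frequencies track generating frequencies
           (binomial oracle)", {
  cfg <- generator_config(n_regions = 2, n_snps = 40, n_scaffolds = 5,
                          n_per_pop = 1000, seed = 6)
  freqs <- gen_frequencies(cfg)
  ds <- gen_genotypes(freqs, cfg)
  pf <- pop_freqs(ds$gm, ds$pm)
  # compare per-site sample frequency to the generator value
  within3 <- sapply(rownames(freqs$p), function(pp) {
    p_true <- freqs$p[pp, match(colnames(ds$gm$dosages), ds$snp_key)]
    p_hat <- pf$p[pp, ]
    se <- sqrt(p_true * (1 - p_true) / (2 * 1000))
    abs(p_hat - p_true) <= 3 * se + 1e-9
  })
  # ~99.7% of sites should fall within 3 binomial SEs
  expect_gt(mean(within3), 0.985)
})

test_that("realized pair-class FST hits the calibration targets
           (0.25 / 0.36 / 0.45 within 0.05) across seeds", {
  devs <- purrr::map_dfr(1:5, function(s) {
    ds <- gen_dataset(generator_config(n_snps = 3000, n_scaffolds = 200,
                                       n_per_pop = 20, seed = 100 + s))
    pf <- pairwise_fst(ds$gm, ds$pm)
    hab <- setNames(ds$pm$populations$habitat,
                    ds$pm$populations$population)
    reg <- setNames(ds$pm$populations$region,
                    ds$pm$populations$population)
    pf |>
      dplyr::mutate(cls = dplyr::case_when(
        hab[pop_a] == "coast" & hab[pop_b] == "coast" ~ "coast-coast",
        hab[pop_a] == "mine" & hab[pop_b] == "mine" ~ "mine-mine",
        reg[pop_a] == reg[pop_b] ~ "mine-coast",
        TRUE ~ "other")) |>
      dplyr::filter(cls != "other") |>
      dplyr::group_by(cls) |>
      dplyr::summarise(fst = mean(fst), .groups = "drop") |>
      dplyr::mutate(seed = s)
  })
  means <- devs |>
    dplyr::group_by(cls) |>
    dplyr::summarise(fst = mean(fst), .groups = "drop")
  target <- c("coast-coast" = 0.25, "mine-coast" = 0.36,
              "mine-mine" = 0.45)
  expect_true(all(abs(means$fst - target[means$cls]) <= 0.05))
})

test_that("mine populations are less diverse than coastal populations", {
  ds <- gen_dataset(generator_config(n_snps = 2000, n_scaffolds = 100,
                                     n_per_pop = 15, seed = 33))
  pis <- purrr::map_dbl(ds$pm$populations$population,
                        ~ nucleotide_diversity(ds$gm, ds$pm, .x)$pi)
  hab <- ds$pm$populations$habitat
  expect_lt(mean(pis[hab == "mine"]), mean(pis[hab == "coast"]))
})

test_that("planted effect zero leaves outlier recall at chance", {
  planted <- tibble::tibble(comparisons = list(paste0("R", 1:4)),
                            n_snps = 40, effect = 0)
  ds <- gen_dataset(generator_config(n_snps = 2000, n_scaffolds = 100,
                                     n_per_pop = 15, seed = 55,
                                     planted_outliers = planted))
  scan <- scan_all_pairs(ds$gm, ds$pm)
  rec <- purrr::map_dbl(paste0("R", 1:4), function(r) {
    os <- scan$outliers[[r]]
    hits <- paste(os$snps$scaffold, os$snps$pos, sep = ":")
    truth <- ds$truth$planted$snp[ds$truth$planted$region == r]
    mean(truth %in% hits)
  })
  expect_lt(mean(rec), 0.3)  # ~5% expected at chance
})

test_that("local mine-coast pairs sit 15-27 km apart", {
  ds <- gen_dataset(generator_config(n_snps = 50, n_scaffolds = 5,
                                     n_per_pop = 3, seed = 2))
  km <- pop_distances(ds$pm)
  pairs <- region_pairs(ds$pm)
  local_km <- purrr::map_dbl(seq_len(nrow(pairs)), function(i) {
    row <- km[(km$pop_a == pairs$mine[i] & km$pop_b == pairs$coast[i]) |
                (km$pop_b == pairs$mine[i] & km$pop_a == pairs$coast[i]), ]
    row$km
  })
  expect_true(all(local_km >= 14 & local_km <= 28))
  expect_equal(mean(local_km), 20.8, tolerance = 0.05)
})

test_that("written dataset round-trips through the I/O layer", {
  dir <- withr::local_tempdir()
  ds <- gen_dataset(generator_config(n_snps = 150, n_scaffolds = 15,
                                     n_per_pop = 5, seed = 77),
                    dir = dir)
  gm2 <- read_vcf(ds$paths$vcf)
  pm2 <- read_popmap(ds$paths$popmap)
  expect_equal(unname(gm2$dosages), unname(ds$gm$dosages))
  expect_equal(gm2$sites, ds$gm$sites)
  expect_equal(nrow(pm2$populations), 8)
  truth <- jsonlite::read_json(ds$paths$truth)
  expect_named(truth, c("planted", "admixture", "F_region", "F_habitat",
                        "F_mine_extra", "target_fst"),
               ignore.order = TRUE)
})
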