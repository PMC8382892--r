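test_that("percentile thresholding flags the top 5% with ties included", {
  tab <- tibble::tibble(scaffold = paste0("s", 1:100), pos = 1:100,
                        fst = (1:100) / 100)
  os <- call_outliers(tab, percentile = 95)
  expect_equal(nrow(os$snps), 5)
  expect_equal(os$n_snps_tested, 100L)
  expect_true(all(os$snps$fst >= os$threshold_value))
  expect_warning(
    call_outliers(tibble::tibble(scaffold = paste0("s", 1:30),
                                 pos = 1:30, fst = rep(0.2, 30))),
    "identical")
  expect_error(call_outliers(tab[1:10, ]), "fewer than 20")
})

test_that("undefined FST values are excluded before ranking", {
  tab <- tibble::tibble(scaffold = "s", pos = 1:40,
                        fst = c(rep(NA, 10), (1:30) / 30))
  os <- call_outliers(tab)
  expect_equal(os$n_snps_tested, 30L)
})

test_that("intersection counts: identical, disjoint and random sets", {
  A <- paste0("x", 1:10)
  ident <- set_intersections(list(a = A, b = A), "inclusive")
  expect_equal(ident$count[ident$subset == "a&b"], 10L)
  excl <- set_intersections(list(a = A, b = A), "exclusive")
  expect_equal(excl$count[excl$degree == 1], c(0L, 0L))
  disj <- set_intersections(list(a = A, b = paste0("y", 1:5)),
                            "inclusive")
  expect_equal(disj$count[disj$subset == "a&b"], 0L)
  # exclusive counts partition the union (property, random sets)
  set.seed(30)
  for (i in 1:5) {
    sets <- lapply(1:4, function(k) sample(1:1000, sample(50:300, 1)))
    names(sets) <- letters[1:4]
    ex <- set_intersections(sets, "exclusive")
    expect_equal(sum(ex$count), length(unique(unlist(sets))))
    # cross-check one inclusive cell by brute-force membership
    inc <- set_intersections(sets, "inclusive")
    expect_equal(inc$count[inc$subset == "a&b&c"],
                 length(intersect(intersect(sets$a, sets$b), sets$c)))
  }
})

test_that("multi-set exact test reduces to the hypergeometric tail for
           m = 2 (exhaustive over small parameter grid)", {
  for (N in c(5, 12, 30)) for (n1 in c(1, N %/% 2, N - 1))
    for (n2 in c(2, N %/% 3 + 1)) {
      kmax <- min(n1, n2)
      for (k in 0:kmax) {
        p <- multiset_exact_p(N, c(n1, n2), k)$p
        p_hyper <- sum(dhyper(k:kmax, n1, N - n1, n2))
        expect_equal(p, p_hyper, tolerance = 1e-10)
      }
    }
})

test_that("m = 3 distribution equals exhaustive enumeration (N = 6)", {
  N <- 6; sizes <- c(3, 3, 3)
  truth <- enumerate_multiset(N, sizes)   # over all C(6,3)^3 draws
  lp <- minepop:::multiset_log_dist(N, sizes)
  expect_equal(exp(lp), truth, tolerance = 1e-9)
  for (k in 0:3)
    expect_equal(multiset_exact_p(N, sizes, k)$p,
                 sum(truth[(k + 1):4]), tolerance = 1e-9)
  # and within 3 SE of a Monte-Carlo draw
  set.seed(61)
  nmc <- 20000
  kmc <- replicate(nmc, {
    picks <- lapply(sizes, function(n) sample.int(N, n))
    length(Reduce(intersect, picks))
  })
  for (k in 1:3) {
    phat <- mean(kmc >= k)
    se <- sqrt(phat * (1 - phat) / nmc)
    expect_lt(abs(multiset_exact_p(N, sizes, k)$p - phat), 3 * se + 1e-4)
  }
})

test_that("exact distribution mean equals N * prod(sizes / N)", {
  cases <- list(list(N = 10, s = c(4, 7)), list(N = 8, s = c(3, 5, 6)),
                list(N = 15, s = c(10, 9, 4, 12)))
  for (cs in cases) {
    lp <- minepop:::multiset_log_dist(cs$N, cs$s)
    mu <- sum((seq_along(lp) - 1) * exp(lp))
    expect_equal(mu, cs$N * prod(cs$s / cs$N), tolerance = 1e-9)
  }
})

test_that("edge contracts: m = 1, impossible k, bad sizes", {
  expect_equal(multiset_exact_p(10, 4, 2)$p, 1)
  res <- multiset_exact_p(10, c(4, 6), 5)
  expect_equal(res$p, 0)
  expect_false(res$valid)
  expect_error(multiset_exact_p(10, c(4, 12), 2), "sizes")
})

test_that("planted shared outliers are recovered and give the smallest
           intersection p at the planted subset", {
  planted <- tibble::tibble(
    comparisons = list(c("R1", "R2", "R3", "R4")),
    n_snps = 25, effect = 1)
  ds <- gen_dataset(generator_config(n_snps = 3000, n_scaffolds = 150,
                                     n_per_pop = 15, seed = 19,
                                     planted_outliers = planted))
  scan <- scan_all_pairs(ds$gm, ds$pm)
  # recall of planted SNPs in each comparison
  for (r in paste0("R", 1:4)) {
    os <- scan$outliers[[r]]
    hits <- paste(os$snps$scaffold, os$snps$pos, sep = ":")
    truth <- ds$truth$planted$snp[ds$truth$planted$region == r]
    expect_gte(mean(truth %in% hits), 0.9)
  }
  snp <- scan$snp_tests
  expect_equal(snp$subset[which.min(snp$p)], "R1&R2&R3&R4")
})

test_that("independent random outliers give calibrated (null) p-values", {
  # sets drawn independently at 5% of a common universe: inclusive
  # intersections should not be systematically significant
  set.seed(71)
  ps <- replicate(40, {
    sets <- lapply(1:4, function(i) sample(1:2000, 100))
    names(sets) <- paste0("R", 1:4)
    inc <- set_intersections(sets, "inclusive")
    inc <- inc[inc$degree >= 2, ]
    sapply(seq_len(nrow(inc)), function(j) {
      nm <- strsplit(inc$subset[j], "&")[[1]]
      multiset_exact_p(2000, rep(100, length(nm)), inc$count[j])$p
    })
  })
  frac_sig <- mean(ps < 0.05)
  expect_lt(abs(frac_sig - 0.05), 0.05)
})
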