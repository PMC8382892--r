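make_freqs <- function(p) {
  structure(list(p = p,
                 n = matrix(10L, nrow(p), ncol(p),
                            dimnames = dimnames(p)),
                 sites = tibble::tibble(
                   scaffold = rep("s", ncol(p)),
                   pos = seq_len(ncol(p)))),
            class = "pop_freqs")
}

test_that("f4 matches the worked 3-site table", {
  p <- rbind(A = c(.5, .2, .9), B = c(.1, .2, .5),
             C = c(.6, .8, .1), D = c(.2, .4, .1))
  # mean of (pA-pB)(pC-pD) = mean(c(0.16, 0, 0))
  expect_equal(f4_statistic(make_freqs(p), "A", "B", "C", "D"),
               0.16 / 3, tolerance = 1e-12)
})

test_that("f4 algebraic identities hold exactly on random tables", {
  set.seed(4)
  for (i in 1:5) {
    p <- matrix(runif(4 * 30), 4, 30,
                dimnames = list(LETTERS[1:4], NULL))
    fr <- make_freqs(p)
    f <- f4_statistic(fr, "A", "B", "C", "D")
    expect_equal(f4_statistic(fr, "B", "A", "C", "D"), -f)
    expect_equal(f4_statistic(fr, "A", "B", "D", "C"), -f)
    expect_equal(f4_statistic(fr, "C", "D", "A", "B"), f)
  }
  p <- matrix(runif(4 * 10), 4, 10,
              dimnames = list(LETTERS[1:4], NULL))
  p["B", ] <- p["A", ]
  expect_equal(f4_statistic(make_freqs(p), "A", "B", "C", "D"), 0)
})

test_that("block jackknife SE equals direct formula evaluation", {
  set.seed(12)
  x <- rnorm(1040, mean = 0.01, sd = 0.3)  # 2 full + 1 ragged block
  res <- block_jackknife_z(x, block_size_snps = 500)
  # independent re-evaluation of the weighted jackknife variance
  n <- length(x)
  block <- (seq_len(n) - 1) %/% 500
  g <- 3
  theta <- mean(x)
  m_j <- tabulate(block + 1)
  theta_mj <- sapply(0:2, function(b) mean(x[block != b]))
  h_j <- n / m_j
  theta_J <- g * theta - sum((1 - m_j / n) * theta_mj)
  tau <- h_j * theta - (h_j - 1) * theta_mj
  se <- sqrt(mean((tau - theta_J)^2 / (h_j - 1)))
  expect_equal(res$se, se, tolerance = 1e-12)
  expect_equal(res$z, theta / se, tolerance = 1e-12)
  expect_equal(res$n_blocks, 3L)
})

test_that("jackknife degenerate and precondition contracts", {
  expect_error(block_jackknife_z(rnorm(100), 100), "at least 2 blocks")
  res <- block_jackknife_z(rep(0.5, 40), 10)
  expect_equal(res$se, 0)
  expect_true(res$degenerate)
  expect_equal(res$z, Inf)
})

test_that("quartet classification covers the six types", {
  hab <- c(m1 = "mine", m2 = "mine", m3 = "mine", m4 = "mine",
           c1 = "coast", c2 = "coast", c3 = "coast", c4 = "coast")
  expect_equal(classify_quartet(c("c1", "c2", "c3", "c4"), hab), 1L)
  expect_equal(classify_quartet(c("m1", "m2", "m3", "m4"), hab), 2L)
  expect_equal(classify_quartet(c("c1", "c2", "c3", "m1"), hab), 3L)
  expect_equal(classify_quartet(c("m1", "m2", "m3", "c1"), hab), 4L)
  t_sister <- classify_quartet(c("m1", "m2", "c1", "c2"), hab)
  t_split <- classify_quartet(c("m1", "c1", "m2", "c2"), hab)
  expect_setequal(c(t_sister, t_split), c(5L, 6L))
  expect_error(classify_quartet(c("m1", "m2", "c1", "zz"), hab),
               "unlabeled")
})

test_that("Dunn-Bonferroni threshold matches normal quantiles", {
  expect_equal(bonferroni_z(0.05, 1), qnorm(0.975), tolerance = 1e-12)
  expect_equal(round(bonferroni_z(0.05, 210), 2), 3.67)
  expect_equal(bonferroni_z(0.05, 2), qnorm(1 - 0.0125),
               tolerance = 1e-12)
  expect_error(bonferroni_z(1.5, 10), "alpha")
})

test_that("run_all_quartets enumerates 3 x C(8,4) rows and flags the
           topology-consistent arrangement", {
  ds <- gen_dataset(generator_config(n_snps = 600, n_scaffolds = 30,
                                     n_per_pop = 10, seed = 8))
  topo <- "(((R1-C,R1-M),(R2-C,R2-M)),((R3-C,R3-M),(R4-C,R4-M)));"
  qt <- run_all_quartets(ds$gm, ds$pm, topo, block_size_snps = 100)
  expect_equal(nrow(qt), 3 * choose(8, 4))
  expect_equal(sum(qt$tested), choose(8, 4))
  # known quartet: ((R1-C,R1-M),(R2-C,R2-M)) is the reference split
  row <- qt[qt$tested & qt$quartet ==
              which(apply(combn(sort(ds$pm$populations$population), 4),
                          2, function(q)
                            setequal(q, c("R1-C", "R1-M", "R2-C",
                                          "R2-M")))), ]
  expect_true(setequal(c(row$pop1, row$pop2), c("R1-C", "R1-M")) ||
                setequal(c(row$pop1, row$pop2), c("R2-C", "R2-M")))
  expect_error(run_all_quartets(ds$gm, ds$pm, "(R1-C,R1-M);"),
               "missing from topology")
})

test_that("tree-like data keep f4 near zero; planted admixture is
           detected in the affected quartet types", {
  cfg <- generator_config(n_snps = 5000, n_scaffolds = 200,
                          n_per_pop = 15, seed = 14,
                          admixture_edges = tibble::tibble(
                            pop_a = "R1-C", pop_b = "R3-C",
                            fraction = 0.25))
  ds <- gen_dataset(cfg)
  topo <- "(((R1-C,R1-M),(R2-C,R2-M)),((R3-C,R3-M),(R4-C,R4-M)));"
  qt <- run_all_quartets(ds$gm, ds$pm, topo, block_size_snps = 250)
  tested <- qt[qt$tested, ]
  z1 <- max(abs(tested$z[tested$type == 1]))  # four-coast quartet
  z2 <- max(abs(tested$z[tested$type == 2]))  # four-mine quartet
  expect_gt(z1, attr(qt, "z_threshold"))
  expect_lt(z2, attr(qt, "z_threshold"))
})
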