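#' f4 statistic for a population quartet
#'
#' Mean over usable sites of `(pA - pB) * (pC - pD)` for the arrangement
#' `((A, B), (C, D))`, where `p` are population alternate-allele
#' frequencies. Sites where any of the four populations has no genotyped
#' allele are excluded. No sample-size bias correction is applied (none
#' is required for f4, unlike f2/f3).
#'
#' @param freqs A [pop_freqs()] object.
#' @param a,b,c,d Population labels: the tested tree is `((a,b),(c,d))`.
#' @return The f4 value (scalar).
#' @export
f4_statistic <- function(freqs, a, b, c, d) {
  mean(f4_site_products(freqs, a, b, c, d))
}

# per-site products, genome order, usable sites only
f4_site_products <- function(freqs, a, b, c, d) {
  stopifnot(inherits(freqs, "pop_freqs"))
  pops <- c(a, b, c, d)
  miss <- setdiff(pops, rownames(freqs$p))
  if (length(miss))
    stop("populations missing from frequency table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  p <- freqs$p[pops, , drop = FALSE]
  usable <- colSums(is.na(p)) == 0L
  if (!any(usable))
    stop("no usable sites for quartet", call. = FALSE)
  (p[1, usable] - p[2, usable]) * (p[3, usable] - p[4, usable])
}

#' Weighted block-jackknife standard error and z-score
#'
#' Delete-one-block jackknife over contiguous blocks of
#' `block_size_snps` sites in genome order, weighted by block size
#' (Busing-style weighted jackknife), for the mean of a per-site
#' statistic. `z = mean / SE`. A zero SE with a non-zero mean yields
#' `z = +/-Inf` with a `degenerate` flag.
#'
#' @param per_site Numeric vector of per-site values in genome order
#'   (e.g. f4 site products).
#' @param block_size_snps Block size in number of sites (default 500).
#' @return A one-row tibble: `estimate`, `se`, `z`, `n_blocks`,
#'   `n_sites`, `degenerate`.
#' @export
block_jackknife_z <- function(per_site, block_size_snps = 500) {
  n <- length(per_site)
  g <- ceiling(n / block_size_snps)
  if (g < 2)
    stop("need at least 2 blocks (", n, " sites, block size ",
         block_size_snps, ")", call. = FALSE)
  block <- (seq_len(n) - 1L) %/% as.integer(block_size_snps)
  tot <- sum(per_site)
  theta <- tot / n
  m_j <- as.numeric(tabulate(block + 1L, nbins = g))
  sum_j <- as.numeric(tapply(per_site, block, sum))
  theta_mj <- (tot - sum_j) / (n - m_j)  # leave-one-block-out means
  h_j <- n / m_j
  theta_jack <- g * theta - sum((1 - m_j / n) * theta_mj)
  tau_j <- h_j * theta - (h_j - 1) * theta_mj
  var_j <- mean((tau_j - theta_jack)^2 / (h_j - 1))
  se <- sqrt(var_j)
  degenerate <- se == 0
  z <- if (degenerate) {
    if (theta == 0) 0 else sign(theta) * Inf
  } else theta / se
  tibble(estimate = theta, se = se, z = z, n_blocks = g,
         n_sites = n, degenerate = degenerate)
}

#' Classify a quartet by mine/coast composition and arrangement
#'
#' Types: 1 = four coast; 2 = four mine; 3 = three coast + one mine;
#' 4 = three mine + one coast; 5 = two mine + two coast with
#' same-habitat populations sister (`((M,M),(C,C))`); 6 = two mine +
#' two coast split across the tested tree (`((M,C),(M,C))`).
#'
#' @param quartet Character vector of 4 population labels; the
#'   arrangement is `((1,2),(3,4))`.
#' @param habitats Named character vector population -> habitat
#'   (`"mine"`/`"coast"`).
#' @return Integer type in 1..6.
#' @export
classify_quartet <- function(quartet, habitats) {
  stopifnot(length(quartet) == 4)
  h <- unname(habitats[quartet])
  if (anyNA(h))
    stop("unlabeled population(s): ",
         paste(quartet[is.na(h)], collapse = ", "), call. = FALSE)
  nm <- sum(h == "mine")
  if (nm == 0) return(1L)
  if (nm == 4) return(2L)
  if (nm == 1) return(3L)
  if (nm == 3) return(4L)
  if (h[1] == h[2]) 5L else 6L
}

#' Dunn-Bonferroni z threshold
#'
#' Two-sided standard-normal quantile at `alpha / n_tests`.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests in the family.
#' @return The z threshold.
#' @export
#'
#' @examples
#' bonferroni_z(0.05, 210)  # 3.67 for 70 quartets x 3 arrangements
bonferroni_z <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  qnorm(1 - alpha / (2 * n_tests))
}

# ((A,B),(C,D)) arrangement consistent with the reference topology,
# via the four-point condition on patristic distances
quartet_arrangements <- function(q, dm) {
  s <- c(dm[q[1], q[2]] + dm[q[3], q[4]],
         dm[q[1], q[3]] + dm[q[2], q[4]],
         dm[q[1], q[4]] + dm[q[2], q[3]])
  arrs <- list(q, q[c(1, 3, 2, 4)], q[c(1, 4, 2, 3)])
  list(arrangements = arrs, tested = which.min(s))
}

#' f4 tests for all population quartets
#'
#' For every 4-subset of populations, computes f4 with block-jackknife
#' z-scores for all three tree arrangements; the arrangement consistent
#' with the supplied reference topology (by the four-point condition on
#' patristic distances) is flagged as the tested tree. Significance is
#' flagged at the Dunn-Bonferroni threshold whose default family size is
#' the number of computed statistics (3 per quartet).
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()] with habitats.
#' @param topology Reference population topology: a Newick string or an
#'   `ape::phylo` whose tip labels are the population names. The package
#'   does not infer it.
#' @param block_size_snps Jackknife block size (default 500).
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Bonferroni family size (default: number of computed
#'   statistics).
#' @return A tibble of class `quartet_tests`, one row per quartet x
#'   arrangement: `pop1..pop4` (arrangement `((1,2),(3,4))`), `type`,
#'   `tested`, `f4`, `se`, `z`, `n_sites`, `n_blocks`, `significant`;
#'   attributes `z_threshold`, `alpha`, `n_tests`.
#' @export
run_all_quartets <- function(gm, pm, topology, block_size_snps = 500,
                             alpha = 0.05, n_tests = NULL) {
  pm <- as_pop_map(pm)
  tree <- if (inherits(topology, "phylo")) topology
          else ape::read.tree(text = topology)
  pops <- pm$populations$population
  miss <- setdiff(pops, tree$tip.label)
  if (length(miss))
    stop("populations missing from topology: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  dm <- ape::cophenetic.phylo(tree)
  habitats <- setNames(pm$populations$habitat,
                       pm$populations$population)
  freqs <- pop_freqs(gm, pm, pops)
  quartets <- utils::combn(sort(pops), 4)
  rows <- purrr::map_dfr(seq_len(ncol(quartets)), function(i) {
    qa <- quartet_arrangements(quartets[, i], dm)
    purrr::map_dfr(seq_along(qa$arrangements), function(k) {
      arr <- qa$arrangements[[k]]
      prods <- f4_site_products(freqs, arr[1], arr[2], arr[3], arr[4])
      jk <- block_jackknife_z(prods, block_size_snps)
      tibble(quartet = i, pop1 = arr[1], pop2 = arr[2], pop3 = arr[3],
             pop4 = arr[4],
             type = classify_quartet(arr, habitats),
             tested = k == qa$tested,
             f4 = jk$estimate, se = jk$se, z = jk$z,
             n_sites = jk$n_sites, n_blocks = jk$n_blocks)
    })
  })
  if (is.null(n_tests)) n_tests <- nrow(rows)
  thr <- bonferroni_z(alpha, n_tests)
  rows$significant <- abs(rows$z) > thr
  structure(rows, class = c("quartet_tests", class(rows)),
            z_threshold = thr, alpha = alpha, n_tests = n_tests)
}
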