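#' Call FST outliers for one comparison
#'
#' SNPs whose per-site FST reaches the stated upper percentile of the
#' defined values (linear-interpolation percentile, ties included) are
#' outlier loci; scaffolds carrying at least one outlier SNP are outlier
#' scaffolds. Undefined (pair-monomorphic) sites are excluded before
#' ranking.
#'
#' @param per_site_fst A tibble with columns `scaffold`, `pos`, `fst`
#'   (e.g. `tidy(wc_fst(...))`), or an `fst_result`.
#' @param percentile Upper percentile (default 95).
#' @param comparison Optional comparison label.
#' @return An object of class `outlier_set`: list with `comparison`,
#'   `snps` (tibble scaffold, pos, fst), `scaffolds` (character),
#'   `threshold_value`, `n_snps_tested`, `n_scaffolds_tested`,
#'   `tested_snps` (scaffold:pos keys), `tested_scaffolds`.
#' @export
call_outliers <- function(per_site_fst, percentile = 95,
                          comparison = NA_character_) {
  if (inherits(per_site_fst, "fst_result")) {
    if (is.na(comparison))
      comparison <- paste(per_site_fst$pair, collapse = "-")
    per_site_fst <- per_site_fst$per_site
  }
  tab <- as_tibble(per_site_fst)
  stopifnot(all(c("scaffold", "pos", "fst") %in% names(tab)))
  tab <- tab[is.finite(tab$fst), , drop = FALSE]
  if (nrow(tab) < 20)
    stop("fewer than 20 defined sites: percentile threshold unstable",
         call. = FALSE)
  thr <- unname(quantile(tab$fst, percentile / 100, type = 7))
  if (length(unique(tab$fst)) == 1L)
    warning("all FST values identical: every SNP ties at the threshold")
  out <- tab[tab$fst >= thr, , drop = FALSE]
  structure(list(comparison = comparison,
                 snps = out[, c("scaffold", "pos", "fst")],
                 scaffolds = unique(out$scaffold),
                 threshold_value = thr,
                 n_snps_tested = nrow(tab),
                 n_scaffolds_tested = dplyr::n_distinct(tab$scaffold),
                 tested_snps = paste(tab$scaffold, tab$pos, sep = ":"),
                 tested_scaffolds = unique(tab$scaffold)),
            class = "outlier_set")
}

#' @exportS3Method base::print
print.outlier_set <- function(x, ...) {
  cat(sprintf(
    "<outlier_set> %s: %d outlier SNPs on %d scaffolds (threshold %.4f, %d tested)\n",
    x$comparison, nrow(x$snps), length(x$scaffolds),
    x$threshold_value, x$n_snps_tested))
  invisible(x)
}

#' Multi-set intersection counts
#'
#' Inclusive mode counts `|intersection of the subset|`; exclusive
#' (upset) mode counts elements belonging to exactly that subset of
#' sets, so exclusive counts partition the union.
#'
#' @param sets Named list of character vectors (>= 2 sets).
#' @param mode `"exclusive"` (upset bars) or `"inclusive"`.
#' @param min_degree Smallest subset size reported (default 1).
#' @return A tibble: `subset` (ampersand-joined set names), `degree`,
#'   `count`.
#' @export
set_intersections <- function(sets, mode = c("exclusive", "inclusive"),
                              min_degree = 1) {
  mode <- match.arg(mode)
  if (length(sets) < 2) stop("need at least 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- purrr::map(sets, unique)
  nm <- names(sets)
  subsets <- unlist(purrr::map(seq_along(sets), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  subsets <- subsets[lengths(subsets) >= min_degree]
  if (mode == "inclusive") {
    counts <- purrr::map_int(subsets, function(ss)
      length(Reduce(intersect, sets[ss])))
  } else {
    universe <- unique(unlist(sets))
    memb <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
    if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                               dimnames = list(NULL, nm))
    pattern <- apply(memb, 1, function(row)
      paste(nm[row], collapse = "&"))
    counts <- purrr::map_int(subsets, function(ss)
      sum(pattern == paste(ss, collapse = "&")))
  }
  tibble(subset = purrr::map_chr(subsets, paste, collapse = "&"),
         degree = lengths(subsets), count = counts)
}

# log-space distribution of |intersection of m independent uniform
# fixed-size subsets| of a universe of size N, by iterated
# hypergeometric compounding
multiset_log_dist <- function(N, sizes) {
  lp <- rep(-Inf, sizes[1] + 1)
  lp[sizes[1] + 1] <- 0  # point mass at n1
  if (length(sizes) > 1) for (j in 2:length(sizes)) {
    nj <- sizes[j]
    smax <- length(lp) - 1L
    tmax <- min(smax, nj)
    new <- vapply(0:tmax, function(t) {
      s <- t:smax
      logsumexp(lp[s + 1] + dhyper(t, s, N - s, nj, log = TRUE))
    }, numeric(1))
    lp <- new
  }
  lp  # lp[k+1] = log P(X = k)
}

#' Exact multi-set intersection tail probability
#'
#' Exact distribution of the intersection size of `m` independently,
#' uniformly drawn fixed-size subsets of a universe of `N` elements
#' (the multi-set extension of Fisher's exact test), computed by
#' iterated hypergeometric compounding in log space. For `m = 2` this
#' is exactly the classical hypergeometric tail. The expected
#' intersection size is `N * prod(sizes / N)`.
#'
#' @param N Universe size.
#' @param sizes Integer vector of set sizes.
#' @param k Observed intersection size.
#' @return A one-row tibble: `N`, `m`, `k`, `expected`,
#'   `p` (= P(X >= k)), `valid` (`FALSE` when `k` is impossible).
#' @export
#'
#' @examples
#' multiset_exact_p(10, c(5, 5), 5)  # 1 / choose(10, 5)
multiset_exact_p <- function(N, sizes, k) {
  sizes <- as.integer(sizes)
  if (any(sizes < 0) || any(sizes > N))
    stop("set sizes must lie in [0, N]", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  expected <- N * prod(sizes / N)
  if (k > min(sizes))
    return(tibble(N = N, m = length(sizes), k = k, expected = expected,
                  p = 0, valid = FALSE))
  if (length(sizes) == 1L)
    return(tibble(N = N, m = 1L, k = k, expected = expected,
                  p = 1, valid = TRUE))
  lp <- multiset_log_dist(N, sizes)
  p <- exp(logsumexp(lp[(k + 1):length(lp)]))
  tibble(N = N, m = length(sizes), k = k, expected = expected,
         p = min(1, p), valid = TRUE)
}

#' FST outlier scan with multi-set overlap tests
#'
#' For each within-region mine-coast pair: per-site Weir-Cockerham FST,
#' outlier calling at the given percentile, then intersection counts
#' (inclusive counts drive the exact tests; exclusive counts mirror
#' upset bars) and the exact multi-set intersection p-value for every
#' subset of comparisons of size >= 2, at both the SNP and the scaffold
#' level. The SNP-level background is the number of SNPs tested in at
#' least one comparison; the scaffold-level background is the number of
#' scaffolds bearing at least one tested SNP.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()] with habitats and regions.
#' @param pairs Optional tibble `region`, `mine`, `coast` (default
#'   [region_pairs()]).
#' @param percentile Outlier percentile (default 95).
#' @return An object of class `outlier_scan`: list with `outliers`
#'   (named list of `outlier_set` per region), `snp_tests` and
#'   `scaffold_tests` (tibbles: subset, degree, inclusive, exclusive,
#'   expected, p), `background` (named counts).
#' @export
scan_all_pairs <- function(gm, pm, pairs = NULL, percentile = 95) {
  pm <- as_pop_map(pm)
  if (is.null(pairs)) pairs <- region_pairs(pm)
  known <- pm$populations$population
  bad <- setdiff(c(pairs$mine, pairs$coast), known)
  if (length(bad))
    stop("pair references unknown population(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  outs <- purrr::map(seq_len(nrow(pairs)), function(i)
    call_outliers(wc_fst(gm, pm, pairs$mine[i], pairs$coast[i]),
                  percentile = percentile,
                  comparison = pairs$region[i]))
  names(outs) <- pairs$region
  snp_sets <- purrr::map(outs, ~ paste(.x$snps$scaffold, .x$snps$pos,
                                       sep = ":"))
  scaf_sets <- purrr::map(outs, "scaffolds")
  n_snp <- length(unique(unlist(purrr::map(outs, "tested_snps"))))
  n_scaf <- length(unique(unlist(purrr::map(outs, "tested_scaffolds"))))
  test_level <- function(sets, N) {
    inc <- set_intersections(sets, "inclusive")
    exc <- set_intersections(sets, "exclusive")
    tab <- dplyr::left_join(inc, exc, by = c("subset", "degree"),
                            suffix = c("_inc", "_exc")) |>
      dplyr::rename(inclusive = "count_inc", exclusive = "count_exc")
    sizes <- purrr::map_int(sets, length)
    tab |>
      dplyr::filter(.data$degree >= 2) |>
      dplyr::rowwise() |>
      dplyr::mutate(res = list(multiset_exact_p(
        N, sizes[strsplit(.data$subset, "&", fixed = TRUE)[[1]]],
        .data$inclusive))) |>
      dplyr::ungroup() |>
      tidyr::unnest_wider("res", names_sep = "_") |>
      dplyr::transmute(.data$subset, .data$degree, .data$inclusive,
                       .data$exclusive, expected = .data$res_expected,
                       p = .data$res_p)
  }
  structure(list(outliers = outs,
                 snp_tests = test_level(snp_sets, n_snp),
                 scaffold_tests = test_level(scaf_sets, n_scaf),
                 background = c(snps = n_snp, scaffolds = n_scaf)),
            class = "outlier_scan")
}

#' @exportS3Method base::print
print.outlier_scan <- function(x, ...) {
  cat(sprintf("<outlier_scan> %d comparisons; background %d SNPs / %d scaffolds\n",
              length(x$outliers), x$background["snps"],
              x$background["scaffolds"]))
  cat("scaffold-level overlaps:\n")
  print(x$scaffold_tests)
  invisible(x)
}

#' @export
tidy.outlier_scan <- function(x, level = c("scaffold", "snp"), ...) {
  level <- match.arg(level)
  if (level == "scaffold") x$scaffold_tests else x$snp_tests
}
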