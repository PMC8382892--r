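#' Weir-Cockerham FST for a population pair
#'
#' Per-site variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) following
#' the Weir & Cockerham (1984) two-allele estimator, and the multilocus
#' estimate as the ratio of sums `sum(a) / sum(a + b + c)`. Sites
#' monomorphic across the pair are flagged undefined and excluded from
#' both numerator and denominator; per-site values are not clamped, and
#' small negative multilocus estimates are possible.
#'
#' A site contributes only when both populations have at least two
#' genotyped individuals there. Missing genotypes are excluded site-wise,
#' never imputed.
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()] (or data frame coercible to one).
#' @param pop_a,pop_b Population labels.
#' @return An object of class `fst_result`: list with `pair`,
#'   `multilocus_fst`, `per_site` (tibble: scaffold, pos, n1, n2, a, b, c,
#'   fst, defined) and `n_sites_used`.
#' @export
#'
#' @examples
#' gm <- geno_matrix(matrix(c(0L, 0L, 2L, 2L), 4, 1),
#'                   "sc1", 1L, paste0("i", 1:4))
#' pm <- pop_map(data.frame(individual = paste0("i", 1:4),
#'                          population = c("A", "A", "B", "B")))
#' wc_fst(gm, pm, "A", "B")$multilocus_fst  # fixed difference -> 1
wc_fst <- function(gm, pm, pop_a, pop_b) {
  stopifnot(inherits(gm, "geno_matrix"))
  pm <- as_pop_map(pm)
  ids_a <- pop_individuals(pm, pop_a)
  ids_b <- pop_individuals(pm, pop_b)
  ids_a <- intersect(ids_a, sample_ids(gm))
  ids_b <- intersect(ids_b, sample_ids(gm))
  if (!length(ids_a) || !length(ids_b))
    stop("no genotyped individuals for population ",
         if (!length(ids_a)) pop_a else pop_b, call. = FALSE)
  comp <- wc_site_components(gm$dosages[ids_a, , drop = FALSE],
                             gm$dosages[ids_b, , drop = FALSE])
  per_site <- dplyr::bind_cols(gm$sites, comp)
  used <- per_site$defined
  if (!any(used))
    stop("no usable polymorphic sites for pair ", pop_a, "-", pop_b,
         " (FST undefined, not zero)", call. = FALSE)
  ml <- sum(per_site$a[used]) /
    sum(per_site$a[used] + per_site$b[used] + per_site$c[used])
  structure(list(pair = c(pop_a, pop_b),
                 multilocus_fst = ml,
                 per_site = per_site,
                 n_sites_used = sum(used)),
            class = "fst_result")
}

# Vectorised W&C (1984) components for r = 2 populations from dosage
# matrices (rows = individuals). Returns a tibble, one row per site.
wc_site_components <- function(d1, d2) {
  n1 <- colSums(!is.na(d1))
  n2 <- colSums(!is.na(d2))
  p1 <- ifelse(n1 > 0, colSums(d1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(d2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(d1 == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(d2 == 1L, na.rm = TRUE) / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  usable <- n1 >= 2 & n2 >= 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  denom <- a + b + c_
  poly <- usable & is.finite(denom) & abs(denom) > 1e-12
  fst <- ifelse(poly, a / denom, NA_real_)
  tibble(n1 = unname(n1), n2 = unname(n2),
         a = unname(ifelse(usable, a, NA_real_)),
         b = unname(ifelse(usable, b, NA_real_)),
         c = unname(ifelse(usable, c_, NA_real_)),
         fst = unname(fst),
         defined = unname(poly))
}

#' All pairwise multilocus FST values
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param pops Populations to include (default all).
#' @return A tibble with columns `pop_a`, `pop_b`, `fst`, `n_sites_used`.
#' @export
pairwise_fst <- function(gm, pm, pops = NULL) {
  pm <- as_pop_map(pm)
  if (is.null(pops)) pops <- pm$populations$population
  prs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(prs)), function(i) {
    f <- wc_fst(gm, pm, prs[1, i], prs[2, i])
    tibble(pop_a = prs[1, i], pop_b = prs[2, i],
           fst = f$multilocus_fst, n_sites_used = f$n_sites_used)
  })
}

#' @exportS3Method base::print
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %s vs %s: multilocus FST = %.4f (%d sites)\n",
              x$pair[1], x$pair[2], x$multilocus_fst, x$n_sites_used))
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_site

#' @export
glance.fst_result <- function(x, ...) {
  tibble(pop_a = x$pair[1], pop_b = x$pair[2],
         multilocus_fst = x$multilocus_fst,
         n_sites_used = x$n_sites_used)
}
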