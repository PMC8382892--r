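#' Genotype dosage matrix
#'
#' The central genotype container: a diploid dosage matrix (individuals in
#' rows, biallelic sites in columns) with per-site scaffold/position
#' metadata. Dosages count copies of the alternate allele (0, 1, 2) and
#' missing genotypes are `NA`. Sites are stored sorted by
#' (scaffold, position) and (scaffold, position) pairs are unique.
#'
#' @param dosages Integer matrix, individuals x sites, values in
#'   `c(0L, 1L, 2L, NA)`.
#' @param site_scaffold Character vector of scaffold identifiers, one per
#'   site.
#' @param site_pos Integer vector of 1-based positions (bp), one per site.
#' @param sample_ids Character vector of unique individual labels, one per
#'   row of `dosages`.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `dosages` (integer matrix with `sample_ids` as rownames) and `sites`
#'   (a tibble with columns `scaffold`, `pos`).
#' @export
#'
#' @examples
#' gm <- geno_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'                   site_scaffold = c("sc1", "sc1"),
#'                   site_pos = c(10L, 20L),
#'                   sample_ids = c("a", "b"))
#' n_sites(gm)
geno_matrix <- function(dosages, site_scaffold, site_pos, sample_ids) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n_ind <- nrow(dosages)
  n_site <- ncol(dosages)
  if (length(sample_ids) != n_ind)
    stop("length(sample_ids) must equal nrow(dosages)", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique", call. = FALSE)
  if (length(site_scaffold) != n_site || length(site_pos) != n_site)
    stop("site metadata lengths must equal ncol(dosages)", call. = FALSE)
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  site_scaffold <- as.character(site_scaffold)
  site_pos <- as.integer(site_pos)
  if (any(is.na(site_pos)) || any(site_pos < 1L))
    stop("site positions must be positive integers", call. = FALSE)
  ord <- order(site_scaffold, site_pos)
  site_scaffold <- site_scaffold[ord]
  site_pos <- site_pos[ord]
  dosages <- dosages[, ord, drop = FALSE]
  if (anyDuplicated(paste(site_scaffold, site_pos)))
    stop("(scaffold, position) pairs must be unique", call. = FALSE)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- paste(site_scaffold, site_pos, sep = ":")
  structure(
    list(dosages = dosages,
         sites = tibble(scaffold = site_scaffold, pos = site_pos)),
    class = "geno_matrix"
  )
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d sites on %d scaffold(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              dplyr::n_distinct(x$sites$scaffold)))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname geno_matrix
#' @param gm A `geno_matrix`.
#' @export
n_sites <- function(gm) ncol(gm$dosages)

#' @rdname geno_matrix
#' @export
n_individuals <- function(gm) nrow(gm$dosages)

#' @rdname geno_matrix
#' @export
sample_ids <- function(gm) rownames(gm$dosages)

#' Subset a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @param individuals Character vector of sample ids, or logical/integer
#'   row index; `NULL` keeps all.
#' @param sites Logical or integer column index; `NULL` keeps all.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(gm, individuals = NULL, sites = NULL) {
  d <- gm$dosages
  s <- gm$sites
  if (!is.null(individuals)) {
    if (is.character(individuals)) {
      miss <- setdiff(individuals, rownames(d))
      if (length(miss))
        stop("unknown individuals: ", paste(miss, collapse = ", "),
             call. = FALSE)
      d <- d[individuals, , drop = FALSE]
    } else {
      d <- d[individuals, , drop = FALSE]
    }
  }
  if (!is.null(sites)) {
    d <- d[, sites, drop = FALSE]
    s <- s[sites, , drop = FALSE]
  }
  geno_matrix(d, s$scaffold, s$pos, rownames(d))
}

#' Drop sites with excessive missing data
#'
#' Mirrors the usual RAD-pipeline site filter: a site is kept when the
#' fraction of missing genotype calls is below `max_missing`.
#'
#' @param gm A [geno_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.2,
#'   i.e. keep sites with less than 20% missing data).
#' @return A filtered `geno_matrix`.
#' @export
filter_missing <- function(gm, max_missing = 0.2) {
  frac <- colMeans(is.na(gm$dosages))
  subset_geno(gm, sites = frac < max_missing)
}

#' Per-population alternate-allele frequencies
#'
#' @param gm A [geno_matrix()].
#' @param pm A [pop_map()].
#' @param pops Populations to include (default: all in the map that have
#'   individuals in `gm`).
#' @return An object of class `pop_freqs`: list with `p` (pops x sites
#'   frequency matrix, `NA` where a population has no genotyped
#'   individuals), `n` (matrix of non-missing allele counts) and `sites`
#'   (site tibble).
#' @export
pop_freqs <- function(gm, pm, pops = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  pm <- as_pop_map(pm)
  ind <- pm$individuals
  ind <- ind[ind$individual %in% sample_ids(gm), , drop = FALSE]
  if (is.null(pops)) pops <- unique(ind$population)
  miss <- setdiff(pops, ind$population)
  if (length(miss))
    stop("populations absent from map/genotypes: ",
         paste(miss, collapse = ", "), call. = FALSE)
  p <- matrix(NA_real_, length(pops), n_sites(gm),
              dimnames = list(pops, colnames(gm$dosages)))
  n <- matrix(0L, length(pops), n_sites(gm), dimnames = dimnames(p))
  for (pp in pops) {
    ids <- ind$individual[ind$population == pp]
    d <- gm$dosages[ids, , drop = FALSE]
    cnt <- 2L * colSums(!is.na(d))
    tot <- colSums(d, na.rm = TRUE)
    p[pp, ] <- ifelse(cnt > 0L, tot / cnt, NA_real_)
    n[pp, ] <- cnt
  }
  structure(list(p = p, n = n, sites = gm$sites), class = "pop_freqs")
}
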