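#' LD pruning of a genotype matrix
#'
#' Two-stage pruning as used ahead of tree building: sites with minor
#' allele frequency below `maf_threshold` are removed first, then a
#' greedy scan in genome order removes the later site of any pair whose
#' genotypic r-squared (squared Pearson correlation of dosage vectors
#' over individuals genotyped at both sites) exceeds `r2_threshold`,
#' considering pairs within a sliding window of `window` sites.
#'
#' @param gm A [geno_matrix()].
#' @param r2_threshold Genotypic r-squared threshold (default 0.1).
#' @param maf_threshold Minor-allele-frequency threshold (default 0.05).
#' @param window Window size in number of (post-MAF-filter) sites
#'   (default 50).
#' @return A pruned [geno_matrix()] (possibly with zero sites).
#' @export
ld_prune <- function(gm, r2_threshold = 0.1, maf_threshold = 0.05,
                     window = 50) {
  stopifnot(inherits(gm, "geno_matrix"))
  d <- gm$dosages
  n_al <- 2 * colSums(!is.na(d))
  p <- ifelse(n_al > 0, colSums(d, na.rm = TRUE) / n_al, NA_real_)
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= maf_threshold
  gm <- subset_geno(gm, sites = keep_maf)
  m <- n_sites(gm)
  if (m <= 1) return(gm)
  d <- gm$dosages
  keep <- logical(m)
  keep[1] <- TRUE
  for (j in 2:m) {
    lo <- max(1L, j - as.integer(window) + 1L)
    cand <- which(keep[lo:(j - 1)]) + lo - 1L
    if (!length(cand)) {
      keep[j] <- TRUE
      next
    }
    r <- suppressWarnings(
      cor(d[, j], d[, cand, drop = FALSE],
          use = "pairwise.complete.obs"))
    r2 <- r^2
    keep[j] <- !any(r2 > r2_threshold, na.rm = TRUE)
  }
  subset_geno(gm, sites = keep)
}
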