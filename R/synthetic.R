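#' Configuration for the synthetic genotype generator
#'
#' The generator emulates the statistical structure the analyses assume:
#' four regions each holding a mine-coast population pair, hierarchical
#' Balding-Nichols differentiation (coast-coast < mine-coast <
#' mine-mine FST), reduced diversity in mines via an extra mine drift
#' step, optional planted high-FST SNPs shared across chosen mine-coast
#' comparisons, and optional admixture edges.
#'
#' The drift intensities default to values calibrated so the realized
#' pair-class Weir-Cockerham FST means land near 0.25 (coast-coast),
#' 0.36 (local mine-coast) and 0.45 (mine-mine).
#'
#' @param n_regions Number of regions (each with one mine and one coast
#'   population; default 4).
#' @param n_per_pop Individuals per population (default 27).
#' @param n_snps Number of biallelic SNPs (default 20000).
#' @param n_scaffolds Number of scaffolds (default 2000).
#' @param F_region Drift intensity of the region step.
#' @param F_habitat Drift intensity of the habitat step.
#' @param mine_diversity_factor In (0, 1): the extra mine drift step has
#'   intensity `1 - mine_diversity_factor`, depressing mine diversity.
#' @param planted_outliers Optional tibble with columns `comparisons`
#'   (list-column of region-id character vectors), `n_snps`, `effect`.
#'   For each row, `n_snps` sites whose coast frequencies in the listed
#'   regions are extreme and consistent are selected, and the mine
#'   frequency there is shifted by the fraction `effect` (in `[0, 1]`)
#'   of its distance to the opposite fixation boundary; `effect = 1`
#'   plants a near-fixed mine-coast difference in every listed
#'   comparison, `effect = 0` plants no signal.
#' @param admixture_edges Optional tibble with columns `pop_a`, `pop_b`,
#'   `fraction`: popB frequencies become
#'   `(1 - f) * pB + f * pA`.
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_regions = 4, n_per_pop = 27,
                             n_snps = 20000, n_scaffolds = 2000,
                             F_region = 0.01, F_habitat = 0.245,
                             mine_diversity_factor = 0.72,
                             planted_outliers = NULL,
                             admixture_edges = NULL, seed = 1L) {
  stopifnot(n_regions >= 2, n_per_pop >= 2, n_snps >= 1,
            n_scaffolds >= 1)
  for (f in c(F_region, F_habitat))
    if (f <= 0 || f >= 1) stop("drift intensities must be in (0, 1)",
                               call. = FALSE)
  if (mine_diversity_factor <= 0 || mine_diversity_factor >= 1)
    stop("mine_diversity_factor must be in (0, 1)", call. = FALSE)
  structure(list(n_regions = as.integer(n_regions),
                 n_per_pop = as.integer(n_per_pop),
                 n_snps = as.integer(n_snps),
                 n_scaffolds = as.integer(n_scaffolds),
                 F_region = F_region, F_habitat = F_habitat,
                 mine_diversity_factor = mine_diversity_factor,
                 planted_outliers = planted_outliers,
                 admixture_edges = admixture_edges,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Balding-Nichols draw around parent frequencies with drift intensity F
bn_draw <- function(p, F) {
  shape1 <- p * (1 - F) / F
  shape2 <- (1 - p) * (1 - F) / F
  stats::rbeta(length(p), shape1, shape2)
}

gen_region_ids <- function(cfg) paste0("R", seq_len(cfg$n_regions))

#' Generate per-population allele frequencies and the planted truth
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); region frequencies are
#' Balding-Nichols draws around them with `F_region`; habitat
#' frequencies are drawn around region values with `F_habitat`, and
#' mine populations take an additional drift step of intensity
#' `1 - mine_diversity_factor`. Planted outliers then shift the mine
#' frequency of selected SNPs toward the fixation boundary opposite the
#' local coast frequencies in the selected comparisons; admixture edges
#' mix recipient frequencies toward the donor.
#'
#' @param cfg A [generator_config()].
#' @return A list with `p` (pops x SNPs frequency matrix; populations
#'   named `"R<k>-M"` / `"R<k>-C"`), `truth` (planted SNP indices per
#'   comparison subset, admixture edges, drift intensities) and `cfg`.
#' @export
gen_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    ns <- cfg$n_snps
    regions <- gen_region_ids(cfg)
    p_anc <- runif(ns, 0.05, 0.95)
    F_extra <- 1 - cfg$mine_diversity_factor
    p <- matrix(NA_real_, 2 * cfg$n_regions, ns)
    rownames(p) <- c(paste0(regions, "-C"), paste0(regions, "-M"))
    for (r in regions) {
      p_reg <- bn_draw(p_anc, cfg$F_region)
      p[paste0(r, "-C"), ] <- bn_draw(p_reg, cfg$F_habitat)
      p[paste0(r, "-M"), ] <- bn_draw(bn_draw(p_reg, cfg$F_habitat),
                                      F_extra)
    }
    planted <- tibble(snp_index = integer(), region = character(),
                      subset_id = integer())
    if (!is.null(cfg$planted_outliers)) {
      po <- as_tibble(cfg$planted_outliers)
      free <- rep(TRUE, ns)
      for (i in seq_len(nrow(po))) {
        comps <- po$comparisons[[i]]
        eff <- po$effect[i]
        if (eff < 0 || eff > 1) {
          warning("planted effect outside [0, 1] is infeasible; ",
                  "clamping to the valid range")
          eff <- min(1, max(0, eff))
        }
        # plant where the coast frequencies of the target regions are
        # extreme and consistent, so a mine shift toward the opposite
        # boundary yields a near-fixed difference in every comparison
        pc_mat <- p[paste0(comps, "-C"), , drop = FALSE]
        score_low <- apply(pc_mat, 2, max)       # fixable toward 1
        score_high <- 1 - apply(pc_mat, 2, min)  # fixable toward 0
        low <- score_low <= score_high
        score <- ifelse(low, score_low, score_high)
        score[!free] <- Inf
        idx <- order(score)[seq_len(po$n_snps[i])]
        free[idx] <- FALSE
        target <- as.numeric(low[idx])
        for (r in comps) {
          pm_old <- p[paste0(r, "-M"), idx]
          p[paste0(r, "-M"), idx] <- pm_old + eff * (target - pm_old)
        }
        planted <- dplyr::bind_rows(planted,
          tidyr::expand_grid(snp_index = idx, region = comps) |>
            dplyr::mutate(subset_id = i))
      }
    }
    if (!is.null(cfg$admixture_edges)) {
      ae <- as_tibble(cfg$admixture_edges)
      for (i in seq_len(nrow(ae))) {
        f <- ae$fraction[i]
        p[ae$pop_b[i], ] <- (1 - f) * p[ae$pop_b[i], ] +
          f * p[ae$pop_a[i], ]
      }
    }
    list(p = p,
         truth = list(planted = planted,
                      admixture = cfg$admixture_edges,
                      F_region = cfg$F_region,
                      F_habitat = cfg$F_habitat,
                      F_mine_extra = F_extra,
                      target_fst = c("coast-coast" = 0.25,
                                     "mine-coast" = 0.36,
                                     "mine-mine" = 0.45)),
         cfg = cfg)
  })
}

# region base coordinates (decimal degrees) and local mine-coast
# separations of ~15-27 km, echoing the sampled populations
region_coords <- function(regions) {
  base <- tibble(lat = c(52.35, 51.60, 51.20, 52.05),
                 lon = c(-4.05, -3.95, -2.60, -9.50),
                 dlat = c(0.1448, 0.1331, 0.2302, 0.2410))
  k <- length(regions)
  base <- base[rep_len(seq_len(4), k), ]
  base$lat <- base$lat + 0.6 * (seq_len(k) - 1) %/% 4
  base$region <- regions
  base
}

#' Sample genotypes from population frequencies
#'
#' Dosages are Binomial(2, p) per individual and site (Hardy-Weinberg
#' within demes). SNPs are assigned to scaffolds with log-normal
#' scaffold lengths (probability proportional to length) and uniform
#' positions. Optionally writes the VCF, popmap and truth JSON that the
#' I/O layer reads back.
#'
#' @param freqs Output of [gen_frequencies()].
#' @param cfg The same [generator_config()] (defaults to the one stored
#'   in `freqs`).
#' @param dir Optional output directory; writes `genotypes.vcf`,
#'   `popmap.tsv`, `truth.json`.
#' @return An object of class `synthetic_dataset`: list with `gm`
#'   ([geno_matrix()]), `pm` ([pop_map()]), `truth` (planted truth with
#'   SNP keys `"scaffold:pos"` and scaffold ids per comparison), and
#'   `paths` (if written).
#' @export
gen_genotypes <- function(freqs, cfg = freqs$cfg, dir = NULL) {
  p <- freqs$p
  ns <- ncol(p)
  with_seed(cfg$seed + 1L, {
    # scaffold assignment
    len <- stats::rlnorm(cfg$n_scaffolds, meanlog = log(5000),
                         sdlog = 0.7)
    len <- pmax(200L, as.integer(len))
    scaf_id <- sprintf("scaffold_%04d", seq_len(cfg$n_scaffolds))
    sc <- sample.int(cfg$n_scaffolds, ns, replace = TRUE,
                     prob = len)
    pos <- as.integer(ceiling(runif(ns) * len[sc]))
    key <- paste(scaf_id[sc], pos, sep = ":")
    while (anyDuplicated(key)) {
      dup <- duplicated(key)
      pos[dup] <- as.integer(ceiling(runif(sum(dup)) * len[sc[dup]]))
      key <- paste(scaf_id[sc], pos, sep = ":")
    }
    # genotypes
    pops <- rownames(p)
    ids <- as.vector(t(outer(pops, sprintf("%02d", seq_len(cfg$n_per_pop)),
                             paste, sep = "_")))
    dos <- matrix(NA_integer_, length(ids), ns)
    for (i in seq_along(pops)) {
      rows <- (i - 1) * cfg$n_per_pop + seq_len(cfg$n_per_pop)
      dos[rows, ] <- matrix(rbinom(cfg$n_per_pop * ns, 2,
                                   rep(p[i, ], each = cfg$n_per_pop)),
                            cfg$n_per_pop, ns)
    }
    gm <- geno_matrix(dos, scaf_id[sc], pos, ids)
    regions <- gen_region_ids(cfg)
    coords <- region_coords(regions)
    pop_tab <- dplyr::bind_rows(
      tibble(population = paste0(regions, "-C"), habitat = "coast",
             region = regions, lat = coords$lat, lon = coords$lon),
      tibble(population = paste0(regions, "-M"), habitat = "mine",
             region = regions, lat = coords$lat + coords$dlat,
             lon = coords$lon))
    pm <- pop_map(tibble(individual = ids,
                         population = rep(pops, each = cfg$n_per_pop)),
                  pop_tab)
    truth <- freqs$truth
    if (nrow(truth$planted)) {
      truth$planted$snp <- key[truth$planted$snp_index]
      truth$planted$scaffold <- scaf_id[sc[truth$planted$snp_index]]
    }
    # snp_key maps the generator's SNP index (columns of freqs$p) to
    # the "scaffold:pos" site keys of the emitted matrix
    out <- list(gm = gm, pm = pm, truth = truth, snp_key = key,
                paths = NULL)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                    popmap = file.path(dir, "popmap.tsv"),
                    truth = file.path(dir, "truth.json"))
      write_vcf(gm, paths$vcf)
      write_popmap(pm, paths$popmap)
      jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                           digits = NA)
      out$paths <- paths
    }
    structure(out, class = "synthetic_dataset")
  })
}

#' One-call synthetic dataset
#'
#' @param cfg A [generator_config()].
#' @param dir Optional output directory (see [gen_genotypes()]).
#' @return A `synthetic_dataset` (see [gen_genotypes()]).
#' @export
gen_dataset <- function(cfg = generator_config(), dir = NULL) {
  gen_genotypes(gen_frequencies(cfg), cfg, dir)
}

#' @exportS3Method base::print
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  print(x$gm)
  cat(sprintf("  %d populations, %d planted outlier records\n",
              nrow(x$pm$populations), nrow(x$truth$planted)))
  invisible(x)
}
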