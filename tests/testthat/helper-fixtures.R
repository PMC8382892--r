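# small in-code fixtures shared across tests

# random valid geno_matrix with optional missingness
random_gm <- function(n_ind = 10, n_site = 50, miss = 0, seed = 1,
                      n_scaffold = 3) {
  set.seed(seed)
  d <- matrix(sample(0:2, n_ind * n_site, replace = TRUE), n_ind, n_site)
  if (miss > 0) d[runif(length(d)) < miss] <- NA_integer_
  scaf <- sprintf("sc%02d", sort(sample.int(n_scaffold, n_site,
                                            replace = TRUE)))
  pos <- integer(n_site)
  for (s in unique(scaf)) {
    k <- sum(scaf == s)
    pos[scaf == s] <- sort(sample.int(1e5, k))
  }
  geno_matrix(d, scaf, pos, sprintf("ind%03d", seq_len(n_ind)))
}

# two-population map over a gm's individuals
two_pop_map <- function(gm, split = NULL) {
  ids <- sample_ids(gm)
  if (is.null(split)) split <- length(ids) %/% 2
  pop_map(data.frame(individual = ids,
                     population = rep(c("A", "B"),
                                      c(split, length(ids) - split))))
}

# dosage-specified two-population gm on one scaffold: rows A then B
paired_gm <- function(dA, dB, positions = NULL) {
  d <- rbind(dA, dB)
  if (is.null(positions)) positions <- seq_len(ncol(d))
  ids <- sprintf("i%02d", seq_len(nrow(d)))
  gm <- geno_matrix(d, rep("sc1", ncol(d)), positions, ids)
  pm <- pop_map(data.frame(individual = ids,
                           population = rep(c("A", "B"),
                                            c(nrow(dA), nrow(dB)))))
  list(gm = gm, pm = pm)
}

# independent hypergeometric-style enumeration of the multi-set
# intersection distribution by exhaustive subset draws (tiny N only)
enumerate_multiset <- function(N, sizes) {
  subs <- lapply(sizes, function(n) combn(N, n, simplify = FALSE))
  counts <- numeric(min(sizes) + 1)
  grids <- expand.grid(lapply(subs, seq_along))
  for (i in seq_len(nrow(grids))) {
    pick <- mapply(function(s, j) s[[j]], subs, as.integer(grids[i, ]),
                   SIMPLIFY = FALSE)
    k <- length(Reduce(intersect, pick))
    counts[k + 1] <- counts[k + 1] + 1
  }
  counts / sum(counts)
}
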