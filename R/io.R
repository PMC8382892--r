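#' Read a VCF into a genotype matrix
#'
#' Reads diploid GT calls from a VCF. Only biallelic SNP records are kept:
#' multiallelic records and indels are skipped with a message giving the
#' count. Missing calls (`./.`) become `NA`. Sites are sorted by
#' (scaffold, position) on the way in.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param missing_policy `"keep"` (default) retains sites regardless of
#'   missingness; `"filter"` applies [filter_missing()] with
#'   `max_missing`.
#' @param max_missing Missing-fraction cutoff used when
#'   `missing_policy = "filter"` (default 0.2).
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, missing_policy = c("keep", "filter"),
                     max_missing = 0.2) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT genotype field: ", path,
                        call. = FALSE)
  samples <- colnames(gt)
  if (anyDuplicated(samples))
    stop("duplicate sample ID(s) in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  gt <- gt[snp, , drop = FALSE]
  scaf <- fix[snp, "CHROM"]
  pos <- as.integer(fix[snp, "POS"])
  if (length(scaf) == 0L) {
    gm <- geno_matrix(matrix(integer(), length(samples), 0),
                      character(), integer(), samples)
    return(gm)
  }
  # "0/1", "0|1", "./." and haploid-coded oddities -> ALT dosage
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  idx <- match(clean, names(known))
  dos[] <- known[idx]
  gm <- geno_matrix(t(dos), scaf, pos, samples)
  if (missing_policy == "filter") gm <- filter_missing(gm, max_missing)
  gm
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a minimal VCFv4.2 with unphased GT-only genotypes; dosages map to
#' `0/0`, `0/1`, `1/1` and `NA` to `./.`. REF/ALT are written as `A`/`T`
#' placeholders (the dosage encoding carries the information).
#' `read_vcf(write_vcf(gm, f))` reproduces `gm`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sample_ids(gm)),
                     collapse = "\t")), con)
  if (n_sites(gm) > 0) {
    code <- c("0/0", "0/1", "1/1")
    d <- gm$dosages
    gtxt <- matrix("./.", nrow(d), ncol(d))
    ok <- !is.na(d)
    gtxt[ok] <- code[d[ok] + 1L]
    lines <- paste(gm$sites$scaffold, gm$sites$pos, ".", "A", "T", ".",
                   ".", ".", "GT", sep = "\t")
    body <- apply(gtxt, 2, paste, collapse = "\t")
    writeLines(paste(lines, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a population map (and optional population metadata) from TSV
#'
#' Accepts two layouts: a single tab-separated file with header columns
#' `individual`, `population` and optionally `habitat`, `region`, `lat`,
#' `lon` repeated per row; or a two-file layout where the second file
#' carries one row per population with those columns.
#'
#' @param path Path to the individual-level TSV.
#' @param pop_path Optional path to the population-level TSV.
#' @return A [pop_map()].
#' @export
read_popmap <- function(path, pop_path = NULL) {
  ind <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("individual", "population") %in% names(ind)))
    stop("popmap must have columns 'individual' and 'population'",
         call. = FALSE)
  if (!is.null(pop_path)) {
    pops <- utils::read.delim(pop_path, sep = "\t",
                              stringsAsFactors = FALSE)
    return(pop_map(ind[, c("individual", "population")], pops))
  }
  as_pop_map(ind)
}

#' Write a population map as TSV
#'
#' Single-file layout readable by [read_popmap()].
#'
#' @param pm A [pop_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  pm <- as_pop_map(pm)
  out <- dplyr::left_join(pm$individuals, pm$populations,
                          by = "population")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
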