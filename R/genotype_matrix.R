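#' Genotype matrix container
#'
#' The central data structure of the package: an ordered set of samples typed
#' at an ordered set of biallelic SNP sites. Genotypes are coded as alt-allele
#' dosages `0`, `1`, `2`, with `NA` for missing. When the data are phased,
#' two haplotype matrices (`hap1`, `hap2`, coded 0/1) accompany the dosage
#' matrix and satisfy `hap1 + hap2 == geno` at every non-missing site.
#'
#' @param samples character vector of unique sample ids (row order of `geno`).
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; positions must be strictly increasing within each chromosome.
#' @param geno integer matrix, samples x sites, values in `{0, 1, 2, NA}`.
#' @param hap1,hap2 optional 0/1 haplotype matrices of the same shape.
#' @param chrom_lengths optional named vector of chromosome lengths in bp.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, sites, geno, hap1 = NULL, hap2 = NULL,
                            chrom_lengths = NULL) {
  samples <- as.character(samples)
  stopifnot(!anyDuplicated(samples),
            is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(geno) == length(samples),
            ncol(geno) == nrow(sites))
  geno <- matrix(as.integer(geno), nrow = nrow(geno), ncol = ncol(geno))
  rownames(geno) <- samples
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("site positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(hap1)) {
    stopifnot(!is.null(hap2), all(dim(hap1) == dim(geno)),
              all(dim(hap2) == dim(geno)))
    hap1 <- matrix(as.integer(hap1), nrow = nrow(geno))
    hap2 <- matrix(as.integer(hap2), nrow = nrow(geno))
    rownames(hap1) <- rownames(hap2) <- samples
    ok <- is.na(geno) | (hap1 + hap2 == geno)
    if (!all(ok, na.rm = TRUE))
      stop("phased haplotypes do not sum to genotype codes")
  }
  structure(list(samples = samples,
                 sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 geno = geno, hap1 = hap1, hap2 = hap2,
                 chrom_lengths = chrom_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d biallelic sites (%d chromosomes)%s\n",
              n_samples(x), n_sites(x), length(unique(x$sites$chrom)),
              if (is_phased(x)) ", phased" else ""))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return An integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Is the genotype matrix phased?
#' @param gm a `genotype_matrix`.
#' @return `TRUE` if haplotype matrices are present.
#' @export
is_phased <- function(gm) !is.null(gm$hap1)

#' Subset a genotype matrix by site index or by sample id
#'
#' Both operations preserve ordering and phasing.
#'
#' @param gm a `genotype_matrix`.
#' @param idx integer or logical index into sites (for `subset_sites`).
#' @param ids character vector of sample ids (for `subset_samples`).
#' @return A new `genotype_matrix`.
#' @export
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$samples, gm$sites[idx, , drop = FALSE],
                  gm$geno[, idx, drop = FALSE],
                  if (is_phased(gm)) gm$hap1[, idx, drop = FALSE],
                  if (is_phased(gm)) gm$hap2[, idx, drop = FALSE],
                  gm$chrom_lengths)
}

#' @rdname subset_sites
#' @export
subset_samples <- function(gm, ids) {
  miss <- setdiff(ids, gm$samples)
  if (length(miss))
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  i <- match(ids, gm$samples)
  genotype_matrix(ids, gm$sites, gm$geno[i, , drop = FALSE],
                  if (is_phased(gm)) gm$hap1[i, , drop = FALSE],
                  if (is_phased(gm)) gm$hap2[i, , drop = FALSE],
                  gm$chrom_lengths)
}

#' Alternate-allele frequencies per site
#'
#' @param gm a `genotype_matrix`.
#' @param samples optional subset of sample ids to estimate from.
#' @return Numeric vector of alt-allele frequencies (NaN where no calls).
#' @export
allele_freq <- function(gm, samples = NULL) {
  g <- if (is.null(samples)) gm$geno else gm$geno[match(samples, gm$samples), , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

chrom_order <- function(gm) unique(gm$sites$chrom)

# chromosome lengths: declared, else max observed position per chromosome
chrom_len <- function(gm) {
  if (!is.null(gm$chrom_lengths)) return(gm$chrom_lengths)
  vapply(split(gm$sites$pos, factor(gm$sites$chrom, levels = chrom_order(gm))),
         max, numeric(1))
}
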