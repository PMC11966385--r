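#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzipped) through `vcfR`, keeping only
#' biallelic SNP records; multiallelic and non-SNP records are dropped with a
#' logged count. Diploid GT fields become alt-allele dosages 0/1/2; haploid
#' calls are folded to homozygous dosages (0 or 2); missing calls become `NA`.
#' If every non-missing diploid call is phased (`|` separator) the two
#' haplotype matrices are populated.
#'
#' @param path VCF or VCF.gz file.
#' @param sheet optional sample sheet (see [read_sample_sheet()]); every VCF
#'   sample must be present in it.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sheet = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  nt <- c("A", "C", "G", "T")
  snp <- fix$REF %in% nt & fix$ALT %in% nt
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop, " multiallelic/non-SNP record(s)")
  gt <- vcf@gt[snp, -1, drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  samples <- colnames(gt)
  if (!is.null(sheet)) {
    missing_ids <- setdiff(samples, sheet$id)
    if (length(missing_ids))
      stop("VCF samples absent from sample sheet: ",
           paste(missing_ids, collapse = ", "))
  }
  # strip any trailing FORMAT fields; GT is first per VCF spec
  gt <- sub(":.*$", "", gt)
  codes <- parse_gt_codes(unique(as.vector(gt)))
  dos <- matrix(codes$dosage[gt], nrow = nrow(gt))
  hap1 <- hap2 <- NULL
  nonmiss <- gt[!is.na(dos)]
  diploid <- grepl("[/|]", nonmiss)
  if (length(nonmiss) && all(diploid) && !any(grepl("/", nonmiss, fixed = TRUE))) {
    hap1 <- matrix(codes$a1[gt], nrow = nrow(gt))
    hap2 <- matrix(codes$a2[gt], nrow = nrow(gt))
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dos <- dos[ord, , drop = FALSE]
  if (!is.null(hap1)) { hap1 <- hap1[ord, , drop = FALSE]; hap2 <- hap2[ord, , drop = FALSE] }
  dup <- duplicated(paste(sites$chrom, sites$pos))
  if (any(dup)) {
    message("read_vcf: dropped ", sum(dup), " duplicate-position record(s)")
    sites <- sites[!dup, , drop = FALSE]
    dos <- dos[!dup, , drop = FALSE]
    if (!is.null(hap1)) { hap1 <- hap1[!dup, , drop = FALSE]; hap2 <- hap2[!dup, , drop = FALSE] }
  }
  genotype_matrix(samples, sites, t(dos),
                  if (!is.null(hap1)) t(hap1), if (!is.null(hap1)) t(hap2),
                  contig_lengths(vcf@meta))
}

# one-pass lookup tables for the distinct GT strings in a file
parse_gt_codes <- function(u) {
  u <- u[!is.na(u)]
  dosage <- a1 <- a2 <- stats::setNames(rep(NA_integer_, length(u)), u)
  for (s in u) {
    parts <- strsplit(s, "[/|]")[[1]]
    if (any(parts == ".") || !length(parts) || s == ".") next
    al <- suppressWarnings(as.integer(parts))
    if (anyNA(al) || any(al > 1L)) stop("malformed or multiallelic GT field: ", s)
    if (length(al) == 1L) {          # haploid call folded to homozygous
      dosage[s] <- 2L * al
    } else if (length(al) == 2L) {
      dosage[s] <- sum(al)
      a1[s] <- al[1]; a2[s] <- al[2]
    } else stop("unsupported ploidy in GT field: ", s)
  }
  list(dosage = dosage, a1 = a1, a2 = a2)
}

contig_lengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  id <- sub('.*ID=([^,>]+).*', "\\1", ln)
  len <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", ln)))
  if (anyNA(len)) return(NULL)
  stats::setNames(len, id)
}

#' Read a sample sheet (id, panel, role)
#'
#' @param path TSV with columns `id`, `panel`
#'   (`species_A` / `species_B` / `none`) and `role` (`panel`, `query`,
#'   `candidate_parent`, `clone_group:<name>`, `distractor`).
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  stopifnot(all(c("id", "panel", "role") %in% names(sheet)))
  if (anyDuplicated(sheet$id)) stop("duplicate sample ids in sheet")
  sheet
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT-only records; phased matrices are written with `|` separators,
#' unphased with `/`. With `haploid = TRUE` dosages 0/2 are written as single
#' haploid alleles (heterozygous dosages become missing, with a logged count).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path; gzip compression when it ends in `.gz`.
#' @param haploid write single-allele GT fields (for chloroplast data).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path, haploid = FALSE) {
  g <- t(gm$geno)                       # sites x samples
  if (haploid) {
    het <- sum(g == 1L, na.rm = TRUE)
    if (het > 0) message("write_vcf: ", het, " heterozygous call(s) written as missing in haploid output")
    chr <- c("0", ".", "1")[ifelse(is.na(g), 2L, g + 1L) ]
    gtchar <- matrix(ifelse(is.na(g), ".", chr), nrow = nrow(g))
  } else if (is_phased(gm)) {
    h1 <- t(gm$hap1); h2 <- t(gm$hap2)
    gtchar <- matrix(ifelse(is.na(h1) | is.na(h2), ".|.",
                            paste0(h1, "|", h2)), nrow = nrow(g))
  } else {
    map <- c("0/0", "0/1", "1/1")
    gtchar <- matrix(ifelse(is.na(g), "./.", map[g + 1L]), nrow = nrow(g))
  }
  lens <- chrom_len(gm)
  header <- c("##fileformat=VCFv4.2",
              "##source=hybriseek",
              sprintf("##contig=<ID=%s,length=%d>", names(lens),
                      as.integer(lens)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- do.call(paste, c(list(gm$sites$chrom, gm$sites$pos, ".",
                                gm$sites$ref, gm$sites$alt, ".", ".", ".", "GT"),
                           lapply(seq_len(ncol(gtchar)), function(j) gtchar[, j]),
                           sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Filter sites on missingness and minor-allele frequency
#'
#' Removes sites whose missing-call fraction exceeds `max_missing` or whose
#' minor-allele frequency (computed from non-missing calls) falls below
#' `min_maf`. Site order is preserved. With `min_maf = 0` the MAF bound is not
#' applied, so fully missing sites pass a `max_missing = 1` filter unchanged.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction per site, in `[0, 1]`.
#' @param min_maf minimum minor-allele frequency, in `[0, 0.5]`.
#' @return A filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, max_missing = 0.2, min_maf = 0.01) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5)
  miss <- colMeans(is.na(gm$geno))
  p <- allele_freq(gm)
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing &
    (min_maf == 0 | (!is.nan(maf) & maf >= min_maf))
  subset_sites(gm, keep)
}

#' LD-prune sites on pairwise genotype correlation
#'
#' Sliding-window greedy pruning on squared Pearson correlation of genotype
#' dosages (pairwise-complete over missing data): within each window, when a
#' retained pair exceeds `r2_max` the later site is removed. Monomorphic
#' sites (undefined r^2) are never pruned on r^2 grounds.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_max maximum tolerated r^2 between retained sites, in `(0, 1]`.
#' @param window_sites,step_sites window size and step in number of sites.
#' @return A pruned `genotype_matrix`.
#' @export
ld_prune <- function(gm, r2_max = 0.9, window_sites = 50, step_sites = 5) {
  stopifnot(r2_max > 0, r2_max <= 1, window_sites >= 2, step_sites >= 1)
  keep <- rep(TRUE, n_sites(gm))
  for (ch in chrom_order(gm)) {
    idx <- which(gm$sites$chrom == ch)
    len <- length(idx)
    if (len < 2) next
    for (s in seq(1, len, by = step_sites)) {
      w <- s:min(s + window_sites - 1, len)
      if (length(w) < 2) next
      cols <- idx[w]
      alive <- keep[cols]
      if (sum(alive) < 2) next
      r2 <- suppressWarnings(
        stats::cor(gm$geno[, cols, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      for (b in 2:length(w)) {
        if (!alive[b]) next
        prev <- which(alive[seq_len(b - 1)])
        if (!length(prev)) next
        v <- r2[prev, b]
        if (any(!is.na(v) & v > r2_max)) alive[b] <- FALSE
      }
      keep[cols] <- alive
      if (max(w) == len) break
    }
  }
  subset_sites(gm, keep)
}
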