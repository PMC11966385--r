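#' Method-of-moments IBD estimation for one sample pair
#'
#' PLINK-style estimator: observed identity-by-state (IBS) 0/1/2 site counts
#' are equated with their expectations under allele frequencies to solve for
#' the probabilities Z0/Z1/Z2 of sharing 0/1/2 alleles identical by descent.
#' Negative raw estimates are truncated to zero and the triple renormalized.
#' `PI_HAT = Z2 + Z1/2`. Frequencies default to the cohort in `gm`; a
#' frequency vector from a reference panel may be supplied instead, which is
#' preferable when the cohort is structured.
#'
#' @param gm a [genotype_matrix()].
#' @param pair character vector of two sample ids.
#' @param freq optional per-site alt-allele frequencies (length `n_sites(gm)`).
#' @param min_sites pairs with fewer informative sites are flagged
#'   low-confidence.
#' @return One-row data frame: `id1`, `id2`, `Z0`, `Z1`, `Z2`, `PI_HAT`, `n`
#'   (sites used), `n_ibs0`/`n_ibs1`/`n_ibs2` (observed IBS site counts;
#'   IBS0 sites are opposing homozygotes), `low_confidence`.
#' @export
ibd_moments <- function(gm, pair, freq = NULL, min_sites = 100) {
  stopifnot(length(pair) == 2)
  if (is.null(freq)) freq <- allele_freq(gm)
  gx <- gm$geno[match(pair[1], gm$samples), ]
  gy <- gm$geno[match(pair[2], gm$samples), ]
  use <- !is.na(gx) & !is.na(gy) & !is.na(freq) & freq > 0 & freq < 1
  p <- freq[use]; q <- 1 - p
  gx <- gx[use]; gy <- gy[use]
  n <- length(p)
  if (n == 0) stop("no informative sites shared by the pair")
  d <- abs(gx - gy)
  N0 <- sum(d == 2); N1 <- sum(d == 1); N2 <- sum(d == 0)
  S00 <- sum(2 * p^2 * q^2)
  S10 <- sum(4 * p * q * (p^2 + q^2))
  S11 <- sum(2 * p * q)
  S20 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  S21 <- sum(1 - 2 * p * q)
  z0 <- N0 / S00
  z1 <- (N1 - z0 * S10) / S11
  z2 <- (N2 - z0 * S20 - z1 * S21) / n
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  data.frame(id1 = pair[1], id2 = pair[2],
             Z0 = z[1], Z1 = z[2], Z2 = z[3],
             PI_HAT = z[3] + z[2] / 2, n = n,
             n_ibs0 = N0, n_ibs1 = N1, n_ibs2 = N2,
             low_confidence = n < min_sites, stringsAsFactors = FALSE)
}

#' Pairwise IBD matrices for a cohort
#'
#' Runs [ibd_moments()] on every unordered pair. Diagonals are set to the
#' self-sharing values (Z2 = 1, PI_HAT = 1).
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional sample subset.
#' @param freq optional allele-frequency vector (see [ibd_moments()]).
#' @return List with `pairs` (long-format data frame) and symmetric matrices
#'   `Z0`, `Z1`, `Z2`, `PI_HAT`.
#' @export
ibd_matrix <- function(gm, samples = NULL, freq = NULL) {
  if (is.null(samples)) samples <- gm$samples
  if (length(samples) < 2) stop("need at least two samples")
  if (is.null(freq)) freq <- allele_freq(gm, samples)
  k <- length(samples)
  mk <- function(diag_val) {
    m <- matrix(NA_real_, k, k, dimnames = list(samples, samples))
    diag(m) <- diag_val
    m
  }
  M <- list(Z0 = mk(0), Z1 = mk(0), Z2 = mk(1), PI_HAT = mk(1))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- ibd_moments(gm, c(samples[i], samples[j]), freq = freq)
    rows[[length(rows) + 1]] <- r
    for (nm in names(M)) M[[nm]][i, j] <- M[[nm]][j, i] <- r[[nm]]
  }
  c(list(pairs = do.call(rbind, rows)), M)
}

#' PCA of the genotype matrix
#'
#' Eigen-analysis of the frequency-standardized genotype matrix: missing
#' genotypes are mean-imputed per site, dosages are centered at `2p` and
#' scaled by `sqrt(2p(1-p))`, constant sites are dropped with a logged count.
#' Component signs are fixed so the entry of largest magnitude is positive.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (< min(n_samples, n_sites)).
#' @param samples optional sample subset.
#' @return List with `scores` (samples x k), `explained` (variance share per
#'   component, non-increasing), and `k`.
#' @export
pca_genotypes <- function(gm, k = 2, samples = NULL) {
  if (is.null(samples)) samples <- gm$samples
  g <- gm$geno[match(samples, gm$samples), , drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  miss <- which(is.na(g), arr.ind = TRUE)
  if (nrow(miss)) g[miss] <- mu[miss[, 2]]
  p <- mu / 2
  keep <- !is.nan(p) & p > 0 & p < 1 & col_sds(g) > 0
  n_drop <- sum(!keep)
  if (n_drop > 0) message("pca_genotypes: dropped ", n_drop, " constant site(s)")
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  if (k >= min(nrow(g), ncol(g))) stop("k must be < min(n_samples, n_sites)")
  x <- sweep(sweep(g, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(x)
  ev <- sv$d^2
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(samples, paste0("PC", seq_len(k)))
  list(scores = scores, explained = ev[seq_len(k)] / sum(ev), k = k)
}

# column standard deviations without extra dependencies
col_sds <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(m^2) - mu^2)
}
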