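#' Mendelian compatibility of an offspring genotype with a parent pair
#'
#' An offspring dosage is compatible when it can be formed from one gamete of
#' each parent. Gamete sets of dosages 0/1/2 are {0}, {0,1}, {1}, so the
#' achievable offspring dosages form the contiguous range from
#' `(gA==2) + (gB==2)` to `(gA>=1) + (gB>=1)`. Vectorized over sites; codes
#' must be 0/1/2 (missing data are excluded upstream).
#'
#' @param g_off,g_a,g_b integer vectors of genotype dosages.
#' @return Logical vector.
#' @export
mendelian_compatible <- function(g_off, g_a, g_b) {
  lo <- (g_a == 2L) + (g_b == 2L)
  hi <- (g_a >= 1L) + (g_b >= 1L)
  g_off >= lo & g_off <= hi
}

#' Trio coincidence probability
#'
#' The fraction (as a percentage) of evaluated SNPs at which the offspring's
#' genotype is Mendelian-compatible with the candidate parent pair. Sites
#' with a missing genotype in any trio member are skipped. With
#' `informative_only = TRUE` (default), sites where every offspring genotype
#' would be compatible (both parents heterozygous) are excluded from the
#' denominator, since they carry no signal against a false pair. The `+/-`
#' dispersion is the standard deviation of per-chromosome coincidence values;
#' a leave-one-chromosome-out jackknife standard error is also available.
#'
#' @param gm a [genotype_matrix()].
#' @param offspring,parent_a,parent_b sample ids.
#' @param informative_only exclude trivially compatible sites from the
#'   denominator.
#' @param dispersion `"chrom_sd"` (default) or `"jackknife"`.
#' @return A `trio_score` list: ids, `n_evaluated`, `n_informative`,
#'   `n_compatible`, `coincidence` (percent), `dispersion`, `per_chrom`
#'   (data frame of per-chromosome values).
#' @export
coincidence_probability <- function(gm, offspring, parent_a, parent_b,
                                    informative_only = TRUE,
                                    dispersion = c("chrom_sd", "jackknife")) {
  dispersion <- match.arg(dispersion)
  ids <- c(offspring, parent_a, parent_b)
  miss <- setdiff(ids, gm$samples)
  if (length(miss)) stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))
  go <- gm$geno[match(offspring, gm$samples), ]
  ga <- gm$geno[match(parent_a, gm$samples), ]
  gb <- gm$geno[match(parent_b, gm$samples), ]
  called <- !is.na(go) & !is.na(ga) & !is.na(gb)
  informative <- called & !(ga == 1L & gb == 1L)
  use <- if (informative_only) informative else called
  use[is.na(use)] <- FALSE
  n_eval <- sum(use)
  if (n_eval == 0) stop("no evaluable sites for this trio")
  comp <- mendelian_compatible(go[use], ga[use], gb[use])
  chrom <- factor(gm$sites$chrom[use], levels = chrom_order(gm))
  per_n <- tapply(comp, chrom, length)
  per_k <- tapply(comp, chrom, sum)
  ok <- !is.na(per_n)
  per_chrom <- data.frame(chrom = names(per_n)[ok],
                          n = as.integer(per_n[ok]),
                          coincidence = 100 * as.numeric(per_k[ok] / per_n[ok]),
                          stringsAsFactors = FALSE)
  disp <- if (dispersion == "chrom_sd") {
    stats::sd(per_chrom$coincidence)
  } else {
    # leave-one-chromosome-out jackknife SE of the global percentage
    tot_k <- sum(per_chrom$n * per_chrom$coincidence / 100)
    theta <- 100 * (tot_k - per_chrom$n * per_chrom$coincidence / 100) /
      (n_eval - per_chrom$n)
    C <- nrow(per_chrom)
    sqrt((C - 1) / C * sum((theta - mean(theta))^2))
  }
  structure(list(offspring = offspring, parent_a = parent_a, parent_b = parent_b,
                 n_evaluated = n_eval, n_informative = sum(informative),
                 n_compatible = sum(comp),
                 coincidence = 100 * mean(comp), dispersion = disp,
                 dispersion_method = dispersion, informative_only = informative_only,
                 per_chrom = per_chrom),
            class = "trio_score")
}

#' @export
print.trio_score <- function(x, ...) {
  cat(sprintf("<trio_score> %s = %s x %s\n", x$offspring, x$parent_a, x$parent_b))
  cat(sprintf("  coincidence: %.2f%% +/- %.2f%% (%s) over %d sites (%s)\n",
              x$coincidence, x$dispersion, x$dispersion_method, x$n_evaluated,
              if (x$informative_only) "informative only" else "all called"))
  invisible(x)
}

#' Score and rank all candidate parent pairs for an offspring
#'
#' Every unordered pair of candidates is scored with
#' [coincidence_probability()] and sorted by coincidence (descending), ties
#' by informative-site count (descending), then lexically by parent ids.
#'
#' @param gm a [genotype_matrix()].
#' @param offspring offspring sample id (removed from candidates with a
#'   warning if listed there).
#' @param candidates character vector of candidate parent ids (>= 2).
#' @param informative_only see [coincidence_probability()].
#' @return Data frame, one row per pair: `parent_a`, `parent_b` (lexical
#'   order within pair), `coincidence`, `dispersion`, `n_evaluated`,
#'   `n_informative`, `n_compatible`, `rank`.
#' @export
rank_parent_pairs <- function(gm, offspring, candidates,
                              informative_only = TRUE) {
  if (offspring %in% candidates) {
    warning("offspring removed from candidate list")
    candidates <- setdiff(candidates, offspring)
  }
  if (length(candidates) < 2) stop("need at least two candidate parents")
  pairs <- utils::combn(sort(candidates), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ts <- coincidence_probability(gm, offspring, pairs[1, k], pairs[2, k],
                                  informative_only = informative_only)
    data.frame(parent_a = ts$parent_a, parent_b = ts$parent_b,
               coincidence = ts$coincidence, dispersion = ts$dispersion,
               n_evaluated = ts$n_evaluated, n_informative = ts$n_informative,
               n_compatible = ts$n_compatible, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$coincidence, -out$n_informative, out$parent_a, out$parent_b)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Chloroplast-distance maternal (seed parent) assignment
#'
#' Computes pairwise p-distances (proportion of differing alleles over shared
#' called sites) between effectively haploid chloroplast haplotypes, assigns
#' the query's maternal candidate as the nearest candidate, and emits a
#' neighbor-joining tree in Newick format. Heterozygous chloroplast calls are
#' dropped with a logged count.
#'
#' @param cp_gm chloroplast [genotype_matrix()] (haploid calls folded to
#'   dosages 0/2).
#' @param query query sample id.
#' @param candidates candidate maternal-parent ids.
#' @return A `cp_distance_result` list: `distances` (symmetric matrix over
#'   query + candidates), `query`, `assigned` (nearest candidate; ties broken
#'   lexically), `newick` (NJ tree).
#' @export
cp_maternal_assign <- function(cp_gm, query, candidates) {
  ids <- unique(c(query, candidates))
  miss <- setdiff(ids, cp_gm$samples)
  if (length(miss)) stop("sample(s) missing cp data: ", paste(miss, collapse = ", "))
  a <- cp_gm$geno[match(ids, cp_gm$samples), , drop = FALSE]
  n_het <- sum(a == 1L, na.rm = TRUE)
  if (n_het > 0) {
    message("cp_maternal_assign: dropped ", n_het, " heterozygous cp call(s)")
    a[a == 1L] <- NA_integer_
  }
  a <- a / 2                       # haploid alleles 0/1
  k <- length(ids)
  D <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    shared <- !is.na(a[i, ]) & !is.na(a[j, ])
    if (!any(shared)) stop("no shared called cp sites between ", ids[i], " and ", ids[j])
    D[i, j] <- D[j, i] <- mean(a[i, shared] != a[j, shared])
  }
  cand <- setdiff(ids, query)
  d_query <- D[query, cand]
  assigned <- cand[order(d_query, cand)][1]
  structure(list(distances = D, query = query, assigned = assigned,
                 newick = nj_newick(D)),
            class = "cp_distance_result")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Textbook NJ (iterative Q-matrix agglomeration). Negative branch lengths
#' are clamped to zero with a logged count. The final edge is split at its
#' midpoint to root the output string, which preserves all leaf-to-leaf path
#' lengths.
#'
#' @param D symmetric distance matrix with dimnames.
#' @return Newick string.
#' @export
nj_newick <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 2, isSymmetric(unname(D)))
  labs <- rownames(D)
  n_clamped <- 0
  if (n == 2) return(sprintf("(%s:%.12g,%s:%.12g);", labs[1], D[1, 2] / 2,
                             labs[2], D[1, 2] / 2))
  repeat {
    n <- nrow(D)
    if (n == 2) break
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]   # deterministic tie-break
    i <- min(k); j <- max(k)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { n_clamped <- n_clamped + 1; lj <- lj + li; li <- 0 }
    if (lj < 0) { n_clamped <- n_clamped + 1; li <- li + lj; lj <- 0 }
    new_lab <- sprintf("(%s:%.12g,%s:%.12g)", labs[i], li, labs[j], lj)
    d_new <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
                c(d_new[keep], 0))
    labs <- c(labs[keep], new_lab)
    dimnames(D2) <- list(labs, labs)
    D <- D2
  }
  if (n_clamped > 0)
    message("nj_newick: clamped ", n_clamped, " negative branch length(s) to 0")
  sprintf("(%s:%.12g,%s:%.12g);", labs[1], max(D[1, 2], 0) / 2,
          labs[2], max(D[1, 2], 0) / 2)
}

#' Aggregate trio, chloroplast and IBD evidence into an origin report
#'
#' Deterministic synthesis of previously computed evidence: the best-ranked
#' candidate pair names the parents; the chloroplast distances orient seed vs
#' pollen parent; IBD1 values are attached as supporting evidence. If the
#' query's chloroplast-nearest candidate is not in the best pair the
#' orientation conflict is reported as `"unresolved"` (never silently
#' overridden); absent chloroplast evidence yields `"undetermined"`.
#'
#' @param trio_scores a [rank_parent_pairs()] result.
#' @param cp_result a [cp_maternal_assign()] result, or `NULL`.
#' @param ibd a [ibd_matrix()] result, or `NULL`.
#' @param offspring offspring/query id (for the IBD lookup).
#' @return An `origin_report` list.
#' @export
decide_origin <- function(trio_scores, cp_result = NULL, ibd = NULL,
                          offspring = NULL) {
  best <- trio_scores[1, ]
  pa <- best$parent_a; pb <- best$parent_b
  status <- "undetermined"; seed <- NA_character_; pollen <- NA_character_
  cp_d <- NULL
  if (!is.null(cp_result)) {
    ids <- rownames(cp_result$distances)
    if (all(c(pa, pb) %in% ids)) {
      da <- cp_result$distances[cp_result$query, pa]
      db <- cp_result$distances[cp_result$query, pb]
      cp_d <- stats::setNames(c(da, db), c(pa, pb))
      if (!(cp_result$assigned %in% c(pa, pb)) ) {
        status <- "unresolved"     # cp-nearest candidate outside the best pair
      } else if (da == db) {
        status <- "undetermined"
      } else {
        status <- "resolved"
        seed <- if (da < db) pa else pb
        pollen <- setdiff(c(pa, pb), seed)
      }
    }
  }
  ibd1 <- NULL
  if (!is.null(ibd) && !is.null(offspring) &&
      all(c(offspring, pa, pb) %in% rownames(ibd$Z1)))
    ibd1 <- stats::setNames(c(ibd$Z1[offspring, pa], ibd$Z1[offspring, pb]),
                            c(pa, pb))
  structure(list(best_pair = c(pa, pb),
                 coincidence = best$coincidence,
                 dispersion = best$dispersion,
                 orientation = status,
                 seed_parent = seed, pollen_parent = pollen,
                 cp_distances = cp_d, ibd1 = ibd1,
                 top_pairs = utils::head(trio_scores, 5)),
            class = "origin_report")
}

#' @export
print.origin_report <- function(x, ...) {
  cat("<origin_report>\n")
  cat(sprintf("  best parent pair: %s x %s (coincidence %.2f%% +/- %.2f%%)\n",
              x$best_pair[1], x$best_pair[2], x$coincidence, x$dispersion))
  if (x$orientation == "resolved") {
    cat(sprintf("  seed parent:   %s\n  pollen parent: %s\n",
                x$seed_parent, x$pollen_parent))
  } else {
    cat(sprintf("  seed/pollen orientation: %s\n", x$orientation))
  }
  if (!is.null(x$cp_distances))
    cat(sprintf("  cp p-distance: %s\n",
                paste(sprintf("%s=%.4g", names(x$cp_distances), x$cp_distances),
                      collapse = ", ")))
  if (!is.null(x$ibd1))
    cat(sprintf("  IBD1 with offspring: %s\n",
                paste(sprintf("%s=%.3f", names(x$ibd1), x$ibd1), collapse = ", ")))
  invisible(x)
}
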