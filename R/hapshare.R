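#' Minimal-cost haplotype copying of a recipient against a donor panel
#'
#' Segments each recipient haplotype into fragments copied from donor
#' haplotypes by dynamic programming (Viterbi-style): copying a site from a
#' donor whose allele mismatches costs `mismatch_cost`, changing donor
#' haplotype between adjacent sites costs `switch_cost`. This is a
#' deterministic analogue of probabilistic chromosome-painting models; the
#' per-donor fragment counts ("copying vector") are the quantity used to rank
#' relatives. Ties are broken toward the lowest-index donor haplotype, and a
#' tie between staying and switching keeps the current donor.
#'
#' Sites where the recipient haplotype is missing are skipped; a missing
#' donor allele costs `mismatch_cost / 2`.
#'
#' @param gm a phased [genotype_matrix()].
#' @param recipient recipient sample id.
#' @param donors character vector of donor sample ids (recipient excluded).
#' @param switch_cost cost per donor change.
#' @param mismatch_cost cost per mismatched copied site.
#' @param haplotypes which recipient haplotypes to paint (default both).
#' @return A `copying_vector` list: `recipient`, `counts` (fragments per
#'   donor), `total` (total fragments), `segments` (data frame: chrom, start,
#'   end in bp, recipient haplotype, donor, donor haplotype), `total_cost`,
#'   `n_mismatch`.
#' @export
copy_paint <- function(gm, recipient, donors, switch_cost = 1.0,
                       mismatch_cost = 0.5, haplotypes = 1:2) {
  if (!is_phased(gm))
    stop("copy_paint requires phased haplotypes; supply phased input")
  donors <- setdiff(donors, recipient)
  if (!length(donors)) stop("need at least one donor distinct from the recipient")
  di <- match(donors, gm$samples)
  ri <- match(recipient, gm$samples)
  if (anyNA(c(di, ri))) stop("unknown sample id among recipient/donors")
  # donor states: two haplotypes per donor, donor-major order
  D <- rbind(gm$hap1[di, , drop = FALSE], gm$hap2[di, , drop = FALSE])
  state_ord <- as.vector(t(matrix(seq_len(2 * length(donors)), ncol = 2)))
  D <- D[state_ord, , drop = FALSE]
  state_donor <- rep(donors, each = 2)
  state_hap <- rep(1:2, times = length(donors))
  lens <- chrom_len(gm)
  segs <- list(); total_cost <- 0; n_mismatch <- 0
  for (h in haplotypes) {
    rhap <- if (h == 1) gm$hap1[ri, ] else gm$hap2[ri, ]
    for (ch in chrom_order(gm)) {
      idx <- which(gm$sites$chrom == ch & !is.na(rhap))
      if (!length(idx)) next
      local <- abs(sweep(D[, idx, drop = FALSE], 2, rhap[idx])) * mismatch_cost
      local[is.na(local)] <- mismatch_cost / 2
      path <- viterbi_min_path(local, switch_cost)
      total_cost <- total_cost + path$cost
      n_mismatch <- n_mismatch + sum(local[cbind(path$states, seq_along(idx))] == mismatch_cost)
      r <- rle(path$states)
      ends_i <- cumsum(r$lengths)
      starts_i <- c(1, utils::head(ends_i, -1) + 1)
      pos <- gm$sites$pos[idx]
      seg_start <- c(1, pos[utils::head(ends_i, -1)] + 1)
      seg_end <- c(pos[utils::head(ends_i, -1)], lens[[ch]])
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = seg_start, end = seg_end, recipient_hap = h,
        donor = state_donor[r$values], donor_hap = state_hap[r$values],
        n_sites = r$lengths, stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  counts <- table(factor(segments$donor, levels = donors))
  structure(list(recipient = recipient,
                 counts = stats::setNames(as.integer(counts), donors),
                 total = nrow(segments), segments = segments,
                 total_cost = total_cost, n_mismatch = n_mismatch),
            class = "copying_vector")
}

# minimal-cost state path through a local-cost matrix (states x sites);
# switching states between adjacent sites costs switch_cost. Deterministic
# tie-breaks: stay beats switch, lower state index beats higher.
viterbi_min_path <- function(local, switch_cost) {
  ns <- nrow(local); m <- ncol(local)
  ptr <- matrix(0L, ns, m)
  f <- local[, 1]
  for (t in seq_len(m)[-1]) {
    best_prev <- which.min(f)           # lowest index on ties
    alt <- f[best_prev] + switch_cost
    stay <- f <= alt                    # tie: stay
    ptr[, t] <- ifelse(stay, seq_len(ns), best_prev)
    f <- ifelse(stay, f, alt) + local[, t]
  }
  end <- which.min(f)
  states <- integer(m)
  states[m] <- end
  if (m > 1) for (t in m:2) states[t - 1] <- ptr[states[t], t]
  list(states = states, cost = unname(f[end]))
}

#' Haplotype-sharing (copying) matrix for candidate ranking
#'
#' Runs [copy_paint()] for every recipient against the donor panel,
#' leave-one-out (a sample never donates to itself). Entry `(r, d)` is the
#' number of fragments recipient `r` copies from donor `d`.
#'
#' @param gm a phased [genotype_matrix()].
#' @param recipients,donors character vectors of sample ids.
#' @param ... passed to [copy_paint()].
#' @return Numeric matrix recipients x donors (`NA` on self entries).
#' @export
sharing_matrix <- function(gm, recipients, donors, ...) {
  out <- matrix(NA_real_, length(recipients), length(donors),
                dimnames = list(recipients, donors))
  for (r in recipients) {
    cv <- copy_paint(gm, r, setdiff(donors, r), ...)
    out[r, names(cv$counts)] <- cv$counts
  }
  out
}

#' Mean shared-fragment count between a donor and a recipient group
#'
#' @param mat a [sharing_matrix()] result.
#' @param donor donor (column) id.
#' @param recipient_group character vector of recipient (row) ids.
#' @return Arithmetic mean fragment count (self entries excluded).
#' @export
mean_shared_fragments <- function(mat, donor, recipient_group) {
  if (!length(recipient_group)) stop("recipient group must be non-empty")
  mean(mat[recipient_group, donor], na.rm = TRUE)
}
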