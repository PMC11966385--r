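#' Ascertain species-diagnostic SNPs from two pure reference panels
#'
#' A site is diagnostic when, with at least `min_panel_n` called samples in
#' each panel, its alt-allele frequency is <= `max_alt_freq` in one panel and
#' >= `1 - max_alt_freq` in the other. The allele-to-species map records which
#' species the alt allele marks. The default `max_alt_freq = 0.05` accepts
#' near-fixed rather than strictly fixed differences, which is robust at small
#' panel sizes.
#'
#' @param gm a [genotype_matrix()].
#' @param sheet sample sheet with `panel` column (`species_A` / `species_B`).
#' @param min_panel_n minimum called samples per panel at a retained site.
#' @param max_alt_freq fixation tolerance in `[0, 0.5)`.
#' @return A `diagnostic_panel` data frame: `chrom`, `pos`, `alt_species`
#'   (species marked by the alt allele), `freq_A`, `freq_B`, `n_A`, `n_B`.
#' @export
ascertain_diagnostic <- function(gm, sheet, min_panel_n = 3, max_alt_freq = 0.05) {
  ids_A <- sheet$id[sheet$panel == "species_A"]
  ids_B <- sheet$id[sheet$panel == "species_B"]
  if (!length(ids_A) || !length(ids_B))
    stop("both species panels must be non-empty")
  gA <- gm$geno[match(ids_A, gm$samples), , drop = FALSE]
  gB <- gm$geno[match(ids_B, gm$samples), , drop = FALSE]
  nA <- colSums(!is.na(gA)); nB <- colSums(!is.na(gB))
  pA <- colMeans(gA, na.rm = TRUE) / 2
  pB <- colMeans(gB, na.rm = TRUE) / 2
  alt_marks_B <- pA <= max_alt_freq & pB >= 1 - max_alt_freq
  alt_marks_A <- pB <= max_alt_freq & pA >= 1 - max_alt_freq
  keep <- nA >= min_panel_n & nB >= min_panel_n &
    !is.na(alt_marks_A) & !is.na(alt_marks_B) & (alt_marks_A | alt_marks_B)
  out <- data.frame(chrom = gm$sites$chrom[keep], pos = gm$sites$pos[keep],
                    alt_species = ifelse(alt_marks_B[keep], "B", "A"),
                    freq_A = pA[keep], freq_B = pB[keep],
                    n_A = nA[keep], n_B = nB[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("diagnostic_panel", class(out))
  out
}

# per-sample evidence class at each diagnostic site: MM / MP / PP / NA
classify_diag_sites <- function(g, alt_species) {
  cls <- rep(NA_character_, length(g))
  homA <- ifelse(alt_species == "A", 2L, 0L)
  cls[!is.na(g) & g == homA] <- "MM"
  cls[!is.na(g) & g == 1L] <- "MP"
  cls[!is.na(g) & g == (2L - homA)] <- "PP"
  cls
}

#' Paint each sample's genome into ancestry windows
#'
#' Classifies every diagnostic genotype as evidence for homozygous species-A
#' (`MM`), homozygous species-B (`PP`) or heterozygous (`MP`) ancestry, then
#' assigns each fixed-width window the class reaching at least
#' `state_threshold` of its classified sites. Windows with fewer than
#' `min_sites` classified calls are `unknown`.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [ascertain_diagnostic()] result.
#' @param window_bp window width in bp (non-overlapping).
#' @param min_sites minimum classified diagnostic calls per called window.
#' @param state_threshold majority-vote fraction required to call a state.
#' @param samples optional subset of sample ids to paint.
#' @return A `painting_track` data frame: `sample`, `chrom`, `start`, `end`,
#'   `state`, `n_sites`, `frac_MM`, `frac_MP`, `frac_PP`.
#' @export
paint_genome <- function(gm, panel, window_bp = 5e5, min_sites = 10,
                         state_threshold = 0.8, samples = NULL) {
  if (!nrow(panel)) stop("diagnostic panel is empty")
  stopifnot(window_bp > 0, state_threshold > 0.5)
  if (is.null(samples)) samples <- gm$samples
  key_gm <- paste(gm$sites$chrom, gm$sites$pos)
  site_idx <- match(paste(panel$chrom, panel$pos), key_gm)
  if (anyNA(site_idx)) stop("diagnostic panel contains sites absent from the genotype matrix")
  lens <- chrom_len(gm)
  # window skeleton shared by all samples
  skel <- do.call(rbind, lapply(chrom_order(gm), function(ch) {
    L <- lens[[ch]]
    starts <- seq(1, L, by = window_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_bp - 1, L), stringsAsFactors = FALSE)
  }))
  win_key <- paste(skel$chrom, skel$start)
  wid <- match(paste(panel$chrom,
                     ((panel$pos - 1) %/% window_bp) * window_bp + 1), win_key)
  states <- c("MM", "MP", "PP")
  tracks <- lapply(samples, function(id) {
    g <- gm$geno[match(id, gm$samples), site_idx]
    cls <- classify_diag_sites(g, panel$alt_species)
    counts <- matrix(0L, nrow(skel), 3, dimnames = list(NULL, states))
    ok <- !is.na(cls)
    if (any(ok)) {
      tab <- table(factor(wid[ok], levels = seq_len(nrow(skel))),
                   factor(cls[ok], levels = states))
      counts <- unclass(as.matrix(tab))
    }
    n <- rowSums(counts)
    frac <- counts / pmax(n, 1)
    best <- max.col(frac, ties.method = "first")
    state <- ifelse(n >= min_sites & frac[cbind(seq_len(nrow(skel)), best)] >= state_threshold,
                    states[best], "unknown")
    data.frame(sample = id, skel, state = state, n_sites = n,
               frac_MM = frac[, "MM"], frac_MP = frac[, "MP"],
               frac_PP = frac[, "PP"], stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, tracks)
  class(out) <- c("painting_track", class(out))
  out
}

#' Length-weighted painting agreement between two samples
#'
#' Proportion of genome length, over windows called (non-`unknown`) in both
#' tracks, where the two tracks carry the same state.
#'
#' @param track_x,track_y single-sample subsets of a [paint_genome()] result
#'   built on the same windowing.
#' @return A proportion in `[0, 1]`.
#' @export
painting_similarity <- function(track_x, track_y) {
  if (nrow(track_x) != nrow(track_y) ||
      !all(track_x$chrom == track_y$chrom & track_x$start == track_y$start &
           track_x$end == track_y$end))
    stop("painting tracks must share the same windowing")
  both <- track_x$state != "unknown" & track_y$state != "unknown"
  if (!any(both)) return(NA_real_)
  w <- (track_x$end - track_x$start + 1)[both]
  sum(w * (track_x$state[both] == track_y$state[both])) / sum(w)
}

#' Length-weighted painting accuracy against simulator ground truth
#'
#' Compares called windows of a painting track with the generator's ancestry
#' blocks (`AA`/`AB`/`BB`, mapped to `MM`/`MP`/`PP`). For every called window
#' the matching truth length is accumulated by interval intersection.
#'
#' @param track a [paint_genome()] result (may hold several samples).
#' @param truth ancestry-truth data frame (`sample`, `chrom`, `start`, `end`,
#'   `state`) as produced by [simulate_cohort()].
#' @return Proportion of called window length painted with the true state.
#' @export
painting_accuracy <- function(track, truth) {
  map <- c(AA = "MM", AB = "MP", BB = "PP")
  truth$state <- map[truth$state]
  called <- track[track$state != "unknown", , drop = FALSE]
  if (!nrow(called)) return(NA_real_)
  total <- 0; matched <- 0
  for (id in unique(called$sample)) {
    tr <- called[called$sample == id, , drop = FALSE]
    tt <- truth[truth$sample == id, , drop = FALSE]
    for (ch in unique(tr$chrom)) {
      trc <- tr[tr$chrom == ch, , drop = FALSE]
      ttc <- tt[tt$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(trc))) {
        total <- total + trc$end[k] - trc$start[k] + 1
        ov <- pmin(ttc$end, trc$end[k]) - pmax(ttc$start, trc$start[k]) + 1
        hit <- ov > 0 & ttc$state == trc$state[k]
        if (any(hit)) matched <- matched + sum(ov[hit])
      }
    }
  }
  matched / total
}
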