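#' Founder model for the synthetic SNP data generator
#'
#' Describes two diverged founder gene pools ("species A", mandarin-like, and
#' "species B", pummelo-like) typed at a shared set of biallelic SNP sites.
#' A fraction of sites carries a fixed allelic difference between the pools
#' (alt frequency 0 in one species, 1 in the other); all remaining sites share
#' a single ancestral allele frequency drawn from a Beta distribution, so that
#' with `fixed_diff_fraction = 0` the two pools are exchangeable.
#'
#' @param n_chrom number of chromosomes (default 9, the citrus karyotype).
#' @param chrom_len_bp chromosome length in bp (recycled across chromosomes).
#' @param n_sites_per_chrom SNP sites per chromosome.
#' @param fixed_diff_fraction proportion of sites fixed-different between the
#'   two species pools, in `[0, 1]`.
#' @param maf_beta shape parameters `c(a, b)` of the Beta distribution of
#'   shared allele frequencies at non-fixed sites.
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (Poisson, no interference).
#' @param seed optional RNG seed recorded with the model.
#' @return A `founder_model` list.
#' @export
founder_model <- function(n_chrom = 9, chrom_len_bp = 3e7,
                          n_sites_per_chrom = 5556,
                          fixed_diff_fraction = 0.3,
                          maf_beta = c(0.5, 0.5),
                          recomb_rate = 1.5, seed = NULL) {
  if (n_chrom < 1 || n_sites_per_chrom < 1)
    stop("founder model needs at least one chromosome and one site per chromosome")
  if (fixed_diff_fraction < 0 || fixed_diff_fraction > 1)
    stop("fixed_diff_fraction must lie in [0, 1]")
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_len_bp = rep_len(as.numeric(chrom_len_bp), n_chrom),
                 n_sites_per_chrom = as.integer(n_sites_per_chrom),
                 fixed_diff_fraction = fixed_diff_fraction,
                 maf_beta = maf_beta,
                 recomb_rate = recomb_rate,
                 seed = seed),
            class = "founder_model")
}

#' Pedigree specification for the synthetic cohort
#'
#' Lays out the cohort the generator emits: two pure reference panels, a set
#' of admixed candidate-parent cultivars (species-A background with spliced-in
#' species-B blocks), the designated seed and pollen parent among them, one F1
#' offspring, a clone group derived from that F1 by somatic mutation, and
#' unrelated admixed distractor cultivars. Defaults are desk-scale stand-ins
#' for the kind of cohort used in citrus parentage studies: pure panels of
#' 20, 20 candidate cultivars, a clone group of 5.
#'
#' @param n_pure_A,n_pure_B pure panel sizes (>= 1).
#' @param candidate_admix named numeric vector: introgressed-genome fraction
#'   per candidate cultivar. Names become sample ids.
#' @param seed_parent,pollen_parent ids (among candidates) of the true parents.
#' @param offspring_id id of the F1 offspring.
#' @param clone_group_size number of clones derived from the F1 (>= 0).
#' @param somatic_rate per-site somatic mutation rate per clone.
#' @param distractor_admix named numeric vector of introgression fractions for
#'   unrelated distractor cultivars.
#' @param error_rate,missing_rate genotype error and missingness applied to
#'   the emitted nuclear matrix (`error_rate + missing_rate < 1`).
#' @param block_mean_bp mean length of introgressed species-B blocks.
#' @param cp_n_sites,cp_mut_rate chloroplast sites and per-site mutation rate
#'   per maternal transmission.
#' @return A `pedigree_spec` list.
#' @export
pedigree_spec <- function(n_pure_A = 20, n_pure_B = 20,
                          candidate_admix = NULL,
                          seed_parent = "cand01", pollen_parent = "cand02",
                          offspring_id = "satsuma",
                          clone_group_size = 5, somatic_rate = 1e-4,
                          distractor_admix = NULL,
                          error_rate = 0.005, missing_rate = 0.02,
                          block_mean_bp = 5e6,
                          cp_n_sites = 200, cp_mut_rate = 0.001) {
  if (is.null(candidate_admix)) {
    candidate_admix <- c(0, 0.10, rep_len(c(0, 0.05, 0.10, 0.15, 0.20), 18))
    names(candidate_admix) <- sprintf("cand%02d", seq_along(candidate_admix))
  }
  if (is.null(distractor_admix)) {
    distractor_admix <- rep_len(c(0.05, 0.15), 5)
    names(distractor_admix) <- sprintf("dist%02d", seq_along(distractor_admix))
  }
  if (!all(c(seed_parent, pollen_parent) %in% names(candidate_admix)))
    stop("seed and pollen parent must be candidate cultivars")
  if (seed_parent == pollen_parent)
    stop("seed parent and pollen parent must differ")
  if (error_rate < 0 || missing_rate < 0 || error_rate + missing_rate >= 1)
    stop("error_rate + missing_rate must lie in [0, 1)")
  structure(list(n_pure_A = n_pure_A, n_pure_B = n_pure_B,
                 candidate_admix = candidate_admix,
                 seed_parent = seed_parent, pollen_parent = pollen_parent,
                 offspring_id = offspring_id,
                 clone_group_size = clone_group_size,
                 somatic_rate = somatic_rate,
                 distractor_admix = distractor_admix,
                 error_rate = error_rate, missing_rate = missing_rate,
                 block_mean_bp = block_mean_bp,
                 cp_n_sites = cp_n_sites, cp_mut_rate = cp_mut_rate),
            class = "pedigree_spec")
}

# ---- internal: sites and frequencies --------------------------------------

sim_sites <- function(model) {
  m_chr <- model$n_sites_per_chrom
  chroms <- sprintf("chr%d", seq_len(model$n_chrom))
  site_list <- lapply(seq_len(model$n_chrom), function(i) {
    pos <- sort(sample.int(model$chrom_len_bp[i] - 1L, m_chr))
    data.frame(chrom = chroms[i], pos = pos, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  m <- nrow(sites)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  sites$ref <- ref
  sites$alt <- unname(alt)
  n_fixed <- round(model$fixed_diff_fraction * m)
  fixed <- rep(FALSE, m)
  fixed[sample.int(m, n_fixed)] <- TRUE
  p_shared <- stats::rbeta(m, model$maf_beta[1], model$maf_beta[2])
  freq_A <- p_shared
  freq_B <- p_shared
  # fixed differences: alt allele fixed in one species, absent in the other
  alt_in_B <- stats::runif(m) < 0.5
  freq_A[fixed] <- ifelse(alt_in_B[fixed], 0, 1)
  freq_B[fixed] <- ifelse(alt_in_B[fixed], 1, 0)
  lens <- stats::setNames(model$chrom_len_bp, chroms)
  list(sites = sites, chrom_lengths = lens,
       freq_A = freq_A, freq_B = freq_B, fixed = fixed)
}

# ---- internal: haplotypes with ancestry tracks ----------------------------
# A haplotype is list(al = 0/1 integer vector over all sites,
#                     anc = data.frame(chrom, start, end, species)) where the
# ancestry blocks tile each chromosome in 1-based closed coordinates.

whole_genome_blocks <- function(chrom_lengths, species) {
  data.frame(chrom = names(chrom_lengths), start = 1,
             end = unname(chrom_lengths), species = species,
             stringsAsFactors = FALSE)
}

draw_pure_hap <- function(fnd, species) {
  f <- if (species == "A") fnd$freq_A else fnd$freq_B
  list(al = as.integer(stats::runif(length(f)) < f),
       anc = whole_genome_blocks(fnd$chrom_lengths, species))
}

# alternating-renewal segmentation: species-B blocks (mean block_mean_bp)
# spliced into a species-A background so that ~frac of length is B
draw_admixed_hap <- function(fnd, frac, block_mean_bp) {
  if (frac <= 0) return(draw_pure_hap(fnd, "A"))
  mean_B <- block_mean_bp
  mean_A <- block_mean_bp * (1 - frac) / frac
  blocks <- lapply(names(fnd$chrom_lengths), function(ch) {
    L <- fnd$chrom_lengths[[ch]]
    pos <- 0
    st <- character(0); s0 <- numeric(0); e0 <- numeric(0)
    state <- if (stats::runif(1) < frac) "B" else "A"
    while (pos < L) {
      len <- max(1, round(stats::rexp(1, 1 / if (state == "B") mean_B else mean_A)))
      s0 <- c(s0, pos + 1); e0 <- c(e0, min(pos + len, L)); st <- c(st, state)
      pos <- pos + len
      state <- if (state == "A") "B" else "A"
    }
    data.frame(chrom = ch, start = s0, end = e0, species = st,
               stringsAsFactors = FALSE)
  })
  anc <- do.call(rbind, blocks)
  sp <- species_at_sites(anc, fnd$sites)
  f <- ifelse(sp == "B", fnd$freq_B, fnd$freq_A)
  list(al = as.integer(stats::runif(length(f)) < f), anc = anc)
}

# species label of each site given a haplotype ancestry track
species_at_sites <- function(anc, sites) {
  out <- character(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- sites$chrom == ch
    b <- anc[anc$chrom == ch, , drop = FALSE]
    out[i] <- b$species[findInterval(sites$pos[i], b$start)]
  }
  out
}

merge_adjacent_blocks <- function(df, label = "species") {
  if (nrow(df) <= 1) return(df)
  keep <- rep(TRUE, nrow(df))
  for (k in 2:nrow(df)) {
    if (df$chrom[k] == df$chrom[k - 1] && df[[label]][k] == df[[label]][k - 1] &&
        df$start[k] == df$end[k - 1] + 1) {
      df$start[k] <- df$start[k - 1]
      keep[k - 1] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

clip_blocks <- function(anc_chr, s, e) {
  b <- anc_chr[anc_chr$end >= s & anc_chr$start <= e, , drop = FALSE]
  b$start <- pmax(b$start, s)
  b$end <- pmin(b$end, e)
  b
}

# one recombinant gamete: Poisson crossover count, uniform breakpoints
draw_gamete <- function(ind, recomb_rate, sites, chrom_lengths) {
  m <- nrow(sites)
  al <- integer(m)
  anc_parts <- list()
  src_parts <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    i <- which(sites$chrom == ch)
    k <- stats::rpois(1, recomb_rate)
    bp <- if (k > 0) sort(sample.int(max(L - 1, 1), min(k, L - 1))) else integer(0)
    cuts <- c(0, bp, L)
    cur <- sample(1:2, 1)
    a1 <- ind$anc1[ind$anc1$chrom == ch, , drop = FALSE]
    a2 <- ind$anc2[ind$anc2$chrom == ch, , drop = FALSE]
    for (s in seq_len(length(cuts) - 1)) {
      lo <- cuts[s] + 1; hi <- cuts[s + 1]
      if (hi < lo) { cur <- 3 - cur; next }
      ii <- i[sites$pos[i] >= lo & sites$pos[i] <= hi]
      al[ii] <- if (cur == 1) ind$a1[ii] else ind$a2[ii]
      anc_parts[[length(anc_parts) + 1]] <-
        clip_blocks(if (cur == 1) a1 else a2, lo, hi)
      src_parts[[length(src_parts) + 1]] <-
        data.frame(chrom = ch, start = lo, end = hi, hap = cur,
                   stringsAsFactors = FALSE)
      cur <- 3 - cur
    }
  }
  list(al = al,
       anc = merge_adjacent_blocks(do.call(rbind, anc_parts)),
       source = merge_adjacent_blocks(do.call(rbind, src_parts), "hap"))
}

# genotype-level ancestry states (AA / AB / BB) from the two haplotype tracks
genotype_anc_blocks <- function(anc1, anc2, chrom_lengths) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    b1 <- anc1[anc1$chrom == ch, , drop = FALSE]
    b2 <- anc2[anc2$chrom == ch, , drop = FALSE]
    cuts <- sort(unique(c(1, b1$start, b2$start, L + 1)))
    s0 <- cuts[-length(cuts)]
    e0 <- cuts[-1] - 1
    sp1 <- b1$species[findInterval(s0, b1$start)]
    sp2 <- b2$species[findInterval(s0, b2$start)]
    state <- ifelse(sp1 == sp2, ifelse(sp1 == "A", "AA", "BB"), "AB")
    out[[ch]] <- data.frame(chrom = ch, start = s0, end = e0, state = state,
                            stringsAsFactors = FALSE)
  }
  merge_adjacent_blocks(do.call(rbind, out), "state")
}

new_ind <- function(id, h1, h2) {
  list(id = id, a1 = h1$al, a2 = h2$al, anc1 = h1$anc, anc2 = h2$anc)
}

# ---- exported simulator operations ----------------------------------------

#' Simulate pure founder panels from a two-species model
#'
#' Draws `n_A` samples from the species-A allele-frequency pool and `n_B`
#' from species B, phased, with per-site metadata. Exactly
#' `round(fixed_diff_fraction * n_sites)` sites are fixed-different between
#' the pools.
#'
#' @param model a [founder_model()].
#' @param n_A,n_B panel sizes (>= 1).
#' @param seed optional RNG seed (falls back to `model$seed`).
#' @return A list with `gm` (phased [genotype_matrix()]), `freq_A`, `freq_B`
#'   (true alt-allele frequencies), and `fixed` (logical fixed-difference
#'   indicator per site).
#' @export
simulate_founders <- function(model, n_A, n_B, seed = NULL) {
  stopifnot(n_A >= 1, n_B >= 1)
  seed <- if (is.null(seed)) model$seed else seed
  if (!is.null(seed)) set.seed(seed)
  fnd <- sim_sites(model)
  ids <- c(sprintf("A%02d", seq_len(n_A)), sprintf("B%02d", seq_len(n_B)))
  sp <- rep(c("A", "B"), c(n_A, n_B))
  m <- nrow(fnd$sites)
  h1 <- h2 <- matrix(0L, length(ids), m)
  for (k in seq_along(ids)) {
    h1[k, ] <- draw_pure_hap(fnd, sp[k])$al
    h2[k, ] <- draw_pure_hap(fnd, sp[k])$al
  }
  gm <- genotype_matrix(ids, fnd$sites, h1 + h2, h1, h2, fnd$chrom_lengths)
  list(gm = gm, freq_A = fnd$freq_A, freq_B = fnd$freq_B, fixed = fnd$fixed,
       panel = stats::setNames(ifelse(sp == "A", "species_A", "species_B"), ids))
}

#' Cross two simulated parents into an F1 offspring
#'
#' Each parent contributes one recombinant gamete; crossover counts per
#' chromosome are Poisson(`recomb_rate`) with uniform breakpoint placement
#' and no interference. Ground-truth gamete source blocks and the offspring's
#' ancestry blocks are returned alongside the genome.
#'
#' @param parent1,parent2 simulated individuals (as produced internally by
#'   [simulate_cohort()]; each carries two haplotypes with ancestry tracks).
#' @param recomb_rate expected crossovers per chromosome.
#' @param sites,chrom_lengths site table and chromosome lengths shared by the
#'   parents.
#' @param offspring_id id for the offspring.
#' @param seed optional RNG seed.
#' @return List with `offspring` (individual), `gametes` (source-block truth
#'   per parent).
#' @export
cross <- function(parent1, parent2, recomb_rate, sites, chrom_lengths,
                  offspring_id = "offspring", seed = NULL) {
  if (length(parent1$a1) != length(parent2$a1))
    stop("parents must share the same site table")
  if (!is.null(seed)) set.seed(seed)
  g1 <- draw_gamete(parent1, recomb_rate, sites, chrom_lengths)
  g2 <- draw_gamete(parent2, recomb_rate, sites, chrom_lengths)
  off <- list(id = offspring_id, a1 = g1$al, a2 = g2$al,
              anc1 = g1$anc, anc2 = g2$anc)
  g1$source$parent <- parent1$id
  g2$source$parent <- parent2$id
  list(offspring = off, gametes = rbind(g1$source, g2$source))
}

#' Derive a clone group from one founder individual by somatic mutation
#'
#' Each clone differs from the founder at ~Poisson(`somatic_rate` * n_sites)
#' sites; a mutation flips one allele of one haplotype, so every mutation
#' changes the genotype dosage by one. Ancestry tracks are inherited
#' unchanged.
#'
#' @param founder a simulated individual.
#' @param group_size number of clones (>= 1).
#' @param somatic_rate per-site mutation rate per clone.
#' @param seed optional RNG seed.
#' @return List with `clones` (list of individuals, ids `<founder>_cl<k>`)
#'   and `lineage` (data frame: clone, founder, n_mutations).
#' @export
clone_lineage <- function(founder, group_size, somatic_rate, seed = NULL) {
  stopifnot(group_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- length(founder$a1)
  clones <- vector("list", group_size)
  nmut <- integer(group_size)
  for (k in seq_len(group_size)) {
    cl <- founder
    cl$id <- sprintf("%s_cl%d", founder$id, k)
    n <- min(stats::rpois(1, somatic_rate * m), m)
    if (n > 0) {
      at <- sample.int(m, n)
      which_hap <- stats::runif(n) < 0.5
      i1 <- at[which_hap]; i2 <- at[!which_hap]
      cl$a1[i1] <- 1L - cl$a1[i1]
      cl$a2[i2] <- 1L - cl$a2[i2]
    }
    nmut[k] <- n
    clones[[k]] <- cl
  }
  list(clones = clones,
       lineage = data.frame(clone = vapply(clones, `[[`, "", "id"),
                            founder = founder$id, n_mutations = nmut,
                            stringsAsFactors = FALSE))
}

#' Apply genotyping error and missingness to a genotype matrix
#'
#' Each genotype is independently flipped to a uniformly chosen different
#' code with probability `error_rate`, and set missing with probability
#' `missing_rate` (missingness wins when both fire). If the matrix is phased,
#' haplotypes at altered sites are re-synced to a canonical phase so the
#' phasing invariant is preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param error_rate,missing_rate probabilities with
#'   `error_rate + missing_rate <= 1`.
#' @param seed optional RNG seed.
#' @return A corrupted `genotype_matrix`.
#' @export
corrupt <- function(gm, error_rate, missing_rate, seed = NULL) {
  if (error_rate < 0 || missing_rate < 0 || error_rate + missing_rate > 1)
    stop("error_rate + missing_rate must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- gm$geno
  n <- length(g)
  u <- stats::runif(n)
  flip <- which(u < error_rate & !is.na(g))
  if (length(flip)) {
    # uniformly one of the two other codes
    shift <- 1L + (stats::runif(length(flip)) < 0.5)
    g[flip] <- (g[flip] + shift) %% 3L
  }
  drop <- which(u >= error_rate & u < error_rate + missing_rate)
  if (length(drop)) g[drop] <- NA_integer_
  h1 <- gm$hap1; h2 <- gm$hap2
  if (!is.null(h1)) {
    changed <- union(flip, drop)
    h1[changed] <- ifelse(is.na(g[changed]), NA_integer_,
                          as.integer(g[changed] == 2L))
    h2[changed] <- ifelse(is.na(g[changed]), NA_integer_,
                          as.integer(g[changed] >= 1L))
  }
  genotype_matrix(gm$samples, gm$sites, g, h1, h2, gm$chrom_lengths)
}

#' Simulate maternally inherited chloroplast haplotypes over a pedigree
#'
#' Every pedigree founder (row with `NA` mother) receives an independent
#' random chloroplast haplotype; every non-founder inherits its mother's
#' haplotype plus Poisson(`cp_mut_rate` * `cp_n_sites`) mutations. Transmission
#' is resolved in topological order; a cyclic pedigree is an error.
#'
#' @param pedigree data frame with columns `sample` and `mother` (`NA` for
#'   founders).
#' @param cp_n_sites number of chloroplast SNP sites.
#' @param cp_mut_rate per-site mutation rate per transmission.
#' @param founder_af alt-allele frequency for founder haplotypes.
#' @param seed optional RNG seed.
#' @return A haploid [genotype_matrix()] on chromosome `"cp"`; haploid calls
#'   are folded to homozygous dosages (ref = 0, alt = 2), the usual VCF
#'   convention for haploid GT fields.
#' @export
simulate_cp <- function(pedigree, cp_n_sites = 200, cp_mut_rate = 0.001,
                        founder_af = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("sample", "mother") %in% names(pedigree)))
  if (any(!is.na(pedigree$mother) & !(pedigree$mother %in% pedigree$sample)))
    stop("every non-founder's mother must be in the pedigree")
  pos <- sort(sample.int(160000L, cp_n_sites))
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, cp_n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  sites <- data.frame(chrom = "cp", pos = pos, ref = ref, alt = unname(alt),
                      stringsAsFactors = FALSE)
  hap <- matrix(NA_integer_, nrow(pedigree), cp_n_sites,
                dimnames = list(pedigree$sample, NULL))
  done <- rep(FALSE, nrow(pedigree))
  for (pass in seq_len(nrow(pedigree) + 1)) {
    todo <- which(!done)
    if (!length(todo)) break
    progressed <- FALSE
    for (k in todo) {
      mom <- pedigree$mother[k]
      if (is.na(mom)) {
        hap[k, ] <- as.integer(stats::runif(cp_n_sites) < founder_af)
      } else {
        mk <- match(mom, pedigree$sample)
        if (!done[mk]) next
        h <- hap[mk, ]
        n <- min(stats::rpois(1, cp_mut_rate * cp_n_sites), cp_n_sites)
        if (n > 0) { at <- sample.int(cp_n_sites, n); h[at] <- 1L - h[at] }
        hap[k, ] <- h
      }
      done[k] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) stop("cyclic pedigree: chloroplast transmission cannot be resolved")
  }
  genotype_matrix(pedigree$sample, sites, 2L * hap,
                  chrom_lengths = c(cp = 160000))
}

#' Simulate a complete synthetic citrus-style cohort with ground truth
#'
#' End-to-end generator: pure species panels, admixed candidate cultivars,
#' the designated seed x pollen cross producing one F1, a clone group derived
#' from the F1 by somatic mutation, unrelated distractors, genotyping
#' error/missingness, and maternally inherited chloroplast haplotypes.
#'
#' @param model a [founder_model()].
#' @param ped a [pedigree_spec()].
#' @param seed RNG seed for the whole run (falls back to `model$seed`).
#' @return A list with components `gm` (phased, corrupted nuclear
#'   [genotype_matrix()]), `gm_clean` (pre-corruption matrix), `cp` (haploid
#'   chloroplast matrix), `sheet` (sample sheet: id, panel, role), `truth`
#'   (list: `pedigree`, `ancestry`, `clones`, `cp_maternal`, `gametes`),
#'   `freq` (true founder allele frequencies and fixed-difference flags), and
#'   `params` (the inputs, for the manifest).
#' @export
simulate_cohort <- function(model = founder_model(), ped = pedigree_spec(),
                            seed = NULL) {
  seed <- if (is.null(seed)) model$seed else seed
  if (!is.null(seed)) set.seed(seed)
  fnd <- sim_sites(model)
  m <- nrow(fnd$sites)

  inds <- list()
  panel <- character(0); role <- character(0)
  add <- function(ind, pan, rol) {
    inds[[ind$id]] <<- ind
    panel[ind$id] <<- pan
    role[ind$id] <<- rol
  }
  for (k in seq_len(ped$n_pure_A))
    add(new_ind(sprintf("A%02d", k), draw_pure_hap(fnd, "A"),
                draw_pure_hap(fnd, "A")), "species_A", "panel")
  for (k in seq_len(ped$n_pure_B))
    add(new_ind(sprintf("B%02d", k), draw_pure_hap(fnd, "B"),
                draw_pure_hap(fnd, "B")), "species_B", "panel")
  for (id in names(ped$candidate_admix))
    add(new_ind(id, draw_admixed_hap(fnd, ped$candidate_admix[[id]], ped$block_mean_bp),
                draw_admixed_hap(fnd, ped$candidate_admix[[id]], ped$block_mean_bp)),
        "none", "candidate_parent")
  for (id in names(ped$distractor_admix))
    add(new_ind(id, draw_admixed_hap(fnd, ped$distractor_admix[[id]], ped$block_mean_bp),
                draw_admixed_hap(fnd, ped$distractor_admix[[id]], ped$block_mean_bp)),
        "none", "distractor")

  cr <- cross(inds[[ped$seed_parent]], inds[[ped$pollen_parent]],
              model$recomb_rate, fnd$sites, fnd$chrom_lengths,
              offspring_id = ped$offspring_id)
  add(cr$offspring, "none", "query")
  clone_truth <- NULL
  if (ped$clone_group_size > 0) {
    cl <- clone_lineage(cr$offspring, ped$clone_group_size, ped$somatic_rate)
    for (c_ind in cl$clones)
      add(c_ind, "none", paste0("clone_group:", ped$offspring_id))
    clone_truth <- cl$lineage
  }

  ids <- names(inds)
  h1 <- t(vapply(inds, function(x) x$a1, integer(m)))
  h2 <- t(vapply(inds, function(x) x$a2, integer(m)))
  gm_clean <- genotype_matrix(ids, fnd$sites, h1 + h2, h1, h2, fnd$chrom_lengths)
  gm <- corrupt(gm_clean, ped$error_rate, ped$missing_rate)

  anc <- do.call(rbind, lapply(ids, function(id) {
    b <- genotype_anc_blocks(inds[[id]]$anc1, inds[[id]]$anc2, fnd$chrom_lengths)
    cbind(sample = id, b)
  }))

  ped_truth <- data.frame(offspring = ped$offspring_id,
                          seed_parent = ped$seed_parent,
                          pollen_parent = ped$pollen_parent,
                          stringsAsFactors = FALSE)
  mothers <- stats::setNames(rep(NA_character_, length(ids)), ids)
  mothers[ped$offspring_id] <- ped$seed_parent
  if (!is.null(clone_truth)) mothers[clone_truth$clone] <- ped$offspring_id
  cp_ped <- data.frame(sample = ids, mother = unname(mothers[ids]),
                       stringsAsFactors = FALSE)
  cp <- simulate_cp(cp_ped, ped$cp_n_sites, ped$cp_mut_rate)

  sheet <- data.frame(id = ids, panel = unname(panel[ids]),
                      role = unname(role[ids]), stringsAsFactors = FALSE)
  list(gm = gm, gm_clean = gm_clean, cp = cp, sheet = sheet,
       truth = list(pedigree = ped_truth, ancestry = anc,
                    clones = clone_truth, cp_maternal = cp_ped,
                    gametes = cr$gametes),
       freq = list(A = fnd$freq_A, B = fnd$freq_B, fixed = fnd$fixed),
       params = list(model = model, ped = ped, seed = seed))
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits `nuclear.vcf.gz` and `cp.vcf.gz` (VCF 4.2, GT only), `samples.tsv`,
#' and the ground-truth files `truth_pedigree.tsv`, `truth_ancestry.bed`
#' (0-based half-open), `truth_clones.tsv`, `truth_cp_maternal.tsv`.
#'
#' @param sim output of [simulate_cohort()].
#' @param outdir output directory (created if absent).
#' @return Invisibly, the vector of paths written.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(nuclear = file.path(outdir, "nuclear.vcf.gz"),
             cp = file.path(outdir, "cp.vcf.gz"),
             samples = file.path(outdir, "samples.tsv"),
             pedigree = file.path(outdir, "truth_pedigree.tsv"),
             ancestry = file.path(outdir, "truth_ancestry.bed"),
             clones = file.path(outdir, "truth_clones.tsv"),
             cp_maternal = file.path(outdir, "truth_cp_maternal.tsv"))
  write_vcf(sim$gm, paths["nuclear"])
  write_vcf(sim$cp, paths["cp"], haploid = TRUE)
  utils::write.table(sim$sheet, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$pedigree, paths["pedigree"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = sim$truth$ancestry$chrom,
                    start = sim$truth$ancestry$start - 1,
                    end = sim$truth$ancestry$end,
                    sample = sim$truth$ancestry$sample,
                    state = sim$truth$ancestry$state)
  utils::write.table(bed, paths["ancestry"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(sim$truth$clones))
    utils::write.table(sim$truth$clones, paths["clones"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$cp_maternal, paths["cp_maternal"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
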