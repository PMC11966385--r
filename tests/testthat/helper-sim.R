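# shared fixtures, built once per test run and cached

.sim_cache <- new.env(parent = emptyenv())

# mid-size cohort with the default error model (13.5k sites)
sim_med <- function() {
  if (!exists("med", .sim_cache)) {
    assign("med", simulate_cohort(founder_model(n_sites_per_chrom = 1500),
                                  pedigree_spec(), seed = 101),
           .sim_cache)
  }
  get("med", .sim_cache)
}

# error-free, fully called, mutation-free chloroplast transmission
sim_clean <- function() {
  if (!exists("clean", .sim_cache)) {
    assign("clean",
           simulate_cohort(founder_model(n_sites_per_chrom = 1500),
                           pedigree_spec(error_rate = 0, missing_rate = 0,
                                         cp_mut_rate = 0),
                           seed = 202),
           .sim_cache)
  }
  get("clean", .sim_cache)
}

# denser sites for window-level painting checks (27k sites)
sim_paint <- function() {
  if (!exists("paint", .sim_cache)) {
    assign("paint", simulate_cohort(founder_model(n_sites_per_chrom = 3000),
                                    pedigree_spec(), seed = 303),
           .sim_cache)
  }
  get("paint", .sim_cache)
}

mandarin_cohort <- function(sim) sim$sheet$id[sim$sheet$panel == "none"]
# reference-panel allele frequencies (IBD expectations need a homogeneous pool)
panel_freq <- function(sim)
  allele_freq(sim$gm, sim$sheet$id[sim$sheet$panel == "species_A"])
clone_ids <- function(sim) sim$sheet$id[startsWith(sim$sheet$role, "clone_group:")]
candidate_ids <- function(sim) sim$sheet$id[sim$sheet$role == "candidate_parent"]

# single-sample view of a painting track
track_of <- function(track, id) {
  tr <- track[track$sample == id, , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

# build a simulator-style individual from rows of a phased genotype matrix,
# with a whole-genome single-species ancestry track
ind_from_gm <- function(gm, id, species = "A") {
  i <- match(id, gm$samples)
  blocks <- data.frame(chrom = names(hybriseek:::chrom_len(gm)), start = 1,
                       end = unname(hybriseek:::chrom_len(gm)),
                       species = species, stringsAsFactors = FALSE)
  list(id = id, a1 = gm$hap1[i, ], a2 = gm$hap2[i, ],
       anc1 = blocks, anc2 = blocks)
}

# append one phased individual to a genotype matrix
gm_append <- function(gm, id, a1, a2) {
  genotype_matrix(c(gm$samples, id), gm$sites,
                  rbind(gm$geno, a1 + a2),
                  rbind(gm$hap1, a1), rbind(gm$hap2, a2),
                  gm$chrom_lengths)
}

# exhaustive gamete-enumeration oracle for trio compatibility
mendel_oracle <- function(go, ga, gb) {
  gam <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  possible <- outer(gam[[as.character(ga)]], gam[[as.character(gb)]], "+")
  go %in% possible
}

# tiny phased matrix on one or more chromosomes, built from explicit
# haplotype rows: hap list entries are (hap1, hap2) per sample
tiny_phased <- function(haps, n_chrom = 1, sites_per_chrom = NULL) {
  m <- length(haps[[1]][[1]])
  if (is.null(sites_per_chrom)) sites_per_chrom <- m / n_chrom
  sites <- data.frame(
    chrom = rep(sprintf("chr%d", seq_len(n_chrom)), each = sites_per_chrom),
    pos = rep(seq_len(sites_per_chrom) * 100, n_chrom),
    ref = "A", alt = "T")
  h1 <- do.call(rbind, lapply(haps, `[[`, 1))
  h2 <- do.call(rbind, lapply(haps, `[[`, 2))
  lens <- stats::setNames(rep(sites_per_chrom * 100 + 50, n_chrom),
                          unique(sites$chrom))
  genotype_matrix(names(haps), sites, h1 + h2, h1, h2, lens)
}

# exhaustive minimal copying cost over all donor-haplotype paths
brute_force_cost <- function(local, switch_cost) {
  ns <- nrow(local); m <- ncol(local)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), m)))
  site_cost <- matrix(local[cbind(as.vector(paths),
                                  rep(seq_len(m), each = nrow(paths)))],
                      nrow(paths), m)
  switches <- rowSums(paths[, -1, drop = FALSE] != paths[, -m, drop = FALSE])
  min(rowSums(site_cost) + switch_cost * switches)
}

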