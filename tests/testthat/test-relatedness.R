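test_that("IBD recovers canonical relationships on clean data", {
  sim <- sim_clean()
  gm <- sim$gm
  f <- panel_freq(sim)

  self <- ibd_moments(gm, c("cand05", "cand05"), freq = f)
  expect_equal(self$Z2, 1)
  expect_equal(self$PI_HAT, 1)

  po <- ibd_moments(gm, c("satsuma", "cand01"), freq = f)
  expect_equal(po$n_ibs0, 0L)          # no opposing homozygotes at zero error
  expect_gt(po$Z1, 0.95)
  expect_lt(po$Z0, 0.05)

  unrel <- ibd_moments(gm, c("dist01", "dist02"), freq = f)
  expect_lt(unrel$PI_HAT, 0.05)

  cl <- ibd_moments(gm, c("satsuma_cl1", "satsuma_cl2"), freq = f)
  expect_gte(cl$PI_HAT, 0.99)
})

test_that("IBS counts match a naive per-site oracle", {
  sim <- sim_clean()
  gm <- subset_sites(sim$gm, seq_len(800))
  f <- panel_freq(sim)[seq_len(800)]
  r <- ibd_moments(gm, c("cand03", "cand07"), freq = f)
  gx <- gm$geno["cand03", ]; gy <- gm$geno["cand07", ]
  ibs_map <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)  # IBS by (gx, gy)
  counts <- c(0L, 0L, 0L)
  for (s in seq_len(n_sites(gm))) {
    if (is.na(gx[s]) || is.na(gy[s]) || f[s] <= 0 || f[s] >= 1) next
    ibs <- ibs_map[gx[s] + 1, gy[s] + 1]
    counts[ibs + 1] <- counts[ibs + 1] + 1L
  }
  expect_identical(c(r$n_ibs0, r$n_ibs1, r$n_ibs2), counts)
  expect_identical(r$n, sum(counts))
})

test_that("full sibs match realized sharing and the pedigree expectation", {
  # a single sib pair's realized IBD fluctuates widely with only nine
  # chromosomes, so the estimator is checked per pair against the realized
  # (haplotype-tagged) sharing, and against (0.25, 0.5, 0.25) on the mean
  # over independent sib pairs
  f <- simulate_founders(founder_model(n_sites_per_chrom = 5556), 20, 2,
                         seed = 31)
  lens <- f$gm$chrom_lengths
  m <- n_sites(f$gm)
  freq <- allele_freq(f$gm, sprintf("A%02d", 1:20))
  zs <- matrix(NA_real_, 8, 3)
  for (k in 1:8) {
    p1 <- ind_from_gm(f$gm, sprintf("A%02d", 2 * k - 1))
    p2 <- ind_from_gm(f$gm, sprintf("A%02d", 2 * k))
    p1t <- p1; p1t$a1 <- rep(1L, m); p1t$a2 <- rep(2L, m)
    p2t <- p2; p2t$a1 <- rep(3L, m); p2t$a2 <- rep(4L, m)
    set.seed(100 + k)
    s1 <- cross(p1, p2, 1.5, f$gm$sites, lens)$offspring
    s2 <- cross(p1, p2, 1.5, f$gm$sites, lens)$offspring
    set.seed(100 + k)   # identical meioses on the tagged copies
    t1 <- cross(p1t, p2t, 1.5, f$gm$sites, lens)$offspring
    t2 <- cross(p1t, p2t, 1.5, f$gm$sites, lens)$offspring
    shared <- (t1$a1 == t2$a1) + (t1$a2 == t2$a2)
    realized <- c(mean(shared == 0), mean(shared == 1), mean(shared == 2))
    gm <- gm_append(gm_append(f$gm, "s1", s1$a1, s1$a2), "s2", s2$a1, s2$a2)
    r <- ibd_moments(gm, c("s1", "s2"), freq = freq)
    zs[k, ] <- c(r$Z0, r$Z1, r$Z2)
    expect_lt(max(abs(zs[k, ] - realized)), 0.06)
  }
  expect_lt(max(abs(colMeans(zs) - c(0.25, 0.5, 0.25))), 0.08)
})

test_that("IBD matrices are symmetric with unit self-sharing", {
  sim <- sim_clean()
  ids <- c("satsuma", "cand01", "cand02", "satsuma_cl1", "dist01")
  gm <- subset_samples(sim$gm, ids)
  M <- ibd_matrix(gm, freq = panel_freq(sim))
  for (nm in c("Z0", "Z1", "Z2", "PI_HAT"))
    expect_equal(M[[nm]], t(M[[nm]]))
  expect_equal(unname(diag(M$Z2)), rep(1, length(ids)))
  expect_gte(M$Z2["satsuma", "satsuma_cl1"], 0.98)   # clone pair
  expect_error(ibd_matrix(subset_samples(gm, "satsuma")))
})

test_that("PCA separates species and collapses the clone group", {
  sim <- sim_med()
  pc <- suppressMessages(pca_genotypes(sim$gm, k = 2))
  a <- pc$scores[sim$sheet$id[sim$sheet$panel == "species_A"], 1]
  b <- pc$scores[sim$sheet$id[sim$sheet$panel == "species_B"], 1]
  # panels separate on PC1 with no overlap
  expect_true(max(min(a), min(b)) > min(max(a), max(b)) ||
                min(a) > max(b) || min(b) > max(a))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1)

  # clone group collapses to a near-single point relative to panel spread
  cl <- pc$scores[clone_ids(sim), , drop = FALSE]
  spread_cl <- max(dist(cl))
  spread_all <- max(dist(pc$scores))
  expect_lt(spread_cl, 0.01 * spread_all)

  # duplicate sample lands on identical coordinates
  gm2 <- genotype_matrix(c(sim$gm$samples, "cand01_dup"), sim$gm$sites,
                         rbind(sim$gm$geno, sim$gm$geno["cand01", ]),
                         chrom_lengths = sim$gm$chrom_lengths)
  pc2 <- suppressMessages(pca_genotypes(gm2, k = 2))
  expect_equal(pc2$scores["cand01", ], pc2$scores["cand01_dup", ],
               ignore_attr = TRUE)
  expect_error(suppressMessages(pca_genotypes(sim$gm, k = n_samples(sim$gm))))
})
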