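small_model <- function(n_sites_per_chrom = 200, ...)
  founder_model(n_sites_per_chrom = n_sites_per_chrom, ...)

test_that("simulation is deterministic given a seed", {
  ped <- pedigree_spec(n_pure_A = 3, n_pure_B = 3, clone_group_size = 2)
  s1 <- simulate_cohort(small_model(), ped, seed = 9)
  s2 <- simulate_cohort(small_model(), ped, seed = 9)
  expect_identical(s1$gm$geno, s2$gm$geno)
  expect_identical(s1$gm$hap1, s2$gm$hap1)
  expect_identical(s1$cp$geno, s2$cp$geno)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(small_model(), ped, seed = 10)
  expect_false(identical(s1$gm$geno, s3$gm$geno))
})

test_that("founder panels honor the fixed-difference fraction", {
  f1 <- simulate_founders(small_model(fixed_diff_fraction = 1), 4, 4, seed = 1)
  gA <- f1$gm$geno[1:4, ]; gB <- f1$gm$geno[5:8, ]
  # every site separates the species perfectly
  expect_true(all(abs(colMeans(gA) - colMeans(gB)) == 2))

  f3 <- simulate_founders(small_model(fixed_diff_fraction = 0.3), 6, 6, seed = 2)
  expect_equal(sum(f3$fixed), round(0.3 * n_sites(f3$gm)))
  # fixed sites separate the emitted panels perfectly (freq 0 vs 1)
  dAB <- abs(colMeans(f3$gm$geno[1:6, ]) - colMeans(f3$gm$geno[7:12, ]))
  expect_true(all(dAB[f3$fixed] == 2))

  # no fixed differences: the species labels are exchangeable, so the
  # between-species frequency contrast matches random same-size splits
  # (brute-force comparison on the emitted haplotypes)
  f0 <- simulate_founders(small_model(fixed_diff_fraction = 0,
                                      n_sites_per_chrom = 1000), 10, 10, seed = 3)
  g <- f0$gm$geno
  contrast <- function(rows) {
    mean(abs(colMeans(g[rows, , drop = FALSE]) -
             colMeans(g[setdiff(1:20, rows), , drop = FALSE])) / 2)
  }
  between <- contrast(1:10)
  set.seed(4)
  shuffled <- replicate(20, contrast(sample(20, 10)))
  # the species split is not an outlier among random splits
  expect_lt(between, max(shuffled) * 1.1)
  expect_gt(between, min(shuffled) * 0.9)
  expect_error(simulate_founders(small_model(), 0, 3))
})

test_that("crossing respects gamete structure and Mendelian inheritance", {
  f <- simulate_founders(small_model(), 4, 4, seed = 11)
  lens <- f$gm$chrom_lengths
  p1 <- ind_from_gm(f$gm, "A01")
  p2 <- ind_from_gm(f$gm, "A02")

  # no recombination: each offspring chromosome copies one intact haplotype
  off0 <- cross(p1, p2, recomb_rate = 0, f$gm$sites, lens, seed = 5)$offspring
  for (ch in unique(f$gm$sites$chrom)) {
    i <- which(f$gm$sites$chrom == ch)
    expect_true(identical(off0$a1[i], p1$a1[i]) || identical(off0$a1[i], p1$a2[i]))
    expect_true(identical(off0$a2[i], p2$a1[i]) || identical(off0$a2[i], p2$a2[i]))
  }

  # identical homozygous parents reproduce themselves exactly
  hom <- p1
  hom$a2 <- hom$a1
  off_h <- cross(hom, hom, recomb_rate = 2, f$gm$sites, lens, seed = 6)$offspring
  expect_identical(off_h$a1 + off_h$a2, hom$a1 + hom$a2)

  # per-site Mendelian consistency vs exhaustive gamete enumeration
  off <- cross(p1, p2, recomb_rate = 1.5, f$gm$sites, lens, seed = 7)$offspring
  go <- off$a1 + off$a2; ga <- p1$a1 + p1$a2; gb <- p2$a1 + p2$a2
  ok <- vapply(seq_along(go), function(s) mendel_oracle(go[s], ga[s], gb[s]),
               logical(1))
  expect_true(all(ok))
  expect_error(cross(p1, list(id = "x", a1 = 1:3, a2 = 1:3), 1, f$gm$sites, lens))
})

test_that("clone groups carry Poisson-scale somatic divergence", {
  f <- simulate_founders(founder_model(n_sites_per_chrom = 2000), 4, 4, seed = 21)
  founder <- ind_from_gm(f$gm, "A01")
  founder$id <- "fnd"
  m <- length(founder$a1)

  cl0 <- clone_lineage(founder, 3, somatic_rate = 0, seed = 1)
  for (cl in cl0$clones) {
    expect_identical(cl$a1, founder$a1)
    expect_identical(cl$a2, founder$a2)
  }

  rate <- 50 / m      # expected 50 mutations per clone
  cl <- clone_lineage(founder, 5, somatic_rate = rate, seed = 2)
  g0 <- founder$a1 + founder$a2
  for (k in 1:5) {
    d <- sum(cl$clones[[k]]$a1 + cl$clones[[k]]$a2 != g0)
    expect_equal(d, cl$lineage$n_mutations[k])
    expect_lt(abs(d - 50), 3 * sqrt(50))
  }
  # at default somatic rates, clone pairwise distance is a tiny fraction of
  # the unrelated-pair distance
  sim <- sim_clean()
  d_clone <- mean(sim$gm$geno["satsuma_cl1", ] != sim$gm$geno["satsuma_cl2", ])
  d_unrel <- mean(sim$gm$geno["dist01", ] != sim$gm$geno["dist02", ])
  expect_lt(d_clone, 0.01 * d_unrel)
})

test_that("corrupt applies calibrated error and missingness", {
  f <- simulate_founders(founder_model(n_sites_per_chrom = 2500), 5, 5, seed = 31)
  gm <- f$gm
  expect_identical(corrupt(gm, 0, 0)$geno, gm$geno)
  expect_true(all(is.na(corrupt(gm, 0, 1)$geno)))
  n <- length(gm$geno)   # 10 x 22500 > 1e5 genotypes
  cor1 <- corrupt(gm, 0.01, 0, seed = 4)
  flips <- sum(cor1$geno != gm$geno, na.rm = TRUE)
  expect_lt(abs(flips - 0.01 * n), 3 * sqrt(n * 0.01 * 0.99))
  # phasing invariant survives corruption
  expect_true(all(is.na(cor1$geno) | cor1$hap1 + cor1$hap2 == cor1$geno))
  expect_error(corrupt(gm, 0.6, 0.5))
})

test_that("chloroplast transmission is maternal", {
  ped <- data.frame(sample = c("mom", "dad", "kid", "other"),
                    mother = c(NA, NA, "mom", NA), stringsAsFactors = FALSE)
  cp0 <- simulate_cp(ped, cp_n_sites = 150, cp_mut_rate = 0, seed = 8)
  a <- cp0$geno / 2
  expect_identical(a["kid", ], a["mom", ])
  hd <- function(x, y) sum(x != y)
  # offspring strictly closer to seed parent whenever parental cp differ
  if (hd(a["mom", ], a["dad", ]) > 0)
    expect_lt(hd(a["kid", ], a["mom", ]), hd(a["kid", ], a["dad", ]))

  cp1 <- simulate_cp(ped, cp_n_sites = 150, cp_mut_rate = 0.005, seed = 9)
  b <- cp1$geno / 2
  expect_lt(hd(b["kid", ], b["mom", ]), hd(b["kid", ], b["other", ]))

  cyc <- data.frame(sample = c("x", "y"), mother = c("y", "x"))
  expect_error(simulate_cp(cyc, 50, 0), "cyclic")
  bad <- data.frame(sample = "x", mother = "ghost")
  expect_error(simulate_cp(bad, 50, 0))
})

test_that("ancestry truth tiles every chromosome without overlap", {
  sim <- sim_med()
  lens <- sim$gm$chrom_lengths
  anc <- sim$truth$ancestry
  for (id in sample(unique(anc$sample), 8)) {
    for (ch in names(lens)) {
      b <- anc[anc$sample == id & anc$chrom == ch, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      expect_equal(b$start[1], 1)
      expect_equal(b$end[nrow(b)], unname(lens[[ch]]))
      if (nrow(b) > 1)
        expect_true(all(b$start[-1] == b$end[-nrow(b)] + 1))
    }
  }
})

test_that("true trios are Mendelian-consistent at zero error", {
  sim <- sim_clean()
  go <- sim$gm$geno["satsuma", ]
  ga <- sim$gm$geno["cand01", ]
  gb <- sim$gm$geno["cand02", ]
  ok <- vapply(seq_along(go), function(s) mendel_oracle(go[s], ga[s], gb[s]),
               logical(1))
  expect_true(all(ok))
})

test_that("datasets round-trip through VCF on disk", {
  ped <- pedigree_spec(n_pure_A = 3, n_pure_B = 3, clone_group_size = 2)
  sim <- simulate_cohort(small_model(), ped, seed = 77)
  out <- withr::local_tempdir()
  paths <- write_dataset(sim, out)
  expect_true(all(file.exists(paths)))

  gm2 <- read_vcf(paths[["nuclear"]], read_sample_sheet(paths[["samples"]]))
  expect_identical(gm2$geno, sim$gm$geno)
  expect_identical(gm2$hap1, sim$gm$hap1)
  expect_equal(gm2$sites, sim$gm$sites, ignore_attr = TRUE)

  cp2 <- suppressMessages(read_vcf(paths[["cp"]]))
  expect_identical(cp2$geno, sim$cp$geno)

  # truth BED is 0-based half-open and tiles each chromosome
  bed <- utils::read.table(paths[["ancestry"]], sep = "\t",
                           col.names = c("chrom", "start", "end", "sample", "state"))
  one <- bed[bed$sample == sim$sheet$id[1] & bed$chrom == "chr1", ]
  one <- one[order(one$start), ]
  expect_equal(one$start[1], 0)
  expect_equal(one$end[nrow(one)], unname(sim$gm$chrom_lengths[["chr1"]]))
  if (nrow(one) > 1) expect_true(all(one$start[-1] == one$end[-nrow(one)]))
})
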