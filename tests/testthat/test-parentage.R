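test_that("mendelian_compatible equals gamete enumeration on all 27 triples", {
  grid <- expand.grid(go = 0:2, ga = 0:2, gb = 0:2)
  got <- mendelian_compatible(grid$go, grid$ga, grid$gb)
  want <- mapply(mendel_oracle, grid$go, grid$ga, grid$gb)
  expect_identical(got, unname(want))
  expect_true(mendelian_compatible(0L, 0L, 0L))
  expect_false(mendelian_compatible(2L, 0L, 0L))
})

test_that("a true error-free trio is fully coincident; impostors are not", {
  sim <- sim_clean()
  ts <- coincidence_probability(sim$gm, "satsuma", "cand01", "cand02",
                                informative_only = FALSE)
  expect_equal(ts$coincidence, 100.0)
  expect_equal(ts$dispersion, 0.0)
  ts_inf <- coincidence_probability(sim$gm, "satsuma", "cand01", "cand02")
  expect_equal(ts_inf$coincidence, 100.0)
  expect_lt(ts_inf$n_evaluated, ts$n_evaluated)   # het x het sites excluded

  # replacing the offspring with an unrelated distractor always scores lower
  for (d in c("dist01", "dist02", "dist03")) {
    imp <- coincidence_probability(sim$gm, d, "cand01", "cand02")
    expect_lt(imp$coincidence, ts_inf$coincidence)
  }
})

test_that("per-chromosome coincidences average back to the global value", {
  sim <- sim_med()
  ts <- coincidence_probability(sim$gm, "satsuma", "cand03", "cand04")
  expect_equal(stats::weighted.mean(ts$per_chrom$coincidence, ts$per_chrom$n),
               ts$coincidence)
  expect_equal(sum(ts$per_chrom$n), ts$n_evaluated)
  tsj <- coincidence_probability(sim$gm, "satsuma", "cand03", "cand04",
                                 dispersion = "jackknife")
  expect_gt(tsj$dispersion, 0)
  expect_error(coincidence_probability(sim$gm, "satsuma", "nobody", "cand04"))
})

test_that("informative-only mode drops exactly the het x het sites", {
  geno <- rbind(off = c(0L, 1L, 1L, 2L),
                pa  = c(1L, 1L, 1L, 0L),
                pb  = c(1L, 1L, 0L, 0L))
  gm <- genotype_matrix(rownames(geno),
                        data.frame(chrom = "chr1", pos = 1:4 * 10,
                                   ref = "A", alt = "T"), geno)
  all_sites <- coincidence_probability(gm, "off", "pa", "pb",
                                       informative_only = FALSE)
  inf <- coincidence_probability(gm, "off", "pa", "pb")
  expect_equal(all_sites$n_evaluated, 4L)
  expect_equal(inf$n_evaluated, 2L)          # sites 1 and 2 are het x het
  expect_equal(inf$n_compatible, 1L)         # site 3 ok, site 4 impossible
  expect_equal(inf$coincidence, 50)
})

test_that("candidate-pair ranking puts the true parents first", {
  sim <- sim_med()
  rk <- rank_parent_pairs(sim$gm, "satsuma", candidate_ids(sim))
  expect_equal(nrow(rk), choose(length(candidate_ids(sim)), 2))
  expect_setequal(c(rk$parent_a[1], rk$parent_b[1]), c("cand01", "cand02"))
  rk2 <- rank_parent_pairs(sim$gm, "satsuma", candidate_ids(sim))
  expect_identical(rk, rk2)                  # deterministic ordering
  expect_warning(one <- rank_parent_pairs(sim$gm, "satsuma",
                                          c("satsuma", "cand01", "cand02")),
                 "offspring")
  expect_equal(nrow(one), 1L)
  expect_error(rank_parent_pairs(sim$gm, "satsuma", "cand01"))
})

test_that("chloroplast distances assign the seed parent", {
  sim <- sim_clean()                         # cp_mut_rate = 0
  a <- sim$cp$geno["cand01", ]
  b <- sim$cp$geno["cand02", ]
  expect_gt(sum(a != b), 0)                  # parental cp haplotypes differ
  res <- cp_maternal_assign(sim$cp, "satsuma", candidate_ids(sim))
  expect_equal(res$assigned, "cand01")       # the seed parent, never pollen
  expect_equal(res$distances["satsuma", "cand01"], 0)
  expect_equal(unname(diag(res$distances)), rep(0, nrow(res$distances)))
  expect_equal(res$distances, t(res$distances))

  # query identical to a candidate is assigned at distance zero
  res2 <- cp_maternal_assign(sim$cp, "satsuma_cl1", c("satsuma", "cand05"))
  expect_equal(res2$assigned, "satsuma")
  expect_error(cp_maternal_assign(sim$cp, "ghost", "cand01"))
})

test_that("neighbor joining matches the 3-taxon closed form and ape", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                    c("a", "b", "c")))
  nwk <- nj_newick(D)
  tr <- ape::read.tree(text = nwk)
  co <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  # closed form: la = (dab + dac - dbc)/2 etc.; path lengths reproduce D
  expect_equal(co, D, tolerance = 1e-8)
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(la, (0.3 + 0.5 - 0.6) / 2)

  # random additive trees: our NJ reproduces ape's path-length matrix
  set.seed(11)
  for (i in 1:3) {
    t0 <- ape::rtree(6)
    D6 <- ape::cophenetic.phylo(t0)
    ours <- ape::cophenetic.phylo(ape::read.tree(text = nj_newick(D6)))
    theirs <- ape::cophenetic.phylo(ape::nj(D6))
    expect_equal(ours[rownames(theirs), colnames(theirs)], theirs,
                 tolerance = 1e-8)
  }
})

test_that("origin reports aggregate and flag conflicts faithfully", {
  sim <- sim_clean()
  rk <- rank_parent_pairs(sim$gm, "satsuma", candidate_ids(sim))
  cp <- cp_maternal_assign(sim$cp, "satsuma", candidate_ids(sim))
  ibd <- ibd_matrix(subset_samples(sim$gm, c("satsuma", "cand01", "cand02")),
                    freq = panel_freq(sim))
  rep1 <- decide_origin(rk, cp, ibd, offspring = "satsuma")
  expect_setequal(rep1$best_pair, c("cand01", "cand02"))
  expect_equal(rep1$orientation, "resolved")
  expect_equal(rep1$seed_parent, sim$truth$pedigree$seed_parent)
  expect_equal(rep1$pollen_parent, sim$truth$pedigree$pollen_parent)
  expect_gt(rep1$ibd1[["cand01"]], 0.9)

  # no chloroplast evidence: pair reported, orientation undetermined
  rep2 <- decide_origin(rk, NULL, NULL)
  expect_setequal(rep2$best_pair, c("cand01", "cand02"))
  expect_equal(rep2$orientation, "undetermined")
  expect_true(is.na(rep2$seed_parent))

  # shuffled cp labels that put the nearest candidate outside the best pair
  cp_bad <- cp
  ids <- rownames(cp_bad$distances)
  d <- cp_bad$distances
  d[, "cand01"] <- d["cand01", ] <- max(d) + 0.1   # push true seed far away
  d["cand01", "cand01"] <- 0
  d["satsuma", "cand07"] <- d["cand07", "satsuma"] <- 0
  cp_bad$distances <- d
  cp_bad$assigned <- "cand07"
  rep3 <- decide_origin(rk, cp_bad, NULL)
  expect_equal(rep3$orientation, "unresolved")
})
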