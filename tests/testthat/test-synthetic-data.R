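test_that("sim_config validates probabilities, weights and reachability", {
  expect_error(sim_config(capture_p = 1.2), "capture_p")
  expect_error(sim_config(hybrid_fitness_w = -1), ">= 0")
  expect_error(sim_config(n_diagnostic_loci = 30), "exceed")
  expect_error(sim_config(source_He_target = 0.9, n_alleles_source = 2),
               "unreachable")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("a zero He target yields monomorphic recipient loci", {
  cfg <- sim_config(recipient_He_target = 0, seed = 3)
  pools <- simulate_source_pools(cfg, n_recipient = 50)
  rec <- gt_subset(pools, which(pools$meta$pop == "recipient"))
  he <- expected_heterozygosity(rec)$per_locus
  expect_true(all(he == 0))
})

test_that("realized mean He tracks the pool targets (Monte Carlo over seeds)", {
  he_rec <- he_src <- numeric(10)
  for (i in 1:10) {
    pools <- simulate_source_pools(sim_config(seed = 100 + i),
                                   n_recipient = 200, n_source = 200)
    he_rec[i] <- expected_heterozygosity(
      gt_subset(pools, which(pools$meta$pop == "recipient")))$mean
    he_src[i] <- expected_heterozygosity(
      gt_subset(pools, which(pools$meta$pop == "source")))$mean
  }
  expect_gt(mean(he_rec), 0.09); expect_lt(mean(he_rec), 0.19)
  expect_gt(mean(he_src), 0.50); expect_lt(mean(he_src), 0.60)
})

test_that("diagnostic alleles are absent from the recipient pool", {
  cfg <- sim_config(seed = 7)
  pools <- simulate_source_pools(cfg, n_recipient = 150, n_source = 150)
  rec_cnt <- allele_counts(gt_subset(pools, which(pools$meta$pop == "recipient")))
  src_cnt <- allele_counts(gt_subset(pools, which(pools$meta$pop == "source")))
  for (l in paste0("L", seq_len(cfg$n_diagnostic_loci))) {
    expect_length(intersect(names(rec_cnt[[l]]), names(src_cnt[[l]])), 0)
  }
})

test_that("neutral sire sampling reproduces the sire-pool F1 fraction", {
  cfg <- sim_config(hybrid_fitness_w = 1, seed = 9)
  pools <- simulate_source_pools(cfg, n_source = 30)
  res <- gt_subset(pools, which(pools$meta$pop == "recipient"))
  src <- gt_subset(pools, which(pools$meta$pop == "source"))
  dams <- resample_gt(res, rep(1:20, length.out = 500), "D")
  sires <- gt_bind(gt_subset(res, 1:21),
                   resample_gt(src, 1:5, "T"))
  b <- breed_cohort(list(dams = dams, sires = sires,
                         dam_class = "resident",
                         sire_class = c(rep("resident", 21),
                                        rep("introduced", 5))),
                    cfg, seed = 10)
  frac_f1 <- mean(b$truth$class == "F1")
  expect_equal(frac_f1, 5 / 26, tolerance = 0.2)  # binomial error, n = 2000
  expect_equal(nrow(b$truth), 500 * cfg$offspring_per_female)
})

test_that("w = 0 silences introduced sires entirely", {
  cfg <- sim_config(hybrid_fitness_w = 0, seed = 12)
  pools <- simulate_source_pools(cfg, n_source = 30)
  res <- gt_subset(pools, which(pools$meta$pop == "recipient"))
  src <- gt_subset(pools, which(pools$meta$pop == "source"))
  b2 <- breed_cohort(list(dams = gt_subset(res, 22:41),
                          sires = gt_bind(gt_subset(res, 1:21),
                                          resample_gt(src, 1:5, "T")),
                          dam_class = "resident",
                          sire_class = c(rep("resident", 21),
                                         rep("introduced", 5))),
                     cfg, seed = 13)
  expect_true(all(b2$truth$class == "resident"))
  # an all-introduced sire pool with w = 0 has no viable sire at all
  expect_error(
    breed_cohort(list(dams = gt_subset(res, 22:41),
                      sires = resample_gt(src, 1:5, "T"),
                      dam_class = "resident", sire_class = "introduced"),
                 cfg, seed = 14),
    "zero")
  expect_error(
    breed_cohort(list(dams = gt_subset(res, 22:41),
                      sires = gt_subset(res, integer(0)),
                      dam_class = "resident", sire_class = character(0)),
                 cfg, seed = 15),
    "no sires")
})

test_that("F1 offspring are heterozygous source/recipient at diagnostic loci", {
  cfg <- sim_config(seed = 21)
  pools <- simulate_source_pools(cfg, n_recipient = 100, n_source = 60)
  panel <- build_panel(gt_subset(pools, which(pools$meta$pop == "source")),
                       gt_subset(pools, which(pools$meta$pop == "recipient")))
  f1 <- breed_type(cfg, 200, "F1", seed = 21, pools = pools)$genotypes
  calls <- classify_ancestry(f1, panel)
  expect_true(all(calls$n_het == calls$n_loci_scored))
})

test_that("every offspring allele exists in one of its parents", {
  cfg <- sim_config(seed = 31)
  pools <- simulate_source_pools(cfg, n_source = 30)
  res <- gt_subset(pools, which(pools$meta$pop == "recipient"))
  src <- gt_subset(pools, which(pools$meta$pop == "source"))
  sires <- gt_bind(gt_subset(res, 1:21), resample_gt(src, 1:5, "T"))
  b <- breed_cohort(list(dams = gt_subset(res, 22:41), sires = sires,
                         dam_class = "resident",
                         sire_class = c(rep("resident", 21),
                                        rep("introduced", 5))),
                    cfg, seed = 32)
  gt <- b$genotypes
  for (i in seq_along(gt$ids)) {
    di <- match(b$truth$dam[i], gt_bind(gt_subset(res, 22:41))$ids)
    dam_all <- rbind(gt_subset(res, 22:41)$a1[di, ], gt_subset(res, 22:41)$a2[di, ])
    si <- match(b$truth$sire[i], sires$ids)
    sire_all <- rbind(sires$a1[si, ], sires$a2[si, ])
    parent_ok <- mapply(function(l) {
      (gt$a1[i, l] %in% dam_all[, l] || gt$a1[i, l] %in% sire_all[, l]) &&
        (gt$a2[i, l] %in% dam_all[, l] || gt$a2[i, l] %in% sire_all[, l])
    }, seq_along(gt$loci))
    expect_true(all(parent_ok))
  }
})

test_that("neutral hybrid counts follow the sire-pool binomial across cohorts", {
  cfg <- sim_config(hybrid_fitness_w = 1, offspring_per_female = 4, seed = 41)
  pools <- simulate_source_pools(cfg, n_source = 30)
  res <- gt_subset(pools, which(pools$meta$pop == "recipient"))
  src <- gt_subset(pools, which(pools$meta$pop == "source"))
  sires <- gt_bind(gt_subset(res, 1:21), resample_gt(src, 1:5, "T"))
  parents <- list(dams = gt_subset(res, 22:27), sires = sires,
                  dam_class = "resident",
                  sire_class = c(rep("resident", 21), rep("introduced", 5)))
  n_off <- 6L * cfg$offspring_per_female   # 24 offspring per cohort
  counts <- vapply(1:200, function(r) {
    sum(breed_cohort(parents, cfg, seed = 5000 + r)$truth$class == "F1")
  }, numeric(1))
  # bin the replicate counts and test against Binomial(24, 5/26) masses
  breaks <- c(-0.5, 2.5, 3.5, 4.5, 5.5, 6.5, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(pbinom(c(-1, 2, 3, 4, 5, 6, n_off), n_off, 5 / 26))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("perfect detection yields all-ones histories for everyone alive", {
  cfg <- sim_config(capture_p = 1, n_secondary = 4, seed = 51)
  ind <- data.frame(id = paste0("i", 1:30), year = 2012)
  ch <- simulate_trapping(ind, cfg)
  m <- generescue:::year_matrix(ch, 2012)
  expect_equal(dim(m), c(30L, 4L))
  expect_true(all(m == 1L))
})

test_that("the expected number of distinct detected individuals is matched", {
  cfg <- sim_config(capture_p = 0.3, n_secondary = 5, seed = 61)
  ind <- data.frame(id = sprintf("i%03d", 1:150), year = 2012)
  seen <- vapply(1:30, function(r) {
    nrow(simulate_trapping(ind, cfg, seed = 700 + r))
  }, numeric(1))
  expected <- 150 * (1 - 0.7^5)   # ~124.8
  expect_equal(mean(seen), expected, tolerance = 0.03)
})

test_that("trapping output is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 71)
  ind <- data.frame(id = paste0("i", 1:40), year = 2013)
  ch1 <- simulate_trapping(ind, cfg, seed = 99)
  ch2 <- simulate_trapping(ind, cfg, seed = 99)
  expect_identical(as.data.frame(ch1), as.data.frame(ch2))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_capture_csv(ch1, f1); write_capture_csv(ch2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("hybrid fitness w is recovered end-to-end across the w grid", {
  for (w_true in c(1.0, 1.65, 2.6)) {
    cfg <- sim_config(hybrid_fitness_w = w_true, seed = 81)
    pools <- simulate_source_pools(cfg, n_recipient = 150, n_source = 60)
    res <- gt_subset(pools, which(pools$meta$pop == "recipient"))
    src <- gt_subset(pools, which(pools$meta$pop == "source"))
    panel <- build_panel(src, res)
    sires <- gt_bind(resample_gt(res, 1:21, "RM"), resample_gt(src, 1:5, "T"))
    dams <- resample_gt(res, 22:71, "D")   # 50 dams x 4 young = 200 offspring
    parents <- list(dams = dams, sires = sires, dam_class = "resident",
                    sire_class = c(rep("resident", 21), rep("introduced", 5)))
    w_hat <- vapply(1:50, function(r) {
      off <- breed_cohort(parents, cfg, seed = 9000 + 100 * w_true + r)$genotypes
      cls <- classify_ancestry(off, panel)$class
      obs_h <- sum(cls != "resident"); obs_n <- sum(cls == "resident")
      e <- expected_f1_counts(obs_h + obs_n, 5, 21)
      relative_fitness(obs_h, obs_n, e[["exp_hybrid"]], e[["exp_nonhybrid"]])
    }, numeric(1))
    expect_lt(abs(median(w_hat) - w_true) / w_true, 0.15)
  }
})

test_that("bootstrap CIs cover the simulated fitness advantage", {
  cfg <- sim_config(hybrid_fitness_w = 2.6, seed = 91)
  pools <- simulate_source_pools(cfg, n_recipient = 120, n_source = 60)
  res <- gt_subset(pools, which(pools$meta$pop == "recipient"))
  src <- gt_subset(pools, which(pools$meta$pop == "source"))
  panel <- build_panel(src, res)
  sires <- gt_bind(resample_gt(res, 1:21, "RM"), resample_gt(src, 1:5, "T"))
  dams <- resample_gt(res, 22:30, "D")     # 9 dams x 4 = 36 new adults
  parents <- list(dams = dams, sires = sires, dam_class = "resident",
                  sire_class = c(rep("resident", 21), rep("introduced", 5)))
  covered <- vapply(1:50, function(r) {
    off <- breed_cohort(parents, cfg, seed = 40000 + r)$genotypes
    cls <- classify_ancestry(off, panel)$class
    obs_h <- sum(cls != "resident"); obs_n <- sum(cls == "resident")
    if (obs_h == 0 || obs_n == 0) return(NA)
    e <- expected_f1_counts(obs_h + obs_n, 5, 21)
    ci <- bootstrap_rf_ci(obs_h, obs_n, e[["exp_hybrid"]], e[["exp_nonhybrid"]],
                          B = 1000, seed = r)
    ci$ci_low <= 2.6 && 2.6 <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered, na.rm = TRUE), 0.8)
})

test_that("the full study simulation is internally consistent", {
  cfg <- sim_config(seed = 5)
  s <- simulate_study(cfg)
  expect_setequal(unique(s$truth$class[s$truth$year_first_adult == s$years$cohort1]),
                  intersect(unique(s$truth$class), c("F1", "resident")))
  # pedigree sanity: F1 truth means one introduced and one resident parent
  f1 <- s$truth[s$truth$class == "F1", ]
  intro <- s$truth$id[s$truth$class == "introduced"]
  expect_true(all(f1$sire %in% intro))
  # capture histories only contain individuals alive (and never translocated)
  expect_false(any(s$histories$id %in% intro))
})
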