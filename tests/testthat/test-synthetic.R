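test_that("Yule simulation is seeded, shaped and calibrated", {
  two <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(ape::Ntip(two), 2)
  expect_equal(two$Nnode, 1)

  a <- simulate_yule_tree(16, 0.7, seed = 42)
  b <- simulate_yule_tree(16, 0.7, seed = 42)
  expect_identical(ape::write.tree(a), ape::write.tree(b))

  expect_true(ape::is.ultrametric(a, tol = 1e-8))
  expect_true(all(node_ages(a)[1:16] == 0))
  expect_true(all(branch_durations(a)$duration > 0))
})

test_that("mean Yule root age matches the closed-form expectation", {
  n <- 8; b <- 1.3
  set.seed(77)
  ages <- replicate(1000, {
    tr <- simulate_yule_tree(n, b)
    node_ages(tr)[n + 1]
  })
  expected <- sum(1 / ((2:n) * b))
  # Monte-Carlo error: sd of a sum of exponentials / sqrt(1000)
  mc_se <- sqrt(sum(1 / ((2:n) * b)^2) / 1000)
  expect_lt(abs(mean(ages) - expected), 4 * mc_se)
})

test_that("BM traits have the constructed covariance", {
  tr <- simulate_yule_tree(8, 1, seed = 3)
  # sigma2 -> 0: every tip collapses to the root state
  tiny <- simulate_bm_trait(tr, sigma2 = 1e-12, root_state = 5, seed = 4)
  expect_equal(unname(tiny), rep(5, 8), tolerance = 1e-4)

  # lambda 0: tips i.i.d. with variance sigma2 * diag(C)
  C <- bm_covariance(tr)
  set.seed(9)
  reps0 <- replicate(2000, simulate_bm_trait(tr, sigma2 = 2,
                                             lambda_true = 0))
  v <- apply(reps0, 1, var)
  expect_equal(unname(v), unname(2 * diag(C)), tolerance = 0.15)
  offdiag <- cov(t(reps0))[upper.tri(C)]
  expect_lt(max(abs(offdiag)), 0.25 * max(2 * diag(C)))

  # lambda 1: sample covariance approaches sigma2 * C entrywise
  # lambda 1: sample covariance matches sigma2 * C entrywise, judged
  # against each entry's exact Monte-Carlo standard error
  # Var(S_ij) = (sig_ii sig_jj + sig_ij^2) / (n - 1) for Gaussian draws
  set.seed(10)
  nrep <- 2000
  reps1 <- replicate(nrep, simulate_bm_trait(tr, sigma2 = 1.5))
  S <- cov(t(reps1))
  Sig <- 1.5 * C
  se <- sqrt((outer(diag(Sig), diag(Sig)) + Sig^2) / (nrep - 1))
  expect_lt(max(abs(S - Sig) / se), 5)
})

test_that("generated specimen tables satisfy every invariant by
           construction", {
  cfg <- simulation_config(seed = 8)
  sim <- generate_specimen_table(cfg)
  expect_s3_class(sim$specimens, "specimen_table")
  expect_s3_class(sim$vertebrae, "vertebra_table")
  expect_equal(nrow(sim$specimens), cfg$n_extinct + cfg$n_extant)
  expect_true(all(sim$specimens$L_axis1 >= sim$specimens$L_axis2))
  expect_true(all(sim$specimens$N_PCV + sim$specimens$N_CV >=
                  cfg$min_total_vertebrae))
  # extinct centra relatively longer, extant counts higher (documented
  # group structure)
  s <- sim$specimens
  ex <- s$status == "extinct"
  expect_gt(mean(s$AR_CV[ex]), mean(s$AR_CV[!ex]))
  expect_lt(mean(s$N_PCV[ex] + s$N_CV[ex]),
            mean(s$N_PCV[!ex] + s$N_CV[!ex]))
})

test_that("specimen generation is byte-identical per seed", {
  cfg <- simulation_config(seed = 99)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_specimen_table(generate_specimen_table(cfg)$specimens, f1)
  write_specimen_table(generate_specimen_table(cfg)$specimens, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tendon generation feeds the estimator end to end", {
  obs <- generate_tendon_observations(c("a", "b", "c"),
                                      k_values = c(1, 2, 2.5), seed = 1)
  expect_equal(nrow(obs), 6)   # ENB + EPB per taxon
  est <- lateral_tendon_length(obs)
  expect_equal(est$tendon_length_vertebrae[match(c("a", "b", "c"),
                                                 est$taxon_id)],
               c(3, 4, 4.5))

  expect_equal(nrow(generate_tendon_observations(character(), 1)), 0)

  set.seed(60)
  for (i in 1:50) {
    taxa <- sprintf("x%d", seq_len(sample(1:6, 1)))
    kv <- cbind(runif(3, 0, 2), runif(3, 2, 4))
    expect_s3_class(generate_tendon_observations(taxa, kv),
                    "tendon_table")
  }
})

test_that("the full synthetic pipeline runs quickly and is schema-valid", {
  t0 <- Sys.time()
  out <- run_pipeline(simulation_config(seed = 5, tree_n_tips = 24),
                      n_permutations = 49)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_s3_class(out$vsi, "vsi_table")
  expect_s3_class(out$pca, "anguimorph_pca")
  expect_s3_class(out$overlap, "overlap_report")
  expect_s3_class(out$k, "signal_result")
  expect_s3_class(out$lambda, "signal_result")
  expect_s3_class(out$asr, "asr_result")
  expect_equal(out$k$n_tips, 24)
})

test_that("fixture directories are complete and reloadable", {
  dir <- withr::local_tempdir()
  write_fixture_dir(simulation_config(seed = 2, tree_n_tips = 8), dir)
  expect_setequal(list.files(dir),
                  c("specimens.csv", "vertebrae.csv", "tendons.csv",
                    "tree.nwk", "tip_ages.csv", "constraints.csv",
                    "config.yaml"))
  specs <- read_specimen_table(file.path(dir, "specimens.csv"))
  expect_s3_class(specs, "specimen_table")
  tr <- read_tree(file.path(dir, "tree.nwk"))
  ages <- read_tip_ages(file.path(dir, "tip_ages.csv"))
  cons <- read_constraints(file.path(dir, "constraints.csv"))
  cal <- calibrate_tree(tr, ages, cons)
  expect_true(all(branch_durations(cal)$duration > 0))
})
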