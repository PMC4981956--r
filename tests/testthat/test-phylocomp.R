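test_that("calibration reproduces bracket means and fossil branch durations", {
  fix <- composite_fixture()
  cal <- calibrate_tree(fix$tree, fix$tip_ages, fix$constraints)
  age <- node_ages(cal)
  ntip <- ape::Ntip(cal)

  # the congroid-muraenoid divergence: unconstrained, bracketed by the
  # crown node (99 Ma) and the congroid node (86 Ma) -> (99 + 86) / 2
  h <- ape::getMRCA(cal, c("Bolcyrus", "Paranguilla"))
  expect_equal(age[h], 92.5)

  # fossil terminal branch = parent age - first occurrence (ghost lineage
  # included): the anguilloid fossil under the 81 Ma node spans 32 Ma
  dur <- branch_durations(cal)
  expect_equal(dur$duration[dur$child_label == "Anguilloides"], 81 - 49)

  # extant tip under a fixed 60 Ma ancestor within a polytomy
  g <- ape::getMRCA(cal, c("Anguilla_ignota", "Anguilla_rostrata"))
  expect_equal(age[g], 60)
  expect_equal(dur$duration[dur$child_label == "Anguilla_rostrata"], 60)

  # every parent strictly older than each child
  expect_true(all(dur$duration > 0))

  # idempotence: recalibrating the calibrated topology changes nothing
  again <- calibrate_tree(cal, fix$tip_ages, fix$constraints)
  expect_equal(node_ages(again), age)
})

test_that("calibration conflicts are raised, not silently adjusted", {
  fix <- composite_fixture()
  bad <- fix$constraints
  # 40 Ma is younger than both the 49 Ma fossil and the 60 Ma node below
  bad$age[bad$age == 81] <- 40
  expect_error(calibrate_tree(fix$tree, fix$tip_ages, bad),
               "conflict.*40.*Ma")

  unknown <- fix$constraints
  unknown$mrca_of[[2]] <- c("Anguilloides", "not_a_tip")
  expect_error(calibrate_tree(fix$tree, fix$tip_ages, unknown),
               "not_a_tip")

  # a minimum constraint older than every descendant is used as-is
  minc <- fix$constraints
  minc$kind[minc$age == 76] <- "minimum"
  minc$age[minc$age == 76] <- 80
  cal <- calibrate_tree(fix$tree, fix$tip_ages, minc)
  k <- ape::getMRCA(cal, c("Paranguilla", "Gymnothorax_moringa"))
  expect_equal(node_ages(cal)[k], 80)

  # a minimum younger than a descendant occurrence is lifted onto it,
  # which collides with the strict parent > child rule and is raised
  minc$age[minc$age == 80] <- 20
  expect_error(calibrate_tree(fix$tree, fix$tip_ages, minc),
               "not older than child Paranguilla")
})

test_that("BM covariance matches star/cherry closed forms and a path-sum
           oracle", {
  st <- star_tree(5, depth = 2.5)
  expect_equal(bm_covariance(st), diag(2.5, 5), ignore_attr = TRUE)

  # two sisters diverging at half depth share half their variance
  phy <- ape::read.tree(text = "((A,B),C);")
  cal <- anguimorph:::.as_dated(phy, c(0, 0, 0, 10, 5))
  C <- bm_covariance(cal)
  expect_equal(C["A", "B"], C["A", "A"] / 2)
  expect_equal(C["A", "C"], 0)

  expect_error(bm_covariance(ape::rtree(5)), "not dated")

  set.seed(4)
  for (i in 1:5) {
    tr <- simulate_yule_tree(12, 1, seed = i)
    expect_equal(bm_covariance(tr), path_sum_covariance(tr),
                 tolerance = 1e-12)
  }
})

test_that("K is exactly 1 on a star tree and affine invariant", {
  st <- star_tree(8, depth = 3)
  set.seed(1)
  x <- setNames(rnorm(8), st$tip.label)
  k <- blomberg_k(st, x, n_permutations = 0)
  expect_equal(k$estimate, 1, tolerance = 1e-10)

  tr <- simulate_yule_tree(16, 1, seed = 99)
  y <- simulate_bm_trait(tr, seed = 100)
  k1 <- blomberg_k(tr, y, n_permutations = 0)
  k2 <- blomberg_k(tr, 3.2 * y - 7, n_permutations = 0)
  expect_equal(k1$estimate, k2$estimate, tolerance = 1e-10)

  # permutation p-value is small for a strongly heritable trait
  kp <- blomberg_k(tr, y, n_permutations = 199, seed = 1)
  expect_lt(kp$p_value, 0.05)
})

test_that("the lambda transform and its MLE behave as defined", {
  tr <- simulate_yule_tree(24, 1, seed = 5)
  C <- bm_covariance(tr)
  expect_equal(anguimorph:::.lambda_transform(C, 1), C)
  expect_equal(anguimorph:::.lambda_transform(C, 0),
               diag(diag(C)), ignore_attr = TRUE)

  y <- simulate_bm_trait(tr, seed = 6)
  fit <- pagel_lambda(tr, y)
  # optimality: no worse than the endpoints
  ll0 <- anguimorph:::.lambda_loglik(0, C, y[tr$tip.label])
  ll1 <- anguimorph:::.lambda_loglik(1, C, y[tr$tip.label])
  expect_gte(fit$log_likelihood, max(ll0, ll1) - 1e-8)
  # affine invariance of the estimate
  fit2 <- pagel_lambda(tr, -2 * y + 11)
  expect_equal(fit$estimate, fit2$estimate, tolerance = 1e-6)

  # independent noise should show weak signal
  noise <- setNames(rnorm(24), tr$tip.label)
  expect_lt(pagel_lambda(tr, noise)$estimate, 0.5)
})

test_that("signal estimators cross-check against phytools on one dataset", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(32, 1, seed = 12)
  y <- simulate_bm_trait(tr, sigma2 = 2, lambda_true = 0.8, seed = 13)
  k_ours <- blomberg_k(tr, y, n_permutations = 0)
  k_ref <- phytools::phylosig(tr, y, method = "K")
  expect_equal(k_ours$estimate, unname(as.numeric(k_ref)),
               tolerance = 1e-6)
  l_ours <- pagel_lambda(tr, y)
  l_ref <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(l_ours$estimate, l_ref$lambda, tolerance = 1e-3)
  expect_equal(l_ours$log_likelihood, l_ref$logL, tolerance = 1e-4)
})

test_that("squared-change parsimony solves closed forms and random trees", {
  # constant trait: every node at the constant, cost 0
  tr <- simulate_yule_tree(10, 1, seed = 20)
  const <- setNames(rep(4, 10), tr$tip.label)
  res <- parsimony_asr(tr, const)
  expect_equal(unname(res$ace), rep(4, tr$Nnode))
  expect_equal(res$cost, 0)

  # two tips: root at the midpoint, cost (a - b)^2 / 2
  two <- ape::read.tree(text = "(A,B);")
  r2 <- parsimony_asr(two, c(A = 1, B = 5))
  expect_equal(unname(r2$ace), 3)
  expect_equal(r2$cost, (1 - 5)^2 / 2)

  # cost matches the definition Sum (parent - child)^2
  y <- simulate_bm_trait(tr, seed = 21)
  r <- parsimony_asr(tr, y)
  all_val <- c(y[tr$tip.label], r$ace)
  expect_equal(r$cost,
               sum((all_val[tr$edge[, 1]] - all_val[tr$edge[, 2]])^2))

  expect_error(parsimony_asr(tr, y[-1]), names(y)[1])
})

test_that("parsimony reconstruction agrees with exhaustive grid
           minimisation on 5-tip trees", {
  set.seed(30)
  for (i in 1:20) {
    tr <- ape::rtree(5)
    y <- setNames(runif(5), tr$tip.label)
    dp <- parsimony_asr(tr, y)
    or <- grid_asr(tr, y, step = 1e-3)
    expect_equal(unname(dp$ace), unname(or$ace), tolerance = 2e-3)
  }
})

test_that("moving a tip toward its neighbour never increases the cost", {
  set.seed(31)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    y <- setNames(rnorm(8), tr$tip.label)
    base <- parsimony_asr(tr, y)
    # move tip 1 toward the reconstructed value of its parent
    par1 <- tr$edge[tr$edge[, 2] == 1, 1]
    target <- base$ace[as.character(par1)]
    y2 <- y
    y2[tr$tip.label[1]] <- y[tr$tip.label[1]] +
      0.5 * (target - y[tr$tip.label[1]])
    expect_lte(parsimony_asr(tr, y2)$cost, base$cost + 1e-12)
  }
})
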