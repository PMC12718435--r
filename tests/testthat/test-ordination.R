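test_that("correlation grouping links duplicates and recovers generative blocks", {
  env <- random_env(35, c("x", "z"), seed = 1)
  env$y <- env$x
  cg <- correlation_groups(env)
  grp <- cg$assignment$group
  names(grp) <- cg$assignment$variable
  expect_equal(grp[["x"]], grp[["y"]])
  expect_false(grp[["z"]] == grp[["x"]])

  # three-block synthetic environment: recovered components = generative blocks
  e <- simulate_env(sim_config(seed = 4))
  cg2 <- correlation_groups(e$env)
  got <- lapply(cg2$groups, sort)
  for (bl in e$blocks) {
    expect_true(any(vapply(got, identical, logical(1), sort(bl))),
                info = paste(bl, collapse = ","))
  }

  const <- random_env(20, "a", seed = 2)
  const$flat <- 1
  expect_warning(correlation_groups(const), "constant")
})

test_that("independent variables stay ungrouped under the null", {
  singletons <- vapply(1:200, function(s) {
    env <- random_env(35, c("a", "b", "c", "d", "e"), seed = s)
    cg <- correlation_groups(env)
    length(cg$groups) == 5
  }, logical(1))
  expect_gte(mean(singletons), 0.95)
})

test_that("DCA gradient length separates short from long gradients", {
  flat <- tibble::tibble(site = sprintf("s%d", 1:6),
                         a = rep(0.5, 6), b = rep(0.3, 6), c = rep(0.2, 6))
  res <- dca_gradient_length(flat)
  expect_equal(res$gradient_length, 0)
  expect_equal(res$recommendation, "RDA")

  x <- seq(0, 10, length.out = 30)
  short <- gaussian_community(x, n_taxa = 12, tolerance = 40)  # tol >> span
  expect_lt(dca_gradient_length(short)$gradient_length, 2)
  expect_equal(dca_gradient_length(short)$recommendation, "RDA")

  long <- gaussian_community(x, n_taxa = 15, tolerance = 1)    # full turnover
  expect_gt(dca_gradient_length(long)$gradient_length, 2)
})

test_that("rda_fit matches the brute-force projection oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(6:10, 1); mm <- sample(3:6, 1)
    sp <- random_species(n, mm, seed = s)
    env <- random_env(n, c("c1", "c2", "z1"), seed = s)
    use_cov <- s %% 2 == 0
    fit <- rda_fit(sp, env, constraints = c("c1", "c2"),
                   covariates = if (use_cov) "z1")
    oracle <- brute_rda(as.matrix(sp[-1]),
                        as.matrix(env[c("c1", "c2")]),
                        if (use_cov) as.matrix(env["z1"]))
    expect_equal(fit$eig_constrained,
                 oracle$eig_c[seq_along(fit$eig_constrained)], tolerance = 1e-8)
    expect_equal(fit$eig_unconstrained,
                 oracle$eig_u[seq_along(fit$eig_unconstrained)], tolerance = 1e-8)
    expect_equal(fit$total, oracle$total, tolerance = 1e-8)
    # conservation: constrained + unconstrained = covariate-adjusted total
    expect_equal(sum(fit$eig_constrained) + sum(fit$eig_unconstrained),
                 fit$total, tolerance = 1e-8)
  }
})

test_that("rda_fit agrees with vegan on eigenvalue structure", {
  sp <- random_species(12, 6, seed = 9)
  env <- random_env(12, c("c1", "z1"), seed = 9)
  fit <- rda_fit(sp, env, constraints = "c1", covariates = "z1")
  v <- vegan::rda(as.matrix(sp[-1]) ~ c1 + Condition(z1),
                  data = as.data.frame(env[-1]))
  expect_equal(unname(fit$eig_constrained),
               unname(v$CCA$eig), tolerance = 1e-8)
  expect_equal(unname(fit$eig_unconstrained[seq_along(v$CA$eig)]),
               unname(v$CA$eig), tolerance = 1e-8)
})

test_that("rda_fit limiting cases: orthogonal constraint and saturation", {
  sp <- random_species(8, 4, seed = 3)
  Y <- as.matrix(sp[-1])
  set.seed(3)
  v <- rnorm(8)
  ortho <- qr.resid(qr(cbind(1, Y)), v)  # orthogonal to every species column
  env <- tibble::tibble(site = sp$site, o = ortho)
  fit <- rda_fit(sp, env, constraints = "o")
  expect_lt(sum(fit$eig_constrained), 1e-10)

  envf <- random_env(8, paste0("v", 1:7), seed = 4)
  fitf <- rda_fit(sp, envf, constraints = paste0("v", 1:7))
  expect_lt(sum(fitf$eig_unconstrained), 1e-8)

  envc <- tibble::tibble(site = sp$site, a = rnorm(8))
  envc$b <- 2 * envc$a
  expect_error(rda_fit(sp, envc, constraints = c("a", "b")), "collinear")
})

test_that("permutation test hits the p floor on strong signal", {
  sp <- random_species(20, 5, seed = 11)
  env <- tibble::tibble(site = sp$site, sig = as.matrix(sp[-1])[, 1])
  pt <- permutation_test(sp, env, "sig", n_perm = 199, seed = 1)
  expect_equal(pt$p, 1 / 200)
  expect_gte(pt$p, 1 / (pt$n_perm + 1))
  pt2 <- permutation_test(sp, env, "sig", n_perm = 199, seed = 2)
  expect_equal(pt2$p, 1 / 200)
  expect_error(permutation_test(sp, env, "sig", n_perm = 0), "n_perm")
})

test_that("forward selection honours alpha limits and redundancy", {
  sp <- random_species(20, 5, seed = 21)
  env <- tibble::tibble(site = sp$site, sig = as.matrix(sp[-1])[, 1])
  sel1 <- forward_select(sp, env, "sig", alpha = 1, n_perm = 49, seed = 1)
  expect_equal(sel1$variable, "sig")
  sel0 <- forward_select(sp, env, "sig", alpha = 0, n_perm = 49, seed = 1)
  expect_equal(nrow(sel0), 0)
  expect_equal(attr(sel0, "rejected")$variable, "sig")

  # one real driver plus its noisy copy: exactly one of the pair selected
  set.seed(5)
  env$copy <- env$sig + rnorm(20, 0, 0.05 * sd(env$sig))
  sel <- forward_select(sp, env, c("sig", "copy"), alpha = 0.05,
                        n_perm = 199, seed = 3)
  expect_equal(nrow(sel), 1)
  expect_true(sel$variable %in% c("sig", "copy"))
})

test_that("independence test separates redundant from orthogonal drivers", {
  sp <- random_species(24, 6, seed = 31)
  Y <- as.matrix(sp[-1])
  env <- tibble::tibble(site = sp$site, a = Y[, 1], b = Y[, 1])
  res <- independence_test(sp, env, "a", "b", n_perm = 99, seed = 1)
  expect_equal(res$verdict, "dependent")
  expect_equal(res$retain, "a")  # equal marginal variance, lexicographic

  env2 <- tibble::tibble(site = sp$site, a = Y[, 1],
                         b = qr.resid(qr(cbind(1, Y[, 1])), Y[, 2]))
  res2 <- independence_test(sp, env2, "a", "b", n_perm = 99, seed = 1)
  expect_equal(res2$verdict, "independent")
})

test_that("variance partition reduces, decomposes and degrades correctly", {
  sp <- random_species(15, 5, seed = 41)
  env <- random_env(15, c("v1", "v2"), seed = 41)

  # single variable, no covariates: partition equals the plain RDA fraction
  vp1 <- variance_partition(sp, env, "v1", n_perm = 49, seed = 1)
  fit1 <- rda_fit(sp, env, "v1")
  expect_equal(vp1$variance_pct, sum(fit1$frac_constrained), tolerance = 1e-8)

  # orthogonal constraints: conditional contributions sum to the joint share
  env$v2 <- qr.resid(qr(cbind(1, env$v1)), env$v2)
  vp <- variance_partition(sp, env, c("v1", "v2"), n_perm = 49, seed = 1)
  expect_equal(sum(vp$variance_pct), attr(vp, "joint_constrained_pct"),
               tolerance = 1e-8)

  # identical constraints: each conditional share collapses to zero
  env$v3 <- env$v1
  vp2 <- variance_partition(sp, env, c("v1", "v3"), n_perm = 49, seed = 1)
  expect_lt(max(vp2$variance_pct), 1e-8)
  expect_gt(attr(vp2, "joint_constrained_pct"), 1)
})

test_that("eigenvalue-ratio screening flags orthogonal constraints as unusable", {
  sp <- random_species(10, 4, seed = 51)
  Y <- as.matrix(sp[-1])
  set.seed(51)
  env <- tibble::tibble(site = sp$site,
                        o = qr.resid(qr(cbind(1, Y)), rnorm(10)))
  lr <- lambda_ratio(sp, env, "o")
  expect_lt(lr$ratio, 1e-8)
  expect_false(lr$usable_for_calibration)
  expect_error(eig_ratio(1, 0), "zero")
})
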