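test_that("taxon responses follow the weighted-averaging arithmetic", {
  sp <- tibble::tibble(site = c("a", "b", "c"),
                       t1 = c(0, 5, 0),      # present only where x = 12
                       t2 = c(1, 0, 1),      # equal weight at 10 and 14
                       t3 = c(2, 1, 1))
  x <- c(10, 12, 14)
  r <- estimate_responses(sp, x)
  expect_equal(r$optimum[r$taxon == "t1"], 12)
  expect_equal(r$tolerance[r$taxon == "t1"], 0)
  expect_equal(r$optimum[r$taxon == "t2"], 12)
  expect_equal(r$tolerance[r$taxon == "t2"], 2)
  expect_equal(r$n2[r$taxon == "t2"], 2)
  expect_equal(r$occurrences[r$taxon == "t2"], 2L)
  expect_equal(r$optimum[r$taxon == "t3"], (2 * 10 + 12 + 14) / 4)

  sp$t4 <- 0
  expect_error(estimate_responses(sp, x), "t4")
})

test_that("y=(1,1) at x=(10,12) gives optimum 11 and tolerance 1", {
  sp <- tibble::tibble(site = c("a", "b"), t1 = c(1, 1))
  r <- estimate_responses(sp, c(10, 12))
  expect_equal(r$optimum, 11)
  expect_equal(r$tolerance, 1)
  expect_equal(r$n2, 2)
})

test_that("WA deshrinking is exact on perfectly separated sites", {
  # one exclusive taxon per site: initial estimates equal x, slope 1
  sp <- tibble::tibble(site = c("a", "b", "c"),
                       t1 = c(3, 0, 0), t2 = c(0, 2, 0), t3 = c(0, 0, 5))
  x <- c(10.5, 11.5, 13)
  for (ds in c("inverse", "classical")) {
    m <- fit_wa(sp, x, deshrink = ds)
    expect_equal(m$fitted, x, tolerance = 1e-10)
    expect_equal(unname(m$coef["slope"]), 1, tolerance = 1e-10)
    expect_equal(predict(m, sp)$pred, x, tolerance = 1e-10)
  }
})

test_that("inverse deshrinking cannot be worse than the raw estimates", {
  b <- make_benchmark(sim_config(seed = 8, n_planktonic = 0))
  filt <- rare_taxon_filter(relative_abundance(b$dataset$counts))
  x <- b$dataset$env$temperature
  m <- fit_wa(filt, x)
  rmse <- function(p) sqrt(mean((p - x)^2))
  expect_lte(rmse(m$fitted), rmse(m$x0) + 1e-12)
})

test_that("WAPLS component 1 reproduces inverse-deshrunk WA exactly", {
  for (s in 1:5) {
    sp <- random_species(12, 8, seed = 60 + s)
    set.seed(s); x <- rnorm(12, 11.5, 0.8)
    wa <- fit_wa(sp, x, "inverse")
    wp <- fit_wapls(sp, x, 1)
    expect_lt(max(abs(wa$fitted - wp$fitted)), 1e-8)
    expect_lt(max(abs(predict(wa, sp)$pred - predict(wp, sp)$pred)), 1e-8)
  }
})

test_that("WAPLS apparent error never rises with extra components", {
  b <- make_benchmark(sim_config(seed = 13, n_planktonic = 0))
  hel <- hellinger(rare_taxon_filter(relative_abundance(b$dataset$counts)))
  x <- b$dataset$env$temperature
  rmse <- vapply(1:3, function(k)
    sqrt(mean((fit_wapls(hel, x, k)$fitted - x)^2)), numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("WAPLS handles constant targets and refuses impossible ranks", {
  sp <- random_species(6, 4, seed = 71)
  m <- fit_wapls(sp, rep(11, 6), 2)
  expect_equal(m$n_components, 0L)
  expect_equal(predict(m, sp)$pred, rep(11, 6))

  set.seed(71)
  expect_error(fit_wapls(random_species(4, 3, seed = 2), rnorm(4), 6),
               "maximum usable")
})

test_that("prediction handles unknown taxa by renormalizing over the known", {
  train <- tibble::tibble(site = c("a", "b", "c"),
                          t1 = c(4, 1, 0), t2 = c(0, 1, 4))
  x <- c(10, 11, 12)
  m <- fit_wa(train, x)
  # round trip on the training matrix
  expect_equal(predict(m, train)$pred, m$fitted, tolerance = 1e-10)

  # a new site: half its valves belong to unknown taxa
  new <- tibble::tibble(site = "n1", t1 = 2, t2 = 2, zz1 = 3, zz2 = 1)
  expect_warning(p <- predict(m, new), "absent from the training set")
  expect_equal(p$coverage, 0.5)
  # hand computation on the known half: x0 = (2*u1 + 2*u2) / 4, deshrunk
  u <- m$optimum
  x0 <- (2 * u[1] + 2 * u[2]) / 4
  expect_equal(p$pred, unname(m$coef["intercept"] + m$coef["slope"] * x0),
               tolerance = 1e-10)

  none <- tibble::tibble(site = "n2", zz1 = 5)
  expect_warning(expect_warning(p0 <- predict(m, none)))
  expect_true(is.na(p0$pred))
  expect_equal(p0$coverage, 0)
})

test_that("WA optima always lie inside the observed gradient", {
  for (s in 1:10) {
    sp <- random_species(9, 7, seed = 80 + s)
    set.seed(s); x <- runif(9, 10, 13)
    r <- estimate_responses(sp, x)
    expect_true(all(r$optimum >= min(x) - 1e-12 & r$optimum <= max(x) + 1e-12))
  }
})

test_that("tolerance down-weighting floors degenerate tolerances", {
  sp <- tibble::tibble(site = c("a", "b", "c", "d"),
                       t1 = c(5, 0, 0, 0),          # single occurrence
                       t2 = c(1, 2, 2, 1), t3 = c(0, 1, 2, 4))
  x <- c(10, 11, 12, 13)
  m <- fit_wa(sp, x, tolerance_dw = TRUE)
  expect_true(all(is.finite(m$weights)))
  expect_true(all(m$weights > 0))
  td <- tidy(m)
  expect_equal(nrow(td), 3)
})

test_that("models serialize to JSON and back without changing predictions", {
  sp <- random_species(10, 6, seed = 91)
  set.seed(91); x <- rnorm(10, 12, 0.7)
  path <- withr::local_tempfile(fileext = ".json")
  for (m in list(fit_wa(sp, x, "classical", tolerance_dw = TRUE),
                 fit_wapls(sp, x, 2))) {
    write_model(m, path)
    m2 <- read_model(path)
    expect_equal(class(m2), class(m))
    expect_equal(predict(m2, sp)$pred, predict(m, sp)$pred, tolerance = 1e-12)
  }
})

test_that("tidy and glance summarise models in broom shapes", {
  sp <- random_species(10, 5, seed = 95)
  set.seed(95); x <- rnorm(10, 12, 0.5)
  wa <- fit_wa(sp, x)
  expect_named(tidy(wa),
               c("taxon", "optimum", "tolerance", "n2", "occurrences", "weight"))
  expect_equal(nrow(glance(wa)), 1)
  wp <- fit_wapls(sp, x, 2)
  td <- tidy(wp)
  expect_setequal(unique(td$component), 1:2)
  expect_equal(nrow(glance(wp)), 1)
})
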