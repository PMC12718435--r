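test_that("load_dataset round-trips CSV bundles and intersects site sets", {
  dir <- withr::local_tempdir()
  counts <- toy_counts()
  env <- tibble::tibble(site = c("B", "C", "D"), temperature = c(11, 12, 13),
                        secchi = c(9, 7, 5))
  readr::write_csv(counts, file.path(dir, "counts.csv"))
  readr::write_csv(env, file.path(dir, "env.csv"))

  expect_message(
    ds <- load_dataset(file.path(dir, "counts.csv"), file.path(dir, "env.csv")),
    "dropped")
  expect_s3_class(ds, "diatom_dataset")
  expect_equal(ds$counts$site, c("B", "C"))
  expect_equal(ds$env$site, c("B", "C"))

  # full identity round-trip through write_dataset
  out <- file.path(dir, "again")
  write_dataset(ds, out)
  ds2 <- load_dataset(file.path(out, "counts.csv"), file.path(out, "env.csv"),
                      taxon_meta_path = file.path(out, "taxon_meta.csv"))
  expect_equal(ds2$counts, ds$counts)
  expect_equal(ds2$env, ds$env)
  expect_equal(ds2$habit, ds$habit)
})

test_that("load_dataset fails loudly on bad cells and empty intersections", {
  dir <- withr::local_tempdir()
  writeLines(c("site,tx1,tx2", "A,1,2", "B,NA,3"), file.path(dir, "bad.csv"))
  expect_error(read_counts(file.path(dir, "bad.csv")), "site 'B', taxon 'tx1'")

  readr::write_csv(toy_counts(), file.path(dir, "counts.csv"))
  readr::write_csv(tibble::tibble(site = c("X", "Y"), temperature = c(1, 2)),
                   file.path(dir, "env.csv"))
  expect_error(load_dataset(file.path(dir, "counts.csv"),
                            file.path(dir, "env.csv")),
               "empty intersection")
})

test_that("relative abundance divides rows by their valve totals", {
  counts <- tibble::tibble(site = c("A", "B", "C"),
                           tx1 = c(1, 400, 10), tx2 = c(1, 0, 1),
                           tx3 = c(2, 0, 489))
  rel <- relative_abundance(counts)
  expect_equal(unlist(rel[1, -1], use.names = FALSE), c(0.25, 0.25, 0.50))
  expect_equal(unlist(rel[2, -1], use.names = FALSE), c(1, 0, 0))
  expect_equal(unlist(rel[3, -1], use.names = FALSE), c(0.02, 0.002, 0.978))
  expect_true(all(abs(rowSums(rel[-1]) - 1) < 1e-12))

  bad <- tibble::tibble(site = "Z", tx1 = 0, tx2 = 0)
  expect_error(relative_abundance(bad), "Z")
})

test_that("rare-taxon filter applies the percent-and-occurrence rule", {
  rel <- tibble::tibble(site = c("s1", "s2"),
                        A = c(0.02, 0.02), B = c(0.002, 0.012),
                        C = c(0.978, 0.968))
  rel <- diatomtf::relative_abundance(
    tibble::tibble(site = rel$site, A = rel$A * 500, B = rel$B * 500,
                   C = rel$C * 500))
  f <- rare_taxon_filter(rel, min_pct = 1, min_occurrences = 2)
  expect_setequal(setdiff(names(f), "site"), c("A", "C"))
  expect_setequal(attr(f, "filter_report")$dropped, "B")

  f1 <- rare_taxon_filter(rel, min_pct = 1, min_occurrences = 1)
  expect_setequal(setdiff(names(f1), "site"), c("A", "B", "C"))

  expect_error(rare_taxon_filter(rel, min_pct = 99, min_occurrences = 2),
               "all taxa dropped")
})

test_that("rare-taxon filter matches an exhaustive per-taxon check and is idempotent", {
  set.seed(42)
  m <- matrix(stats::rexp(20 * 12), 12, 20,
              dimnames = list(sprintf("s%d", 1:12), sprintf("t%d", 1:20)))
  counts <- tibble::as_tibble(m) |> tibble::add_column(site = rownames(m),
                                                       .before = 1)
  rel <- relative_abundance(counts)
  f <- rare_taxon_filter(rel, min_pct = 5, min_occurrences = 3)

  relm <- as.matrix(rel[-1])
  expected <- colnames(relm)[vapply(seq_len(ncol(relm)), function(k) {
    sum(relm[, k] >= 0.05) >= 3       # brute force over every taxon
  }, logical(1))]
  expect_setequal(setdiff(names(f), "site"), expected)

  f2 <- rare_taxon_filter(f, min_pct = 5, min_occurrences = 3)
  expect_equal(as.matrix(f2[-1]), as.matrix(f[-1]))
})

test_that("Hellinger transform yields unit row sums of squares and refuses to stack", {
  rel <- relative_abundance(toy_counts())
  h <- hellinger(rel)
  expect_equal(unname(as.matrix(h[-1])[1, ]),
               sqrt(c(0.25, 0.25, 0.5)), tolerance = 1e-12)
  expect_true(all(abs(rowSums(as.matrix(h[-1])^2) - 1) < 1e-12))
  expect_error(hellinger(h), "already Hellinger")

  one <- relative_abundance(tibble::tibble(site = "A", only = 400))
  expect_equal(as.numeric(as.matrix(hellinger(one)[-1])[1, 1]), 1)
})

test_that("environment transform logs skewed variables and standardizes all", {
  env <- tibble::tibble(site = sprintf("s%d", 1:8),
                        sym = c(1, 2, 3, 4, 5, 6, 7, 8),
                        skewed = c(0, 0, 0, 0, 0, 0, 0, 999))
  tr <- transform_env(env)
  lg <- attr(tr, "transform_log")
  expect_false(lg[["sym"]])
  expect_true(lg[["skewed"]])
  m <- as.matrix(tr[-1])
  expect_true(all(abs(colMeans(m)) < 1e-9))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-9))

  # log10(x+1) reduces the skewness it was triggered by
  set.seed(1)
  ln <- tibble::tibble(site = sprintf("s%d", 1:50),
                       v = stats::rlnorm(50, 0, 1.2), filler = rnorm(50))
  sk_before <- e1071::skewness(ln$v, type = 2)
  sk_after <- e1071::skewness(log10(ln$v + 1), type = 2)
  expect_lt(abs(sk_after), abs(sk_before))
  expect_true(attr(transform_env(ln), "transform_log")[["v"]])

  neg <- tibble::tibble(site = sprintf("s%d", 1:6),
                        v = c(-1, 0, 0, 0, 0, 50))
  expect_error(transform_env(neg), "'v'")
})
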