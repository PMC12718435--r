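# small in-code fixtures and independent oracles shared across the suite

toy_counts <- function() {
  tibble::tibble(site = c("A", "B", "C"),
                 tx1 = c(1, 10, 0), tx2 = c(1, 1, 2), tx3 = c(2, 489, 398))
}

# Gaussian-response community matrix built directly (no generator), for
# ordination fixtures: optima evenly spaced over x, common tolerance
gaussian_community <- function(x, n_taxa, tolerance, seed = 1) {
  set.seed(seed)
  opt <- seq(min(x), max(x), length.out = n_taxa)
  E <- exp(-outer(x, opt, "-")^2 / (2 * tolerance^2))
  P <- E / rowSums(E)
  m <- P + matrix(abs(rnorm(length(P), 0, 1e-3)), nrow(P))
  colnames(m) <- sprintf("t%02d", seq_len(n_taxa))
  rownames(m) <- sprintf("s%02d", seq_along(x))
  tibble::as_tibble(m, .name_repair = "minimal") |>
    tibble::add_column(site = rownames(m), .before = 1)
}

random_species <- function(n, m, seed) {
  set.seed(seed)
  mat <- matrix(stats::rexp(n * m), n, m,
                dimnames = list(sprintf("s%d", 1:n), sprintf("t%d", 1:m)))
  tibble::as_tibble(mat, .name_repair = "minimal") |>
    tibble::add_column(site = rownames(mat), .before = 1)
}

random_env <- function(n, vars, seed) {
  set.seed(seed + 1000)
  out <- tibble::tibble(site = sprintf("s%d", 1:n))
  for (v in vars) out[[v]] <- rnorm(n)
  out
}

# Brute-force RDA oracle: explicit projection matrices and a dense
# eigendecomposition, independent of the qr/svd path in the package.
brute_rda <- function(Y, X, Z = NULL) {
  ctr <- function(M) sweep(M, 2, colMeans(M))
  n <- nrow(Y)
  Yc <- ctr(Y); Xc <- ctr(X)
  if (!is.null(Z)) {
    Zc <- ctr(Z)
    Pz <- Zc %*% solve(crossprod(Zc)) %*% t(Zc)
    Yc <- Yc - Pz %*% Yc
    Xc <- Xc - Pz %*% Xc
  }
  Px <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  Fit <- Px %*% Yc
  Res <- Yc - Fit
  keep_pos <- function(v) v[v > 1e-10 * max(1, sum(Yc^2))] / (n - 1)
  list(eig_c = keep_pos(eigen(crossprod(Fit), symmetric = TRUE)$values),
       eig_u = keep_pos(eigen(crossprod(Res), symmetric = TRUE)$values),
       total = sum(Yc^2) / (n - 1))
}

expect_no_extra <- function(x) invisible(x)  # readability shim
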