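#' Group redundant environmental variables by correlation
#'
#' Computes Pearson r and its two-sided p (t distribution, n - 2 df) for all
#' variable pairs, links pairs with |r| > `threshold_r` and p < `threshold_p`,
#' and returns the connected components of the link graph: each component is a
#' group of mutually redundant variables from which screening retains one
#' representative. Constant columns are excluded with a warning.
#'
#' @param env Environment tibble (`site` column plus variables).
#' @param threshold_r,threshold_p Link thresholds.
#' @return A `correlation_groups` object: `assignment` tibble
#'   (variable, group), `groups` list, `pairs` tibble with r and p.
#' @export
correlation_groups <- function(env, threshold_r = 0.8, threshold_p = 0.001) {
  m <- comm_matrix(env, "environment table")
  n <- nrow(m)
  if (n < 3) abort("need at least 3 sites for correlation screening")
  const <- apply(m, 2, sd) == 0
  if (any(const)) {
    warn(sprintf("excluding constant variable(s): %s",
                 paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
  }
  vars <- colnames(m)
  R <- cor(m)
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(-abs(tstat), df = n - 2)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- tibble::tibble(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                          r = R[idx], p = P[idx],
                          linked = abs(R[idx]) > threshold_r & P[idx] < threshold_p)
  # connected components by label propagation over the link edges
  comp <- seq_along(vars); names(comp) <- vars
  repeat {
    changed <- FALSE
    for (e in which(pairs$linked)) {
      a <- pairs$var1[e]; b <- pairs$var2[e]
      lab <- min(comp[a], comp[b])
      if (comp[a] != lab || comp[b] != lab) {
        comp[comp == comp[a] | comp == comp[b]] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  group_id <- match(comp, sort(unique(comp)))
  assignment <- tibble::tibble(variable = vars, group = group_id)
  groups <- split(assignment$variable, assignment$group)
  structure(list(assignment = assignment, groups = unname(groups),
                 pairs = pairs, threshold_r = threshold_r,
                 threshold_p = threshold_p),
            class = "correlation_groups")
}

#' @export
print.correlation_groups <- function(x, ...) {
  multi <- Filter(function(g) length(g) > 1, x$groups)
  cat(sprintf("<correlation_groups> |r| > %s, p < %s: %d group(s), %d with >1 member\n",
              x$threshold_r, x$threshold_p, length(x$groups), length(multi)))
  for (g in multi) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

# ---- RDA internals ---------------------------------------------------------

# residualize columns of Y on Z (with intercept); Z NULL -> just centre
resid_on <- function(Y, Z = NULL) {
  Y <- scale(Y, scale = FALSE)
  if (is.null(Z) || ncol(Z) == 0) return(Y)
  Z <- scale(Z, scale = FALSE)
  qr.resid(qr(Z), Y)
}

# drop constraint columns that the covariates absorbed entirely: their
# residual is numerical noise and must not define a projection direction
drop_null_cols <- function(Xr, X) {
  ref <- sqrt(colSums(scale(X, scale = FALSE)^2))
  keep <- sqrt(colSums(Xr^2)) > 1e-8 * pmax(ref, .Machine$double.eps)
  Xr[, keep, drop = FALSE]
}

# constrained/residual sums of squares for a fast permutation loop;
# X and Y are already centred (and residualized on covariates)
rda_inertia <- function(Y, X) {
  if (ncol(X) == 0) {
    return(list(constrained = 0, residual = sum(Y^2), rank = 0L,
                fitted = Y * 0))
  }
  qx <- qr(X)
  fit <- qr.fitted(qx, Y)
  list(constrained = sum(fit^2), residual = sum((Y - fit)^2),
       rank = qx$rank, fitted = fit)
}

build_xz <- function(env, constraints, covariates) {
  m <- comm_matrix(env, "environment table")
  miss <- setdiff(c(constraints, covariates), colnames(m))
  if (length(miss)) abort(sprintf("unknown variable(s): %s",
                                  paste(miss, collapse = ", ")))
  if (length(intersect(constraints, covariates))) {
    abort("constraints and covariates must be disjoint")
  }
  list(X = m[, constraints, drop = FALSE],
       Z = if (length(covariates)) m[, covariates, drop = FALSE])
}

#' Redundancy analysis (RDA), optionally partial
#'
#' Species columns are centred (after residualization on the covariates when
#' given); the constrained axes are the principal components of the fitted
#' values of the multivariate regression of species on the constraints, and
#' the residual axes the principal components of the regression residuals.
#' Eigenvalues use the sum-of-squares/(n-1) convention; axis variance
#' fractions are percentages of the covariate-adjusted total. The grand total
#' (before covariate adjustment) is kept so partial models can be reported on
#' the total-variance scale.
#'
#' @param species Community tibble (Hellinger-transformed for the standard
#'   workflow, but any centred-scale matrix is accepted).
#' @param env Environment tibble sharing the site ordering.
#' @param constraints Character vector of constraining variables.
#' @param covariates Optional character vector of conditioning variables.
#' @return An `rda_fit` object.
#' @export
rda_fit <- function(species, env, constraints, covariates = NULL) {
  Y <- comm_matrix(species, "species table")
  check_sites_match(rownames(Y), env$site, "species and environment tables")
  xz <- build_xz(env, constraints, covariates)
  n <- nrow(Y)
  grand_total <- sum(scale(Y, scale = FALSE)^2) / (n - 1)
  # collinearity among the constraints themselves is a user error; a
  # constraint absorbed entirely by the covariates just explains nothing
  qc <- qr(scale(xz$X, scale = FALSE))
  if (qc$rank < ncol(xz$X)) {
    abort(sprintf("collinear constraint set (rank %d < %d): %s", qc$rank,
                  ncol(xz$X), paste(constraints, collapse = ", ")))
  }
  Yr <- resid_on(Y, xz$Z)
  Xr <- drop_null_cols(resid_on(xz$X, xz$Z), xz$X)
  ii <- rda_inertia(Yr, Xr)
  fit <- ii$fitted
  resid <- Yr - fit
  tol <- 1e-10 * max(1, sum(Yr^2))
  svc <- svd(fit); svu <- svd(resid)
  eig_c <- (svc$d^2 / (n - 1)); eig_c <- eig_c[svc$d^2 > tol]
  eig_u <- (svu$d^2 / (n - 1)); eig_u <- eig_u[svu$d^2 > tol]
  total <- sum(Yr^2) / (n - 1)
  kc <- length(eig_c); ku <- length(eig_u)
  site_scores <- svc$u[, seq_len(kc), drop = FALSE] %*%
    diag(svc$d[seq_len(kc)], kc)
  species_scores <- svc$v[, seq_len(kc), drop = FALSE]
  rownames(site_scores) <- rownames(Y)
  rownames(species_scores) <- colnames(Y)
  biplot <- if (kc > 0 && ncol(Xr) > 0) cor(Xr, site_scores) else NULL
  structure(list(
    eig_constrained = eig_c, eig_unconstrained = eig_u,
    total = total, grand_total = grand_total,
    frac_constrained = 100 * eig_c / total,
    frac_unconstrained = 100 * eig_u / total,
    site_scores = site_scores, species_scores = species_scores,
    biplot_scores = biplot,
    constraints = constraints, covariates = covariates %||% character(),
    n = n, rank_constraints = ii$rank),
    class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("<rda_fit> %s%s\n", paste(x$constraints, collapse = " + "),
              if (length(x$covariates))
                paste0(" | ", paste(x$covariates, collapse = " + ")) else ""))
  cat(sprintf("  constrained: %.1f%% of adjusted total on %d axis/axes\n",
              sum(x$frac_constrained), length(x$eig_constrained)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rda_fit <- function(x, ...) {
  tibble::tibble(
    axis = c(paste0("RDA", seq_along(x$eig_constrained)),
             paste0("PC", seq_along(x$eig_unconstrained))),
    component = rep(c("constrained", "unconstrained"),
                    c(length(x$eig_constrained), length(x$eig_unconstrained))),
    eigenvalue = c(x$eig_constrained, x$eig_unconstrained),
    variance_pct = c(x$frac_constrained, x$frac_unconstrained))
}

#' @exportS3Method generics::glance
glance.rda_fit <- function(x, ...) {
  tibble::tibble(n = x$n,
                 n_constraints = length(x$constraints),
                 n_covariates = length(x$covariates),
                 constrained_pct = sum(x$frac_constrained),
                 total = x$total, grand_total = x$grand_total)
}

#' Monte Carlo permutation test for (partial) RDA
#'
#' The pseudo-F is `(constrained/q) / (residual/(n - q - pcov - 1))`; the null
#' distribution is built by unrestricted random permutation of the site labels
#' of the constraint columns while the covariates stay fixed, and
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @inheritParams rda_fit
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation stream.
#' @return A one-row tibble: `pseudo_f`, `p`, `q`, `n_perm`.
#' @export
permutation_test <- function(species, env, constraints, covariates = NULL,
                             n_perm = 999, seed = 1) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  Y <- comm_matrix(species, "species table")
  xz <- build_xz(env, constraints, covariates)
  n <- nrow(Y)
  Yr <- resid_on(Y, xz$Z)
  pcov <- if (is.null(xz$Z)) 0L else qr(scale(xz$Z, scale = FALSE))$rank
  f_of <- function(X) {
    ii <- rda_inertia(Yr, drop_null_cols(resid_on(X, xz$Z), X))
    q <- ii$rank
    if (q == 0) return(0)
    (ii$constrained / q) / (ii$residual / (n - q - pcov - 1))
  }
  f_obs <- f_of(xz$X)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm),
                   function(i) f_of(xz$X[sample.int(n), , drop = FALSE]),
                   numeric(1))
  Xr0 <- drop_null_cols(resid_on(xz$X, xz$Z), xz$X)
  tibble::tibble(pseudo_f = f_obs,
                 p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 q = if (ncol(Xr0)) qr(Xr0)$rank else 0L, n_perm = n_perm)
}

#' Forward selection of constraining variables
#'
#' At each step the candidate adding the most explained variance, among those
#' whose conditional permutation test (already-selected variables plus any
#' covariates as conditioning set) gives p <= `alpha`, joins the model; the
#' loop stops when no candidate qualifies. Ties on added variance break
#' lexicographically so runs are reproducible. An empty selection is a valid
#' outcome.
#'
#' @inheritParams permutation_test
#' @param candidates Character vector of candidate variables.
#' @param alpha Inclusion threshold for the permutation p value.
#' @return A `selection_report` tibble of selected variables (step, added
#'   variance as % of the covariate-adjusted total, pseudo-F, p) with the
#'   rejected candidates in the `rejected` attribute.
#' @export
forward_select <- function(species, env, candidates, covariates = NULL,
                           alpha = 0.01, n_perm = 999, seed = 1) {
  if (length(candidates) == 0) abort("candidates must be non-empty")
  Y <- comm_matrix(species, "species table")
  n <- nrow(Y)
  xz0 <- build_xz(env, candidates, covariates)
  total <- sum(resid_on(Y, xz0$Z)^2) / (n - 1)
  selected <- character()
  rows <- list()
  remaining <- sort(candidates)
  step <- 1L
  while (length(remaining)) {
    stats <- purrr::map_dfr(remaining, function(v) {
      pt <- permutation_test(species, env, constraints = v,
                             covariates = c(selected, covariates %||% character()),
                             n_perm = n_perm,
                             seed = stage_seed(seed, paste0("fs", step, v)))
      m <- comm_matrix(env, "env")
      Z <- if (length(c(selected, covariates)))
        m[, c(selected, covariates), drop = FALSE]
      ii <- rda_inertia(resid_on(Y, Z), resid_on(m[, v, drop = FALSE], Z))
      tibble::tibble(variable = v, added_pct = 100 * ii$constrained / (n - 1) / total,
                     pseudo_f = pt$pseudo_f, p = pt$p)
    })
    ok <- stats[stats$p <= alpha, , drop = FALSE]
    if (nrow(ok) == 0) break
    pick <- ok[order(-ok$added_pct, ok$variable), ][1, ]
    pick$step <- step
    rows[[step]] <- pick
    selected <- c(selected, pick$variable)
    remaining <- setdiff(remaining, pick$variable)
    step <- step + 1L
  }
  out <- if (length(rows)) dplyr::bind_rows(rows)[, c("step", "variable",
                                                      "added_pct", "pseudo_f", "p")]
  else tibble::tibble(step = integer(), variable = character(),
                      added_pct = numeric(), pseudo_f = numeric(), p = numeric())
  attr(out, "rejected") <- tibble::tibble(variable = remaining,
                                          reason = rep("non-significant",
                                                       length(remaining)))
  class(out) <- c("selection_report", class(out))
  out
}

#' Test whether two selected variables explain independent variance
#'
#' Each variable is tested with the other as covariate; a variable that loses
#' significance once the other is conditioned on is declared dependent on it.
#' For a dependent pair the variable with the larger marginal explained
#' variance is retained (lexicographic tie-break).
#'
#' @inheritParams permutation_test
#' @param varA,varB The two variables (must differ).
#' @param alpha Significance level for the conditional tests.
#' @return A list: `verdict` ("independent"/"dependent"), `retain`, and a
#'   `detail` tibble with marginal and conditional shares.
#' @export
independence_test <- function(species, env, varA, varB, covariates = NULL,
                              alpha = 0.01, n_perm = 999, seed = 1) {
  if (identical(varA, varB)) abort("varA and varB must differ")
  one <- function(v, other, tag) {
    marg <- rda_fit(species, env, constraints = v, covariates = covariates)
    cond <- permutation_test(species, env, constraints = v,
                             covariates = c(other, covariates %||% character()),
                             n_perm = n_perm, seed = stage_seed(seed, tag))
    tibble::tibble(variable = v, conditioned_on = other,
                   marginal_pct = sum(marg$frac_constrained),
                   conditional_p = cond$p,
                   conditional_f = cond$pseudo_f)
  }
  detail <- dplyr::bind_rows(one(varA, varB, "ab"), one(varB, varA, "ba"))
  dep <- any(detail$conditional_p > alpha)
  retain <- if (dep) {
    detail$variable[order(-detail$marginal_pct, detail$variable)][1]
  } else NA_character_
  list(verdict = if (dep) "dependent" else "independent",
       retain = retain, detail = detail, alpha = alpha)
}

#' Per-variable variance partition via partial RDA
#'
#' For each selected variable, a partial RDA with that variable as the sole
#' constraint and (by default) all other selected variables plus the
#' covariates as conditioning set gives its conditional explained variance.
#' Percentages are on the total-variance scale so the joint, covariate and
#' total explained shares decompose the assemblage variance the way a
#' screening table reports it.
#'
#' @inheritParams permutation_test
#' @param selected Character vector of retained variables.
#' @param conditioning `"others_plus_covariates"` (default) conditions each
#'   variable on the remaining selected variables and the covariates;
#'   `"covariates_only"` conditions on the covariates alone.
#' @return A `variance_partition` tibble (variable, variance %, RDA1 %,
#'   PC1 %, lambda ratio, p) with joint/covariate/total shares as attributes.
#' @export
variance_partition <- function(species, env, selected, covariates = NULL,
                               conditioning = c("others_plus_covariates",
                                                "covariates_only"),
                               n_perm = 999, seed = 1) {
  if (length(selected) == 0) abort("selected must be non-empty")
  conditioning <- match.arg(conditioning)
  rows <- purrr::map_dfr(selected, function(v) {
    conds <- switch(conditioning,
                    others_plus_covariates = c(setdiff(selected, v),
                                               covariates %||% character()),
                    covariates_only = covariates %||% character())
    if (length(conds) == 0) conds <- NULL
    fit <- rda_fit(species, env, constraints = v, covariates = conds)
    pt <- permutation_test(species, env, constraints = v, covariates = conds,
                           n_perm = n_perm, seed = stage_seed(seed, v))
    scale_pct <- 100 / fit$grand_total
    l1 <- if (length(fit$eig_constrained)) fit$eig_constrained[1] else 0
    tibble::tibble(
      variable = v,
      variance_pct = sum(fit$eig_constrained) * scale_pct,
      rda1_pct = l1 * scale_pct,
      pc1_pct = fit$eig_unconstrained[1] * scale_pct,
      lambda_ratio = eig_ratio(l1, fit$eig_unconstrained[1]),
      p = pt$p)
  })
  # the joint fit tolerates redundant selections: reduce to an independent
  # subset (pivoted QR) so duplicated variables do not abort the summary
  Xall <- comm_matrix(env, "env")[, selected, drop = FALSE]
  qp <- qr(scale(Xall, scale = FALSE), LAPACK = FALSE)
  indep <- selected[sort(qp$pivot[seq_len(qp$rank)])]
  joint <- rda_fit(species, env, constraints = indep, covariates = covariates)
  attr(rows, "joint_constrained_pct") <-
    sum(joint$eig_constrained) / joint$grand_total * 100
  attr(rows, "covariate_pct") <-
    (joint$grand_total - joint$total) / joint$grand_total * 100
  attr(rows, "total_explained_pct") <-
    attr(rows, "joint_constrained_pct") + attr(rows, "covariate_pct")
  class(rows) <- c("variance_partition", class(rows))
  rows
}

#' Eigenvalue ratio of a constrained axis over the first residual axis
#'
#' The ratio of the variance carried by the single constrained axis to that of
#' the first unconstrained (residual) axis of the same partial model. A ratio
#' above 0.5 is the conventional signal that the variable structures the
#' assemblage strongly enough to calibrate against.
#'
#' @param lambda1,lambda2 Variance of the constrained axis and of the first
#'   residual axis, in any common unit (raw eigenvalues or percentages).
#' @return `lambda1 / lambda2`.
#' @export
eig_ratio <- function(lambda1, lambda2) {
  if (any(lambda2 <= 0)) abort("first residual eigenvalue is zero")
  lambda1 / lambda2
}

#' lambda1/lambda2 screening of a single variable
#'
#' Fits a partial RDA with `variable` as the sole constraint and reports the
#' first constrained and first residual axis shares together with their ratio
#' and the `usable_for_calibration` flag (ratio > 0.5).
#'
#' @inheritParams rda_fit
#' @param variable Single variable name.
#' @return One-row tibble: variable, rda1_pct, pc1_pct, ratio, flag.
#' @export
lambda_ratio <- function(species, env, variable, covariates = NULL) {
  stopifnot(length(variable) == 1)
  fit <- rda_fit(species, env, constraints = variable, covariates = covariates)
  l1 <- if (length(fit$eig_constrained)) fit$eig_constrained[1] else 0
  if (length(fit$eig_unconstrained) == 0) {
    abort("no residual axis: first unconstrained eigenvalue is zero")
  }
  l2 <- fit$eig_unconstrained[1]
  r <- eig_ratio(l1, l2)
  tibble::tibble(variable = variable,
                 rda1_pct = 100 * l1 / fit$grand_total,
                 pc1_pct = 100 * l2 / fit$grand_total,
                 ratio = r,
                 usable_for_calibration = r > 0.5)
}

#' Gradient length by detrended correspondence analysis
#'
#' Runs DCA (correspondence analysis with detrending by segments, optional
#' nonlinear rescaling) and returns the length of the first axis in species
#' turnover (SD) units. Lengths under 2 SD indicate that species responses are
#' close to monotone over the gradient and linear ordination (RDA) is the
#' appropriate constrained method.
#'
#' @param species Community tibble (non-negative values).
#' @param n_segments Number of detrending segments.
#' @param rescale Apply nonlinear rescaling (recommended; lengths are then in
#'   SD units).
#' @return One-row tibble: `gradient_length`, `recommendation`.
#' @export
dca_gradient_length <- function(species, n_segments = 26, rescale = TRUE) {
  m <- comm_matrix(species, "species table")
  if (nrow(m) < 3 || ncol(m) < 2) abort("need at least 3 sites and 2 taxa")
  if (any(rowSums(m) <= 0) || any(colSums(m) <= 0)) {
    abort("all-zero rows or columns are not allowed in DCA")
  }
  prof <- m / rowSums(m)
  if (max(apply(prof, 2, function(c) diff(range(c)))) < 1e-12) {
    return(tibble::tibble(gradient_length = 0, recommendation = "RDA"))
  }
  if (qr(scale(prof, scale = FALSE))$rank < 2) {
    abort("degenerate species matrix (rank < 2)")
  }
  dca <- vegan::decorana(m, ira = 0, iresc = if (rescale) 4 else 0,
                         mk = n_segments)
  sc <- vegan::scores(dca, display = "sites", choices = 1)
  len <- diff(range(sc))
  tibble::tibble(gradient_length = len,
                 recommendation = if (len < 2) "RDA" else "CCA")
}
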