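# ---- matrix-level cores ----------------------------------------------------
# All fitting happens here on plain matrices; the exported functions wrap
# these with tibble I/O. The leave-one-out and RNE loops call the cores
# directly to avoid per-fold data-frame overhead.

responses_core <- function(Y, x) {
  S1 <- colSums(Y)
  if (any(S1 <= 0)) {
    abort(sprintf("all-zero taxon: %s", colnames(Y)[which(S1 <= 0)[1]]))
  }
  opt <- unname(as.vector(crossprod(Y, x)) / S1)
  ex2 <- unname(as.vector(crossprod(Y, x^2)) / S1)
  tol <- sqrt(pmax(ex2 - opt^2, 0))
  n2 <- unname(S1^2 / colSums(Y^2))
  occ <- unname(colSums(Y > 0))
  list(taxa = colnames(Y), optimum = opt, tolerance = tol, n2 = n2,
       occurrences = occ)
}

# floor for tolerance down-weighting: zero tolerances (single effective
# occurrence) would otherwise give infinite weight
tstar_of <- function(resp, x, eps = 0.01) {
  span <- diff(range(x))
  ts <- pmax(resp$tolerance, eps * span)
  single <- resp$occurrences <= 1
  if (any(single)) {
    fill <- if (all(single)) 0.25 * span else mean(ts[!single])
    ts[single] <- fill
  }
  ts
}

wa_core <- function(Y, x, deshrink = "inverse", tolerance_dw = FALSE) {
  resp <- responses_core(Y, x)
  w <- if (tolerance_dw) 1 / tstar_of(resp, x)^2 else rep(1, ncol(Y))
  x0 <- as.vector(Y %*% (resp$optimum * w)) / as.vector(Y %*% w)
  if (sd(x0) < 1e-12) abort("degenerate deshrinking: initial estimates have zero variance")
  if (deshrink == "inverse") {
    b <- cov(x0, x) / var(x0)
    a <- mean(x) - b * mean(x0)
    fitted <- a + b * x0
  } else {
    d <- cov(x, x0) / var(x)
    c0 <- mean(x0) - d * mean(x)
    fitted <- (x0 - c0) / d
    a <- c0; b <- d
  }
  c(resp, list(weights = w, deshrink = deshrink, tolerance_dw = tolerance_dw,
               coef = c(intercept = a, slope = b), x0 = x0, fitted = fitted,
               x = x, gradient = range(x)))
}

wa_predict_core <- function(fit, Ynew) {
  num <- as.vector(Ynew %*% (fit$optimum * fit$weights))
  den <- as.vector(Ynew %*% fit$weights)
  x0 <- ifelse(den > 0, num / den, NA_real_)
  a <- fit$coef[["intercept"]]; b <- fit$coef[["slope"]]
  if (fit$deshrink == "inverse") a + b * x0 else (x0 - a) / b
}

wapls_core <- function(Y, x, n_components) {
  if (n_components < 1) abort("n_components must be at least 1")
  csum <- colSums(Y)
  if (any(csum <= 0)) {
    abort(sprintf("all-zero taxon: %s", colnames(Y)[which(csum <= 0)[1]]))
  }
  n <- nrow(Y)
  P <- Y / rowSums(Y)
  if (sd_pop(x) < 1e-12) {
    # constant target: every component is degenerate, predict the constant
    return(list(taxa = colnames(Y), scores = matrix(0, ncol(Y), 0),
                b0 = mean(x), b = numeric(0), fitted = rep(mean(x), n),
                n_components = 0L, x = x, gradient = range(x)))
  }
  scores <- matrix(0, ncol(Y), 0)
  Tmat <- matrix(0, n, 0)
  e <- x - mean(x)
  b <- numeric(0)
  for (a in seq_len(n_components)) {
    u <- as.vector(crossprod(Y, e)) / csum
    t_raw <- as.vector(P %*% u)
    ut <- u
    if (a > 1) {
      # fold the Gram-Schmidt step back into the taxon scores so that every
      # component stays an exact weighted average of stored scores
      alpha <- as.vector(crossprod(Tmat, t_raw)) / n
      t_raw <- t_raw - as.vector(Tmat %*% alpha)
      ut <- ut - as.vector(scores %*% alpha)
    }
    mcen <- mean(t_raw)
    t_c <- t_raw - mcen
    s <- sd_pop(t_c)
    if (s < 1e-9 * max(1, sd_pop(x))) {
      abort(sprintf("requested components exceed usable rank; maximum usable is %d",
                    a - 1L))
    }
    t_c <- t_c / s
    ut <- (ut - mcen) / s
    Tmat <- cbind(Tmat, t_c)
    scores <- cbind(scores, ut)
    b <- as.vector(crossprod(Tmat, x)) / n  # components are orthonormal in 1/n
    e <- x - (mean(x) + as.vector(Tmat %*% b))
  }
  fitted <- mean(x) + as.vector(Tmat %*% b)
  colnames(scores) <- paste0("comp", seq_len(ncol(scores)))
  rownames(scores) <- colnames(Y)
  list(taxa = colnames(Y), scores = scores, b0 = mean(x), b = b,
       fitted = fitted, n_components = ncol(scores), x = x,
       gradient = range(x))
}

wapls_predict_core <- function(fit, Ynew) {
  rs <- rowSums(Ynew)
  if (fit$n_components == 0) {
    return(ifelse(rs > 0, fit$b0, NA_real_))
  }
  P <- Ynew / ifelse(rs > 0, rs, 1)
  pred <- fit$b0 + as.vector((P %*% fit$scores) %*% fit$b)
  ifelse(rs > 0, pred, NA_real_)
}

# ---- exported API ----------------------------------------------------------

#' Weighted-averaging optima, tolerances and effective occurrences
#'
#' For each taxon: the optimum is the abundance-weighted mean of the
#' environmental variable over the training sites, the tolerance the
#' abundance-weighted SD, and N2 Hill's effective number of occurrences
#' `(sum y)^2 / sum y^2`. Taxa with low N2 have optima supported by few
#' effective sites and should be interpreted with care.
#'
#' @param species Community tibble (counts, proportions or Hellinger values).
#' @param x Numeric environmental vector aligned with the rows.
#' @param n2_correct Apply the `1/sqrt(1 - 1/N2)` small-sample inflation to
#'   tolerances (off by default).
#' @return A tibble: taxon, optimum, tolerance, n2, occurrences.
#' @export
estimate_responses <- function(species, x, n2_correct = FALSE) {
  Y <- comm_matrix(species, "species table")
  stopifnot(length(x) == nrow(Y))
  r <- responses_core(Y, x)
  tol <- r$tolerance
  if (n2_correct) {
    ok <- r$n2 > 1
    tol[ok] <- tol[ok] / sqrt(1 - 1 / r$n2[ok])
  }
  tibble::tibble(taxon = r$taxa, optimum = r$optimum, tolerance = tol,
                 n2 = r$n2, occurrences = as.integer(r$occurrences))
}

#' Fit a weighted-averaging transfer function
#'
#' Site estimates are abundance-weighted means of taxon optima (optionally
#' down-weighting taxa by the inverse square of their tolerance), then
#' deshrunk: inverse deshrinking regresses the observations on the estimates,
#' classical deshrinking regresses the estimates on the observations and
#' inverts the line. Both regressions use equal site weights (ordinary least
#' squares), which keeps a one-component WAPLS and inverse-deshrunk WA
#' numerically identical.
#'
#' @param species Community tibble.
#' @param x Environmental vector aligned with the rows.
#' @param deshrink `"inverse"` or `"classical"`.
#' @param tolerance_dw Down-weight taxa by 1/tolerance^2.
#' @return A `wa_model`.
#' @export
fit_wa <- function(species, x, deshrink = c("inverse", "classical"),
                   tolerance_dw = FALSE) {
  deshrink <- match.arg(deshrink)
  Y <- comm_matrix(species, "species table")
  stopifnot(length(x) == nrow(Y))
  if (nrow(Y) < 3) abort("need at least 3 sites")
  core <- wa_core(Y, x, deshrink, tolerance_dw)
  structure(c(core, list(sites = rownames(Y),
                         transform = transform_state(species))),
            class = "wa_model")
}

#' Fit a weighted-averaging partial least squares (WAPLS) transfer function
#'
#' Components are built by weighted averaging of the running residual of the
#' target variable: taxon scores are column-weighted averages of the
#' residual, site scores are row-weighted averages of the taxon scores, each
#' new component is orthogonalized against the previous ones and standardized,
#' and the target is regressed on all components to date. The orthogonalized,
#' standardized taxon-score chain is stored so prediction for new assemblages
#' applies the identical linear map. The first component with this equal-site-
#' weight regression reproduces inverse-deshrunk WA exactly.
#'
#' @inheritParams fit_wa
#' @param n_components Number of WAPLS components (>= 1, below the usable
#'   rank of the species matrix).
#' @return A `wapls_model`.
#' @export
fit_wapls <- function(species, x, n_components = 2) {
  Y <- comm_matrix(species, "species table")
  stopifnot(length(x) == nrow(Y))
  core <- wapls_core(Y, x, n_components)
  structure(c(core, list(sites = rownames(Y),
                         transform = transform_state(species))),
            class = "wapls_model")
}

align_new_matrix <- function(taxa, newdata) {
  Yn <- comm_matrix(newdata, "new species table")
  unknown <- setdiff(colnames(Yn), taxa)
  if (length(unknown)) {
    warn(sprintf("%d taxa absent from the training set dropped: %s%s",
                 length(unknown), paste(head(unknown, 5), collapse = ", "),
                 if (length(unknown) > 5) ", ..." else ""))
  }
  tot <- rowSums(Yn)
  A <- matrix(0, nrow(Yn), length(taxa), dimnames = list(rownames(Yn), taxa))
  shared <- intersect(taxa, colnames(Yn))
  A[, shared] <- Yn[, shared]
  coverage <- unname(ifelse(tot > 0, rowSums(A) / tot, 0))
  list(Y = A, coverage = coverage)
}

predict_model <- function(object, newdata, core_fn) {
  al <- align_new_matrix(object$taxa, newdata)
  pred <- core_fn(object, al$Y)
  bad <- al$coverage <= 0
  if (any(bad)) {
    warn(sprintf("%d site(s) have zero training-taxon coverage; predictions flagged NA",
                 sum(bad)))
    pred[bad] <- NA_real_
  }
  tibble::tibble(site = rownames(al$Y), pred = as.vector(pred),
                 coverage = al$coverage)
}

#' Predict the environment from new assemblages
#'
#' Taxa unknown to the training set are dropped with a warning; the reported
#' `coverage` is the fraction of each new assemblage (by value) represented
#' by training taxa. Sites with zero coverage get an `NA` prediction rather
#' than a silently extrapolated number.
#'
#' @param object A fitted `wa_model`.
#' @param newdata Community tibble on the training taxon codes (extra taxa
#'   are dropped).
#' @param ... Unused.
#' @return A tibble: site, pred, coverage.
#' @export
predict.wa_model <- function(object, newdata, ...) {
  predict_model(object, newdata, wa_predict_core)
}

#' @rdname predict.wa_model
#' @export
predict.wapls_model <- function(object, newdata, ...) {
  predict_model(object, newdata, wapls_predict_core)
}

#' @export
print.wa_model <- function(x, ...) {
  cat(sprintf("<wa_model> %s deshrinking%s; %d taxa, %d sites, gradient %.2f-%.2f\n",
              x$deshrink, if (x$tolerance_dw) " + tolerance down-weighting" else "",
              length(x$taxa), length(x$x), x$gradient[1], x$gradient[2]))
  invisible(x)
}

#' @export
print.wapls_model <- function(x, ...) {
  cat(sprintf("<wapls_model> %d component(s); %d taxa, %d sites, gradient %.2f-%.2f\n",
              x$n_components, length(x$taxa), length(x$x),
              x$gradient[1], x$gradient[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wa_model <- function(x, ...) {
  tibble::tibble(taxon = x$taxa, optimum = x$optimum, tolerance = x$tolerance,
                 n2 = x$n2, occurrences = as.integer(x$occurrences),
                 weight = x$weights)
}

#' @exportS3Method generics::tidy
tidy.wapls_model <- function(x, ...) {
  if (x$n_components == 0) {
    return(tibble::tibble(taxon = character(), component = integer(),
                          score = numeric()))
  }
  tibble::as_tibble(x$scores, rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "component", values_to = "score") |>
    dplyr::mutate(component = as.integer(sub("comp", "", .data$component)))
}

#' @exportS3Method generics::glance
glance.wa_model <- function(x, ...) {
  performance_stats(x$x, x$fitted)
}

#' @exportS3Method generics::glance
glance.wapls_model <- function(x, ...) {
  performance_stats(x$x, x$fitted)
}

#' Serialize a calibration model to JSON
#'
#' Writes all coefficients (taxon scores or optima, deshrinking/regression
#' parameters, gradient summary) to a versioned JSON document that
#' [read_model()] restores.
#'
#' @param model A `wa_model` or `wapls_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  fields <- unclass(model)
  if (!is.null(fields$coef)) fields$coef <- as.list(fields$coef)
  if (!is.null(fields$scores)) {
    fields$scores <- list(nrow = nrow(model$scores), ncol = ncol(model$scores),
                          values = as.vector(model$scores))
  }
  doc <- list(format = "diatomtf-model", version = 1L,
              class = class(model)[1], fields = fields)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "diatomtf-model")) abort("not a diatomtf model file")
  f <- doc$fields
  for (nm in c("optimum", "tolerance", "n2", "occurrences", "weights",
               "x0", "fitted", "x", "gradient", "b")) {
    if (!is.null(f[[nm]])) f[[nm]] <- as.numeric(f[[nm]])
  }
  if (!is.null(f$coef)) f$coef <- unlist(f$coef)
  if (!is.null(f$scores)) {
    f$scores <- matrix(as.numeric(f$scores$values), nrow = f$scores$nrow,
                       ncol = f$scores$ncol, dimnames = list(f$taxa, NULL))
  }
  structure(f, class = doc$class)
}
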