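#' Describe a calibration model to be fitted
#'
#' A lightweight specification used by the cross-validation and
#' model-selection machinery, so a model can be refitted many times (once per
#' leave-one-out fold, per deletion scheme, per radius) from one description.
#'
#' @param type `"wa"` or `"wapls"`.
#' @param deshrink,tolerance_dw WA options (see [fit_wa()]).
#' @param n_components WAPLS component count.
#' @return A `model_spec`.
#' @export
model_spec <- function(type = c("wa", "wapls"),
                       deshrink = c("inverse", "classical"),
                       tolerance_dw = FALSE, n_components = 1) {
  type <- match.arg(type)
  deshrink <- match.arg(deshrink)
  structure(list(type = type, deshrink = deshrink,
                 tolerance_dw = tolerance_dw,
                 n_components = n_components), class = "model_spec")
}

spec_label <- function(spec) {
  if (spec$type == "wa") {
    paste0("WA_", if (spec$tolerance_dw) "tol_" else "",
           if (spec$deshrink == "inverse") "inv" else "cla")
  } else {
    sprintf("WAPLS(%d)", spec$n_components)
  }
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", spec_label(x), "\n")
  invisible(x)
}

#' Fit a model from a specification
#'
#' @param spec A [model_spec()].
#' @param species Community tibble.
#' @param x Environmental vector.
#' @return A fitted `wa_model` or `wapls_model`.
#' @export
fit_model <- function(spec, species, x) {
  if (spec$type == "wa") {
    fit_wa(species, x, deshrink = spec$deshrink,
           tolerance_dw = spec$tolerance_dw)
  } else {
    fit_wapls(species, x, n_components = spec$n_components)
  }
}

# matrix-level fit/predict used by all the resampling loops; taxa with no
# occurrence in the training rows are dropped for that fit
fit_core <- function(spec, Y, x) {
  keep <- colSums(Y) > 0
  Yk <- Y[, keep, drop = FALSE]
  if (ncol(Yk) == 0) return(NULL)
  if (spec$type == "wa") {
    fit <- wa_core(Yk, x, spec$deshrink, spec$tolerance_dw)
    list(taxa = colnames(Yk), predict = function(Yn)
      wa_predict_core(fit, Yn[, colnames(Yk), drop = FALSE]))
  } else {
    fit <- wapls_core(Yk, x, spec$n_components)
    list(taxa = colnames(Yk), predict = function(Yn)
      wapls_predict_core(fit, Yn[, colnames(Yk), drop = FALSE]))
  }
}

# leave-one-out predictions with per-fold training deletions (del_list[[i]]
# holds extra row indices to drop when predicting row i)
loo_core <- function(spec, Y, x, del_list = NULL) {
  n <- nrow(Y)
  pred <- rep(NA_real_, n)
  coverage <- rep(NA_real_, n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    drop <- unique(c(i, del_list[[i]]))
    if (length(drop) >= n) { flagged[i] <- TRUE; next }
    # a fold whose depleted training set cannot support the model (no shared
    # taxa, or too few sites for the requested rank) is flagged, not fatal
    ft <- tryCatch(fit_core(spec, Y[-drop, , drop = FALSE], x[-drop]),
                   error = function(e) NULL)
    if (is.null(ft)) { flagged[i] <- TRUE; next }
    yn <- Y[i, , drop = FALSE]
    tot <- sum(yn)
    coverage[i] <- if (tot > 0) sum(yn[, ft$taxa]) / tot else 0
    if (coverage[i] <= 0) { flagged[i] <- TRUE; next }
    pred[i] <- ft$predict(yn)
  }
  list(pred = pred, coverage = coverage, flagged = flagged)
}

#' Leave-one-out (jackknife) predictions
#'
#' Refits the full model -- taxon response estimation, deshrinking or WAPLS
#' regression included -- without each site in turn and predicts the held-out
#' site. Taxa absent from the reduced training set are dropped for that fold;
#' folds where the held-out assemblage shares nothing with the training taxa
#' are flagged rather than given a number.
#'
#' @param species Community tibble (>= 4 sites).
#' @param x Environmental vector.
#' @param spec A [model_spec()].
#' @return A tibble: site, observed, pred, coverage, flagged.
#' @export
loo_predictions <- function(species, x, spec = model_spec("wa")) {
  Y <- comm_matrix(species, "species table")
  if (nrow(Y) < 4) abort("need at least 4 sites for leave-one-out")
  stopifnot(length(x) == nrow(Y))
  r <- loo_core(spec, Y, x)
  tibble::tibble(site = rownames(Y), observed = x, pred = r$pred,
                 coverage = r$coverage, flagged = r$flagged)
}

#' Transfer-function performance statistics
#'
#' RMSE(P), squared Pearson correlation between predictions and observations,
#' average bias (mean residual), and maximum bias: the largest absolute mean
#' residual within equal-width segments of the gradient, which exposes
#' systematic over- or under-prediction at the gradient ends that a global
#' mean hides.
#'
#' @param observed,predicted Equal-length numeric vectors (NA pairs dropped;
#'   at least 3 finite pairs required).
#' @param n_segments Number of equal-width gradient segments for max bias.
#' @return A one-row tibble: rmse, r2, avg_bias, max_bias, n, n_segments.
#' @export
performance_stats <- function(observed, predicted, n_segments = 10) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3) abort("need at least 3 finite observation/prediction pairs")
  o <- observed[ok]; p <- predicted[ok]
  res <- p - o
  r2 <- if (sd(o) == 0) {
    warn("observed values have zero variance; r2 undefined")
    NA_real_
  } else if (sd(p) == 0) 0 else cor(o, p)^2
  brk <- seq(min(o), max(o), length.out = n_segments + 1)
  seg <- if (diff(range(o)) == 0) rep(1L, length(o)) else
    cut(o, breaks = brk, include.lowest = TRUE, labels = FALSE)
  seg_bias <- tapply(res, seg, mean)  # empty segments never appear in tapply
  tibble::tibble(rmse = sqrt(mean(res^2)), r2 = r2, avg_bias = mean(res),
                 max_bias = max(abs(seg_bias)), n = sum(ok),
                 n_segments = n_segments)
}

default_model_grid <- function() {
  list(model_spec("wa", "inverse"),
       model_spec("wa", "classical"),
       model_spec("wa", "inverse", tolerance_dw = TRUE),
       model_spec("wa", "classical", tolerance_dw = TRUE),
       model_spec("wapls", n_components = 1),
       model_spec("wapls", n_components = 2),
       model_spec("wapls", n_components = 3))
}

#' Model-selection grid with apparent and leave-one-out performance
#'
#' Evaluates a grid of calibration models (by default the seven standard
#' ones: WA with inverse/classical deshrinking, with and without tolerance
#' down-weighting, and WAPLS with 1-3 components) under each requested
#' transformation, reporting apparent RMSE/r2 and cross-validated
#' RMSEP/r2_jack/average/maximum bias. The `selected` column marks the best
#' model by the documented lexicographic rule: highest r2_jack, then lowest
#' RMSEP, then lowest maximum bias. The full grid is always returned so the
#' analyst can override the rule.
#'
#' @param species Community tibble of untransformed proportions.
#' @param x Environmental vector.
#' @param specs List of [model_spec()]s.
#' @param transforms Subset of `c("hellinger", "none")`.
#' @param n_segments Segments for maximum bias.
#' @return A `model_selection` tibble.
#' @export
model_selection_table <- function(species, x, specs = default_model_grid(),
                                  transforms = c("hellinger", "none"),
                                  n_segments = 10) {
  if (length(specs) == 0) abort("need at least one model spec")
  P <- comm_matrix(species, "species table")
  P <- P / rowSums(P)
  rows <- purrr::map_dfr(transforms, function(tr) {
    Yt <- if (tr == "hellinger") sqrt(P) else P
    Yt_tbl <- set_transform_state(comm_tibble(Yt), tr)
    purrr::map_dfr(specs, function(sp) {
      fit <- fit_model(sp, Yt_tbl, x)
      app <- performance_stats(x, fit$fitted, n_segments)
      cv <- loo_core(sp, Yt, x)
      cvs <- performance_stats(x, cv$pred, n_segments)
      tibble::tibble(model = spec_label(sp), transform = tr,
                     rmse = app$rmse, r2 = app$r2,
                     rmsep = cvs$rmse, r2_jack = cvs$r2,
                     avg_bias = cvs$avg_bias, max_bias = cvs$max_bias)
    })
  })
  best <- order(-rows$r2_jack, rows$rmsep, rows$max_bias)[1]
  rows$selected <- seq_len(nrow(rows)) == best
  class(rows) <- c("model_selection", class(rows))
  rows
}

#' Screen for sites the model cannot predict
#'
#' Flags sites whose absolute leave-one-out residual exceeds `k_sd` residual
#' standard deviations and reports performance before and after removing
#' them. Removal is a report, never an automatic act: excluding a flagged
#' site is the analyst's decision, recorded in the pipeline configuration.
#'
#' @inheritParams loo_predictions
#' @param k_sd Residual SD multiplier for flagging.
#' @return A list: `flagged` tibble, `before` and `after` performance rows.
#' @export
outlier_screen <- function(species, x, spec = model_spec("wa"), k_sd = 2.5) {
  loo <- loo_predictions(species, x, spec)
  res <- loo$pred - loo$observed
  s <- sd(res, na.rm = TRUE)
  flag <- !is.na(res) & s > 0 & abs(res) > k_sd * s
  before <- performance_stats(loo$observed, loo$pred)
  after <- if (any(flag) && sum(!flag) >= 4) {
    keep_tbl <- species[!flag, , drop = FALSE]
    keep_tbl <- set_transform_state(keep_tbl, transform_state(species))
    loo2 <- loo_predictions(keep_tbl, x[!flag], spec)
    performance_stats(loo2$observed, loo2$pred)
  } else before
  list(flagged = loo[flag, , drop = FALSE] |>
         dplyr::mutate(residual = res[flag]),
       before = before, after = after, k_sd = k_sd)
}

site_distances <- function(coords) {
  mode <- attr(coords, "crs_mode") %||%
    if (all(c("lat", "lon") %in% names(coords))) "lonlat" else "linear"
  if (mode == "lonlat") {
    geosphere::distm(cbind(coords$lon, coords$lat)) / 1000
  } else {
    abs(outer(coords$km, coords$km, "-"))
  }
}

#' Random / neighbour / environment (RNE) deletion analysis
#'
#' Diagnoses inflation of cross-validated skill by spatial autocorrelation.
#' For each deletion radius and each leave-one-out fold, the *neighbour*
#' scheme deletes all training sites within that geographic distance of the
#' test site; the *environment* scheme deletes the same number of training
#' sites closest to the test site in the target variable; and the *random*
#' scheme deletes that number at random (averaged over `n_random_reps`
#' repetitions). If neighbour deletion degrades r2 much faster than random
#' deletion, the cross-validated skill leans on spatial structure rather than
#' on the species-environment relationship.
#'
#' @inheritParams loo_predictions
#' @param coords Coordinates tibble (`lat`/`lon` in degrees, haversine km; or
#'   `km` along a linear transect).
#' @param radii Deletion radii in km (0 = plain leave-one-out).
#' @param n_random_reps Repetitions of the random scheme.
#' @param seed Seed for the random deletions.
#' @return An `rne_result` tibble: radius, scheme, r2, mean_n_deleted.
#' @export
rne_analysis <- function(species, x, coords, spec = model_spec("wa"),
                         radii = c(0, 1, 2, 5, 10, 20, 40),
                         n_random_reps = 10, seed = 1) {
  Y <- comm_matrix(species, "species table")
  check_sites_match(rownames(Y), coords$site, "species table and coordinates")
  D <- site_distances(coords)
  n <- nrow(Y)
  r2_of <- function(del_list) {
    r <- loo_core(spec, Y, x, del_list)
    if (any(r$flagged)) {
      warn(sprintf("%d fold(s) lost their whole training set; r2 over remaining folds",
                   sum(r$flagged)))
    }
    if (sum(is.finite(r$pred)) < 3) return(NA_real_)
    performance_stats(x, r$pred)$r2
  }
  set.seed(seed)
  rows <- purrr::map_dfr(radii, function(d) {
    nb <- lapply(seq_len(n), function(i) {
      if (d <= 0) integer(0) else setdiff(which(D[i, ] <= d), i)
    })
    ndel <- lengths(nb)
    envd <- lapply(seq_len(n), function(i) {
      if (ndel[i] == 0) return(integer(0))
      others <- setdiff(seq_len(n), i)
      others[order(abs(x[others] - x[i]))][seq_len(ndel[i])]
    })
    r2_rand <- mean(vapply(seq_len(n_random_reps), function(rep) {
      rnd <- lapply(seq_len(n), function(i) {
        if (ndel[i] == 0) return(integer(0))
        sample(setdiff(seq_len(n), i), ndel[i])
      })
      r2_of(rnd)
    }, numeric(1)), na.rm = TRUE)
    tibble::tibble(radius = d,
                   scheme = c("random", "neighbor", "environment"),
                   r2 = c(r2_rand, r2_of(nb), r2_of(envd)),
                   mean_n_deleted = mean(ndel))
  })
  class(rows) <- c("rne_result", class(rows))
  rows
}
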