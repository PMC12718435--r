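#' Configuration for the synthetic coastal-transect generator
#'
#' The defaults emulate the statistical structure of the training set the
#' package is designed for: 35 sites along an 80-km coastline, a short
#' temperature gradient (10.3-13 degC) with a contiguous warm, turbid bay
#' block, three blocks of mutually correlated water-column variables
#' (salinity proxies; ions plus dissolved silica; physical variables), a few
#' river-mouth sites with diluted ions and elevated silica, and 55 benthic
#' plus 19 planktonic taxa counted to 400-500 valves per site.
#'
#' @param n_sites Number of sites along the transect.
#' @param n_benthic,n_planktonic Numbers of taxa per habit.
#' @param transect_length Transect length in km.
#' @param temp_range Temperature range (degC) spanned by the sites.
#' @param count_total Range of valve counts per site.
#' @param noise_sd SD (degC) of site-level noise on the effective gradient the
#'   assemblages respond to (unmeasured-variable noise).
#' @param spatial_range Correlation length (km) of the exponential-covariance
#'   Gaussian process behind the temperature field; 0 gives an iid field.
#' @param patchiness SD (log scale) of spatially structured per-taxon
#'   abundance anomalies (patchy habitat effects shared by neighbouring
#'   sites; their correlation length is `spatial_range`). These anomalies are
#'   what make leave-one-out skill spatially inflatable, so the RNE
#'   diagnostic has something real to detect; 0 disables them.
#' @param bay_amplitude Warm-bay offset in latent (SD) units; set to 0
#'   together with `spatial_range = 0` for a spatially unstructured null.
#' @param env_block_r Target within-block correlation of the ion block.
#' @param secchi_r Target correlation between Secchi depth and temperature.
#' @param n_river_sites Number of river-mouth sites.
#' @param seed Master seed; all generator stages derive their streams from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 35, n_benthic = 55, n_planktonic = 19,
                       transect_length = 80, temp_range = c(10.3, 13),
                       count_total = c(400, 500), noise_sd = 0.25,
                       spatial_range = 10, bay_amplitude = 1.5,
                       patchiness = 0.4, env_block_r = 0.9, secchi_r = -0.9,
                       n_river_sites = 3, seed = 1) {
  stopifnot(n_sites > 1, n_benthic > 0, transect_length > 0,
            temp_range[1] < temp_range[2], count_total[1] <= count_total[2],
            noise_sd >= 0, spatial_range >= 0, env_block_r > 0)
  if (n_river_sites >= n_sites) abort("n_river_sites must be < n_sites")
  structure(list(n_sites = n_sites, n_benthic = n_benthic,
                 n_planktonic = n_planktonic,
                 transect_length = transect_length, temp_range = temp_range,
                 count_total = count_total, noise_sd = noise_sd,
                 spatial_range = spatial_range, bay_amplitude = bay_amplitude,
                 patchiness = patchiness,
                 env_block_r = env_block_r, secchi_r = secchi_r,
                 n_river_sites = n_river_sites, seed = seed),
            class = "sim_config")
}

# zero-mean unit-ish GP over 1-D positions with exponential covariance;
# range 0 degenerates to iid standard normal
gp_field <- function(pos, range) {
  n <- length(pos)
  if (range <= 1e-9) return(rnorm(n))
  K <- exp(-abs(outer(pos, pos, "-")) / range)
  L <- chol(K + diag(1e-8, n))
  as.vector(crossprod(L, rnorm(n)))
}

# map a latent vector onto a stated [lo, hi] range (affine, so correlations
# between variables are untouched)
to_range <- function(z, lo, hi) {
  if (diff(range(z)) < 1e-12) return(rep((lo + hi) / 2, length(z)))
  lo + (z - min(z)) / diff(range(z)) * (hi - lo)
}

# indices of the warm-bay block and the river-mouth sites
transect_layout <- function(config) {
  n <- config$n_sites
  bay <- seq(max(1L, floor(n * 0.45)), min(n, floor(n * 0.72)))
  anchors <- c(0.37, 0.85, 0.9, 0.2, 0.6, 0.95, 0.05)
  river <- unique(pmax(1L, pmin(n, round(anchors * n))))
  river <- setdiff(river, bay)[seq_len(min(config$n_river_sites,
                                           length(setdiff(river, bay))))]
  list(bay = bay, river = river)
}

#' Simulate the environmental tables of a coastal transect
#'
#' Temperature is a smooth spatial field (exponential covariance along the
#' transect) plus a contiguous warm-bay offset, mapped onto the configured
#' range; Secchi depth is a noisy negative affine of temperature; turbidity
#' and Mn follow temperature (the "physical" block); salinity, TDS and
#' conductivity share one latent factor with dips at river mouths; Cl, Na, K,
#' SO4 and Mg share a second latent with stronger river dilution, and DSi
#' mirrors that latent negatively (rivers are silica-rich). All variables are
#' mapped onto plausible coastal ranges.
#'
#' @param config A [sim_config()].
#' @return A list with elements `env` (tibble), `coords` (tibble, `site, km`)
#'   and `blocks` (generative block membership, for recovery tests).
#' @export
simulate_env <- function(config) {
  set.seed(stage_seed(config$seed, "env"))
  n <- config$n_sites
  pos <- seq(0, config$transect_length, length.out = n)
  lay <- transect_layout(config)

  bay_ind <- as.numeric(seq_len(n) %in% lay$bay)
  river_ind <- as.numeric(seq_len(n) %in% lay$river)

  # loading shared by the members of each correlated block; chosen so that
  # empirical pairwise |r| at n = 35 sits safely above the 0.8 grouping rule
  lam <- sqrt(max(config$env_block_r, 0.8))
  noisy <- function(latent, load = lam) {
    z <- scale(latent)[, 1]
    load * z + sqrt(max(0, 1 - load^2)) * rnorm(n)
  }

  temp_lat <- gp_field(pos, config$spatial_range) + config$bay_amplitude * bay_ind
  temp_z <- scale(temp_lat)[, 1]
  temperature <- to_range(temp_z, config$temp_range[1], config$temp_range[2])

  rs <- abs(config$secchi_r)
  secchi_z <- -(rs * temp_z + sqrt(1 - rs^2) * rnorm(n))
  turb_z <- noisy(temp_z, 0.95)
  mn_z <- noisy(temp_z, 0.93)

  sal_lat <- gp_field(pos, config$spatial_range) - 2.5 * river_ind
  ion_lat <- gp_field(pos, config$spatial_range) - 3 * river_ind - 0.5 * bay_ind

  env <- tibble::tibble(
    site = sprintf("S%02d", seq_len(n)),
    temperature = temperature,
    secchi = to_range(secchi_z, 4.2, 18.4),
    turbidity = to_range(turb_z, 0.5, 2.8),
    mn = to_range(mn_z, 2, 16),
    salinity = to_range(noisy(sal_lat, 0.97), 22.5, 29.3),
    tds = to_range(noisy(sal_lat), 15.9, 23.5),
    conductivity = to_range(noisy(sal_lat), 34.4, 46.9),
    cl = to_range(noisy(ion_lat), 3.9, 20),
    na = to_range(noisy(ion_lat), 2.1, 10.1),
    k = to_range(noisy(ion_lat), 87.2, 396),
    so4 = to_range(noisy(ion_lat), 735.5, 2815),
    mg = to_range(noisy(ion_lat), 259.3, 1205),
    dsi = to_range(-noisy(ion_lat), 0, 1.5))

  coords <- tibble::tibble(site = env$site, km = pos)
  attr(coords, "crs_mode") <- "linear"
  blocks <- list(physical = c("temperature", "secchi", "turbidity", "mn"),
                 salinity = c("salinity", "tds", "conductivity"),
                 ions = c("cl", "na", "k", "so4", "mg", "dsi"))
  list(env = env, coords = coords, blocks = blocks, layout = lay)
}

#' Draw taxon response parameters (the generator's ground truth)
#'
#' Optima are spread evenly over the temperature range (with jitter) so the
#' gradient is covered; tolerances and peak abundances vary between taxa.
#'
#' @param config A [sim_config()].
#' @return A tibble: `taxon, true_optimum, true_tolerance, max_abundance,
#'   habit`.
#' @export
make_taxon_truth <- function(config) {
  set.seed(stage_seed(config$seed, "truth"))
  draw <- function(k, prefix, habit) {
    span <- diff(config$temp_range)
    opt <- seq(config$temp_range[1], config$temp_range[2], length.out = k) +
      rnorm(k, 0, 0.04 * span)
    tibble::tibble(
      taxon = sprintf("%s%02d", prefix, seq_len(k)),
      true_optimum = pmin(pmax(opt, config$temp_range[1]), config$temp_range[2]),
      true_tolerance = runif(k, 0.15 * span, 0.45 * span),
      max_abundance = stats::rlnorm(k, 0, 0.6),
      habit = habit)
  }
  dplyr::bind_rows(draw(config$n_benthic, "B", "benthic"),
                   if (config$n_planktonic > 0)
                     draw(config$n_planktonic, "P", "planktonic"))
}

#' Simulate a valve-count community along a gradient
#'
#' Expected proportions follow unimodal (Gaussian) responses,
#' `p_ik proportional to a_k * exp(-(x_i - u_k)^2 / (2 t_k^2))`, where `x_i`
#' is site temperature plus site-level noise (`noise_sd`); counts are drawn
#' multinomially with row totals uniform over `count_total`. This is the
#' canonical generative model under which weighted-averaging calibration is
#' consistent, which is what makes parameter recovery on these data a
#' meaningful check.
#'
#' @param env Environment tibble containing a `temperature` column.
#' @param truth Taxon truth tibble from [make_taxon_truth()].
#' @param config A [sim_config()].
#' @return A counts tibble (`site` plus one column per taxon).
#' @export
simulate_community <- function(env, truth, config) {
  set.seed(stage_seed(config$seed, "community"))
  n <- nrow(env)
  x <- env$temperature + rnorm(n, 0, config$noise_sd)
  mu <- outer(x, truth$true_optimum, "-")
  E <- exp(-(mu^2) / (2 * rep(truth$true_tolerance^2, each = length(x)))) *
    rep(truth$max_abundance, each = length(x))
  if (config$patchiness > 0) {
    # spatially coherent per-taxon abundance anomalies (patchy habitat):
    # neighbouring sites share them, distant sites do not
    pos <- seq(0, config$transect_length, length.out = n)
    G <- if (config$spatial_range <= 1e-9) {
      matrix(rnorm(n * nrow(truth)), n)
    } else {
      K <- exp(-abs(outer(pos, pos, "-")) / config$spatial_range)
      crossprod(chol(K + diag(1e-8, n)), matrix(rnorm(n * nrow(truth)), n))
    }
    E <- E * exp(config$patchiness * G)
  }
  rs <- rowSums(E)
  if (any(rs <= 0 | !is.finite(rs))) {
    abort("all expected proportions are zero at some site; widen tolerances")
  }
  P <- E / rs
  totals <- sample(seq(config$count_total[1], config$count_total[2]),
                   length(x), replace = TRUE)
  cm <- vapply(seq_along(x),
               function(i) stats::rmultinom(1, totals[i], P[i, ])[, 1],
               numeric(nrow(truth)))
  counts <- if (is.matrix(cm)) t(cm) else matrix(cm, ncol = 1)
  colnames(counts) <- colnames(P) <- truth$taxon
  rownames(counts) <- rownames(P) <- env$site
  out <- comm_tibble(counts)
  attr(out, "expected") <- P       # noise-free proportions, for recovery tests
  attr(out, "x_effective") <- x    # the gradient the assemblages actually saw
  out
}

#' Generate a complete synthetic benchmark dataset
#'
#' Bundles [simulate_env()], [make_taxon_truth()] and [simulate_community()]
#' into a `diatom_dataset` plus its ground truth; optionally writes the CSV
#' bundle (counts, environment, coordinates, taxon metadata, truth) and a
#' YAML dump of the configuration.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for the CSV bundle.
#' @return A `synthetic_dataset`: list with `dataset`, `truth`, `config`,
#'   `blocks`.
#' @export
make_benchmark <- function(config = sim_config(), dir = NULL) {
  envres <- simulate_env(config)
  truth <- make_taxon_truth(config)
  counts <- simulate_community(envres$env, truth, config)
  ds <- new_dataset(counts, envres$env, envres$coords,
                    setNames(truth$habit, truth$taxon))
  out <- structure(list(dataset = ds, truth = truth, config = config,
                        blocks = envres$blocks, layout = envres$layout),
                   class = "synthetic_dataset")
  if (!is.null(dir)) {
    write_dataset(ds, dir)
    readr::write_csv(truth, file.path(dir, "truth.csv"))
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> seed %s\n", x$config$seed))
  print(x$dataset)
  invisible(x)
}
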