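#' Read a valve-count table
#'
#' Reads a CSV whose first column is `site` and whose remaining columns are
#' taxon codes holding non-negative integer valve counts. Any cell that does
#' not parse as a number (including literal `NA`) is a fatal error naming the
#' site and taxon, because a count sheet with holes cannot feed a calibration.
#'
#' @param path Path to the counts CSV.
#' @return A tibble with a `site` column and one numeric column per taxon.
#' @export
read_counts <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw)[1] <- "site"
  out <- raw["site"]
  for (tx in setdiff(names(raw), "site")) {
    v <- suppressWarnings(as.numeric(raw[[tx]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("non-numeric count cell at site '%s', taxon '%s' (value '%s')",
                    raw$site[i], tx, raw[[tx]][i] %||% "NA"))
    }
    out[[tx]] <- v
  }
  validate_counts(tibble::as_tibble(out))
}

validate_counts <- function(counts) {
  m <- comm_matrix(counts, "counts")
  if (anyDuplicated(rownames(m))) abort("duplicate site identifiers in counts")
  if (anyDuplicated(colnames(m))) abort("duplicate taxon codes in counts")
  if (any(m < 0)) abort("negative counts are not allowed")
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(sprintf("zero row total at site(s): %s",
                  paste(rownames(m)[rs <= 0], collapse = ", ")))
  }
  counts
}

#' Read a site-by-variable environment table
#'
#' @param path Path to the environment CSV (first column `site`).
#' @return A tibble of site rows and numeric variable columns.
#' @export
read_env <- function(path) {
  env <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(env)[1] <- "site"
  env$site <- as.character(env$site)
  m <- comm_matrix(env, "environment table")
  if (any(!is.finite(m))) abort("environment table contains non-finite values")
  env
}

#' Read site coordinates
#'
#' Accepts either `site, lat, lon` (decimal degrees) or `site, km` (position
#' along a linear transect). The mode is recorded in the `crs_mode` attribute
#' and drives how the RNE neighbourhood distances are computed.
#'
#' @param path Path to the coordinates CSV.
#' @return A tibble with a `crs_mode` attribute of `"lonlat"` or `"linear"`.
#' @export
read_coords <- function(path) {
  co <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(co)[1] <- "site"
  co$site <- as.character(co$site)
  if (all(c("lat", "lon") %in% names(co))) {
    if (any(abs(co$lat) > 90)) abort("latitude outside [-90, 90]")
    attr(co, "crs_mode") <- "lonlat"
  } else if ("km" %in% names(co)) {
    attr(co, "crs_mode") <- "linear"
  } else {
    abort("coordinates must have columns lat/lon or km")
  }
  if (anyDuplicated(co$site)) abort("duplicate site in coordinates")
  co
}

#' Assemble a calibration dataset from CSV files
#'
#' Intersects the site sets of the counts, environment and (optional)
#' coordinate tables, reorders everything to the counts order, and reports any
#' site dropped on the way. An empty intersection is fatal.
#'
#' @param count_path,env_path CSV paths (see [read_counts()], [read_env()]).
#' @param coords_path Optional coordinates CSV.
#' @param taxon_meta_path Optional CSV with columns `taxon, habit`
#'   (habit one of benthic/planktonic/unknown).
#' @return A `diatom_dataset`: list with `counts`, `env`, `coords`, `habit`.
#' @export
load_dataset <- function(count_path, env_path, coords_path = NULL,
                         taxon_meta_path = NULL) {
  counts <- read_counts(count_path)
  env <- read_env(env_path)
  coords <- if (!is.null(coords_path)) read_coords(coords_path)
  habit <- NULL
  if (!is.null(taxon_meta_path)) {
    meta <- readr::read_csv(taxon_meta_path, show_col_types = FALSE, progress = FALSE)
    habit <- setNames(as.character(meta$habit), as.character(meta$taxon))
  }
  new_dataset(counts, env, coords, habit)
}

#' Construct a dataset from in-memory tables
#'
#' @param counts,env,coords Tibbles as produced by the readers.
#' @param habit Optional named character vector of per-taxon habit labels.
#' @return A `diatom_dataset`.
#' @export
new_dataset <- function(counts, env, coords = NULL, habit = NULL) {
  counts <- validate_counts(tibble::as_tibble(counts))
  counts$site <- as.character(counts$site)
  env$site <- as.character(env$site)
  keep <- intersect(counts$site, env$site)
  if (!is.null(coords)) keep <- intersect(keep, as.character(coords$site))
  if (length(keep) == 0) abort("empty intersection of site sets")
  dropped <- setdiff(unique(c(counts$site, env$site,
                              if (!is.null(coords)) coords$site)), keep)
  if (length(dropped)) {
    inform(sprintf("dropped %d site(s) absent from some table: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- counts$site[counts$site %in% keep]  # preserve counts order
  counts <- counts[match(keep, counts$site), , drop = FALSE]
  env <- env[match(keep, env$site), , drop = FALSE]
  if (!is.null(coords)) {
    mode <- attr(coords, "crs_mode") %||%
      if (all(c("lat", "lon") %in% names(coords))) "lonlat" else "linear"
    coords <- coords[match(keep, coords$site), , drop = FALSE]
    attr(coords, "crs_mode") <- mode
  }
  taxa <- setdiff(names(counts), "site")
  hab <- setNames(rep("unknown", length(taxa)), taxa)
  if (!is.null(habit)) hab[intersect(names(habit), taxa)] <-
      habit[intersect(names(habit), taxa)]
  structure(list(counts = counts, env = env, coords = coords, habit = hab),
            class = "diatom_dataset")
}

#' @export
print.diatom_dataset <- function(x, ...) {
  cat(sprintf("<diatom_dataset> %d sites, %d taxa (%d benthic, %d planktonic), %d environmental variables%s\n",
              nrow(x$counts), length(x$habit),
              sum(x$habit == "benthic"), sum(x$habit == "planktonic"),
              ncol(x$env) - 1L,
              if (is.null(x$coords)) "" else ", with coordinates"))
  invisible(x)
}

#' Write a dataset back to CSV files
#'
#' @param dataset A `diatom_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$counts, file.path(dir, "counts.csv"))
  readr::write_csv(dataset$env, file.path(dir, "env.csv"))
  if (!is.null(dataset$coords)) {
    readr::write_csv(dataset$coords, file.path(dir, "coords.csv"))
  }
  readr::write_csv(tibble::tibble(taxon = names(dataset$habit),
                                  habit = unname(dataset$habit)),
                   file.path(dir, "taxon_meta.csv"))
  invisible(dir)
}

#' Keep only taxa with a given habit label
#'
#' The published calibration uses benthic taxa only; this subsets the count
#' table before any preprocessing.
#'
#' @param counts Counts tibble.
#' @param habit Named character vector of habit labels.
#' @param keep Labels to retain (default `"benthic"`).
#' @return The filtered counts tibble.
#' @export
habit_filter <- function(counts, habit, keep = "benthic") {
  taxa <- setdiff(names(counts), "site")
  sel <- taxa[habit[taxa] %in% keep]
  if (length(sel) == 0) abort("no taxa left after habit filter")
  counts[c("site", sel)]
}

#' Convert valve counts to relative abundances
#'
#' Each row is divided by its total valve count. Row totals are kept as an
#' attribute so that downstream filtering can still report the fraction of
#' counted valves retained.
#'
#' @param counts Counts tibble (`site` column plus taxon columns).
#' @return A proportion tibble with `transform_state = "none"`.
#' @export
relative_abundance <- function(counts) {
  m <- comm_matrix(counts, "counts")
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(sprintf("zero row total at site '%s'", rownames(m)[which(rs <= 0)[1]]))
  }
  out <- comm_tibble(m / rs)
  attr(out, "row_totals") <- setNames(rs, rownames(m))
  set_transform_state(out, "none")
}

#' Drop rare taxa from a relative-abundance table
#'
#' Retains taxa whose relative abundance reaches at least `min_pct` percent in
#' at least `min_occurrences` sites (the training-set cut-off: >= 1% in two or
#' more samples). Proportions are not renormalized afterwards, so each row sum
#' still reports the share of counted valves the retained taxa represent; the
#' per-run summary is attached as the `filter_report` attribute.
#'
#' @param rel Proportion tibble from [relative_abundance()].
#' @param min_pct Abundance threshold in percent.
#' @param min_occurrences Minimum number of sites at or above the threshold.
#' @param renormalize If `TRUE`, rescale rows to sum to 1 after filtering.
#' @return The filtered proportion tibble.
#' @export
rare_taxon_filter <- function(rel, min_pct = 1, min_occurrences = 2,
                              renormalize = FALSE) {
  if (transform_state(rel) != "none") {
    abort("rare_taxon_filter expects untransformed proportions")
  }
  m <- comm_matrix(rel, "abundance table")
  hits <- colSums(m >= min_pct / 100)
  keep <- names(hits)[hits >= min_occurrences]
  if (length(keep) == 0) abort("all taxa dropped by the rare-taxon filter")
  km <- m[, keep, drop = FALSE]
  totals <- attr(rel, "row_totals")
  frac <- if (!is.null(totals)) {
    sum(totals * rowSums(km)) / sum(totals)
  } else {
    mean(rowSums(km))
  }
  if (renormalize) km <- km / rowSums(km)
  out <- comm_tibble(km)
  attr(out, "row_totals") <- totals
  attr(out, "filter_report") <- list(
    retained = keep,
    dropped = setdiff(colnames(m), keep),
    valve_fraction = frac,
    min_pct = min_pct, min_occurrences = min_occurrences)
  set_transform_state(out, "none")
}

#' Hellinger transformation
#'
#' Square root of row-normalized proportions, the transformation that makes
#' Euclidean distances (and hence linear ordination) behave sensibly on
#' community data while damping the leverage of dominant taxa.
#'
#' @param rel Proportion tibble with `transform_state = "none"`.
#' @return A tibble with `transform_state = "hellinger"`; each row's sum of
#'   squares is 1.
#' @export
hellinger <- function(rel) {
  if (transform_state(rel) == "hellinger") {
    abort("input is already Hellinger-transformed (double transform)")
  }
  m <- comm_matrix(rel, "abundance table")
  rs <- rowSums(m)
  if (any(rs <= 0)) abort("zero row total; cannot Hellinger-transform")
  out <- comm_tibble(sqrt(m / rs))
  attr(out, "row_totals") <- attr(rel, "row_totals")
  set_transform_state(out, "hellinger")
}

#' Transform and scale an environment table for ordination
#'
#' Variables whose adjusted Fisher-Pearson sample skewness exceeds
#' `skew_threshold` in absolute value are log10(x + 1)-transformed; every
#' column is then centred and scaled to unit SD. The log flags, centres and
#' scales are recorded as attributes so the transform can be replayed.
#'
#' @param env Environment tibble (raw, unscaled).
#' @param skew_threshold Absolute skewness above which a variable is logged.
#' @return The scaled tibble; attributes `transform_log`, `center`, `scale`.
#' @export
transform_env <- function(env, skew_threshold = 1.0) {
  m <- comm_matrix(env, "environment table")
  if (any(!is.finite(m))) abort("environment table contains non-finite values")
  logged <- setNames(rep(FALSE, ncol(m)), colnames(m))
  for (v in colnames(m)) {
    sk <- e1071::skewness(m[, v], type = 2)
    if (is.finite(sk) && abs(sk) > skew_threshold) {
      if (any(m[, v] < 0)) {
        abort(sprintf("variable '%s' flagged for log10(x+1) has negative values", v))
      }
      m[, v] <- log10(m[, v] + 1)
      logged[v] <- TRUE
    }
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant variable(s) cannot be scaled: %s",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  sc <- scale(m)
  out <- comm_tibble(sc[, , drop = FALSE])
  attr(out, "transform_log") <- logged
  attr(out, "center") <- setNames(attr(sc, "scaled:center"), colnames(m))
  attr(out, "scale") <- setNames(attr(sc, "scaled:scale"), colnames(m))
  attr(out, "scaled") <- TRUE
  out
}
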