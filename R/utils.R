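#' @importFrom rlang %||% abort warn inform
#' @importFrom stats cor sd var lm coef predict pt rnorm runif setNames
#' @importFrom utils head modifyList
NULL

# Convert a site-keyed tibble (first column `site`, remaining columns numeric)
# to a plain numeric matrix with site rownames. All numerical cores work on
# matrices; tibbles only live at the API surface.
comm_matrix <- function(tbl, what = "table") {
  if (!is.data.frame(tbl)) abort(sprintf("%s must be a data frame", what))
  if (!"site" %in% names(tbl)) {
    abort(sprintf("%s must have a `site` column", what))
  }
  vals <- tbl[setdiff(names(tbl), "site")]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric columns in %s: %s", what,
                  paste(bad, collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(tbl$site)
  m
}

comm_tibble <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    tibble::add_column(site = rownames(m), .before = 1)
}

# carry the transform bookkeeping that AbundanceMatrix-style tibbles use
transform_state <- function(x) attr(x, "transform_state") %||% "counts"

set_transform_state <- function(x, state) {
  attr(x, "transform_state") <- state
  x
}

# Deterministic per-stage seed derived from a master seed and a stage label,
# so inserting a stage never reshuffles the randomness of the ones after it.
# Plain polynomial rolling hash; kept below .Machine$integer.max.
stage_seed <- function(master, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647L
  as.integer((as.numeric(master) %% 65521 * 7919 + h) %% 2147483647)
}

# population SD (divisor n); components and scores are scaled with this
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

check_sites_match <- function(a, b, what = "tables") {
  if (!identical(as.character(a), as.character(b))) {
    abort(sprintf("site ordering differs between %s", what))
  }
  invisible(TRUE)
}
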