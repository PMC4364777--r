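# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed for a named simulation stage
#'
#' One shared generator per dataset, keyed by `(seed, stage)`: adding a new
#' stage to the generator does not perturb the draws of earlier stages.
#' The polynomial string hash is reduced mod 2^31 - 2 so the result is a
#' valid 32-bit integer seed.
#'
#' @param seed integer master seed.
#' @param stage character scalar naming the stage.
#' @return an integer usable with [set.seed()].
#' @keywords internal
#' @noRd
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  m <- 2147483646  # 2^31 - 2, keeps everything in exact double range
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m + 1)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(stage_seed(seed, stage))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Stop with a descriptive message unless all named columns are present.
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

# Log a message to stderr; every warning-level condition also goes through
# base warning() so callers can trap it.
xci_log <- function(..., level = c("info", "warn")) {
  level <- match.arg(level)
  msg <- paste0(...)
  if (level == "warn") warning(msg, call. = FALSE)
  else message("[xciescape] ", msg)
  invisible(msg)
}

# Stable hash of a configuration object, for output provenance headers.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  # version 2 serialization is stable across the R versions we support
  saveRDS(config, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

# Format numerics with 6 significant digits for diffable table output.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

# Merge overlapping/abutting intervals given sorted-by-start vectors.
# Returns a list(start, end, group) where group maps inputs to clusters.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  n <- length(start)
  if (n == 0L) return(list(start = numeric(0), end = numeric(0),
                           group = integer(0)))
  grp <- integer(n)
  grp[1L] <- 1L
  cur_end <- end[1L]
  for (i in seq_len(n)[-1L]) {
    if (start[i] <= cur_end) {
      grp[i] <- grp[i - 1L]
      cur_end <- max(cur_end, end[i])
    } else {
      grp[i] <- grp[i - 1L] + 1L
      cur_end <- end[i]
    }
  }
  ms <- tapply(start, grp, min)
  me <- tapply(end, grp, max)
  g <- integer(n); g[o] <- grp
  list(start = as.numeric(ms), end = as.numeric(me), group = g)
}

# Jaccard index of two [start, end) intervals.
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- (max(a[2], b[2]) - min(a[1], b[1]))
  if (uni <= 0) return(0)
  inter / uni
}
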