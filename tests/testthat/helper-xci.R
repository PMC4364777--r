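# Shared test helpers: tiny fixtures built in code and independent oracles.

# Jaccard index of two [start, end) intervals (independent of the package's
# internal helper).
jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni <= 0) 0 else inter / uni
}

# Small simulation configuration that keeps unit tests fast.
tiny_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_genes_x = 20, n_genes_autosome = 10,
                   chrom_length_bp = 5e5)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Independent escape-decision oracle: the Wald lower limit is positive
# iff n0 (1 + z^2/n) > z^2, derived by squaring p-hat > z * se. Uses qt
# with infinite df as a second quantile source.
wald_lower_positive_oracle <- function(n0, n1, alpha = 0.01) {
  n <- n0 + n1
  z <- stats::qt(1 - alpha / 2, df = Inf)
  n0 > 0 & n0 * (1 + z^2 / n) > z^2
}

# Brute-force binomial tails by pmf summation.
tail_upper_brute <- function(k, n, p) sum(stats::dbinom(k:n, n, p))
tail_lower_brute <- function(k, n, p) sum(stats::dbinom(0:k, n, p))

# Brute-force window scan: count peak midpoints per window by explicit
# interval comparison, one window at a time.
brute_scan <- function(mid, chrom_length, window = 5e5, step = 1e3) {
  starts <- seq(0, chrom_length - window, by = step)
  counts <- vapply(starts, function(s)
    sum(mid >= s & mid < s + window), 0L)
  lambda <- mean(counts)
  p <- if (lambda == 0) rep(1, length(counts))
       else stats::ppois(counts - 1, lambda, lower.tail = FALSE)
  data.frame(start = starts, peak_count = counts, p_value = p)
}
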