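# The binomial model of expression from the inactive X: estimation,
# bias correction, confidence limits, escape calling and cross-tissue
# classification.

# Monotone mapping-bias correction map: observed-scale proportion p to
# bias-corrected scale, f(p) = p / (p + r_m (1 - p)). Strictly increasing
# for all r_m > 0; identity at r_m = 1.
bias_correct <- function(p, r_m) p / (p + r_m * (1 - p))

#' Estimate the Xi expression proportion with bias correction and Wald CI
#'
#' For a gene with \eqn{n_0} Xi-allele and \eqn{n_1} Xa-allele reads
#' (\eqn{n = n_0 + n_1}), models \eqn{n_0 \sim Binomial(n, p)} and
#' estimates \eqn{\hat p = n_0 / n} with the Wald interval
#' \eqn{\hat p \pm z_{\alpha/2} \sqrt{\hat p (1 - \hat p)/n}}, where
#' \eqn{z_{\alpha/2}} is the \eqn{100(1-\alpha/2)}-th percentile of the
#' standard normal. Mapping bias is removed through the monotone map
#' \eqn{f(p) = p/(p + r_m(1-p))}: the corrected estimate is
#' \eqn{\bar p = n_0/(n_0 + r_m n_1) = f(\hat p)} and the confidence
#' limits are corrected accordingly (i.e. transformed by the same map,
#' which preserves their order and sign). Reported limits are clipped to
#' `[0, 1]`; the pre-clip lower limit is retained because the escape
#' criterion tests it strictly against zero.
#'
#' All arguments recycle; `n = 0` rows are returned as unassessable
#' (`NA` estimates) rather than raising an error.
#'
#' @param n0,n1 Xi- and Xa-allele read counts.
#' @param r_m mapping-bias ratio (autosomal Xi-genome/Xa-genome read
#'   ratio); 1 means no bias.
#' @param alpha two-sided significance level of the interval (default 0.01,
#'   a 99\% interval).
#' @param exact use Clopper-Pearson instead of Wald limits (sensitivity
#'   analysis; the standard pipeline uses Wald).
#' @return a data frame with columns `n0`, `n1`, `n`, `p_hat`, `r_m`,
#'   `p_bar`, `alpha`, `ci_lower`, `ci_upper` (clipped, corrected) and
#'   `ci_lower_raw` (pre-clip corrected lower limit).
#' @examples
#' estimate_escape(12, 210)          # ~5.4% Xi reads, lower limit > 0
#' estimate_escape(10, 90, r_m = 1.2)  # correction shrinks the estimate
#' @export
estimate_escape <- function(n0, n1, r_m = 1, alpha = 0.01, exact = FALSE) {
  stopifnot(is_count(n0), is_count(n1), all(r_m > 0),
            all(alpha > 0), all(alpha < 1))
  k <- max(length(n0), length(n1), length(r_m), length(alpha))
  n0 <- rep_len(n0, k); n1 <- rep_len(n1, k)
  r_m <- rep_len(r_m, k); alpha <- rep_len(alpha, k)
  n <- n0 + n1
  p_hat <- ifelse(n > 0, n0 / n, NA_real_)
  if (exact) {
    lo <- ifelse(n0 > 0, stats::qbeta(alpha / 2, n0, n1 + 1), 0)
    hi <- ifelse(n1 > 0, stats::qbeta(1 - alpha / 2, n0 + 1, n1), 1)
  } else {
    half <- stats::qnorm(1 - alpha / 2) * sqrt(p_hat * (1 - p_hat) / n)
    lo <- p_hat - half
    hi <- p_hat + half
  }
  p_bar <- bias_correct(p_hat, r_m)
  lo_c <- bias_correct(lo, r_m)
  hi_c <- bias_correct(hi, r_m)
  data.frame(n0 = n0, n1 = n1, n = n, p_hat = p_hat, r_m = r_m,
             p_bar = p_bar, alpha = alpha,
             ci_lower = pmin(pmax(lo_c, 0), 1),
             ci_upper = pmin(pmax(hi_c, 0), 1),
             ci_lower_raw = lo_c)
}

#' Call escape from XCI for one estimate
#'
#' A gene escapes XCI in a sample when all three published criteria hold:
#' (1) the lower confidence limit of the Xi proportion exceeds zero
#' (significant Xi contribution), (2) diploid expression RPKM is at least
#' `rpkm_min` (the gene is expressed), and (3) Xi-SRPM is at least
#' `xi_srpm_min` (sufficient reads from the Xi). Thresholds are inclusive.
#'
#' @param estimate output row(s) of [estimate_escape()].
#' @param rpkm,xi_srpm per-sample diploid RPKM and Xi-SRPM.
#' @param rpkm_min,xi_srpm_min thresholds (defaults 1 and 2).
#' @param min_n totals below this are unassessable (default 1, i.e. only
#'   `n = 0` is unassessable).
#' @return `estimate` with added columns `rpkm`, `xi_srpm`, `passes_ci`,
#'   `passes_rpkm`, `passes_srpm`, `assessable`, `is_escape`.
#' @examples
#' est <- estimate_escape(12, 210)
#' call_escape(est, rpkm = 131, xi_srpm = 12)$is_escape  # TRUE
#' @export
call_escape <- function(estimate, rpkm, xi_srpm, rpkm_min = 1,
                        xi_srpm_min = 2, min_n = 1) {
  est <- estimate
  est$rpkm <- rep_len(rpkm, nrow(est))
  est$xi_srpm <- rep_len(xi_srpm, nrow(est))
  est$passes_ci <- !is.na(est$ci_lower_raw) & est$ci_lower_raw > 0
  est$passes_rpkm <- est$rpkm >= rpkm_min
  est$passes_srpm <- est$xi_srpm >= xi_srpm_min
  est$assessable <- est$n >= max(1, min_n)
  est$is_escape <- est$assessable & est$passes_ci & est$passes_rpkm &
    est$passes_srpm
  est
}

#' Fit the XCI escape model to a table of allele-specific counts
#'
#' The package's central model fit. `counts` holds one row per gene and
#' sample with Xi/Xa allele-specific read counts; the fitter estimates the
#' mapping-bias ratio per sample from the autosomal rows (unless `r_m` is
#' supplied), computes the bias-corrected Xi proportion and Wald limits for
#' every X-linked row, applies the three escape criteria, and returns a
#' classed object with the usual modelling methods (`print`, `summary`,
#' `coef`, `confint`, `fitted`, `plot`, `simulate`).
#'
#' Required columns: `gene`, `n0`, `n1`. Optional: `sample` (default one
#' sample), `chrom` (needed to estimate `r_m` and to restrict the fit to X
#' rows), `tissue` and `replicate` (enable cross-replicate and cross-tissue
#' classification in `summary()`), and either precomputed `rpkm` and
#' `xi_srpm` or the raw ingredients `total_reads`, `exon_length_bp`,
#' `library_size` from which RPKM and SRPM are computed.
#'
#' @param counts data frame as described above.
#' @param r_m mapping-bias ratio: a single number, a named per-sample
#'   vector, or `NULL` to estimate from autosomal rows via
#'   [compute_mapping_bias()].
#' @param alpha significance level of the confidence interval (default
#'   0.01).
#' @param rpkm_min,xi_srpm_min escape thresholds (defaults 1 and 2).
#' @param x_chrom X chromosome label (default `"chrX"`).
#' @param min_n minimum informative reads for assessability.
#' @param exact use Clopper-Pearson limits (see [estimate_escape()]).
#' @return an object of class `"xci_fit"`: a list with `calls` (per
#'   gene-sample data frame of estimates and escape calls), `r_m` (named
#'   per-sample vector), `alpha`, `thresholds`, and the matched call.
#' @examples
#' counts <- data.frame(gene = c("g1", "g2", "auto"),
#'                      chrom = c("chrX", "chrX", "chr1"),
#'                      n0 = c(12, 0, 5000), n1 = c(210, 50, 5000),
#'                      rpkm = c(131, 6, 10), xi_srpm = c(12, 0, 50))
#' fit <- xci_fit(counts)
#' coef(fit)
#' @export
xci_fit <- function(counts, r_m = NULL, alpha = 0.01, rpkm_min = 1,
                    xi_srpm_min = 2, x_chrom = "chrX", min_n = 1,
                    exact = FALSE) {
  check_columns(counts, c("gene", "n0", "n1"), "counts")
  counts$sample <- as.character(counts$sample %||% "sample1")
  samples <- unique(counts$sample)

  if (is.null(r_m)) {
    if (!"chrom" %in% names(counts))
      stop("estimating r_m needs a 'chrom' column (or supply r_m directly)")
    r_m <- vapply(samples, function(s)
      compute_mapping_bias(counts[counts$sample == s, ], x_chrom = x_chrom),
      0)
  } else if (length(r_m) == 1L) {
    r_m <- stats::setNames(rep(r_m, length(samples)), samples)
  } else {
    if (is.null(names(r_m)) || !all(samples %in% names(r_m)))
      stop("a vector r_m must be named by sample")
    r_m <- r_m[samples]
  }

  x <- if ("chrom" %in% names(counts))
    counts[counts$chrom == x_chrom, ] else counts
  if (nrow(x) == 0L) stop("no rows on ", x_chrom, " to fit")

  if (!"rpkm" %in% names(x)) {
    check_columns(x, c("total_reads", "exon_length_bp", "library_size"),
                  "counts (to compute rpkm)")
    x$rpkm <- compute_rpkm(x$total_reads, x$exon_length_bp, x$library_size)
  }
  if (!"xi_srpm" %in% names(x)) {
    check_columns(x, "library_size", "counts (to compute xi_srpm)")
    x$xi_srpm <- compute_srpm(x$n0, x$library_size)
    x$xa_srpm <- compute_srpm(x$n1, x$library_size)
  }

  est <- estimate_escape(x$n0, x$n1, r_m = unname(r_m[x$sample]),
                         alpha = alpha, exact = exact)
  calls <- cbind(x[, intersect(c("gene", "sample", "tissue", "replicate"),
                               names(x)), drop = FALSE],
                 est[, setdiff(names(est), c("n0", "n1"))],
                 x[, intersect(c("n0", "n1", "rpkm", "xi_srpm", "xa_srpm"),
                               names(x)), drop = FALSE])
  calls <- call_escape(calls, rpkm = calls$rpkm, xi_srpm = calls$xi_srpm,
                       rpkm_min = rpkm_min, xi_srpm_min = xi_srpm_min,
                       min_n = min_n)
  rownames(calls) <- NULL
  structure(list(calls = calls, r_m = r_m, alpha = alpha,
                 thresholds = list(rpkm_min = rpkm_min,
                                   xi_srpm_min = xi_srpm_min, min_n = min_n),
                 exact = exact, call = match.call()),
            class = "xci_fit")
}

#' @export
print.xci_fit <- function(x, ...) {
  cat("XCI escape model fit\n")
  cat(sprintf("  %d gene-sample observations, %d gene(s), %d sample(s)\n",
              nrow(x$calls), length(unique(x$calls$gene)),
              length(x$r_m)))
  cat(sprintf("  alpha = %g (%g%% CI, %s); RPKM >= %g; Xi-SRPM >= %g\n",
              x$alpha, 100 * (1 - x$alpha),
              if (x$exact) "Clopper-Pearson" else "Wald",
              x$thresholds$rpkm_min, x$thresholds$xi_srpm_min))
  cat("  r_m:", paste(sprintf("%s = %.4g", names(x$r_m), x$r_m),
                      collapse = ", "), "\n")
  ass <- x$calls$assessable
  cat(sprintf("  escape calls: %d of %d assessable observations\n",
              sum(x$calls$is_escape), sum(ass)))
  invisible(x)
}

#' @method coef xci_fit
#' @export
coef.xci_fit <- function(object, ...) {
  cl <- object$calls
  nm <- if (length(object$r_m) > 1L) paste(cl$gene, cl$sample, sep = ":")
        else cl$gene
  stats::setNames(cl$p_bar, nm)
}

#' @export
fitted.xci_fit <- function(object, ...) coef(object)

#' @method confint xci_fit
#' @export
confint.xci_fit <- function(object, parm, level = 1 - object$alpha, ...) {
  cl <- object$calls
  if (abs(level - (1 - object$alpha)) > 1e-12) {
    est <- estimate_escape(cl$n0, cl$n1, r_m = cl$r_m, alpha = 1 - level,
                           exact = object$exact)
    lo <- est$ci_lower; hi <- est$ci_upper
  } else {
    lo <- cl$ci_lower; hi <- cl$ci_upper
  }
  nm <- if (length(object$r_m) > 1L) paste(cl$gene, cl$sample, sep = ":")
        else cl$gene
  out <- cbind(lo, hi)
  dimnames(out) <- list(nm, sprintf("%g %%", 100 * c((1 - level) / 2,
                                                     1 - (1 - level) / 2)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @method as.data.frame xci_fit
#' @export
as.data.frame.xci_fit <- function(x, ...) x$calls

#' Simulate allele-specific counts from a fitted escape model
#'
#' Draws new Xi-allele counts \eqn{n_0^* \sim Binomial(n, \hat p)} for each
#' gene-sample observation, at the observed (uncorrected) scale, i.e. a
#' parametric bootstrap of the fitted binomial model.
#'
#' @param object an [xci_fit()] object.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `gene`, `sample`,
#'   `n0`, `n1`.
#' @export
simulate.xci_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cl <- object$calls
  lapply(seq_len(nsim), function(i) {
    n0 <- ifelse(cl$n > 0, stats::rbinom(nrow(cl), cl$n, cl$p_hat), 0L)
    data.frame(gene = cl$gene, sample = cl$sample, n0 = n0, n1 = cl$n - n0)
  })
}

#' @method plot xci_fit
#' @export
plot.xci_fit <- function(x, ...) {
  cl <- x$calls[order(x$calls$p_bar), ]
  cl <- cl[cl$assessable, ]
  i <- seq_len(nrow(cl))
  col <- ifelse(cl$is_escape, "#7a0177", "grey60")
  graphics::plot(i, cl$p_bar, ylim = c(0, 1), pch = 19, col = col,
                 xlab = "gene-sample observations (ordered)",
                 ylab = "Xi expression proportion (bias-corrected)", ...)
  graphics::segments(i, cl$ci_lower, i, cl$ci_upper, col = col)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", pch = 19, col = c("#7a0177", "grey60"),
                   legend = c("escape", "subject/not called"), bty = "n")
  invisible(x)
}

#' Combine per-replicate escape calls into a tissue status
#'
#' Biological replicates are analysed separately; their calls are then
#' reconciled: escape in every assessable replicate gives `escape`, escape
#' in some but not all gives `variable` (the "escaped in only one
#' biological replicate" case for two replicates), escape in none gives
#' `subject`. A single assessable replicate stands as its own call; if no
#' replicate is assessable the gene is `unassessable` in that tissue.
#'
#' @param is_escape logical vector of per-replicate escape calls.
#' @param assessable logical vector (same length); defaults to all `TRUE`.
#' @return one of `"escape"`, `"variable"`, `"subject"`, `"unassessable"`.
#' @examples
#' combine_replicates(c(TRUE, TRUE))    # escape
#' combine_replicates(c(TRUE, FALSE))   # variable
#' @export
combine_replicates <- function(is_escape, assessable = NULL) {
  if (length(is_escape) == 0L) stop("no replicate calls supplied")
  assessable <- assessable %||% rep(TRUE, length(is_escape))
  stopifnot(length(assessable) == length(is_escape))
  esc <- is_escape[assessable]
  if (length(esc) == 0L) return("unassessable")
  if (all(esc)) return("escape")
  if (!any(esc)) return("subject")
  "variable"
}

#' Per-tissue XCI status table from a model fit
#'
#' Applies [combine_replicates()] within each gene and tissue of a fit.
#'
#' @param fit an [xci_fit()] object whose `counts` carried `tissue` (and
#'   ideally `replicate`) columns.
#' @return data frame: `gene`, `tissue`, `status`.
#' @export
tissue_status <- function(fit) {
  cl <- if (inherits(fit, "xci_fit")) fit$calls else fit
  check_columns(cl, c("gene", "tissue", "is_escape", "assessable"),
                "calls")
  grp <- interaction(cl$gene, cl$tissue, drop = TRUE)
  st <- vapply(split(seq_len(nrow(cl)), grp), function(i)
    combine_replicates(cl$is_escape[i], cl$assessable[i]), "")
  first <- !duplicated(grp)
  out <- data.frame(gene = cl$gene[first], tissue = cl$tissue[first],
                    status = unname(st[as.character(grp[first])]))
  out[order(out$gene, out$tissue), ]
}

#' Classify genes into common and tissue-specific escape groups
#'
#' Group 1 collects genes escaping XCI in at least two tissues (common
#' escape); group 2 collects genes escaping in exactly one tissue with no
#' escape - not even variable escape - in any replicate of the other
#' tissues (tissue-specific escape). Genes with variable status are
#' excluded from both groups.
#'
#' @param statuses data frame from [tissue_status()] (`gene`, `tissue`,
#'   `status`), covering at least two tissues.
#' @return data frame: `gene`, `group` (`"group1"`, `"group2"`, `"none"`),
#'   `group2_tissue` (`NA` unless group 2).
#' @examples
#' classify_groups(data.frame(
#'   gene = "Cfp", tissue = c("brain", "spleen", "ovary"),
#'   status = c("subject", "escape", "subject")))
#' @export
classify_groups <- function(statuses) {
  check_columns(statuses, c("gene", "tissue", "status"), "statuses")
  if (length(unique(statuses$tissue)) < 2L)
    stop("group classification needs statuses for at least two tissues")
  out <- do.call(rbind, lapply(split(statuses, statuses$gene), function(s) {
    esc <- s$tissue[s$status == "escape"]
    blocked <- s$status %in% c("escape", "variable")
    group <- if (length(esc) >= 2L) "group1"
      else if (length(esc) == 1L && sum(blocked) == 1L) "group2"
      else "none"
    data.frame(gene = s$gene[1], group = group,
               group2_tissue = if (group == "group2") esc else NA_character_)
  }))
  rownames(out) <- NULL
  out[order(out$gene), ]
}

#' Summarise Xi expression relative to the Xa across escape calls
#'
#' For every escaping gene-sample observation, the Xi level as a percent of
#' the Xa level (`100 * Xi-SRPM / Xa-SRPM`). `Xist` - expressed from the Xi
#' by definition - is excluded. Observations with `Xa-SRPM = 0` but Xi
#' signal have an undefined ratio; they are counted but excluded from the
#' summary statistics.
#'
#' @param calls an [xci_fit()] object or its `calls` data frame (needs
#'   `gene`, `is_escape`, `xi_srpm`, `xa_srpm`).
#' @param exclude genes to drop (default `"Xist"`).
#' @return list: `min`, `median`, `max`, `n`, `n_undefined_ratio`, and the
#'   per-observation `percent` vector.
#' @examples
#' summarize_xi_xa(data.frame(gene = "Ddx3x", is_escape = TRUE,
#'                            xi_srpm = 56, xa_srpm = 178))$median
#' @export
summarize_xi_xa <- function(calls, exclude = "Xist") {
  cl <- if (inherits(calls, "xci_fit")) calls$calls else calls
  check_columns(cl, c("gene", "is_escape", "xi_srpm", "xa_srpm"), "calls")
  cl <- cl[cl$is_escape & !(cl$gene %in% exclude), ]
  if (nrow(cl) == 0L) stop("no escape calls to summarise")
  undef <- cl$xa_srpm == 0
  pct <- 100 * cl$xi_srpm[!undef] / cl$xa_srpm[!undef]
  list(min = min(pct), median = stats::median(pct), max = max(pct),
       n = length(pct), n_undefined_ratio = sum(undef), percent = pct)
}

#' @method summary xci_fit
#' @export
summary.xci_fit <- function(object, ...) {
  cl <- object$calls
  out <- list(fit = object)
  if ("tissue" %in% names(cl)) {
    out$tissue_status <- tissue_status(object)
    if (length(unique(cl$tissue)) >= 2L)
      out$groups <- classify_groups(out$tissue_status)
  }
  if (any(cl$is_escape) && "xa_srpm" %in% names(cl)) {
    s <- summarize_xi_xa(object)
    out$xi_xa <- s[c("min", "median", "max", "n", "n_undefined_ratio")]
  }
  class(out) <- "summary.xci_fit"
  out
}

#' @export
print.summary.xci_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$tissue_status)) {
    tab <- table(x$tissue_status$tissue, x$tissue_status$status)
    cat("\nPer-tissue status counts:\n")
    print(tab)
  }
  if (!is.null(x$groups)) {
    cat("\nGroups: ", sum(x$groups$group == "group1"), " common (group 1), ",
        sum(x$groups$group == "group2"), " tissue-specific (group 2)\n",
        sep = "")
  }
  if (!is.null(x$xi_xa))
    cat(sprintf("\nXi/Xa expression among escape calls (excl. Xist): %.0f-%.0f%% (median %.0f%%), n = %d\n",
                x$xi_xa$min, x$xi_xa$max, x$xi_xa$median, x$xi_xa$n))
  invisible(x)
}

#' Table-1-style escape report
#'
#' One row per gene: per-tissue Xi/Xa SRPM (replicate means, rounded),
#' per-tissue RPKM, and the group classification.
#'
#' @param fit an [xci_fit()] with tissue information.
#' @return a data frame.
#' @export
escape_report <- function(fit) {
  stopifnot(inherits(fit, "xci_fit"))
  cl <- fit$calls
  check_columns(cl, c("tissue", "xa_srpm"), "calls")
  st <- tissue_status(fit)
  groups <- if (length(unique(cl$tissue)) >= 2L) classify_groups(st) else NULL
  genes <- sort(unique(cl$gene))
  out <- data.frame(gene = genes)
  for (ti in unique(cl$tissue)) {
    sub <- cl[cl$tissue == ti, ]
    xi <- tapply(sub$xi_srpm, sub$gene, mean)[genes]
    xa <- tapply(sub$xa_srpm, sub$gene, mean)[genes]
    rp <- tapply(sub$rpkm, sub$gene, mean)[genes]
    out[[paste0(ti, "_srpm")]] <- sprintf("%.0f/%.0f", xi, xa)
    out[[paste0(ti, "_rpkm")]] <- round(rp)
    out[[paste0(ti, "_status")]] <-
      st$status[match(paste(genes, ti), paste(st$gene, st$tissue))]
  }
  if (!is.null(groups)) {
    out$group <- groups$group[match(genes, groups$gene)]
    out$group2_tissue <- groups$group2_tissue[match(genes, groups$gene)]
  }
  out
}
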