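# End-to-end orchestration: configuration in, report tables out.

resolve_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  config
}

require_file <- function(path, what) {
  if (is.null(path)) stop("configuration lacks ", what)
  if (!file.exists(path)) stop(what, " not found: ", path)
  path
}

#' Run the escape-calling pipeline
#'
#' Reads a per-gene allele-specific count table, fits the binomial escape
#' model per sample (estimating the mapping-bias ratio from autosomal rows
#' unless given), reconciles replicates into per-tissue statuses,
#' classifies genes into common and tissue-specific escape groups, and
#' writes the report tables. Outputs are deterministic given the
#' configuration; every table carries a header naming the configuration
#' hash.
#'
#' Configuration fields (a named list, or a YAML file path): `counts_file`
#' or an inline `counts` data frame; `out_dir`; optional `sample_sheet`
#' (data frame or TSV path with `sample` plus any of `tissue`,
#' `replicate`, `library_size`) merged into the counts by sample; optional
#' `r_m`, `alpha`, `rpkm_min`, `xi_srpm_min`, `min_n`, `x_chrom`, `seed`.
#'
#' @param config list or YAML path.
#' @return invisibly, a list with the fitted [xci_fit()], the report
#'   tables, the configuration hash, and the written file paths.
#' @export
run_escape_pipeline <- function(config) {
  config <- resolve_config(config)
  counts <- config[["counts"]]
  if (is.null(counts))
    counts <- read_counts_tsv(require_file(config[["counts_file"]],
                                           "counts_file"))
  if (nrow(counts) == 0L) stop("empty count table; nothing to fit")

  if (!is.null(config[["sample_sheet"]])) {
    ss <- config[["sample_sheet"]]
    if (is.character(ss)) ss <- utils::read.delim(ss)
    check_columns(ss, "sample", "sample_sheet")
    if (nrow(ss) == 0L) stop("empty sample sheet")
    if (!"sample" %in% names(counts))
      stop("counts need a 'sample' column to join the sample sheet")
    miss <- setdiff(unique(counts$sample), ss$sample)
    if (length(miss))
      stop("sample sheet lacks sample(s): ", paste(miss, collapse = ", "))
    add <- setdiff(names(ss), names(counts))
    counts <- cbind(counts, ss[match(counts$sample, ss$sample), add,
                               drop = FALSE])
  }

  hash <- config_hash(config)
  xci_log("escape pipeline start; config hash ", hash,
          if (!is.null(config[["seed"]])) paste0("; seed ", config[["seed"]]) else "")

  fit <- xci_fit(counts,
                 r_m = config[["r_m"]] %||% NULL,
                 alpha = config[["alpha"]] %||% 0.01,
                 rpkm_min = config[["rpkm_min"]] %||% 1,
                 xi_srpm_min = config[["xi_srpm_min"]] %||% 2,
                 x_chrom = config[["x_chrom"]] %||% "chrX",
                 min_n = config[["min_n"]] %||% 1)

  out <- list(fit = fit, hash = hash, files = character(0))
  if (!is.null(config[["out_dir"]])) {
    dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      p <- file.path(config[["out_dir"]], name)
      write_report_tsv(df, p, hash)
      out$files[name] <<- p
    }
    wr(fit$calls, "escape_calls.tsv")
    if ("tissue" %in% names(fit$calls)) {
      out$tissue_status <- tissue_status(fit)
      wr(out$tissue_status, "tissue_status.tsv")
      if (length(unique(fit$calls$tissue)) >= 2L) {
        out$groups <- classify_groups(out$tissue_status)
        wr(out$groups, "groups.tsv")
        out$report <- escape_report(fit)
        wr(out$report, "escape_report.tsv")
      }
    }
  } else {
    if ("tissue" %in% names(fit$calls)) {
      out$tissue_status <- tissue_status(fit)
      if (length(unique(fit$calls$tissue)) >= 2L) {
        out$groups <- classify_groups(out$tissue_status)
        out$report <- escape_report(fit)
      }
    }
  }
  invisible(out)
}

#' Run the allelic peak classification and clustering pipeline
#'
#' Reads a diploid peak set with allele-specific counts, applies the
#' assessability filter, estimates the X (and autosomal) allelic
#' background, classifies peak preference by exact binomial tails, scans
#' the X for clusters of Xi- and both-preferred peaks, and - when gene
#' models and XCI statuses are supplied - tests cluster/escape-gene
#' co-localization and classifies transition regions. Deterministic given
#' the configuration.
#'
#' Configuration fields: `peaks_file` or inline `peaks`; `library_size`;
#' `chrom_length`; optional `xi_allele` (default `"spretus"`), `x_chrom`,
#' `peak_alpha`, `both_min`, `window`, `step`, `cutoff`, `bounds`,
#' `exclude_promoters` (needs genes), `promoter_flank`; optional `genes`
#' (data frame or BED12 path) and `statuses` (data frame `gene`,`status`)
#' enabling the co-localization and transition reports; `out_dir`.
#'
#' @param config list or YAML path.
#' @return invisibly, a list with the classified peaks, background, scan,
#'   optional co-localization and transition results, hash and file paths.
#' @export
run_peaks_pipeline <- function(config) {
  config <- resolve_config(config)
  peaks <- config[["peaks"]]
  if (is.null(peaks))
    peaks <- read_peaks_bed(require_file(config[["peaks_file"]], "peaks_file"))
  if (is.null(config[["library_size"]])) stop("configuration lacks library_size")
  if (is.null(config[["chrom_length"]])) stop("configuration lacks chrom_length")
  x_chrom <- config[["x_chrom"]] %||% "chrX"

  hash <- config_hash(config)
  xci_log("peaks pipeline start; config hash ", hash)

  peaks <- filter_assessable(peaks, config[["library_size"]])
  background <- estimate_background(peaks[peaks$assessable, ], x_chrom)
  peaks <- classify_peaks(peaks, background,
                          xi_allele = config[["xi_allele"]] %||% "spretus",
                          alpha = config[["peak_alpha"]] %||% 0.05,
                          both_min = config[["both_min"]] %||% 0.25,
                          x_chrom = x_chrom)

  genes <- config[["genes"]]
  if (is.character(genes)) genes <- read_gene_models_bed12(genes)
  scan_input <- peaks
  if (isTRUE(config[["exclude_promoters"]])) {
    if (is.null(genes)) stop("exclude_promoters needs gene models")
    scan_input <- exclude_promoter_peaks(peaks, genes,
                                         flank = config[["promoter_flank"]] %||% 1000)
  }
  scan <- scan_xi_clusters(scan_input[is.na(scan_input$preference) |
                                        scan_input$preference != "low_coverage", ],
                           chrom_length = config[["chrom_length"]],
                           bounds = config[["bounds"]] %||% "peaks",
                           window = config[["window"]] %||% 5e5,
                           step = config[["step"]] %||% 1e3,
                           cutoff = config[["cutoff"]] %||% 0.01,
                           x_chrom = x_chrom)

  out <- list(peaks = peaks, background = background, scan = scan,
              hash = hash, files = character(0))

  statuses <- config[["statuses"]]
  if (!is.null(statuses) && !is.null(genes)) {
    esc <- statuses$gene[statuses$status == "escape"]
    gx <- genes[genes$chrom == x_chrom, ]
    if (length(esc) && nrow(scan$clusters))
      out$colocalization <- colocalization_test(scan$clusters, gx, esc)
    gs <- merge(gx, statuses, by = "gene")
    gs <- gs[gs$status %in% c("escape", "subject"), ]
    out$transitions <- transition_classify(gs, peaks[peaks$chrom == x_chrom &
                                                       !is.na(peaks$preference) &
                                                       peaks$preference != "low_coverage", ])
  }

  if (!is.null(config[["out_dir"]])) {
    dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      p <- file.path(config[["out_dir"]], name)
      write_report_tsv(df, p, hash)
      out$files[name] <<- p
    }
    wr(peaks, "classified_peaks.tsv")
    wr(data.frame(p_x = background$p_x, p_autosome = background$p_autosome,
                  n_x_bl = background$n_x_bl, n_x_sp = background$n_x_sp),
       "background.tsv")
    wr(scan$windows, "windows.tsv")
    wr(scan$clusters, "clusters.tsv")
    if (!is.null(out$transitions)) wr(out$transitions$transitions,
                                      "transitions.tsv")
  }
  invisible(out)
}
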