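# Poisson sliding-window clustering of Xi-bound peaks, co-localization
# with escape genes, transition-region classification, and allele-specific
# promoter/metagene signal summaries.

#' Poisson sliding-window density scan of a peak set
#'
#' Slides a `window`-wide window along one chromosome in `step` increments,
#' counts peaks per window by their midpoints (so each peak belongs to a
#' window at most once per offset despite the heavy window overlap), fits a
#' single Poisson rate as the mean count over all windows (the Poisson
#' maximum-likelihood estimate), and assigns each window the upper-tail
#' probability \eqn{P(Poisson(\lambda) \ge count)}.
#'
#' @param peaks data frame with `start`, `end` on one chromosome (checked),
#'   or a numeric vector of midpoints.
#' @param chrom_length chromosome length in bp.
#' @param window,step window and step size in bp (defaults 500 kb / 1 kb).
#' @param cutoff significance cutoff stored for downstream use
#'   (default 0.01).
#' @return data frame of class `"density_windows"`: `start`, `end`,
#'   `peak_count`, `p_value`, with attributes `lambda`, `window`, `step`,
#'   `cutoff`, `chrom`.
#' @examples
#' w <- window_density_scan(data.frame(start = c(1e5, 1.2e5, 4e5),
#'                                     end = c(1.01e5, 1.21e5, 4.01e5)),
#'                          chrom_length = 1e6)
#' attr(w, "lambda")
#' @export
window_density_scan <- function(peaks, chrom_length, window = 5e5,
                                step = 1e3, cutoff = 0.01) {
  stopifnot(chrom_length >= window, window > 0, step > 0,
            window %% step == 0)
  chrom <- NA_character_
  if (is.data.frame(peaks)) {
    check_columns(peaks, c("start", "end"), "peaks")
    if ("chrom" %in% names(peaks)) {
      if (length(unique(peaks$chrom)) > 1L)
        stop("scan one chromosome at a time")
      chrom <- if (nrow(peaks)) peaks$chrom[1] else NA_character_
    }
    mid <- (peaks$start + peaks$end) / 2
  } else mid <- as.numeric(peaks)
  mid <- mid[mid >= 0 & mid < chrom_length]

  starts <- seq(0, chrom_length - window, by = step)
  nbin <- ceiling(chrom_length / step)
  bins <- tabulate(pmin(nbin, floor(mid / step) + 1L), nbins = nbin)
  cum <- cumsum(c(0, bins))
  k <- window / step
  idx <- starts / step
  counts <- as.integer(cum[idx + k + 1] - cum[idx + 1])

  lambda <- mean(counts)
  if (lambda == 0) {
    xci_log("no peaks on the chromosome; all windows non-significant",
            level = "warn")
    p <- rep(1, length(counts))
  } else {
    p <- stats::ppois(counts - 1, lambda, lower.tail = FALSE)
  }
  structure(data.frame(start = starts, end = starts + window,
                       peak_count = counts, p_value = p),
            lambda = lambda, window = window, step = step, cutoff = cutoff,
            chrom = chrom, class = c("density_windows", "data.frame"))
}

#' Merge significant scan windows into clusters
#'
#' Takes the windows whose Poisson upper-tail probability falls below
#' `cutoff` and merges maximal runs of overlapping or abutting significant
#' windows into single clusters spanning their union. Clusters are
#' disjoint, sorted, and idempotent under re-merging.
#'
#' @param windows output of [window_density_scan()].
#' @param cutoff p-value cutoff (default the scan's stored cutoff, 0.01).
#' @return data frame: `start`, `end`, `member_windows`, `min_p`. Zero rows
#'   when nothing is significant.
#' @export
merge_significant_windows <- function(windows,
                                      cutoff = attr(windows, "cutoff") %||% 0.01) {
  check_columns(windows, c("start", "end", "p_value"), "windows")
  sig <- windows[windows$p_value < cutoff, ]
  if (nrow(sig) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      member_windows = integer(0), min_p = numeric(0)))
  m <- merge_intervals(sig$start, sig$end)
  data.frame(start = m$start, end = m$end,
             member_windows = as.integer(table(m$group)),
             min_p = as.numeric(tapply(sig$p_value, m$group, min)))
}

#' Scan a classified peak set for Xi-binding clusters
#'
#' The full clustering path: select the Xi-relevant peaks (by default the
#' Xi- and both-preferred sets jointly), run the Poisson window scan, merge
#' significant windows, and report cluster intervals. With
#' `bounds = "peaks"` (default) each cluster interval is trimmed to the
#' span of the peaks inside its merged window run - the merged "adjacent
#' peaks" themselves - which removes the half-window boundary slack that
#' window unions carry; `bounds = "windows"` reports the raw window unions.
#'
#' @param peaks classified peaks from [classify_peaks()] (columns `chrom`,
#'   `start`, `end`, `xi_face`).
#' @param chrom_length chromosome length.
#' @param faces which `xi_face` categories to scan (default Xi- plus
#'   both-preferred).
#' @param bounds cluster boundary rule, `"peaks"` or `"windows"`.
#' @param window,step,cutoff scan parameters (see
#'   [window_density_scan()]).
#' @param x_chrom chromosome to scan.
#' @return list of class `"xi_cluster_scan"`: `clusters` (data frame
#'   `chrom`, `start`, `end`, `member_windows`, `min_p`), `windows`,
#'   `lambda`, `n_peaks_scanned`.
#' @export
scan_xi_clusters <- function(peaks, chrom_length,
                             faces = c("Xi_preferred", "both"),
                             bounds = c("peaks", "windows"),
                             window = 5e5, step = 1e3, cutoff = 0.01,
                             x_chrom = "chrX") {
  bounds <- match.arg(bounds)
  check_columns(peaks, c("chrom", "start", "end", "xi_face"), "peaks")
  sel <- peaks[peaks$chrom == x_chrom & peaks$xi_face %in% faces, ]
  w <- window_density_scan(sel[, c("start", "end")], chrom_length,
                           window = window, step = step, cutoff = cutoff)
  cl <- merge_significant_windows(w, cutoff)
  if (bounds == "peaks" && nrow(cl) > 0L) {
    mid <- (sel$start + sel$end) / 2
    for (i in seq_len(nrow(cl))) {
      inside <- mid >= cl$start[i] & mid < cl$end[i]
      if (any(inside)) {
        cl$start[i] <- min(sel$start[inside])
        cl$end[i] <- max(sel$end[inside])
      }
    }
  }
  cl <- if (nrow(cl)) cbind(chrom = x_chrom, cl) else
    cbind(chrom = character(0), cl)
  structure(list(clusters = cl, windows = w, lambda = attr(w, "lambda"),
                 n_peaks_scanned = nrow(sel)),
            class = "xi_cluster_scan")
}

#' @export
print.xi_cluster_scan <- function(x, ...) {
  cat(sprintf("Xi-binding cluster scan: %d peak(s) scanned, lambda = %.3f, %d cluster(s)\n",
              x$n_peaks_scanned, x$lambda, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Remove peaks overlapping promoter windows
#'
#' Drops every peak whose interval overlaps any TSS +/- `flank` window
#' (overlap is inclusive: touching the flank by a single base removes the
#' peak). Used to focus the cluster scan on intergenic, potentially
#' structural binding.
#'
#' @param peaks data frame: `chrom`, `start`, `end`.
#' @param genes gene models with `chrom`, `tss`, `strand`.
#' @param flank promoter half-width in bp (default 1000).
#' @return the subset of `peaks` away from all promoters.
#' @export
exclude_promoter_peaks <- function(peaks, genes, flank = 1000) {
  check_columns(peaks, c("chrom", "start", "end"), "peaks")
  check_columns(genes, c("chrom", "tss"), "genes")
  if (nrow(peaks) == 0L) return(peaks)
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(1, genes$tss - flank + 1),
                                                  genes$tss + flank))
  hit <- IRanges::overlapsAny(pk, prom)
  peaks[!hit, , drop = FALSE]
}

#' Test co-localization of clusters with escape genes
#'
#' Builds the 2x2 table of escape versus background genes against
#' overlapping versus not overlapping any cluster (a gene overlaps when its
#' body intersects a cluster interval), and computes the exact
#' (hypergeometric) test. The default background is all supplied
#' non-escape genes (deterministic); `mode = "sampled"` instead draws
#' `n_background` background genes with a recorded seed, mirroring a
#' random-sample comparison.
#'
#' @param clusters data frame: `chrom`, `start`, `end`.
#' @param genes data frame of X-linked genes: `gene`, `chrom`, `start`,
#'   `end`.
#' @param escape_genes character vector of escape gene names (must be
#'   non-empty and present in `genes`).
#' @param mode `"all"` or `"sampled"`.
#' @param n_background,seed sampled-background parameters.
#' @return list of class `"coloc_test"`: `table` (2x2), `odds_ratio`,
#'   `p_value` (two-sided exact), `p_greater` (one-sided enrichment),
#'   `mode`, `seed`.
#' @export
colocalization_test <- function(clusters, genes, escape_genes,
                                mode = c("all", "sampled"),
                                n_background = 500, seed = NULL) {
  mode <- match.arg(mode)
  check_columns(genes, c("gene", "chrom", "start", "end"), "genes")
  if (length(escape_genes) == 0L) stop("empty escape gene set")
  esc <- genes[genes$gene %in% escape_genes, ]
  if (nrow(esc) == 0L) stop("none of the escape genes are in `genes`")
  bg <- genes[!(genes$gene %in% escape_genes), ]
  if (mode == "sampled") {
    if (!is.null(seed)) set.seed(seed)
    bg <- bg[sample.int(nrow(bg), min(n_background, nrow(bg))), ]
  }
  overlaps <- function(g) {
    if (nrow(clusters) == 0L) return(rep(FALSE, nrow(g)))
    gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1, g$end))
    cr <- GenomicRanges::GRanges(clusters$chrom,
                                 IRanges::IRanges(clusters$start + 1,
                                                  clusters$end))
    IRanges::overlapsAny(gr, cr)
  }
  tab <- rbind(escape = c(inside = sum(overlaps(esc)),
                          outside = sum(!overlaps(esc))),
               background = c(inside = sum(overlaps(bg)),
                              outside = sum(!overlaps(bg))))
  ft2 <- stats::fisher.test(tab)
  ftg <- stats::fisher.test(tab, alternative = "greater")
  structure(list(table = tab, odds_ratio = unname(ft2$estimate),
                 p_value = ft2$p.value, p_greater = ftg$p.value,
                 mode = mode, seed = seed),
            class = "coloc_test")
}

#' @export
print.coloc_test <- function(x, ...) {
  cat("Cluster / escape-gene co-localization (exact test)\n")
  print(x$table)
  cat(sprintf("  odds ratio %.3g; two-sided p = %.3g; enrichment p = %.3g (%s background)\n",
              x$odds_ratio, x$p_value, x$p_greater, x$mode))
  invisible(x)
}

#' Classify transitions between adjacent genes by XCI status
#'
#' Walks consecutive gene pairs along a chromosome and classifies each
#' intergenic transition as S-S (both subject), E-S (different status) or
#' E-E (both escape), then asks whether any peak lies wholly or partly in
#' the intergenic gap. Overlapping gene pairs have no gap and are skipped
#' with a warning.
#'
#' @param genes data frame sorted by `start`: `gene`, `chrom`, `start`,
#'   `end`, `status` (`"escape"` or `"subject"`).
#' @param peaks data frame: `chrom`, `start`, `end` (may be empty).
#' @return list of class `"transition_table"`: `transitions` (data frame
#'   `left_gene`, `right_gene`, `cls`, `gap_start`, `gap_end`,
#'   `has_ctcf_peak`) and `fractions` (named vector: fraction of
#'   transitions with an intergenic peak, per class).
#' @export
transition_classify <- function(genes, peaks) {
  check_columns(genes, c("gene", "chrom", "start", "end", "status"), "genes")
  stopifnot(all(genes$status %in% c("escape", "subject")))
  out <- NULL
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) < 2L) next
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g) - 1L)) {
      gap <- c(g$end[i], g$start[i + 1L])
      if (gap[2] <= gap[1]) {
        xci_log("genes ", g$gene[i], " and ", g$gene[i + 1L],
                " overlap; transition skipped", level = "warn")
        next
      }
      st <- sort(c(g$status[i], g$status[i + 1L]))
      cls <- if (all(st == "subject")) "S-S"
             else if (all(st == "escape")) "E-E" else "E-S"
      has <- nrow(pk) > 0L && any(pk$start < gap[2] & pk$end > gap[1])
      out <- rbind(out, data.frame(left_gene = g$gene[i],
                                   right_gene = g$gene[i + 1L], cls = cls,
                                   gap_start = gap[1], gap_end = gap[2],
                                   has_ctcf_peak = has))
    }
  }
  out <- out %||% data.frame(left_gene = character(0),
                             right_gene = character(0), cls = character(0),
                             gap_start = numeric(0), gap_end = numeric(0),
                             has_ctcf_peak = logical(0))
  fr <- tapply(out$has_ctcf_peak, factor(out$cls,
                                         levels = c("S-S", "E-S", "E-E")),
               mean)
  structure(list(transitions = out, fractions = fr),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("Transition regions between adjacent genes:\n")
  print(table(x$transitions$cls))
  cat("Fraction with an intergenic CTCF peak:\n")
  print(round(x$fractions, 3))
  invisible(x)
}

# Strand-aware offset of signal positions from the TSS: 0 is `span` bp
# upstream, increasing in the direction of transcription; half-open
# [0, 2 * span). Mirrored exactly for minus-strand genes.
tss_offset <- function(pos, tss, strand, span) {
  if (strand == "+") pos - (tss - span) else (tss + span) - pos
}

#' Count allele-specific signal reads around each TSS
#'
#' Tallies Xi- and Xa-labelled signal records whose position falls within
#' TSS +/- `flank` (half-open on the downstream edge, mirrored for
#' minus-strand genes so the window is strand-symmetric).
#'
#' @param signal data frame: `chrom`, `pos` (0-based), `allele`
#'   (`"Xi"`/`"Xa"`).
#' @param genes gene models: `gene`, `chrom`, `tss`, `strand`.
#' @param flank half-width in bp (default 500).
#' @return data frame: `gene`, `xi_count`, `xa_count`.
#' @export
promoter_counts <- function(signal, genes, flank = 500) {
  check_columns(signal, c("chrom", "pos", "allele"), "signal")
  check_columns(genes, c("gene", "chrom", "tss", "strand"), "genes")
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    s <- signal[signal$chrom == g$chrom, ]
    off <- tss_offset(s$pos, g$tss, g$strand, flank)
    inside <- off >= 0 & off < 2 * flank
    data.frame(gene = g$gene,
               xi_count = sum(inside & s$allele == "Xi"),
               xa_count = sum(inside & s$allele == "Xa"))
  }))
  rownames(out) <- NULL
  out
}

#' Average allele-specific metagene profile around TSSs
#'
#' Bins Xi- and Xa-labelled signal positions into `bin`-bp windows across
#' TSS +/- `span` for each gene, flips minus-strand genes so bin 1 is
#' always the far upstream end, and averages the per-gene bin counts over
#' the gene set for each allele.
#'
#' @param signal data frame: `chrom`, `pos` (0-based), `allele`.
#' @param genes gene models (`gene`, `chrom`, `tss`, `strand`); at least
#'   one gene.
#' @param span,bin profile half-width and bin size in bp (defaults 3000
#'   and 100, i.e. 60 bins).
#' @return data frame of class `"metagene_profile"`: `bin` (1-based),
#'   `offset_bp` (bin start relative to the TSS), `xa`, `xi` (mean counts
#'   per gene); attribute `n_genes`.
#' @export
metagene_profile <- function(signal, genes, span = 3000, bin = 100) {
  check_columns(signal, c("chrom", "pos", "allele"), "signal")
  check_columns(genes, c("gene", "chrom", "tss", "strand"), "genes")
  if (nrow(genes) == 0L) stop("empty gene set")
  stopifnot(span %% bin == 0)
  nb <- 2L * span / bin
  acc <- matrix(0, nrow = nb, ncol = 2,
                dimnames = list(NULL, c("xa", "xi")))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- signal[signal$chrom == g$chrom, ]
    off <- tss_offset(s$pos, g$tss, g$strand, span)
    inside <- off >= 0 & off < 2 * span
    b <- floor(off[inside] / bin) + 1L
    al <- s$allele[inside]
    if (any(al == "Xa"))
      acc[, "xa"] <- acc[, "xa"] + tabulate(b[al == "Xa"], nbins = nb)
    if (any(al == "Xi"))
      acc[, "xi"] <- acc[, "xi"] + tabulate(b[al == "Xi"], nbins = nb)
  }
  structure(data.frame(bin = seq_len(nb),
                       offset_bp = seq(-span, span - bin, by = bin),
                       xa = acc[, "xa"] / nrow(genes),
                       xi = acc[, "xi"] / nrow(genes)),
            n_genes = nrow(genes),
            class = c("metagene_profile", "data.frame"))
}

#' @method plot metagene_profile
#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::matplot(x$offset_bp, cbind(x$xa, x$xi), type = "l", lty = 1,
                    col = c("#2b6cb0", "#2f855a"),
                    xlab = "distance from TSS (bp)",
                    ylab = "mean SNP read count per gene", ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = c("Xa", "Xi"), lty = 1,
                   col = c("#2b6cb0", "#2f855a"), bty = "n")
  invisible(x)
}
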