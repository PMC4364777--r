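# Readers and writers for the standard formats the pipeline exchanges:
# TSV SNP tables (1-based), BED12 gene models, BED6+2 allelic peak files,
# per-gene count tables, and YAML run configurations.

#' Read / write a diagnostic SNP table
#'
#' Tab-separated with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#'
#' @param path file path.
#' @param snps data frame to write.
#' @return `read_snp_table()`: the validated data frame.
#' @export
read_snp_table <- function(path) {
  snps <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(snps, c("chrom", "pos", "ref", "alt"), path)
  if (any(snps$pos < 1)) stop("SNP table has non-positive positions: ", path)
  if (any(snps$ref == snps$alt)) stop("SNP table has ref == alt rows: ", path)
  snps
}

#' @rdname read_snp_table
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps[, c("chrom", "pos", "ref", "alt")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene models as BED12
#'
#' The on-disk representation of gene models (0-based half-open, exons as
#' blocks). Reading converts to the package's flat gene-model data frame
#' and derives the TSS from the strand.
#'
#' @param path file path.
#' @param genes gene-model data frame (as from [sim_gene_models()]).
#' @return `read_gene_models_bed12()`: a gene-model data frame.
#' @export
read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  blocks <- gr$blocks
  if (is.null(blocks))
    blocks <- IRanges::IRangesList(lapply(end - start, function(w)
      IRanges::IRanges(1L, w)))
  exon_starts <- vapply(seq_along(gr), function(i)
    paste(start[i] + IRanges::start(blocks[[i]]) - 1L, collapse = ","), "")
  exon_sizes <- vapply(seq_along(gr), function(i)
    paste(IRanges::width(blocks[[i]]), collapse = ","), "")
  data.frame(gene = gr$name, chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start, end = end, strand = strand,
             tss = ifelse(strand == "+", start, end - 1L),
             exon_starts = exon_starts, exon_sizes = exon_sizes,
             exon_length_bp = vapply(seq_along(gr), function(i)
               sum(IRanges::width(blocks[[i]])), 0))
}

#' @rdname read_gene_models_bed12
#' @export
write_gene_models_bed12 <- function(genes, path) {
  check_columns(genes, c("gene", "chrom", "start", "end", "strand",
                         "exon_starts", "exon_sizes"), "genes")
  rel_starts <- vapply(seq_len(nrow(genes)), function(i) {
    ab <- as.numeric(strsplit(genes$exon_starts[i], ",")[[1]])
    paste(ab - genes$start[i], collapse = ",")
  }, "")
  n_blocks <- vapply(strsplit(genes$exon_sizes, ","), length, 0L)
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene, 0L,
                    genes$strand, genes$start, genes$end, "0,0,0",
                    n_blocks, genes$exon_sizes, rel_starts)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write allelic peak files (BED6+2)
#'
#' BED intervals with two extra columns holding the per-peak BL6- and
#' spretus-SNP read counts. Written plainly (name in column 4, zero score,
#' `.` strand); read through `rtracklayer` with declared extra columns.
#'
#' @param path file path.
#' @param peaks data frame with `chrom`, `start`, `end`, `peak_id`,
#'   `n_bl`, `n_sp`.
#' @return `read_peaks_bed()`: a peak data frame.
#' @export
read_peaks_bed <- function(path) {
  raw <- readLines(path)
  starts <- suppressWarnings(as.numeric(vapply(strsplit(raw, "\t"),
                                               `[`, "", 2L)))
  bad <- which(is.na(starts) | starts < 0)
  if (length(bad))
    stop(sprintf("invalid or negative start coordinate in %s at line %d",
                 path, bad[1]))
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(n_bl = "integer",
                                          n_sp = "integer"))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             peak_id = gr$name %||% paste0("peak", seq_along(gr)),
             n_bl = gr$n_bl, n_sp = gr$n_sp)
}

#' @rdname read_peaks_bed
#' @export
write_peaks_bed <- function(peaks, path) {
  check_columns(peaks, c("chrom", "start", "end", "peak_id", "n_bl",
                         "n_sp"), "peaks")
  if (any(peaks$start < 0)) stop("negative peak coordinate")
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    0L, ".", peaks$n_bl, peaks$n_sp)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-gene allele-specific count table
#'
#' Tab-separated, one row per gene and sample, with at least `gene`, `n0`,
#' `n1` (see [xci_fit()] for the optional columns).
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  check_columns(x, c("gene", "n0", "n1"), path)
  bad <- which(x$n0 < 0 | x$n1 < 0)
  if (length(bad))
    stop(sprintf("negative count in %s at data line %d", path, bad[1]))
  x
}

# Write a pipeline output table with a provenance header naming the
# configuration hash; numbers carry 6 significant digits for diffability.
write_report_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML with the input paths, thresholds and the sample sheet (see
#' [run_escape_pipeline()] for the recognised fields). A list can be
#' passed anywhere a configuration path is accepted.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed configuration: ", path)
  cfg
}

#' The published three-tissue escape gene table as a packaged fixture
#'
#' A plain-text transcription of the printed summary table of mouse escape
#' genes: per tissue the replicate-averaged Xi/Xa SRPM values and RPKM,
#' the group 1 / group 2 assignment, and the human-escape annotation.
#' SRPM values are on the reads-per-10-million scale; tests that need raw
#' counts reuse them as count surrogates, which is recorded where done.
#'
#' @return a data frame with columns `gene`, `group`, per-tissue
#'   `*_xi`, `*_xa`, `*_rpkm`, `human_escape`, and `count_scope`.
#' @examples
#' t1 <- table1_fixture()
#' subset(t1, gene == "Cfp")
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_escape_srpm.tsv",
                      package = "xciescape", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reshape the packaged escape table into a count table for the fitter
#'
#' Expands the per-tissue SRPM columns of [table1_fixture()] into the long
#' per-gene-per-sample layout [xci_fit()] consumes, using the SRPM values
#' as allele-specific read-count surrogates and the printed RPKM directly.
#' Each tissue appears as one sample (the printed values are replicate
#' averages; ovary is a single pooled sample).
#'
#' @param t1 optionally, the fixture data frame.
#' @return a data frame with `gene`, `chrom`, `tissue`, `replicate`,
#'   `sample`, `n0`, `n1`, `rpkm`, `xi_srpm`, `xa_srpm`.
#' @export
table1_counts <- function(t1 = table1_fixture()) {
  tissues <- c("brain", "spleen", "ovary")
  out <- do.call(rbind, lapply(tissues, function(ti) {
    xi <- t1[[paste0(ti, "_xi")]]
    xa <- t1[[paste0(ti, "_xa")]]
    data.frame(gene = t1$gene, chrom = "chrX", tissue = ti, replicate = 1L,
               sample = ti, n0 = xi, n1 = xa,
               rpkm = t1[[paste0(ti, "_rpkm")]], xi_srpm = xi, xa_srpm = xa)
  }))
  rownames(out) <- NULL
  out
}
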