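# Pseudo-genome construction, SNP-based read segregation and per-gene
# allele-specific counting.

#' Build a pseudo-genome by substituting SNP alleles into a reference
#'
#' Produces the alternate parental genome used for unbiased allele-specific
#' alignment: the reference sequence with every diagnostic SNP's `alt` base
#' substituted at its (1-based) position. The reference base is asserted at
#' every SNP before substitution, so a stale or mismatched SNP table fails
#' loudly rather than corrupting the output; for the same reason, applying a
#' table to an already-substituted genome is rejected.
#'
#' @param genome a named [Biostrings::DNAStringSet], a named character
#'   vector of sequences, or a single unnamed sequence string (then the SNP
#'   table must contain a single chromosome).
#' @param snps data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @return a [Biostrings::DNAStringSet] of the same length and names as the
#'   input, differing from it exactly at the SNP positions.
#' @examples
#' as.character(build_pseudo_genome(c(chr1 = "ACGT"),
#'   data.frame(chrom = "chr1", pos = 2, ref = "C", alt = "T")))
#' @export
build_pseudo_genome <- function(genome, snps) {
  check_columns(snps, c("chrom", "pos", "ref", "alt"), "snps")
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      if (length(genome) != 1L || length(unique(snps$chrom)) > 1L)
        stop("unnamed genome sequences require a single-chromosome SNP table")
      names(genome) <- if (nrow(snps)) snps$chrom[1] else "chr"
    }
    genome <- Biostrings::DNAStringSet(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (any(snps$ref == snps$alt)) stop("SNP with ref equal to alt")
  out <- genome
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, ]
    if (!ch %in% names(genome))
      stop("SNP chromosome not in genome: ", ch)
    w <- length(genome[[ch]])
    bad <- s$pos < 1 | s$pos > w
    if (any(bad))
      stop(sprintf("SNP position out of bounds at %s:%d", ch,
                   s$pos[which(bad)[1]]))
    have <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(s$pos, s$pos)))
    bad <- have != s$ref
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("reference base mismatch at %s:%d (expected %s, found %s)",
                   ch, s$pos[i], s$ref[i], have[i]))
    }
    out[[ch]] <- Biostrings::replaceLetterAt(
      genome[[ch]], s$pos, paste(s$alt, collapse = ""))
  }
  out
}

#' Segregate reads into allele-specific categories by diagnostic SNPs
#'
#' Implements the high-quality read triage: reads below the MAPQ threshold
#' are set aside (`low_mapq`); reads overlapping no diagnostic SNP are
#' `uninformative`; reads whose observed bases all match one parental allele
#' get that allele's label, reported as `xi_specific`/`xa_specific` given
#' which parental allele is inactive; reads with mixed parental matches are
#' `conflicting`. An observed base matching neither `ref` nor `alt` is
#' treated as a sequencing error: that SNP is ignored for that read and a
#' summary is logged.
#'
#' @param reads data frame: `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `mapq`.
#' @param observations data frame of per-read SNP observations: `read_id`,
#'   `chrom`, `pos` (1-based SNP position), `base`.
#' @param snps SNP table (`chrom`, `pos`, `ref`, `alt`).
#' @param xi_allele `"ref"` or `"alt"`: which parental allele (column of the
#'   SNP table) lies on the inactive X in this sample.
#' @param mapq_min MAPQ threshold for the `low_mapq` triage (default 30).
#' @return the `reads` data frame with two added columns: `base_label`, the
#'   allele category ignoring MAPQ (`xi_specific`, `xa_specific`,
#'   `uninformative`, `conflicting`), and `label`, the final category with
#'   the MAPQ filter applied. Every read receives exactly one label.
#' @export
segregate_reads <- function(reads, observations, snps,
                            xi_allele = c("alt", "ref"), mapq_min = 30) {
  xi_allele <- match.arg(xi_allele)
  check_columns(reads, c("read_id", "chrom", "start", "end", "mapq"), "reads")
  check_columns(observations, c("read_id", "chrom", "pos", "base"),
                "observations")
  check_columns(snps, c("chrom", "pos", "ref", "alt"), "snps")
  stopifnot(all(reads$start < reads$end), all(reads$mapq >= 0))

  key <- paste(observations$chrom, observations$pos)
  skey <- paste(snps$chrom, snps$pos)
  idx <- match(key, skey)
  if (anyNA(idx))
    stop("observation at a position absent from the SNP table: ",
         key[which(is.na(idx))[1]])
  match_ref <- observations$base == snps$ref[idx]
  match_alt <- observations$base == snps$alt[idx]
  n_err <- sum(!match_ref & !match_alt)
  if (n_err > 0)
    xci_log(n_err, " observed base(s) matched neither parental allele; ",
            "treated as sequencing error and ignored")

  rid <- factor(observations$read_id, levels = reads$read_id)
  n_ref <- tapply(match_ref, rid, sum, default = 0L)
  n_alt <- tapply(match_alt, rid, sum, default = 0L)
  n_ref <- n_ref[as.character(reads$read_id)]
  n_alt <- n_alt[as.character(reads$read_id)]
  n_ref[is.na(n_ref)] <- 0L
  n_alt[is.na(n_alt)] <- 0L

  allele <- ifelse(n_ref > 0 & n_alt > 0, "conflicting",
            ifelse(n_ref > 0, "ref", ifelse(n_alt > 0, "alt",
                   "uninformative")))
  xi_lab <- xi_allele
  base_label <- ifelse(allele == xi_lab, "xi_specific",
                ifelse(allele %in% c("ref", "alt"), "xa_specific", allele))
  reads$base_label <- as.vector(base_label)
  reads$label <- ifelse(reads$mapq < mapq_min, "low_mapq", reads$base_label)
  reads
}

# Parse the comma-string exon columns of a gene-model data frame into an
# IRanges per gene (absolute, 0-based half-open -> IRanges is 1-based).
gene_exon_ranges <- function(gene_row) {
  st <- as.numeric(strsplit(gene_row$exon_starts, ",")[[1]])
  sz <- as.numeric(strsplit(gene_row$exon_sizes, ",")[[1]])
  IRanges::IRanges(start = st + 1, width = sz)
}

#' Count allele-specific reads per gene
#'
#' Assigns segregated reads to genes by interval overlap and tallies the
#' Xi- and Xa-specific counts plus the total informative reads per gene.
#' By default only exonic overlap counts and reads labelled `conflicting`
#' or `low_mapq` are excluded. `overrides` relaxes either rule for named
#' genes: `count_scope = "exonic+intronic"` counts reads anywhere in the
#' gene body (the lncRNA-with-intronic-SNPs case), and a per-gene
#' `mapq_min` rescues exonic reads that failed the global MAPQ filter (the
#' paralog-shadowed-exon case). A read overlapping several genes counts for
#' each; the multi-gene fraction is logged.
#'
#' @param reads output of [segregate_reads()].
#' @param genes gene models as from [sim_gene_models()] /
#'   [read_gene_models_bed12()].
#' @param overrides optional data frame: `gene`, and any of `count_scope`,
#'   `mapq_min`.
#' @param mapq_min global MAPQ threshold (must match the segregation call).
#' @return data frame: `gene`, `chrom`, `n0` (Xi), `n1` (Xa),
#'   `total_reads`, `exon_length_bp`.
#' @export
count_gene_alleles <- function(reads, genes, overrides = NULL,
                               mapq_min = 30) {
  check_columns(reads, c("read_id", "chrom", "start", "end", "mapq",
                         "base_label"), "reads")
  check_columns(genes, c("gene", "chrom", "start", "end", "exon_starts",
                         "exon_sizes", "exon_length_bp"), "genes")
  if (any(genes$exon_length_bp <= 0))
    stop("gene with zero exon length: ",
         genes$gene[which(genes$exon_length_bp <= 0)[1]])
  ov_scope <- ov_mapq <- NULL
  if (!is.null(overrides)) {
    check_columns(overrides, "gene", "overrides")
    ov_scope <- stats::setNames(overrides$count_scope %||%
                                  rep(NA, nrow(overrides)), overrides$gene)
    ov_mapq <- stats::setNames(overrides$mapq_min %||%
                                 rep(NA, nrow(overrides)), overrides$gene)
  }
  hits_per_read <- integer(nrow(reads))
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    scope <- ov_scope[g$gene] %||% NA
    scope <- if (!is.na(scope)) scope else "exonic"
    gm <- ov_mapq[g$gene] %||% NA
    gm <- if (!is.na(gm)) gm else mapq_min
    target <- if (scope == "exonic+intronic")
      IRanges::IRanges(g$start + 1, g$end) else gene_exon_ranges(g)
    on_chrom <- which(reads$chrom == g$chrom)
    r <- reads[on_chrom, ]
    hit <- IRanges::overlapsAny(IRanges::IRanges(r$start + 1, r$end), target)
    keep <- hit & r$mapq >= gm & r$base_label != "conflicting"
    hits_per_read[on_chrom[hit]] <<- hits_per_read[on_chrom[hit]] + 1L
    lab <- r$base_label[keep]
    data.frame(gene = g$gene, chrom = g$chrom,
               n0 = sum(lab == "xi_specific"),
               n1 = sum(lab == "xa_specific"),
               total_reads = sum(keep),
               exon_length_bp = g$exon_length_bp)
  }))
  multi <- mean(hits_per_read > 1L)
  if (is.finite(multi) && multi > 0)
    xci_log(sprintf("%.1f%% of reads overlap more than one gene and were counted for each",
                    100 * multi))
  rownames(out) <- NULL
  out
}

#' SNP reads per 10 million uniquely mapped reads (SRPM)
#'
#' The haploid expression unit: allele-specific SNP-containing exonic reads
#' scaled to a library of 10 million uniquely mapped reads, so counts are
#' comparable across samples.
#'
#' @param allele_read_count allele-specific read count(s).
#' @param library_size uniquely mapped reads in the sample.
#' @return `allele_read_count / (library_size / 1e7)`.
#' @examples
#' compute_srpm(40, 2e7)  # 20
#' @export
compute_srpm <- function(allele_read_count, library_size) {
  stopifnot(is.numeric(allele_read_count), all(allele_read_count >= 0))
  if (any(library_size <= 0)) stop("library_size must be positive")
  allele_read_count / (library_size / 1e7)
}

#' Reads per kilobase of exon per million mapped reads (RPKM)
#'
#' Diploid expression from total exonic reads, exon length and library size.
#'
#' @param total_exonic_reads total reads in the gene's exons.
#' @param exon_length_bp summed exon length in bp.
#' @param library_size mapped reads in the sample.
#' @return `1e9 * total_exonic_reads / (exon_length_bp * library_size)`.
#' @examples
#' compute_rpkm(1000, 2000, 1e7)  # 50
#' @export
compute_rpkm <- function(total_exonic_reads, exon_length_bp, library_size) {
  stopifnot(is.numeric(total_exonic_reads), all(total_exonic_reads >= 0))
  if (any(exon_length_bp <= 0)) stop("exon_length_bp must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  1e9 * total_exonic_reads / (exon_length_bp * library_size)
}

#' Estimate the mapping-bias ratio from autosomal allelic counts
#'
#' Alignment to two parental genomes is not perfectly symmetric; the
#' residual bias is estimated per experiment as \eqn{r_m = N_{A0}/N_{A1}},
#' the ratio of autosomal allele-specific reads mapped to the Xi-containing
#' genome versus the Xa-containing genome. Autosomes are biallelically
#' expressed, so any departure from 1 reflects mapping bias rather than
#' biology. All supplied autosomal counts are used; restrict the input
#' rows to exonic counts beforehand if desired.
#'
#' @param counts data frame with `chrom`, `n0`, `n1` (per gene or any other
#'   unit; rows on `x_chrom` are ignored).
#' @param x_chrom label of the X chromosome (excluded).
#' @param min_autosomal_reads below this total a warning is emitted, since
#'   the ratio becomes unstable.
#' @return the scalar ratio \eqn{r_m}.
#' @examples
#' compute_mapping_bias(data.frame(chrom = "chr1", n0 = 1.1e6, n1 = 1e6))
#' @export
compute_mapping_bias <- function(counts, x_chrom = "chrX",
                                 min_autosomal_reads = 1000) {
  check_columns(counts, c("chrom", "n0", "n1"), "counts")
  a <- counts[counts$chrom != x_chrom, ]
  if (nrow(a) == 0L) stop("no autosomal rows to estimate mapping bias from")
  n0 <- sum(a$n0); n1 <- sum(a$n1)
  if (n1 == 0 || n0 == 0)
    stop("mapping-bias estimate needs allele-specific autosomal reads on both sides")
  if (n0 + n1 < min_autosomal_reads)
    xci_log("only ", n0 + n1, " autosomal allele-specific reads; ",
            "mapping-bias estimate may be unstable", level = "warn")
  n0 / n1
}
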