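## File formats. All internal coordinates are 1-based inclusive; the BED
## half-open convention is translated in bed_to_1based()/write_bed() only.
## Reading relies on the standard Bioconductor parsers (VariantAnnotation,
## rtracklayer, Biostrings); writers emit the minimal dialect the simulator
## produces (haploid GT:DP:AF VCF, gene/mRNA/CDS/UTR GFF3, plain BED).

#' Read a haploid-genotype VCF into a variant panel
#'
#' Expects the minimal VCF v4.2 dialect written by [write_vcf()]: haploid `GT`
#' plus per-sample `DP` (depth) and `AF` (fraction of reads supporting the
#' called allele). Genotype indices are resolved to nucleotide alleles.
#'
#' @param path VCF file.
#' @return a `variant_panel` (see [variant_panel()]).
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(altl), function(i) paste(as.character(altl[[i]]), collapse = ","),
                character(1))
  sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      ref = ref, alt = alt,
                      qual = as.numeric(VariantAnnotation::qual(vcf)),
                      stringsAsFactors = FALSE)
  g <- VariantAnnotation::geno(vcf)
  gt_idx <- g$GT
  dn <- list(NULL, colnames(gt_idx))
  gt <- matrix(NA_character_, nrow(gt_idx), ncol(gt_idx), dimnames = dn)
  alleles <- mapply(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1]]),
                    ref, alt, SIMPLIFY = FALSE)
  for (j in seq_len(ncol(gt_idx))) {
    idx <- suppressWarnings(as.integer(gt_idx[, j]))
    gt[, j] <- vapply(seq_along(idx), function(i) {
      if (is.na(idx[i])) NA_character_ else alleles[[i]][idx[i] + 1L]
    }, character(1))
  }
  rownames(sites) <- NULL
  variant_panel(sites, gt = gt,
                dp = matrix(as.integer(g$DP), nrow(gt), ncol(gt), dimnames = dn),
                af = matrix(as.numeric(g$AF), nrow(gt), ncol(gt), dimnames = dn))
}

#' Write a variant panel as a minimal haploid VCF
#'
#' @param panel a `variant_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "variant_panel"))
  s <- panel$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Fraction of reads supporting the called allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            panel$individuals), collapse = "\t")), con)
  for (i in seq_len(nrow(s))) {
    alleles <- c(s$ref[i], strsplit(s$alt[i], ",", fixed = TRUE)[[1]])
    idx <- match(panel$gt[i, ], alleles) - 1L
    if (anyNA(idx)) stop_input("site %s:%d carries an allele absent from REF/ALT", s$chrom[i], s$pos[i])
    fmt <- sprintf("%d:%d:%.4f", idx, panel$dp[i, ], panel$af[i, ])
    writeLines(paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i],
                       sprintf("%.6g", s$qual[i]), ".", ".", "GT:DP:AF", fmt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED file (0-based half-open).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write 1-based inclusive intervals as BED
#' @param intervals data.frame with `chrom`, `start`, `end`, optional `name`.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  cols <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end)
  if (!is.null(intervals$name)) cols$name <- intervals$name
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 (+ optional CDS FASTA)
#'
#' Supports the subset written by [write_gene_models()]: `gene`, `mRNA`, `CDS`
#' and UTR features, one mRNA per gene.
#'
#' @param gff_path GFF3 file.
#' @param cds_fasta_path optional FASTA of spliced CDS sequences named by gene id.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(gff_path, cds_fasta_path = NULL) {
  gr <- rtracklayer::import(gff_path, format = "GFF3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  gene_rows <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = gene_rows$ID,
                      chrom = gene_rows$seqnames,
                      strand = as.character(gene_rows$strand),
                      start = gene_rows$start, end = gene_rows$end,
                      stringsAsFactors = FALSE)
  mrna <- df[df$type == "mRNA", ]
  mrna2gene <- setNames(vapply(mrna$Parent, `[`, character(1), 1), mrna$ID)
  feat_tab <- function(types) {
    rows <- df[df$type %in% types, ]
    if (!nrow(rows)) return(data.frame(gene_id = character(), chrom = character(),
                                       start = integer(), end = integer()))
    parent <- vapply(rows$Parent, `[`, character(1), 1)
    gene_id <- ifelse(parent %in% names(mrna2gene), mrna2gene[parent], parent)
    data.frame(gene_id = unname(gene_id), chrom = rows$seqnames,
               start = rows$start, end = rows$end, stringsAsFactors = FALSE)
  }
  cds_seq <- NULL
  if (!is.null(cds_fasta_path)) {
    ss <- Biostrings::readDNAStringSet(cds_fasta_path)
    cds_seq <- setNames(as.character(ss), names(ss))
  }
  gene_models(genes,
              cds = feat_tab("CDS"),
              utr = feat_tab(c("five_prime_UTR", "three_prime_UTR", "UTR")),
              cds_seq = cds_seq)
}

#' Write gene models as GFF3 (and optionally the CDS FASTA)
#' @param models a `gene_models` object.
#' @param gff_path output GFF3 file.
#' @param cds_fasta_path optional output FASTA for spliced CDS sequences.
#' @export
write_gene_models <- function(models, gff_path, cds_fasta_path = NULL) {
  stopifnot(inherits(models, "gene_models"))
  con <- file(gff_path, "w")
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, start, end, strand, attrs)
    paste(chrom, "supergeneASE", type, start, end, ".", strand, ".", attrs, sep = "\t")
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    writeLines(fmt(g$chrom, "gene", g$start, g$end, g$strand,
                   sprintf("ID=%s", g$gene_id)), con)
    writeLines(fmt(g$chrom, "mRNA", g$start, g$end, g$strand,
                   sprintf("ID=%s.t1;Parent=%s", g$gene_id, g$gene_id)), con)
    cds <- models$cds[models$cds$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(cds)))
      writeLines(fmt(g$chrom, "CDS", cds$start[j], cds$end[j], g$strand,
                     sprintf("ID=%s.cds;Parent=%s.t1", g$gene_id, g$gene_id)), con)
    utr <- models$utr[models$utr$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(utr)))
      writeLines(fmt(g$chrom, "UTR", utr$start[j], utr$end[j], g$strand,
                     sprintf("ID=%s.utr%d;Parent=%s.t1", g$gene_id, j, g$gene_id)), con)
  }
  close(con)
  if (!is.null(cds_fasta_path) && !is.null(models$cds_seq)) {
    ss <- Biostrings::DNAStringSet(models$cds_seq)
    Biostrings::writeXStringSet(ss, cds_fasta_path)
  }
  invisible(gff_path)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers around [utils::read.delim()]/[utils::write.table()] with the
#' conventions used throughout the package (header row, no quoting, no row
#' names). CRLF input is handled by the base reader.
#'
#' @param path file path.
#' @return `read_tsv`: a data.frame.
#' @export
read_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) > 1 && length(unique(nf)) > 1)
    stop_input("malformed TSV '%s': line %d has %d fields (header has %d)",
               path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  tryCatch(
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE, fill = FALSE),
    error = function(e) stop_input("malformed TSV '%s': %s", path, conditionMessage(e)))
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
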