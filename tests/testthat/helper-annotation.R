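# Builders for annotation scenarios shared by the annotate and acceptance
# tests.

# df has gene_id, chrom, start, end, strand, optionally biotype; exons is a
# named list of start/end matrices.
make_genes <- function(df, exons = list(), chrom_length = NULL) {
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    gene_id = df$gene_id, symbol = toupper(df$gene_id),
    biotype = if (!is.null(df$biotype)) df$biotype else "protein_coding")
  names(gr) <- df$gene_id
  ex <- lapply(df$gene_id, function(g) {
    if (is.null(exons[[g]])) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom[df$gene_id == g],
                           IRanges::IRanges(exons[[g]][, 1], exons[[g]][, 2]))
  })
  names(ex) <- df$gene_id
  S4Vectors::metadata(gr)$exons <- GenomicRanges::GRangesList(ex)
  if (!is.null(chrom_length))
    GenomeInfoDb::seqlengths(gr) <-
      setNames(rep(chrom_length, length(unique(df$chrom))), unique(df$chrom))
  gr
}

anchored_peaks <- function(anchors, chrom = "chr1", half_width = 50) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(pmax(1, anchors - half_width),
                                          anchors + half_width),
                         anchor = as.integer(anchors))
}

# Random single-chromosome genome (non-overlapping genes, half with a
# two-exon structure) plus random anchor positions.
random_annotation_case <- function(L = 100000, n_genes = 8, n_peaks = 15) {
  start <- sort(sample.int(L - 3000, n_genes))
  len <- sample(500:2000, n_genes, replace = TRUE)
  df <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                   chrom = "chr1", start = start,
                   end = pmin(start + len, L),
                   strand = sample(c("+", "-"), n_genes, replace = TRUE))
  keep <- c(TRUE, df$start[-1] > df$end[-n_genes])
  df <- df[keep, ]
  exons <- list()
  for (g in df$gene_id[sample.int(nrow(df), ceiling(nrow(df) / 2))]) {
    row <- df[df$gene_id == g, ]
    w <- row$end - row$start
    if (w < 10) next
    mid <- row$start + sample.int(w - 5, 1)
    exons[[g]] <- cbind(c(row$start, mid + 3), c(mid, row$end))
  }
  list(genes = make_genes(df, exons, chrom_length = L),
       anchors = sample.int(L, n_peaks), L = L)
}

# Reflect a gene set through position L: coordinates reverse, strands flip.
mirror_genes <- function(genes, L) {
  ex <- S4Vectors::metadata(genes)$exons
  df <- data.frame(gene_id = S4Vectors::mcols(genes)$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(genes)),
                   start = L + 1 - GenomicRanges::end(genes),
                   end = L + 1 - GenomicRanges::start(genes),
                   strand = ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                                   "-", "+"))
  mex <- list()
  for (g in df$gene_id) {
    e <- ex[[g]]
    if (length(e))
      mex[[g]] <- cbind(rev(L + 1 - GenomicRanges::end(e)),
                        rev(L + 1 - GenomicRanges::start(e)))
  }
  make_genes(df, mex, chrom_length = L)
}
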