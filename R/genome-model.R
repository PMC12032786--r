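#' Read gene models from a GFF3 annotation
#'
#' Parses gene-level records (and their exon children) from a GFF3 stream into
#' a `GRanges` of gene models. GFF3 coordinates are 1-based inclusive and are
#' kept in that convention inside the `GRanges` container; BED-family inputs
#' are converted at their own readers instead.
#'
#' Gene strand must be `+` or `-`: a transcription start site is undefined
#' without strand, so records with strand `.` are rejected. The biotype is
#' taken from a `biotype=` or `gene_biotype=` attribute; for records whose
#' feature type is `tRNA` it falls back to `"tRNA"`, otherwise to
#' `"protein_coding"`.
#'
#' @param path path to a GFF3 file (plain or gzip).
#' @param feature_types feature types (column 3) treated as gene-level records.
#' @return a `GRanges` with metadata columns `gene_id`, `symbol`, `biotype`;
#'   exon children are attached as a named `GRangesList` in
#'   `S4Vectors::metadata(x)$exons` (one element per gene, possibly empty).
#'   Chromosome lengths found in `##sequence-region` pragmas are recorded as
#'   `seqlengths`.
#' @export
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;biotype=protein_coding"), gff)
#' genes <- read_gene_annotation(gff)
#' tss(genes)
read_gene_annotation <- function(path, feature_types = c("gene", "tRNA")) {
  lines <- readLines(gzfile(path), warn = FALSE)
  seqlens <- integer(0)
  genes <- list()
  exons <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    if (startsWith(line, "##sequence-region")) {
      f <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(f) >= 4) seqlens[f[2]] <- as.integer(f[4])
      next
    }
    if (startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stopf("GFF3 parse error at line %d: expected 9 tab-separated columns, found %d",
            i, length(f))
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1L || end < start)
      stopf("GFF3 parse error at line %d: invalid coordinates '%s'-'%s'",
            i, f[4], f[5])
    if (!f[7] %in% c("+", "-", "."))
      stopf("GFF3 parse error at line %d: invalid strand '%s'", i, f[7])
    attrs <- parse_gff3_attributes(f[9], i)
    type <- f[3]
    if (type %in% feature_types) {
      gid <- attrs[["ID"]]
      if (is.null(gid))
        stopf("GFF3 parse error at line %d: gene-level record lacks an ID attribute", i)
      if (f[7] == ".")
        stopf("gene record '%s' (line %d) has strand '.': TSS undefined without strand",
              gid, i)
      if (!is.null(genes[[gid]]))
        stopf("duplicate gene ID '%s' at line %d", gid, i)
      biotype <- attrs[["biotype"]] %||% attrs[["gene_biotype"]] %||%
        (if (type == "tRNA") "tRNA" else "protein_coding")
      genes[[gid]] <- list(chrom = f[1], start = start, end = end,
                           strand = f[7], gene_id = gid,
                           symbol = attrs[["Name"]] %||% gid,
                           biotype = biotype)
    } else if (type == "exon") {
      parent <- attrs[["Parent"]]
      if (is.null(parent))
        stopf("GFF3 parse error at line %d: exon record lacks a Parent attribute", i)
      exons[[parent]] <- rbind(exons[[parent]],
                               data.frame(chrom = f[1], start = start, end = end,
                                          line = i))
    }
  }
  gr <- if (length(genes)) {
    GenomicRanges::GRanges(
      seqnames = unname(vapply(genes, `[[`, "", "chrom")),
      ranges = IRanges::IRanges(unname(vapply(genes, `[[`, 0L, "start")),
                                unname(vapply(genes, `[[`, 0L, "end"))),
      strand = unname(vapply(genes, `[[`, "", "strand")),
      gene_id = unname(vapply(genes, `[[`, "", "gene_id")),
      symbol = unname(vapply(genes, `[[`, "", "symbol")),
      biotype = unname(vapply(genes, `[[`, "", "biotype")))
  } else {
    GenomicRanges::GRanges(gene_id = character(0), symbol = character(0),
                           biotype = character(0))
  }
  names(gr) <- mcols(gr)$gene_id
  orphan <- setdiff(names(exons), names(gr))
  if (length(orphan))
    stopf("exon records reference unknown Parent gene(s): %s",
          paste(orphan, collapse = ", "))
  exon_list <- lapply(names(gr), function(gid) {
    ex <- exons[[gid]]
    if (is.null(ex)) return(GenomicRanges::GRanges())
    ex <- ex[order(ex$start), , drop = FALSE]
    gx <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
    g <- gr[gid]
    if (any(GenomicRanges::start(gx) < GenomicRanges::start(g)) ||
        any(GenomicRanges::end(gx) > GenomicRanges::end(g)) ||
        any(as.character(seqnames(gx)) != as.character(seqnames(g))))
      stopf("exon of gene '%s' extends outside the gene interval", gid)
    if (length(gx) > 1 &&
        any(GenomicRanges::start(gx)[-1] <= GenomicRanges::end(gx)[-length(gx)]))
      stopf("exons of gene '%s' overlap", gid)
    gx
  })
  names(exon_list) <- names(gr)
  if (length(seqlens)) {
    keep <- intersect(names(seqlens), seqlevels(gr))
    if (length(keep)) seqlengths(gr)[keep] <- seqlens[keep]
  }
  metadata(gr)$exons <- GenomicRanges::GRangesList(exon_list)
  gr
}

parse_gff3_attributes <- function(field, line_no) {
  if (!nzchar(field) || field == ".") return(list())
  pairs <- strsplit(field, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in trimws(pairs)) {
    if (!nzchar(p)) next
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0)
      stopf("GFF3 parse error at line %d: attribute '%s' is not key=value", line_no, p)
    out[[substr(p, 1, eq - 1)]] <- substr(p, eq + 1, nchar(p))
  }
  out
}

#' Write gene models back to GFF3
#'
#' Inverse of [read_gene_annotation()]: emits one `gene` (or `tRNA`) record per
#' gene model plus its exon children, with `##sequence-region` pragmas for any
#' known chromosome lengths. Reading the result reproduces the input
#' coordinates exactly.
#'
#' @param genes a `GRanges` of gene models as returned by
#'   [read_gene_annotation()] or [simulate_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- "##gff-version 3"
  sl <- seqlengths(genes)
  for (chr in names(sl)[!is.na(sl)])
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", chr, sl[[chr]]))
  exons <- metadata(genes)$exons
  for (i in seq_along(genes)) {
    g <- genes[i]
    gid <- mcols(g)$gene_id
    type <- if (mcols(g)$biotype == "tRNA") "tRNA" else "gene"
    lines <- c(lines, sprintf(
      "%s\tchipcons\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=%s",
      as.character(seqnames(g)), type, start(g), end(g),
      as.character(GenomicRanges::strand(g)), gid, mcols(g)$symbol,
      mcols(g)$biotype))
    ex <- exons[[gid]]
    if (!is.null(ex) && length(ex)) {
      lines <- c(lines, sprintf(
        "%s\tchipcons\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        as.character(seqnames(g)), start(ex), end(ex),
        as.character(GenomicRanges::strand(g)), gid, seq_along(ex), gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Transcription start sites of gene models
#'
#' The TSS is the first transcribed base: the gene start for `+` strand genes
#' and the gene end for `-` strand genes (1-based coordinates).
#'
#' @param genes a `GRanges` of gene models.
#' @return an integer vector of 1-based TSS positions, named by `gene_id` when
#'   available.
#' @export
tss <- function(genes) {
  s <- as.character(GenomicRanges::strand(genes))
  if (any(!s %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'; TSS is undefined otherwise")
  out <- ifelse(s == "+", start(genes), end(genes))
  names(out) <- mcols(genes)$gene_id
  out
}

#' Promoter windows around transcription start sites
#'
#' The promoter is the region from `upstream` bp before to `downstream` bp
#' after the TSS, measured in the direction of transcription and including the
#' TSS base itself (so the unclamped width is `upstream + downstream + 1`).
#' With the symmetric defaults (1000/1000) the genomic window does not depend
#' on strand. Windows are clamped to chromosome bounds where chromosome
#' lengths are known (never dropped).
#'
#' @param genes a `GRanges` of gene models with strand `+`/`-`.
#' @param upstream,downstream non-negative extents in bp before/after the TSS.
#' @return a `GRanges` of promoter windows carrying `gene_id`.
#' @export
promoter_windows <- function(genes, upstream = 1000, downstream = 1000) {
  stopifnot(upstream >= 0, downstream >= 0)
  if (length(genes) == 0) return(genes)
  win <- suppressWarnings(GenomicRanges::promoters(genes, upstream = upstream,
                                                   downstream = downstream + 1))
  win <- GenomicRanges::trim(win)
  GenomicRanges::start(win) <- pmax(GenomicRanges::start(win), 1L)
  win
}
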