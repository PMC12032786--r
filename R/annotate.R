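#' Assign consensus peaks to genomic features and target genes
#'
#' Each peak is represented by a single anchor point (its `anchor` metadata
#' column when present — consensus peaks carry the member-summit median — else
#' the floor midpoint of the interval) and assigned exactly one feature
#' category with the precedence
#' promoter > exon > intron/gene_body > downstream > distal_intergenic:
#' \itemize{
#'   \item `promoter`: anchor inside a gene's promoter window
#'     ([promoter_windows()]);
#'   \item `exon` / `intron`: anchor inside the gene span of a gene with exon
#'     structure, in or between its exons; `gene_body` when the gene has no
#'     exon records;
#'   \item `downstream`: anchor within `downstream_bp` past the transcription
#'     end site, in the direction of transcription;
#'   \item `distal_intergenic`: everything else; the nearest gene (by distance
#'     to TSS on the same chromosome) is still reported.
#' }
#' Among genes qualifying at the winning category the one with the smallest
#' absolute TSS distance is assigned; ties break lexicographically on
#' `gene_id`. The signed `distance_to_tss` is positive in the direction of
#' transcription of the assigned gene.
#'
#' @param peaks a `GRanges` of (consensus) peaks; an optional integer `anchor`
#'   metadata column fixes the anchor point (1-based).
#' @param genes a `GRanges` of gene models from [read_gene_annotation()] or
#'   [simulate_genome()].
#' @param promoter_up,promoter_down promoter extents in bp before/after the
#'   TSS (defaults 1000/1000).
#' @param downstream_bp extent of the downstream category past the gene end
#'   (default 3000, the convention of standard peak annotators).
#' @return `peaks` with added metadata columns `anchor`, `category`,
#'   `gene_id`, `symbol`, `biotype`, `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_up = 1000,
                           promoter_down = 1000, downstream_bp = 3000) {
  if (length(genes) == 0) stopf("annotate_peaks: empty gene set")
  if (length(peaks) == 0) {
    mcols(peaks)$anchor <- integer(0)
    mcols(peaks)$category <- character(0)
    mcols(peaks)$gene_id <- character(0)
    mcols(peaks)$symbol <- character(0)
    mcols(peaks)$biotype <- character(0)
    mcols(peaks)$distance_to_tss <- integer(0)
    return(peaks)
  }
  anchor <- mcols(peaks)$anchor
  if (is.null(anchor))
    anchor <- as.integer(floor((start(peaks) - 1 + end(peaks)) / 2) + 1L)
  anchors <- GenomicRanges::GRanges(seqnames(peaks),
                                    IRanges::IRanges(anchor, width = 1))

  tss_pos <- tss(genes)
  gene_strand <- as.character(GenomicRanges::strand(genes))
  gene_ids <- mcols(genes)$gene_id
  exons <- metadata(genes)$exons
  has_exons <- if (is.null(exons)) rep(FALSE, length(genes))
               else lengths(exons)[gene_ids] > 0

  # signed distance from anchor to a gene's TSS, + in transcription direction
  signed_dist <- function(peak_i, gene_j) {
    d <- anchor[peak_i] - tss_pos[gene_j]
    ifelse(gene_strand[gene_j] == "+", d, -d)
  }
  # candidate hits (peak i, gene j) per category
  hits_in <- function(windows) {
    h <- GenomicRanges::findOverlaps(anchors, windows, ignore.strand = TRUE)
    cbind(queryHits(h), subjectHits(h))
  }

  prom <- promoter_windows(genes, promoter_up, promoter_down)
  cand_prom <- hits_in(prom)

  exon_hits <- matrix(integer(0), ncol = 2)
  if (any(has_exons)) {
    flat <- unlist(exons, use.names = FALSE)
    flat_gene <- rep(match(names(exons), gene_ids), lengths(exons))
    if (length(flat)) {
      h <- GenomicRanges::findOverlaps(anchors, flat, ignore.strand = TRUE)
      exon_hits <- unique(cbind(queryHits(h), flat_gene[subjectHits(h)]))
    }
  }
  cand_body <- hits_in(genes)

  down_start <- ifelse(gene_strand == "+", end(genes) + 1L,
                       pmax(1L, start(genes) - downstream_bp))
  down_end <- ifelse(gene_strand == "+", end(genes) + downstream_bp,
                     start(genes) - 1L)
  ok <- down_end >= down_start
  down_win <- GenomicRanges::GRanges(seqnames(genes)[ok],
                                     IRanges::IRanges(down_start[ok], down_end[ok]))
  cand_down <- hits_in(down_win)
  if (nrow(cand_down)) cand_down[, 2] <- which(ok)[cand_down[, 2]]

  n <- length(peaks)
  category <- character(n)
  gene_idx <- integer(n)
  distance <- integer(n)

  pick_best <- function(cand, i) {
    js <- cand[cand[, 1] == i, 2]
    if (!length(js)) return(NULL)
    d <- signed_dist(i, js)
    ord <- order(abs(d), gene_ids[js])
    list(j = js[ord[1]], d = d[ord[1]])
  }

  peak_chrom <- as.character(seqnames(anchors))
  gene_chrom <- as.character(seqnames(genes))
  for (i in seq_len(n)) {
    best <- pick_best(cand_prom, i)
    if (!is.null(best)) {
      category[i] <- "promoter"
    } else if (!is.null(best <- pick_best(exon_hits, i))) {
      category[i] <- "exon"
    } else if (!is.null(best <- pick_best(cand_body, i))) {
      category[i] <- if (has_exons[best$j]) "intron" else "gene_body"
    } else if (!is.null(best <- pick_best(cand_down, i))) {
      category[i] <- "downstream"
    } else {
      js <- which(gene_chrom == peak_chrom[i])
      if (!length(js)) {
        category[i] <- "distal_intergenic"
        gene_idx[i] <- NA_integer_
        distance[i] <- NA_integer_
        next
      }
      d <- signed_dist(i, js)
      ord <- order(abs(d), gene_ids[js])
      best <- list(j = js[ord[1]], d = d[ord[1]])
      category[i] <- "distal_intergenic"
    }
    gene_idx[i] <- best$j
    distance[i] <- best$d
  }

  mcols(peaks)$anchor <- anchor
  mcols(peaks)$category <- category
  mcols(peaks)$gene_id <- ifelse(is.na(gene_idx), NA_character_,
                                 gene_ids[gene_idx])
  mcols(peaks)$symbol <- ifelse(is.na(gene_idx), NA_character_,
                                mcols(genes)$symbol[gene_idx])
  mcols(peaks)$biotype <- ifelse(is.na(gene_idx), NA_character_,
                                 mcols(genes)$biotype[gene_idx])
  mcols(peaks)$distance_to_tss <- distance
  peaks
}

#' Feature categories recognised by the annotator
#' @export
feature_categories <- function() {
  c("promoter", "exon", "intron", "gene_body", "downstream",
    "distal_intergenic")
}

#' Proportion of peaks per annotated feature
#'
#' @param annotated a non-empty `GRanges` from [annotate_peaks()].
#' @return a named numeric vector over all categories (absent categories
#'   report 0) summing to 1.
#' @export
feature_distribution <- function(annotated) {
  if (length(annotated) == 0)
    stopf("feature_distribution: empty input")
  cats <- factor(mcols(annotated)$category, levels = feature_categories())
  frac <- as.vector(table(cats)) / length(annotated)
  setNames(frac, feature_categories())
}

#' Promoter target-gene table for one condition
#'
#' Restricts annotated peaks to the promoter category, removes rows whose
#' assigned gene has an excluded biotype (by default tRNA, whose dense
#' promoter-like hits would otherwise inflate target counts), and reports the
#' unique-peak and unique-gene tallies.
#'
#' @param annotated a `GRanges` from [annotate_peaks()], all from one
#'   condition.
#' @param condition condition label; defaults to the label carried by the
#'   peaks.
#' @param exclude_biotypes character vector of gene biotypes to drop
#'   (default `"tRNA"`).
#' @return an object of class `target_table`: a list with `condition`,
#'   `rows` (data frame: consensus_id, gene_id, symbol, biotype, category,
#'   distance_to_tss), `n_unique_peaks`, `n_unique_genes`.
#' @export
target_table <- function(annotated, condition = NULL,
                         exclude_biotypes = "tRNA") {
  if (is.null(condition)) {
    condition <- unique(mcols(annotated)$condition)
    condition <- condition[!is.na(condition)]
    if (length(condition) > 1)
      stopf("target_table: peaks mix condition labels")
    if (length(condition) == 0) condition <- NA_character_
  }
  mc <- as.data.frame(mcols(annotated))
  if (is.null(mc$consensus_id))
    mc$consensus_id <- paste0("peak_", seq_len(length(annotated)))
  keep <- mc$category == "promoter" & !(mc$biotype %in% exclude_biotypes)
  keep[is.na(keep)] <- FALSE
  rows <- data.frame(
    consensus_id = mc$consensus_id[keep],
    gene_id = mc$gene_id[keep],
    symbol = mc$symbol[keep],
    biotype = mc$biotype[keep],
    category = mc$category[keep],
    distance_to_tss = mc$distance_to_tss[keep])
  structure(list(condition = condition, rows = rows,
                 n_unique_peaks = length(unique(rows$consensus_id)),
                 n_unique_genes = length(unique(rows$gene_id))),
            class = "target_table")
}

#' @export
print.target_table <- function(x, ...) {
  cat(sprintf("Promoter target table [%s]: %d unique peaks -> %d unique genes\n",
              x$condition, x$n_unique_peaks, x$n_unique_genes))
  if (nrow(x$rows)) print(head(x$rows, 10))
  invisible(x)
}
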