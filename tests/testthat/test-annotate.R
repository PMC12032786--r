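test_that("anchor on the TSS yields promoter with distance 0; strand sets the distance sign", {
  genes <- make_genes(data.frame(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(10000, 20001), end = c(12000, 25000),
    strand = c("+", "-")))
  ann <- annotate_peaks(anchored_peaks(c(10000, 25000)), genes)
  expect_equal(S4Vectors::mcols(ann)$category, c("promoter", "promoter"))
  expect_equal(S4Vectors::mcols(ann)$gene_id, c("plus", "minus"))
  expect_equal(S4Vectors::mcols(ann)$distance_to_tss, c(0L, 0L))

  # minus-strand gene, anchor 499 bp downstream in transcription direction
  ann <- annotate_peaks(anchored_peaks(25000 - 499), genes)
  expect_equal(S4Vectors::mcols(ann)$distance_to_tss, 499L)
  # plus-strand gene, anchor 300 bp before the TSS: negative distance
  ann <- annotate_peaks(anchored_peaks(10000 - 300), genes)
  expect_equal(S4Vectors::mcols(ann)$distance_to_tss, -300L)
})

test_that("category precedence and exon structure drive the assignment", {
  genes <- make_genes(
    data.frame(gene_id = c("gx", "gp"), chrom = "chr1",
               start = c(10000, 40000), end = c(20000, 46000),
               strand = "+"),
    exons = list(gx = cbind(c(10000, 15000), c(11000, 16000))))
  cases <- list(
    list(anchor = 10500, cat = "promoter", gene = "gx"),   # in exon AND promoter
    list(anchor = 15500, cat = "exon", gene = "gx"),
    list(anchor = 13000, cat = "intron", gene = "gx"),
    list(anchor = 43000, cat = "gene_body", gene = "gp"),  # no exon records
    list(anchor = 21000, cat = "downstream", gene = "gx"),
    # equally far from both gene bodies but nearer gp's TSS (10 kb vs 20 kb)
    list(anchor = 30000, cat = "distal_intergenic", gene = "gp"))
  for (cs in cases) {
    ann <- annotate_peaks(anchored_peaks(cs$anchor), genes)
    expect_equal(S4Vectors::mcols(ann)$category, cs$cat, label = cs$anchor)
    expect_equal(S4Vectors::mcols(ann)$gene_id, cs$gene, label = cs$anchor)
  }
})

test_that("distal peaks report the nearest gene by TSS distance with lexicographic ties", {
  genes <- make_genes(data.frame(
    gene_id = c("b_gene", "a_gene"), chrom = "chr1",
    start = c(10000, 30000), end = c(11000, 31000), strand = "+"))
  # anchor equidistant (10 kb) from both TSSs
  ann <- annotate_peaks(anchored_peaks(20000), genes,
                        promoter_up = 100, promoter_down = 100,
                        downstream_bp = 100)
  expect_equal(S4Vectors::mcols(ann)$category, "distal_intergenic")
  expect_equal(S4Vectors::mcols(ann)$gene_id, "a_gene")
  expect_equal(abs(S4Vectors::mcols(ann)$distance_to_tss), 10000L)
})

test_that("without an anchor column the floor midpoint is used", {
  genes <- make_genes(data.frame(gene_id = "g", chrom = "chr1",
                                 start = 5000, end = 6000, strand = "+"))
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4901, 5100))
  ann <- annotate_peaks(pk, genes)
  expect_equal(S4Vectors::mcols(ann)$anchor, 5001L)  # floor((4900+5100)/2)+1
  expect_equal(S4Vectors::mcols(ann)$category, "promoter")
})

test_that("feature fractions cover all categories and sum to one", {
  genes <- make_genes(data.frame(gene_id = "g", chrom = "chr1",
                                 start = 5000, end = 6000, strand = "+"))
  ann <- annotate_peaks(anchored_peaks(c(5000, 5010, 5100, 50000)), genes)
  fd <- feature_distribution(ann)
  expect_named(fd, feature_categories())
  expect_equal(sum(fd), 1, tolerance = 1e-12)
  expect_equal(unname(fd["promoter"]), 0.75)
  expect_equal(unname(fd["distal_intergenic"]), 0.25)
  expect_error(feature_distribution(ann[0]), "empty")
})

test_that("target tables keep promoter rows and apply biotype exclusion", {
  genes <- make_genes(data.frame(
    gene_id = c("g1", "t7"), chrom = "chr1",
    start = c(10000, 30000), end = c(12000, 30072),
    strand = "+", biotype = c("protein_coding", "tRNA")))
  pk <- anchored_peaks(c(10000, 10400, 30000, 50000))
  S4Vectors::mcols(pk)$consensus_id <- paste0("cons_", 1:4)
  S4Vectors::mcols(pk)$condition <- "adult_male"
  ann <- annotate_peaks(pk, genes)
  expect_equal(S4Vectors::mcols(ann)$category[1:3], rep("promoter", 3))

  tt <- target_table(ann)
  expect_equal(tt$condition, "adult_male")
  expect_equal(tt$n_unique_peaks, 2)   # two peaks on g1's promoter
  expect_equal(tt$n_unique_genes, 1)   # the tRNA target is excluded
  expect_false("t7" %in% tt$rows$gene_id)

  tt_all <- target_table(ann, exclude_biotypes = character(0))
  expect_equal(tt_all$n_unique_genes, 2)
  expect_equal(tt_all$n_unique_peaks, 3)
})

test_that("annotation is invariant under coordinate mirroring", {
  set.seed(777)
  for (i in 1:100) {
    case <- random_annotation_case()
    ann <- annotate_peaks(anchored_peaks(case$anchors, half_width = 20),
                          case$genes)
    m_ann <- annotate_peaks(
      anchored_peaks(case$L + 1 - case$anchors, half_width = 20),
      mirror_genes(case$genes, case$L))
    expect_equal(S4Vectors::mcols(m_ann)$category,
                 S4Vectors::mcols(ann)$category)
    expect_equal(S4Vectors::mcols(m_ann)$gene_id,
                 S4Vectors::mcols(ann)$gene_id)
    expect_equal(S4Vectors::mcols(m_ann)$distance_to_tss,
                 S4Vectors::mcols(ann)$distance_to_tss)
  }
})

test_that("enlarging promoter extents never decreases promoter-annotated peaks", {
  set.seed(888)
  for (i in 1:20) {
    case <- random_annotation_case()
    peaks <- anchored_peaks(case$anchors)
    n_prom <- vapply(c(200, 500, 1000, 2000), function(ext) {
      ann <- annotate_peaks(peaks, case$genes,
                            promoter_up = ext, promoter_down = ext)
      sum(S4Vectors::mcols(ann)$category == "promoter")
    }, 0)
    expect_true(all(diff(n_prom) >= 0))
  }
})
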