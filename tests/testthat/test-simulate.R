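small_config <- function(seed = 1, frac_trna = 0.1, ...) {
  sim_config(seed = seed, n_chroms = 1, chrom_length = 5e5, n_genes = 50,
             frac_trna = frac_trna,
             conditions = data.frame(label = "cond_a", n_replicates = 3,
                                     n_target_genes = 10),
             ...)
}

test_that("simulated genomes are deterministic, non-overlapping and respect the gene gap", {
  cfg <- small_config(seed = 11)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_gene_annotation(g1, f1)
  write_gene_annotation(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(length(g1), 50)
  expect_equal(sum(S4Vectors::mcols(g1)$biotype == "tRNA"), 5)
  expect_true(all(start(g1) >= 1 & end(g1) <= 5e5))
  ord <- order(start(g1))
  gaps <- start(g1)[ord][-1] - end(g1)[ord][-50] - 1
  expect_true(all(gaps >= cfg$min_gene_gap))

  # tRNA fraction of zero and an empty genome are honoured
  expect_equal(sum(S4Vectors::mcols(simulate_genome(
    small_config(frac_trna = 0)))$biotype == "tRNA"), 0)
  g0 <- simulate_genome(sim_config(n_genes = 0, conditions = data.frame(
    label = "c", n_replicates = 2, n_target_genes = 0)))
  expect_equal(length(g0), 0)
})

test_that("infeasible gene packing is rejected", {
  expect_error(simulate_genome(sim_config(
    n_genes = 100, chrom_length = 1e4,
    conditions = data.frame(label = "c", n_replicates = 2,
                            n_target_genes = 1))),
    "infeasible packing")
})

test_that("simulated genomes round-trip through GFF3", {
  g1 <- simulate_genome(small_config(seed = 5))
  f <- tempfile(fileext = ".gff3")
  write_gene_annotation(g1, f)
  g2 <- read_gene_annotation(f)
  expect_equal(start(g2), start(g1))
  expect_equal(end(g2), end(g1))
  expect_equal(as.character(strand(g2)), as.character(strand(g1)))
  expect_equal(S4Vectors::mcols(g2)$biotype, S4Vectors::mcols(g1)$biotype)
  expect_equal(lengths(S4Vectors::metadata(g2)$exons),
               lengths(S4Vectors::metadata(g1)$exons))
})

test_that("condition simulation is deterministic and consistent with its ground truth", {
  cfg <- small_config(seed = 21)
  genome <- simulate_genome(cfg)
  s1 <- simulate_condition(cfg, genome, "cond_a")
  s2 <- simulate_condition(cfg, genome, "cond_a")
  expect_equal(s1$truth, s2$truth)
  expect_equal(lapply(s1$peaks, as.data.frame), lapply(s2$peaks, as.data.frame))

  expect_equal(length(s1$truth$planted), 10)
  trna_ids <- S4Vectors::mcols(genome)$gene_id[
    S4Vectors::mcols(genome)$biotype == "tRNA"]
  expect_length(intersect(s1$truth$planted, trna_ids), 0)
  for (em in s1$truth$emitted)
    expect_true(all(em %in% s1$truth$planted))
  prom <- promoter_windows(genome)
  for (gr in s1$peaks) {
    expect_true(all(start(gr) >= 1 & end(gr) <= cfg$chrom_length))
    mc <- S4Vectors::mcols(gr)
    expect_true(all(mc$peak >= 0 & mc$peak < GenomicRanges::width(gr)))
    # planted anchors sit inside their promoter window; background avoids all
    summit <- GenomicRanges::GRanges(seqnames(gr),
                                     IRanges::IRanges(start(gr) + mc$peak,
                                                      width = 1))
    is_bg <- grepl("_bg_", mc$name)
    expect_true(all(IRanges::overlapsAny(summit[!is_bg], prom,
                                         ignore.strand = TRUE)))
    expect_false(any(IRanges::overlapsAny(gr[is_bg], prom,
                                          ignore.strand = TRUE)))
  }
})

test_that("noiseless simulation is recovered exactly by the consensus pipeline", {
  cfg <- small_config(seed = 31, detection_prob = 1, jitter_sd = 0,
                      background_peaks_per_replicate = 0)
  genome <- simulate_genome(cfg)
  sim <- simulate_condition(cfg, genome, "cond_a")
  recovered <- recover_targets(cfg, genome, sim)
  expect_setequal(recovered, sim$truth$planted)
})

test_that("zero targets and zero background produce empty peak sets", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 1e5, n_genes = 10,
                    conditions = data.frame(label = "c", n_replicates = 2,
                                            n_target_genes = 0),
                    background_peaks_per_replicate = 0)
  sim <- simulate_condition(cfg, simulate_genome(cfg), "c")
  expect_true(all(lengths(sim$peaks) == 0))
})

test_that("over-subscribed target counts are rejected", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 2e5, n_genes = 10,
                    conditions = data.frame(label = "c", n_replicates = 2,
                                            n_target_genes = 50))
  expect_error(simulate_condition(cfg, simulate_genome(cfg), "c"),
               "exceeds available non-tRNA genes")
})

test_that("mapping-stats simulation is deterministic with exact means at zero dispersion", {
  t1 <- simulate_mapping_stats(seed = 9)
  t2 <- simulate_mapping_stats(seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 20)

  t0 <- simulate_mapping_stats(seed = 9, dispersion = 0, total_reads = 1e6)
  expect_equal(unique(t0$frac_unique[t0$assembly_id == "original"]), 0.645)
  expect_equal(unique(t0$frac_unique[t0$assembly_id == "updated"]), 0.795)
  expect_error(simulate_mapping_stats(seed = 1, assembly_effects = list(
    bad = c(unique = 0.5, multi = 0.1, unmapped = 0.1))),
    "summing to 1")
})
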