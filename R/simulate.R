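#' Configuration for the synthetic ChIP-Seq dataset generator
#'
#' Defaults describe a small but realistic benchmark: one 2 Mb chromosome
#' carrying 200 non-overlapping genes (10% tRNA biotype), five experimental
#' conditions of three biological replicates each, 40 planted promoter
#' target genes per condition, a 90% per-replicate detection probability,
#' 2 bp Gaussian boundary jitter, and 50 replicate-private background peaks.
#'
#' @param seed integer seed; a hierarchical stream is derived from it so the
#'   genome, each condition, and each replicate are independent.
#' @param n_chroms,chrom_length,n_genes,frac_trna,min_gene_gap,gene_length_range
#'   genome layout parameters (bp / counts / fraction).
#' @param conditions data frame with columns `label`, `n_replicates`,
#'   `n_target_genes`.
#' @param detection_prob per-replicate probability that a planted peak is
#'   called.
#' @param jitter_sd standard deviation (bp) of the independent Gaussian
#'   jitter on each peak boundary.
#' @param peak_width_range (min, max) nominal peak width in bp.
#' @param background_peaks_per_replicate replicate-private noise peaks,
#'   placed outside promoter windows by rejection sampling so that false
#'   target genes can only arise through the consensus tolerance rule.
#' @param promoter_offset_max maximum |distance| (bp) of a planted peak
#'   anchor from its gene's TSS; must not exceed the promoter extent.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L,
                       chrom_length = 2e6,
                       n_genes = 200L,
                       frac_trna = 0.1,
                       min_gene_gap = 500L,
                       gene_length_range = c(1000L, 5000L),
                       conditions = data.frame(
                         label = c("adult_male", "adult_female",
                                   "juv_male_nonsinging", "juv_male_singing",
                                   "juv_female"),
                         n_replicates = 3L,
                         n_target_genes = 40L),
                       detection_prob = 0.9,
                       jitter_sd = 2,
                       peak_width_range = c(150L, 400L),
                       background_peaks_per_replicate = 50L,
                       promoter_offset_max = 500L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), frac_trna = frac_trna,
              min_gene_gap = as.integer(min_gene_gap),
              gene_length_range = as.integer(gene_length_range),
              conditions = conditions,
              detection_prob = detection_prob, jitter_sd = jitter_sd,
              peak_width_range = as.integer(peak_width_range),
              background_peaks_per_replicate =
                as.integer(background_peaks_per_replicate),
              promoter_offset_max = as.integer(promoter_offset_max))
  stopifnot(cfg$frac_trna >= 0, cfg$frac_trna <= 1,
            cfg$detection_prob >= 0, cfg$detection_prob <= 1,
            cfg$jitter_sd >= 0, cfg$promoter_offset_max >= 0,
            all(c("label", "n_replicates", "n_target_genes") %in%
                  names(cfg$conditions)),
            !anyDuplicated(cfg$conditions$label))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome annotation
#'
#' Places `n_genes` non-overlapping genes (separated by at least
#' `min_gene_gap` bp) on `n_chroms` chromosomes of `chrom_length` bp, with
#' random strand, lengths uniform in `gene_length_range`, a `frac_trna`
#' fraction of tRNA biotype, and 1-5 exons for most protein-coding genes.
#' Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return a `GRanges` of gene models in the same shape as
#'   [read_gene_annotation()] returns (mcols `gene_id`, `symbol`, `biotype`;
#'   exons in `metadata(x)$exons`; seqlengths set).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genome"), {
    n <- config$n_genes
    chroms <- paste0("chr", seq_len(config$n_chroms))
    max_len <- config$gene_length_range[2]
    per_chrom_cap <- (config$chrom_length - config$min_gene_gap) %/%
      (max_len + config$min_gene_gap)
    if (n > per_chrom_cap * config$n_chroms)
      stopf("infeasible packing: %d genes cannot fit %d chromosome(s) of %d bp",
            n, config$n_chroms, config$chrom_length)
    chrom_of <- sort(rep_len(seq_len(config$n_chroms), n))
    rows <- list()
    for (c_i in unique(chrom_of)) {
      k <- sum(chrom_of == c_i)
      lens <- if (k) sample(config$gene_length_range[1]:max_len, k,
                            replace = TRUE) else integer(0)
      slack <- config$chrom_length - sum(lens) - (k + 1) * config$min_gene_gap
      # random extra gaps: k+1 non-negative integers summing to <= slack
      cuts <- sort(sample.int(slack + 1, k + 1, replace = TRUE) - 1L)
      extra <- diff(c(0L, cuts))
      cursor <- 0L
      for (j in seq_len(k)) {
        gstart <- cursor + config$min_gene_gap + extra[j] + 1L
        rows[[length(rows) + 1L]] <-
          list(chrom = chroms[c_i], start = gstart,
               end = gstart + lens[j] - 1L)
        cursor <- gstart + lens[j] - 1L
      }
    }
    starts <- vapply(rows, `[[`, 0L, "start")
    ends <- vapply(rows, `[[`, 0L, "end")
    gene_id <- sprintf("gene_%03d", seq_len(n))
    is_trna <- seq_len(n) %in% sample.int(n, round(config$frac_trna * n))
    gr <- GenomicRanges::GRanges(
      seqnames = vapply(rows, `[[`, "", "chrom"),
      ranges = IRanges::IRanges(starts, ends),
      strand = sample(c("+", "-"), n, replace = TRUE),
      gene_id = gene_id,
      symbol = toupper(gene_id),
      biotype = ifelse(is_trna, "tRNA", "protein_coding"))
    names(gr) <- gene_id
    GenomeInfoDb::seqlevels(gr) <- chroms
    seqlengths(gr) <- setNames(rep(config$chrom_length, config$n_chroms),
                               chroms)
    exon_list <- lapply(seq_len(n), function(i) {
      if (is_trna[i] || runif(1) < 0.3) return(GenomicRanges::GRanges())
      len <- ends[i] - starts[i] + 1L
      k <- sample(1:5, 1)
      # k exon spans inside the gene: pick 2k distinct breakpoints
      bp <- sort(sample.int(len, min(2 * k, len)))
      if (length(bp) < 2) return(GenomicRanges::GRanges())
      ex_start <- starts[i] + bp[seq(1, length(bp) - 1, by = 2)] - 1L
      ex_end <- starts[i] + bp[seq(2, length(bp), by = 2)] - 1L
      GenomicRanges::GRanges(as.character(seqnames(gr))[i],
                             IRanges::IRanges(ex_start, ex_end))
    })
    names(exon_list) <- gene_id
    metadata(gr)$exons <- GenomicRanges::GRangesList(exon_list)
    gr
  })
}

#' Simulate one condition's replicate peak sets
#'
#' Draws the condition's planted target genes (without replacement, from
#' non-tRNA genes) and, per replicate, emits a narrowPeak call for each
#' planted target with probability `detection_prob`. The peak is anchored at
#' a fixed per-target offset within `promoter_offset_max` bp of the TSS
#' (shared across replicates, as a real binding site would be), with
#' independent Gaussian boundary jitter per replicate. Background peaks are
#' replicate-private and rejected out of all promoter windows.
#'
#' @param config a [sim_config()].
#' @param genome the `GRanges` from [simulate_genome()].
#' @param condition_label one of `config$conditions$label`.
#' @param trna_controls additionally plant this many targets on tRNA-biotype
#'   genes (default 0); used to verify that biotype exclusion removes them.
#' @return list with `peaks` (named list of per-replicate `GRanges`),
#'   `truth` (list: `planted` gene ids, `trna_planted`, `emitted` per
#'   replicate).
#' @export
simulate_condition <- function(config, genome, condition_label,
                               trna_controls = 0L) {
  stopifnot(inherits(config, "sim_config"))
  row <- config$conditions[config$conditions$label == condition_label, ]
  if (nrow(row) != 1)
    stopf("condition '%s' not present in config", condition_label)
  prom <- promoter_windows(genome)
  with_seed(derive_seed(config$seed, "condition", condition_label), {
    non_trna <- which(mcols(genome)$biotype != "tRNA")
    trna <- which(mcols(genome)$biotype == "tRNA")
    if (row$n_target_genes > length(non_trna))
      stopf("n_target_genes (%d) exceeds available non-tRNA genes (%d)",
            row$n_target_genes, length(non_trna))
    if (trna_controls > length(trna))
      stopf("trna_controls (%d) exceeds available tRNA genes (%d)",
            trna_controls, length(trna))
    targets <- sort(non_trna[sample.int(length(non_trna), row$n_target_genes)])
    trna_targets <- if (trna_controls > 0)
      sort(trna[sample.int(length(trna), trna_controls)]) else integer(0)
    planted <- c(targets, trna_targets)
    tss_pos <- tss(genome)[planted]
    offmax <- config$promoter_offset_max
    offsets <- if (offmax > 0) sample(seq(-offmax, offmax), length(planted),
                                      replace = TRUE)
               else rep(0L, length(planted))
    anchors <- tss_pos + offsets
    widths <- sample(config$peak_width_range[1]:config$peak_width_range[2],
                     length(planted), replace = TRUE)
    rep_seeds <- vapply(seq_len(row$n_replicates), function(r)
      derive_seed(config$seed, "condition", condition_label, "rep", r), 0L)
    planted_ids <- mcols(genome)$gene_id[planted]
    chroms <- as.character(seqnames(genome))[planted]
    chrom_len <- config$chrom_length
    peaks <- list()
    emitted <- list()
    for (r in seq_len(row$n_replicates)) {
      rep_id <- sprintf("%s_rep%d", condition_label, r)
      with_seed(rep_seeds[r], {
        called <- runif(length(planted)) < config$detection_prob
        st <- pmax(1L, pmin(anchors - widths %/% 2 +
                              as.integer(round(rnorm(length(planted), 0,
                                                     config$jitter_sd))),
                            anchors))
        en <- pmin(chrom_len,
                   pmax(anchors + widths %/% 2 +
                          as.integer(round(rnorm(length(planted), 0,
                                                 config$jitter_sd))),
                        anchors))
        target_gr <- GenomicRanges::GRanges(
          chroms[called], IRanges::IRanges(st[called], en[called]),
          name = sprintf("%s_tgt_%s", rep_id, planted_ids[called]),
          score = as.integer(round(runif(sum(called), 200, 1000))),
          signalValue = round(runif(sum(called), 3, 25), 3),
          pValue = round(runif(sum(called), 5, 40), 3),
          qValue = round(runif(sum(called), 2, 30), 3),
          peak = (anchors - st)[called],
          replicate_id = rep(rep_id, sum(called)),
          condition = rep(condition_label, sum(called)))
        bg <- simulate_background_peaks(config, genome, prom, rep_id,
                                        condition_label)
        gr <- sort(c(target_gr, bg), ignore.strand = TRUE)
        peaks[[rep_id]] <- gr
        emitted[[rep_id]] <- planted_ids[called]
      })
    }
    list(peaks = peaks,
         truth = list(planted = mcols(genome)$gene_id[targets],
                      trna_planted = mcols(genome)$gene_id[trna_targets],
                      emitted = emitted))
  })
}

# Replicate-private noise peaks, rejection-sampled out of promoter windows.
simulate_background_peaks <- function(config, genome, prom, rep_id,
                                      condition_label) {
  n_bg <- config$background_peaks_per_replicate
  if (n_bg == 0) {
    gr <- GenomicRanges::GRanges()
    mcols(gr) <- mcols(GenomicRanges::GRanges(
      name = character(0), score = integer(0), signalValue = numeric(0),
      pValue = numeric(0), qValue = numeric(0), peak = integer(0),
      replicate_id = character(0), condition = character(0)))
    return(gr)
  }
  chroms <- paste0("chr", seq_len(config$n_chroms))
  got <- GenomicRanges::GRanges()
  attempts <- 0L
  while (length(got) < n_bg && attempts < 200L) {
    attempts <- attempts + 1L
    need <- n_bg - length(got)
    w <- sample(config$peak_width_range[1]:config$peak_width_range[2],
                2 * need, replace = TRUE)
    st <- as.integer(ceiling(runif(2 * need, 1, config$chrom_length - w)))
    cand <- GenomicRanges::GRanges(sample(chroms, 2 * need, replace = TRUE),
                                   IRanges::IRanges(st, st + w - 1L))
    cand <- cand[!IRanges::overlapsAny(cand, prom, ignore.strand = TRUE)]
    got <- c(got, cand)
  }
  if (length(got) < n_bg)
    stopf("could not place %d background peaks outside promoter windows", n_bg)
  got <- got[seq_len(n_bg)]
  mcols(got)$name <- sprintf("%s_bg_%d", rep_id, seq_len(n_bg))
  mcols(got)$score <- as.integer(round(runif(n_bg, 100, 600)))
  mcols(got)$signalValue <- round(runif(n_bg, 1, 8), 3)
  mcols(got)$pValue <- round(runif(n_bg, 2, 15), 3)
  mcols(got)$qValue <- round(runif(n_bg, 1, 10), 3)
  mcols(got)$peak <- GenomicRanges::width(got) %/% 2L
  mcols(got)$replicate_id <- rep_id
  mcols(got)$condition <- condition_label
  got
}

#' Simulate a complete benchmark dataset
#'
#' Genome plus all configured conditions; optionally written to disk as
#' GFF3 + per-replicate narrowPeak + ground-truth TSV.
#'
#' @param config a [sim_config()].
#' @param dir if non-NULL, write `genes.gff3`, `<replicate>.narrowPeak`, and
#'   `ground_truth.tsv` under this directory.
#' @return list with `genome`, `conditions` (per label: `peaks`, `truth`),
#'   and `paths` when `dir` was given.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  genome <- simulate_genome(config)
  conditions <- lapply(config$conditions$label, function(lab)
    simulate_condition(config, genome, lab))
  names(conditions) <- config$conditions$label
  out <- list(genome = genome, conditions = conditions)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gff3 = file.path(dir, "genes.gff3"), peaks = list())
    write_gene_annotation(genome, paths$gff3)
    truth_rows <- list()
    for (lab in names(conditions)) {
      for (rep_id in names(conditions[[lab]]$peaks)) {
        p <- file.path(dir, paste0(rep_id, ".narrowPeak"))
        write_narrowpeak(conditions[[lab]]$peaks[[rep_id]], p)
        paths$peaks[[lab]] <- c(paths$peaks[[lab]], p)
      }
      truth_rows[[lab]] <- data.frame(
        condition = lab, gene_id = conditions[[lab]]$truth$planted)
    }
    paths$truth <- file.path(dir, "ground_truth.tsv")
    write_tsv_plain(do.call(rbind, truth_rows), paths$truth)
    out$paths <- paths
  }
  out
}

#' Simulate per-sample read-mapping summary tables
#'
#' Emulates aligning the same libraries to two (or more) genome assemblies:
#' per-sample category fractions are the assembly means perturbed by
#' Gaussian noise (sd = `dispersion`), renormalised, and converted to read
#' counts.
#'
#' @param seed integer seed.
#' @param n_samples samples per assembly.
#' @param assembly_effects named list; per assembly a named numeric
#'   `c(unique=, multi=, unmapped=)` summing to 1. Defaults emulate an
#'   original vs an updated assembly with a 15-point gain in the uniquely
#'   mapped fraction.
#' @param dispersion sd of the per-sample noise on each fraction (default
#'   0.015, giving sample-to-sample spread comparable to replicate
#'   sequencing libraries).
#' @param total_reads nominal reads per sample.
#' @return a data frame as from [read_mapping_stats()] (counts + fractions).
#' @export
simulate_mapping_stats <- function(seed, n_samples = 10,
                                   assembly_effects = list(
                                     original = c(unique = 0.645, multi = 0.25,
                                                  unmapped = 0.105),
                                     updated = c(unique = 0.795, multi = 0.13,
                                                 unmapped = 0.075)),
                                   dispersion = 0.015,
                                   total_reads = 18e6) {
  for (nm in names(assembly_effects)) {
    eff <- assembly_effects[[nm]]
    if (!isTRUE(all.equal(sum(eff), 1)) || any(eff < 0) ||
        !all(c("unique", "multi", "unmapped") %in% names(eff)))
      stopf("assembly_effects[['%s']] must be non-negative unique/multi/unmapped fractions summing to 1", nm)
  }
  rows <- list()
  for (nm in names(assembly_effects)) {
    eff <- assembly_effects[[nm]][c("unique", "multi", "unmapped")]
    with_seed(derive_seed(seed, "mapping", nm), {
      for (s in seq_len(n_samples)) {
        p <- pmax(eff + rnorm(3, 0, dispersion), 1e-6)
        p <- p / sum(p)
        counts <- round(p * total_reads)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_s%02d", nm, s), assembly_id = nm,
          n_unique = counts[1], n_multi = counts[2], n_unmapped = counts[3])
      }
    })
  }
  add_mapping_fractions(do.call(rbind, rows))
}
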