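#' Run the consensus -> annotate -> compare -> enrich pipeline
#'
#' Orchestrates the full downstream analysis from per-replicate narrowPeak
#' files and a GFF3 annotation: per condition, consensus peaks are built,
#' annotated, and reduced to a promoter target-gene table; configured
#' condition comparisons (Venn partitions), assembly-style concordance
#' checks, and hypergeometric enrichment tests are then run on the gene
#' sets. All stage outputs are written as plain BED/TSV/JSON files, and a
#' manifest records the parameters actually used plus a hash of the
#' configuration, so re-running on identical inputs yields identical
#' outputs.
#'
#' @param config a named list, or the path to a YAML file with the same
#'   structure:
#' \describe{
#'   \item{gff3}{path to the gene annotation.}
#'   \item{conditions}{named list: condition label -> character vector of
#'     replicate narrowPeak paths (replicate id = file base name).}
#'   \item{tol_bp, min_support, tol_mode}{consensus parameters (5, 2,
#'     "both").}
#'   \item{promoter_up, promoter_down, downstream_bp}{annotation extents
#'     (1000, 1000, 3000).}
#'   \item{exclude_biotypes}{biotypes dropped from target tables ("tRNA").}
#'   \item{comparisons}{optional list of 2-3 element character vectors of
#'     condition labels to partition.}
#'   \item{concordance}{optional list of `list(name=, a=, b=)` gene-list
#'     path pairs.}
#'   \item{enrichment}{optional list of `list(name=, prior=, universe=)`
#'     gene-list paths, tested against every condition's target genes.}
#' }
#' @param out_dir output directory (created if needed).
#' @return an object of class `run_report`: list with `out_dir`, `files`,
#'   `summary` (per-condition counts), `targets` (per-condition gene-id
#'   sets), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- apply_config_defaults(config)
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  log_stage <- function(fmt, ...) message(sprintf(paste0("[chipcons] ", fmt), ...))

  genes <- read_gene_annotation(config$gff3)
  log_stage("annotation: %d gene models (%d tRNA)", length(genes),
            sum(mcols(genes)$biotype == "tRNA"))

  summary_rows <- list()
  targets <- list()
  distributions <- list()
  for (lab in names(config$conditions)) {
    paths <- config$conditions[[lab]]
    reps <- lapply(paths, function(p)
      read_narrowpeak(p, replicate_id = sub("\\.[^.]*$", "", basename(p)),
                      condition = lab))
    n_in <- sum(lengths(reps))
    cons <- consensus_peaks(reps, tol_bp = config$tol_bp,
                            min_support = config$min_support,
                            tol_mode = config$tol_mode)
    ann <- annotate_peaks(cons, genes,
                          promoter_up = config$promoter_up,
                          promoter_down = config$promoter_down,
                          downstream_bp = config$downstream_bp)
    tt <- target_table(ann, condition = lab,
                       exclude_biotypes = config$exclude_biotypes)
    dist <- if (length(ann)) feature_distribution(ann) else
      setNames(rep(NA_real_, length(feature_categories())),
               feature_categories())

    bed <- file.path(out_dir, paste0(lab, ".consensus.bed"))
    cons_out <- cons
    if (length(cons_out)) {
      mcols(cons_out)$name <- mcols(cons_out)$consensus_id
      mcols(cons_out)$score <- mcols(cons_out)$support
    }
    write_bed6(cons_out, bed)
    members <- file.path(out_dir, paste0(lab, ".members.tsv"))
    write_tsv_plain(metadata(cons)$members, members)
    ann_path <- file.path(out_dir, paste0(lab, ".annotated.tsv"))
    write_tsv_plain(annotated_as_df(ann), ann_path)
    dist_path <- file.path(out_dir, paste0(lab, ".feature_distribution.tsv"))
    write_tsv_plain(data.frame(category = names(dist),
                               fraction = unname(dist)), dist_path)
    tt_path <- file.path(out_dir, paste0(lab, ".target_genes.tsv"))
    write_tsv_plain(tt$rows, tt_path)
    files[[lab]] <- c(consensus = bed, members = members, annotated = ann_path,
                      feature_distribution = dist_path, targets = tt_path)
    targets[[lab]] <- unique(tt$rows$gene_id)
    distributions[[lab]] <- dist
    summary_rows[[lab]] <- data.frame(
      condition = lab, n_replicates = length(reps), peaks_in = n_in,
      consensus_peaks = length(cons),
      promoter_fraction = unname(dist["promoter"]),
      n_unique_peaks = tt$n_unique_peaks, n_unique_genes = tt$n_unique_genes)
    log_stage("%s: %d peaks in -> %d consensus (promoter fraction %s) -> %d target genes",
              lab, n_in, length(cons),
              ifelse(is.na(dist["promoter"]), "NA",
                     sprintf("%.2f", dist["promoter"])),
              tt$n_unique_genes)
  }
  summary_df <- do.call(rbind, summary_rows)
  rownames(summary_df) <- NULL
  write_tsv_plain(summary_df, file.path(out_dir, "summary.tsv"))
  files$summary <- file.path(out_dir, "summary.tsv")

  comparisons <- list()
  for (cmp in config$comparisons %||% list()) {
    missing <- setdiff(cmp, names(targets))
    if (length(missing))
      stopf("comparison stage: unknown condition label(s) %s",
            paste(missing, collapse = ", "))
    part <- partition_gene_sets(setNames(targets[cmp], cmp))
    comparisons[[paste(cmp, collapse = "_vs_")]] <- list(
      set_labels = part$set_labels,
      region_counts = as.list(part$region_counts),
      universe_size = part$universe_size)
  }
  if (length(comparisons)) {
    files$comparisons <- file.path(out_dir, "comparisons.json")
    write_json_plain(comparisons, files$comparisons)
  }

  concordances <- list()
  for (cc in config$concordance %||% list()) {
    res <- assembly_concordance(read_gene_list(cc$a), read_gene_list(cc$b))
    concordances[[cc$name]] <- res[c("only_a", "only_b", "both",
                                     "concordance", "concordance_min_set")]
  }
  if (length(concordances)) {
    files$concordance <- file.path(out_dir, "concordance.json")
    write_json_plain(concordances, files$concordance)
  }

  enrichments <- list()
  for (en in config$enrichment %||% list()) {
    universe <- read_gene_list(en$universe)
    prior <- read_gene_list(en$prior)
    for (lab in names(targets)) {
      res <- overlap_enrichment(targets[[lab]], prior, universe)
      enrichments[[paste(en$name, lab, sep = "_")]] <-
        res[c("q", "m", "n", "k", "p_density", "p_upper",
              "expected_overlap", "fold_enrichment")]
    }
  }
  if (length(enrichments)) {
    files$enrichment <- file.path(out_dir, "enrichment.json")
    write_json_plain(enrichments, files$enrichment)
  }

  manifest <- list(
    package = "chipcons",
    version = as.character(packageVersion("chipcons")),
    config_hash = rlang::hash(config),
    parameters = config[c("tol_bp", "min_support", "tol_mode", "promoter_up",
                          "promoter_down", "downstream_bp",
                          "exclude_biotypes")],
    conditions = lapply(config$conditions, basename),
    outputs = lapply(files, function(f) basename(unname(f))))
  files$manifest <- file.path(out_dir, "manifest.json")
  write_json_plain(manifest, files$manifest)
  log_stage("done: %d condition(s), outputs under %s", length(targets), out_dir)

  structure(list(out_dir = out_dir, files = files, summary = summary_df,
                 targets = targets, distributions = distributions,
                 manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("chipcons run report\n")
  print(x$summary)
  invisible(x)
}

apply_config_defaults <- function(config) {
  defaults <- list(tol_bp = 5, min_support = 2, tol_mode = "both",
                   promoter_up = 1000, promoter_down = 1000,
                   downstream_bp = 3000, exclude_biotypes = "tRNA")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

validate_run_config <- function(config) {
  if (is.null(config$gff3) || !file.exists(config$gff3))
    stopf("config stage: gff3 path missing or does not exist: %s",
          config$gff3 %||% "<null>")
  if (is.null(config$conditions) || !length(config$conditions))
    stopf("config stage: no conditions given")
  if (is.null(names(config$conditions)) ||
      anyDuplicated(names(config$conditions)))
    stopf("config stage: condition labels must be unique names")
  for (lab in names(config$conditions)) {
    for (p in config$conditions[[lab]])
      if (!file.exists(p))
        stopf("config stage: replicate file for '%s' does not exist: %s", lab, p)
  }
  for (cc in config$concordance %||% list())
    for (p in c(cc$a, cc$b))
      if (!file.exists(p)) stopf("config stage: gene list does not exist: %s", p)
  for (en in config$enrichment %||% list())
    for (p in c(en$prior, en$universe))
      if (!file.exists(p)) stopf("config stage: gene list does not exist: %s", p)
  invisible(TRUE)
}

annotated_as_df <- function(ann) {
  cid <- mcols(ann)$consensus_id %||% paste0("peak_", seq_along(ann))
  df <- data.frame(
    consensus_id = cid,
    chrom = as.character(seqnames(ann)),
    start = start(ann) - 1L,
    end = end(ann),
    support = mcols(ann)$support %||% rep(NA_integer_, length(ann)),
    anchor = mcols(ann)$anchor,
    category = mcols(ann)$category,
    gene_id = mcols(ann)$gene_id,
    symbol = mcols(ann)$symbol,
    biotype = mcols(ann)$biotype,
    distance_to_tss = mcols(ann)$distance_to_tss)
  df
}

# Deterministic JSON writer: stable key order as constructed, no
# auto-unboxing surprises for length-1 vectors.
write_json_plain <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
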