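# Independent oracles used by the tests. These deliberately avoid the code
# paths (and, where possible, the library calls) they check.

# Brute-force all-pairs union-find clustering of peaks under the tolerance
# rule. `df` has 1-based closed chrom/start/end plus replicate and a unique
# `name` per peak. Returns clusters meeting min_support as a list of:
# member names (sorted), support, union start/end.
oracle_consensus <- function(df, tol, min_support = 2, mode = "both") {
  n <- nrow(df)
  if (n == 0) return(list())
  maxgap <- if (mode == "both") 2 * tol else tol
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (df$chrom[i] != df$chrom[j]) next
      gap <- max(0, max(df$start[i], df$start[j]) -
                   min(df$end[i], df$end[j]) - 1)
      if (gap <= maxgap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  clusters <- split(seq_len(n), roots)
  out <- list()
  for (cl in clusters) {
    support <- length(unique(df$replicate[cl]))
    if (support < min_support) next
    key <- paste(sort(df$name[cl]), collapse = ",")
    out[[key]] <- list(members = sort(df$name[cl]), support = support,
                       start = min(df$start[cl]), end = max(df$end[cl]))
  }
  if (!length(out)) return(list())
  out[base::order(names(out))]
}

# Convert a consensus_peaks() result into the same cluster shape.
clusters_from_consensus <- function(cons) {
  members <- S4Vectors::metadata(cons)$members
  out <- list()
  for (k in seq_along(cons)) {
    cid <- S4Vectors::mcols(cons)$consensus_id[k]
    rows <- members[members$consensus_id == cid, ]
    key <- paste(sort(rows$name), collapse = ",")
    out[[key]] <- list(members = sort(rows$name),
                       support = S4Vectors::mcols(cons)$support[k],
                       start = GenomicRanges::start(cons)[k],
                       end = GenomicRanges::end(cons)[k])
  }
  if (!length(out)) return(list())
  out[base::order(names(out))]
}

# Random peak instance: up to max_peaks peaks over n_reps replicates on 1-2
# chromosomes, 1-based closed coordinates.
random_peak_instance <- function(max_peaks = 50, n_reps = 3,
                                 chrom_pool = c("chr1", "chr2"),
                                 span = 3000) {
  n <- sample.int(max_peaks, 1)
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(80, n, replace = TRUE)
  data.frame(chrom = sample(chrom_pool, n, replace = TRUE),
             start = start, end = start + width - 1L,
             replicate = sprintf("rep%d", sample.int(n_reps, n, replace = TRUE)),
             name = sprintf("p%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

peaks_df_to_granges <- function(df, condition = "c1") {
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    name = df$name, score = 0L, signalValue = 0, pValue = 0, qValue = 0,
    peak = -1L, replicate_id = df$replicate, condition = condition)
}

# Exact hypergeometric draw counts by Pascal-recurrence dynamic programming:
# ways(N, k) = number of k-subsets of N items, built without choose().
pascal_table <- function(N) {
  tab <- matrix(0, nrow = N + 1, ncol = N + 1)
  tab[, 1] <- 1
  for (n in seq_len(N)) {
    for (k in seq_len(n)) {
      tab[n + 1, k + 1] <- tab[n, k] + tab[n, k + 1]
    }
  }
  tab  # tab[n+1, k+1] = #k-subsets of n
}

oracle_hyper_density <- function(q, m, n, k, tab = pascal_table(m + n)) {
  (tab[m + 1, q + 1] * tab[n + 1, k - q + 1]) / tab[m + n + 1, k + 1]
}

# Literal enumeration of every k-draw from m white + n black items.
enumerate_hyper_density <- function(q, m, n, k) {
  draws <- utils::combn(m + n, k)
  whites <- colSums(draws <= m)
  sum(whites == q) / ncol(draws)
}

# Direct transcription of the Welch statistics, oriented b minus a.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Promoter-target recovery of a simulated condition against ground truth.
recover_targets <- function(config, genome, sim, exclude_biotypes = "tRNA") {
  cons <- chipcons::consensus_peaks(sim$peaks, tol_bp = 5, min_support = 2)
  ann <- chipcons::annotate_peaks(cons, genome)
  tt <- chipcons::target_table(ann, exclude_biotypes = exclude_biotypes)
  unique(tt$rows$gene_id)
}
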