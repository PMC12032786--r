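#' Hypergeometric density for a gene-set overlap
#'
#' Probability of drawing exactly `q` previously-reported target genes when
#' `k` genes are drawn from a universe containing `m` reported targets and
#' `n` non-targets: `C(m,q) C(n,k-q) / C(m+n,k)`, evaluated in log space.
#'
#' @param q overlap count (genes in both studies).
#' @param m number of target genes in the prior study.
#' @param n number of universe genes not in the prior study.
#' @param k number of target genes in the present study.
#' @return `P(X = q)`.
#' @export
hypergeom_density <- function(q, m, n, k) {
  check_hyper_input(q, m, n, k)
  dhyper(q, m, n, k)
}

#' Upper-tail hypergeometric probability for a gene-set overlap
#'
#' `P(X >= q)`: the enrichment p-value for observing an overlap at least as
#' large as `q`.
#'
#' @inheritParams hypergeom_density
#' @return `P(X >= q)`.
#' @export
hypergeom_upper <- function(q, m, n, k) {
  check_hyper_input(q, m, n, k)
  phyper(q - 1, m, n, k, lower.tail = FALSE)
}

check_hyper_input <- function(q, m, n, k) {
  vals <- c(q = q, m = m, n = n, k = k)
  if (any(is.na(vals)) || any(vals != floor(vals)))
    stopf("hypergeometric input must be integral, got (%s)",
          paste(sprintf("%s=%s", names(vals), vals), collapse = ", "))
  if (any(vals < 0))
    stopf("hypergeometric input violates bound: %s < 0",
          names(vals)[which(vals < 0)[1]])
  if (q > min(m, k))
    stopf("hypergeometric input violates bound: q (%d) > min(m, k) = %d",
          q, min(m, k))
  if (k > m + n)
    stopf("hypergeometric input violates bound: k (%d) > m + n = %d",
          k, m + n)
  invisible(TRUE)
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' Tests whether the overlap between this study's target genes and a prior
#' study's target genes is larger than expected for random draws from a
#' common gene universe. Parameters follow the phyper convention:
#' q = overlap, m = prior-study targets, n = universe minus prior targets,
#' k = this-study targets. Both the point density `P(X = q)` and the
#' enrichment-appropriate upper tail `P(X >= q)` are reported; the upper tail
#' is the headline p-value.
#'
#' @param our_genes,prior_genes character vectors of gene ids; elements
#'   outside `universe` are dropped with a warning.
#' @param universe character vector: the gene universe both sets are drawn
#'   from (must be explicit; no default exists that is defensible across
#'   annotations).
#' @return an object of class `enrichment_result`: list with `q`, `m`, `n`,
#'   `k`, `p_density`, `p_upper`, `expected_overlap` (`k*m/(m+n)`) and
#'   `fold_enrichment` (`q/expected_overlap`, `NA` when the expectation is 0).
#' @export
overlap_enrichment <- function(our_genes, prior_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0)
    stopf("overlap_enrichment: empty universe")
  ours <- unique(as.character(our_genes))
  prior <- unique(as.character(prior_genes))
  out_u <- setdiff(ours, universe)
  out_p <- setdiff(prior, universe)
  if (length(out_u) || length(out_p))
    warning(sprintf("overlap_enrichment: dropping %d study / %d prior gene(s) outside the universe",
                    length(out_u), length(out_p)), call. = FALSE)
  ours <- intersect(ours, universe)
  prior <- intersect(prior, universe)
  q <- length(intersect(ours, prior))
  m <- length(prior)
  n <- length(universe) - m
  k <- length(ours)
  expected <- k * m / (m + n)
  structure(list(q = q, m = m, n = n, k = k,
                 p_density = hypergeom_density(q, m, n, k),
                 p_upper = hypergeom_upper(q, m, n, k),
                 expected_overlap = expected,
                 fold_enrichment = if (expected > 0) q / expected else NA_real_),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Overlap enrichment: q=%d, m=%d, n=%d, k=%d\n", x$q, x$m, x$n, x$k))
  cat(sprintf("  expected overlap %.2f, fold %.2f, P(X=q)=%.3g, P(X>=q)=%.3g\n",
              x$expected_overlap, x$fold_enrichment, x$p_density, x$p_upper))
  invisible(x)
}

#' Read a read-mapping summary table
#'
#' @param path TSV with header
#'   `sample_id assembly_id n_unique n_multi n_unmapped`.
#' @return a data frame with the counts plus derived fractions `frac_unique`,
#'   `frac_multi`, `frac_unmapped` (per-sample, over the three categories).
#' @export
read_mapping_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "assembly_id", "n_unique", "n_multi", "n_unmapped")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stopf("mapping-stats table lacks column(s): %s", paste(missing, collapse = ", "))
  add_mapping_fractions(df)
}

add_mapping_fractions <- function(df) {
  total <- df$n_unique + df$n_multi + df$n_unmapped
  if (any(total <= 0) || any(c(df$n_unique, df$n_multi, df$n_unmapped) < 0))
    stopf("mapping-stats counts must be non-negative with positive totals")
  df$frac_unique <- df$n_unique / total
  df$frac_multi <- df$n_multi / total
  df$frac_unmapped <- df$n_unmapped / total
  df
}

#' Two-sample t-test on mapping fractions between assemblies
#'
#' Compares the per-sample fraction of reads in one mapping category between
#' two groups of samples (e.g. the same libraries aligned to an original and
#' an updated genome assembly). The test runs on fractions rather than raw
#' counts so that library-size differences do not drive the comparison, and
#' uses the Welch (unequal-variance) flavour by default. The orientation is
#' fixed: the t statistic has the sign of `mean(group_b) - mean(group_a)`,
#' so with `group_a` = original and `group_b` = updated a positive t means
#' the updated assembly increased the fraction.
#'
#' @param group_a,group_b data frames with mapping fractions (see
#'   [read_mapping_stats()]); at least 2 samples each.
#' @param category one of `"unique"`, `"multi"`, `"unmapped"`.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return an object of class `two_sample_test`: list with `category`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_mapping_stats <- function(group_a, group_b,
                                  category = c("unique", "multi", "unmapped"),
                                  var_equal = FALSE) {
  category <- match.arg(category)
  col <- paste0("frac_", category)
  for (g in list(group_a, group_b))
    if (!col %in% names(g))
      stopf("compare_mapping_stats: groups must carry %s (see read_mapping_stats)", col)
  xa <- group_a[[col]]
  xb <- group_b[[col]]
  if (length(xa) < 2 || length(xb) < 2)
    stopf("compare_mapping_stats: need >= 2 samples per group")
  if (stats::var(xa) == 0 && stats::var(xb) == 0) {
    same <- isTRUE(all.equal(mean(xa), mean(xb)))
    return(structure(list(category = category,
                          t_statistic = if (same) 0 else sign(mean(xb) - mean(xa)) * Inf,
                          degrees_of_freedom = length(xa) + length(xb) - 2,
                          p_value = if (same) 1 else 0,
                          mean_a = mean(xa), mean_b = mean(xb)),
                     class = "two_sample_test"))
  }
  tt <- t.test(xb, xa, var.equal = var_equal)
  structure(list(category = category,
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(xa), mean_b = mean(xb)),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat(sprintf("Two-sample t test on frac_%s: t = %.3f, df = %.2f, p = %.3g\n",
              x$category, x$t_statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("  group means: a = %.4f, b = %.4f\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' Read a gene list (one symbol per line)
#'
#' @param path text file; blank lines and `#` comments are skipped.
#' @return a character vector of unique gene symbols, input order preserved.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(gzfile(path), warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
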