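#' Venn-style partition of 2 or 3 gene sets
#'
#' Computes the disjoint-region counts of the Venn diagram over the union of
#' the input sets: for each non-empty subset of set labels, the number of
#' elements belonging to exactly those sets. Used to compare promoter
#' target-gene catalogs across experimental conditions.
#'
#' @param named_sets a named list of 2 or 3 character vectors (gene ids);
#'   duplicates within a set are ignored.
#' @return an object of class `set_partition`: list with `set_labels`,
#'   `region_counts` (named by label subsets joined with `&`),
#'   `universe_size`, and `regions` (the element ids per region).
#' @export
#' @examples
#' partition_gene_sets(list(A = c("g1", "g2"), B = c("g2", "g3")))
partition_gene_sets <- function(named_sets) {
  if (!is.list(named_sets) || length(named_sets) < 2 || length(named_sets) > 3)
    stopf("partition_gene_sets: expected 2 or 3 named sets, got %d",
          length(named_sets))
  labels <- names(named_sets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
    stopf("partition_gene_sets: sets must carry unique non-empty names")
  sets <- lapply(named_sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- matrix(vapply(sets, function(s) universe %in% s,
                              logical(length(universe))),
                       nrow = length(universe),
                       dimnames = list(NULL, labels))
  subsets <- region_labels(labels)
  regions <- lapply(subsets, function(sub) {
    in_sub <- rowSums(membership[, sub, drop = FALSE]) == length(sub) &
      rowSums(membership) == length(sub)
    universe[in_sub]
  })
  names(regions) <- vapply(subsets, paste, "", collapse = "&")
  structure(list(set_labels = labels,
                 region_counts = lengths(regions),
                 universe_size = length(universe),
                 regions = regions),
            class = "set_partition")
}

region_labels <- function(labels) {
  k <- length(labels)
  subs <- list()
  for (size in seq_len(k))
    subs <- c(subs, utils::combn(labels, size, simplify = FALSE))
  subs
}

#' @export
print.set_partition <- function(x, ...) {
  cat(sprintf("Partition of %d elements over sets {%s}\n", x$universe_size,
              paste(x$set_labels, collapse = ", ")))
  for (nm in names(x$region_counts))
    cat(sprintf("  %-20s %d\n", nm, x$region_counts[[nm]]))
  invisible(x)
}

#' Concordance of two gene sets (e.g. across genome assemblies)
#'
#' Reports the counts of genes found only with set A, only with set B, and
#' with both, and the concordance rate. The headline rate is the Jaccard
#' index |A∩B| / |A∪B|; the intersection over the smaller set is also
#' reported since published concordance percentages do not always state
#' their denominator.
#'
#' @param genes_a,genes_b character vectors of gene ids sharing a namespace.
#' @param synonyms optional named character vector mapping alternate symbols
#'   to canonical ones; applied to both sets before comparison.
#' @return an object of class `concordance_result`: list with `only_a`,
#'   `only_b`, `both`, `concordance` (Jaccard) and `concordance_min_set`.
#' @export
assembly_concordance <- function(genes_a, genes_b, synonyms = NULL) {
  canon <- function(x) {
    x <- unique(as.character(x))
    if (!is.null(synonyms)) {
      hit <- x %in% names(synonyms)
      x[hit] <- synonyms[x[hit]]
      x <- unique(x)
    }
    x
  }
  a <- canon(genes_a)
  b <- canon(genes_b)
  if (length(a) == 0 && length(b) == 0)
    stopf("assembly_concordance: both sets empty, concordance undefined")
  both <- length(intersect(a, b))
  only_a <- length(setdiff(a, b))
  only_b <- length(setdiff(b, a))
  structure(list(only_a = only_a, only_b = only_b, both = both,
                 concordance = both / (only_a + only_b + both),
                 concordance_min_set =
                   if (min(length(a), length(b)) > 0)
                     both / min(length(a), length(b)) else NA_real_),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Gene-set concordance: %d both, %d only A, %d only B\n",
              x$both, x$only_a, x$only_b))
  cat(sprintf("  intersection/union: %.3f; intersection/smaller set: %.3f\n",
              x$concordance, x$concordance_min_set))
  invisible(x)
}
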