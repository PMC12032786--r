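gr1 <- function(chrom, start, end)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))

test_that("tolerance matching expands each peak and bridges bounded gaps", {
  a <- gr1("chr1", 101, 200)
  expect_true(match_with_tolerance(a, gr1("chr1", 151, 250), tol_bp = 0))
  # gap of 8 bp (0-based 208 vs end 200): bridged at tol 5 in both-sides mode
  expect_true(match_with_tolerance(a, gr1("chr1", 209, 300), tol_bp = 5))
  # gap of 15 bp exceeds 2 * tol
  expect_false(match_with_tolerance(a, gr1("chr1", 216, 300), tol_bp = 5))
  # single-sided mode bridges at most tol
  expect_false(match_with_tolerance(a, gr1("chr1", 209, 300), tol_bp = 5,
                                    tol_mode = "single"))
  expect_true(match_with_tolerance(a, gr1("chr1", 206, 300), tol_bp = 5,
                                   tol_mode = "single"))
  expect_false(match_with_tolerance(a, gr1("chr2", 101, 200), tol_bp = 5))
})

test_that("consensus rule: support unreachable with one replicate, idempotent on identical peaks", {
  one_rep <- peaks_df_to_granges(data.frame(
    chrom = "chr1", start = 101, end = 200, replicate = "rep1", name = "p1"))
  expect_equal(length(consensus_peaks(list(one_rep))), 0)

  same <- do.call(c, lapply(1:3, function(r) peaks_df_to_granges(data.frame(
    chrom = "chr1", start = 101, end = 200,
    replicate = sprintf("rep%d", r), name = sprintf("p%d", r)))))
  cons <- consensus_peaks(same)
  expect_equal(length(cons), 1)
  expect_equal(c(start(cons), end(cons)), c(101, 200))
  expect_equal(S4Vectors::mcols(cons)$support, 3L)
})

test_that("tolerance-bridged peaks from two of three replicates form one union-span consensus", {
  df <- data.frame(chrom = "chr1", start = c(101, 209), end = c(200, 300),
                   replicate = c("rep1", "rep2"), name = c("p1", "p2"))
  cons <- consensus_peaks(peaks_df_to_granges(df), tol_bp = 5, min_support = 2)
  expect_equal(length(cons), 1)
  expect_equal(c(start(cons), end(cons)), c(101, 300))
  expect_equal(S4Vectors::mcols(cons)$support, 2L)
})

test_that("multiple peaks from one replicate count once toward support", {
  df <- data.frame(chrom = "chr1", start = c(101, 105, 110),
                   end = c(200, 205, 210),
                   replicate = c("rep1", "rep1", "rep1"),
                   name = c("p1", "p2", "p3"))
  expect_equal(length(consensus_peaks(peaks_df_to_granges(df), min_support = 2)), 0)
  cons <- consensus_peaks(peaks_df_to_granges(df), min_support = 1)
  expect_equal(S4Vectors::mcols(cons)$support, 1L)
  expect_equal(S4Vectors::mcols(cons)$n_members, 3L)
})

test_that("mixed condition labels are rejected", {
  a <- peaks_df_to_granges(data.frame(chrom = "chr1", start = 1, end = 10,
                                      replicate = "r1", name = "p1"),
                           condition = "c1")
  b <- peaks_df_to_granges(data.frame(chrom = "chr1", start = 1, end = 10,
                                      replicate = "r2", name = "p2"),
                           condition = "c2")
  expect_error(consensus_peaks(list(a, b)), "condition")
})

test_that("clustering equals the brute-force union-find oracle on random instances", {
  set.seed(101)
  for (i in 1:150) {
    tol <- sample(c(0, 5, 10), 1)
    mode <- sample(c("both", "single"), 1)
    min_support <- sample(1:2, 1)
    df <- random_peak_instance(max_peaks = 40,
                               n_reps = sample(2:4, 1))
    expected <- oracle_consensus(df, tol, min_support, mode)
    got <- clusters_from_consensus(
      consensus_peaks(peaks_df_to_granges(df), tol_bp = tol,
                      min_support = min_support, tol_mode = mode))
    expect_equal(lapply(got, `[[`, "members"),
                 lapply(expected, `[[`, "members"))
    expect_equal(lapply(got, `[[`, "support"),
                 lapply(expected, `[[`, "support"))
    expect_equal(lapply(got, `[[`, "start"), lapply(expected, `[[`, "start"))
    expect_equal(lapply(got, `[[`, "end"), lapply(expected, `[[`, "end"))
  }
})

test_that("no two emitted consensus peaks on one chromosome still match each other", {
  set.seed(202)
  for (i in 1:25) {
    df <- random_peak_instance(max_peaks = 50, n_reps = 3)
    cons <- consensus_peaks(peaks_df_to_granges(df), tol_bp = 5,
                            min_support = 1)
    if (length(cons) < 2) next
    for (a in seq_len(length(cons) - 1))
      expect_false(any(match_with_tolerance(cons[a], cons[(a + 1):length(cons)],
                                            tol_bp = 5)))
  }
})

test_that("with min_support = 1 every input peak lands in exactly one cluster", {
  set.seed(303)
  for (i in 1:25) {
    df <- random_peak_instance()
    cons <- consensus_peaks(peaks_df_to_granges(df), min_support = 1)
    members <- S4Vectors::metadata(cons)$members
    expect_setequal(members$name, df$name)
    expect_equal(anyDuplicated(members$name), 0)
  }
})

test_that("output is invariant to replicate and within-replicate peak order", {
  set.seed(404)
  df <- random_peak_instance(max_peaks = 30, n_reps = 3)
  base <- consensus_peaks(peaks_df_to_granges(df))
  for (i in 1:5) {
    perm <- df[sample.int(nrow(df)), ]
    shuffled <- consensus_peaks(peaks_df_to_granges(perm))
    expect_equal(clusters_from_consensus(shuffled),
                 clusters_from_consensus(base))
  }
})
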