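#' Do two intervals match under the coordinate tolerance rule?
#'
#' Two peaks are at "the same locus" when, after expanding each by `tol_bp`
#' on both sides, the expanded intervals meet; equivalently when the gap
#' between them (0 for overlapping or book-ended intervals) is at most
#' `2 * tol_bp`. `tol_mode = "single"` applies the expansion to one peak only,
#' bounding the bridged gap by `tol_bp` instead.
#'
#' @param a,b `GRanges` of equal length (compared element-wise) or one of
#'   length 1 (recycled). Intervals on different chromosomes never match.
#' @param tol_bp non-negative tolerance in bp added to each side (default 5).
#' @param tol_mode `"both"` (default; each peak expanded, max bridged gap
#'   `2*tol_bp`) or `"single"` (max bridged gap `tol_bp`).
#' @return logical vector.
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(209, 300))
#' match_with_tolerance(a, b, tol_bp = 5)   # gap 8 <= 10
match_with_tolerance <- function(a, b, tol_bp = 5,
                                 tol_mode = c("both", "single")) {
  tol_mode <- match.arg(tol_mode)
  stopifnot(tol_bp >= 0)
  maxgap <- if (tol_mode == "both") 2 * tol_bp else tol_bp
  same_chrom <- as.character(seqnames(a)) == as.character(seqnames(b))
  gap <- pmax(0L, pmax(start(a), start(b)) - pmin(end(a), end(b)) - 1L)
  same_chrom & gap <= maxgap
}

#' Build replicate-consensus peaks
#'
#' Clusters peaks across replicates of one condition by single linkage under
#' [match_with_tolerance()] (the transitive closure of the pairwise rule) and
#' emits each cluster supported by at least `min_support` distinct replicates
#' as a consensus peak. The consensus interval is the union span of the member
#' peaks (minimum start to maximum end): replicate peaks jittered by a few bp
#' can satisfy the tolerance rule yet have an empty intersection, so the
#' union is the only span that preserves every covered base. Multiple peaks
#' from one replicate inside a cluster count once toward support.
#'
#' @param replicate_peaks a list of per-replicate `GRanges` (as returned by
#'   [read_narrowpeak()]), or a single combined `GRanges` with a
#'   `replicate_id` column. All peaks must carry the same `condition` label.
#' @param tol_bp,tol_mode tolerance rule parameters; see
#'   [match_with_tolerance()].
#' @param min_support minimum number of distinct supporting replicates
#'   (default 2).
#' @return a `GRanges` of consensus peaks sorted by (chromosome, start), with
#'   metadata columns `consensus_id` (`cons_<k>`), `support`, `n_members`,
#'   `anchor` (1-based anchor position: the floor of the median member summit
#'   when any member has one, else the floor midpoint of the union span) and
#'   `condition`. The full member assignment is attached as a data frame in
#'   `S4Vectors::metadata(x)$members` with one row per member peak.
#' @export
consensus_peaks <- function(replicate_peaks, tol_bp = 5, min_support = 2,
                            tol_mode = c("both", "single")) {
  tol_mode <- match.arg(tol_mode)
  stopifnot(tol_bp >= 0, min_support >= 1)
  peaks <- if (is(replicate_peaks, "GRanges")) replicate_peaks
           else do.call(c, unname(replicate_peaks))
  if (is.null(mcols(peaks)$replicate_id))
    stopf("peaks must carry a 'replicate_id' metadata column")
  cond <- unique(mcols(peaks)$condition)
  cond <- cond[!is.na(cond)]
  if (length(cond) > 1)
    stopf("consensus_peaks: peaks mix condition labels (%s); run one condition at a time",
          paste(cond, collapse = ", "))
  cond <- if (length(cond)) cond else NA_character_
  empty <- GenomicRanges::GRanges(
    consensus_id = character(0), support = integer(0), n_members = integer(0),
    anchor = integer(0), condition = character(0))
  metadata(empty)$members <- empty_members_table()
  if (length(peaks) == 0) return(empty)

  maxgap <- if (tol_mode == "both") 2 * tol_bp else tol_bp
  red <- GenomicRanges::reduce(peaks, min.gapwidth = maxgap + 1,
                               ignore.strand = TRUE, with.revmap = TRUE)
  revmap <- mcols(red)$revmap
  support <- vapply(revmap, function(ii)
    length(unique(mcols(peaks)$replicate_id[ii])), 0L)
  keep <- support >= min_support
  red <- red[keep]
  revmap <- revmap[keep]
  support <- support[keep]
  if (length(red) == 0) return(empty)

  ord <- order(as.character(seqnames(red)), start(red))
  red <- red[ord]
  revmap <- revmap[ord]
  support <- support[ord]

  anchor <- vapply(seq_along(red), function(k) {
    ii <- revmap[[k]]
    summit <- mcols(peaks)$peak[ii]
    pos <- start(peaks)[ii] + summit      # 1-based absolute summit
    pos <- pos[!is.na(summit) & summit >= 0]
    if (length(pos)) as.integer(floor(median(pos)))
    else as.integer(floor((start(red)[k] - 1 + end(red)[k]) / 2) + 1L)
  }, 0L)

  out <- GenomicRanges::granges(red, use.mcols = FALSE)
  mcols(out)$consensus_id <- paste0("cons_", seq_along(out))
  mcols(out)$support <- support
  mcols(out)$n_members <- lengths(revmap)
  mcols(out)$anchor <- anchor
  mcols(out)$condition <- cond
  members <- do.call(rbind, lapply(seq_along(out), function(k) {
    ii <- revmap[[k]]
    data.frame(consensus_id = mcols(out)$consensus_id[k],
               replicate_id = mcols(peaks)$replicate_id[ii],
               chrom = as.character(seqnames(peaks)[ii]),
               start = start(peaks)[ii] - 1L,   # 0-based on output, BED-style
               end = end(peaks)[ii],
               name = mcols(peaks)$name[ii],
               score = mcols(peaks)$score[ii],
               signalValue = mcols(peaks)$signalValue[ii],
               pValue = mcols(peaks)$pValue[ii],
               qValue = mcols(peaks)$qValue[ii],
               peak = mcols(peaks)$peak[ii])
  }))
  metadata(out)$members <- members
  out
}

empty_members_table <- function() {
  data.frame(consensus_id = character(0), replicate_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), score = integer(0), signalValue = numeric(0),
             pValue = numeric(0), qValue = numeric(0), peak = integer(0))
}
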