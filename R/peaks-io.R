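#' Read MACS2 narrowPeak peak calls
#'
#' Reads a 10-column narrowPeak (BED6+4) file into a `GRanges`. narrowPeak
#' coordinates are 0-based half-open on disk and are converted to the 1-based
#' closed convention of `GRanges` (`start + 1`, `end`). Track and comment
#' lines are skipped; data lines are kept in input order.
#'
#' @param path path to a narrowPeak file (plain or gzip).
#' @param replicate_id label of the originating replicate, stored per peak.
#' @param condition label of the experimental condition, stored per peak.
#' @return a `GRanges` with metadata columns `name`, `score`, `signalValue`,
#'   `pValue`, `qValue`, `peak` (summit offset from the 0-based start, or -1
#'   if absent), `replicate_id`, `condition`. The narrowPeak strand column is
#'   retained in the `GRanges` strand slot but is ignored by downstream logic
#'   (peak strand carries no meaning for transcription-factor binding).
#' @export
read_narrowpeak <- function(path, replicate_id = NA_character_,
                            condition = NA_character_) {
  lines <- readLines(gzfile(path), warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 10L)) {
    bad <- idx[which(ncols != 10L)[1]]
    stopf("narrowPeak parse error at line %d: expected 10 tab-separated columns, found %d",
          bad, ncols[which(ncols != 10L)[1]])
  }
  if (length(fields) == 0) {
    return(GenomicRanges::GRanges(
      name = character(0), score = integer(0), signalValue = numeric(0),
      pValue = numeric(0), qValue = numeric(0), peak = integer(0),
      replicate_id = character(0), condition = character(0)))
  }
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0 | start0 < 0)
  if (length(bad))
    stopf("narrowPeak parse error at line %d: invalid interval %s-%s",
          idx[bad[1]], m[bad[1], 2], m[bad[1], 3])
  summit <- suppressWarnings(as.integer(m[, 10]))
  width <- end0 - start0
  bad <- which(is.na(summit) | (summit != -1L & (summit < 0L | summit >= width)))
  if (length(bad))
    stopf("narrowPeak parse error at line %d: summit offset %s outside peak of width %d",
          idx[bad[1]], m[bad[1], 10], width[bad[1]])
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start0 + 1L, end0),
    strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"),
    name = m[, 4],
    score = as.integer(m[, 5]),
    signalValue = as.numeric(m[, 7]),
    pValue = as.numeric(m[, 8]),
    qValue = as.numeric(m[, 9]),
    peak = summit,
    replicate_id = replicate_id,
    condition = condition)
}

#' Write peaks to narrowPeak
#'
#' Inverse of [read_narrowpeak()]: emits canonical tab-separated 10-column
#' narrowPeak with 0-based half-open coordinates. Reading the output back
#' reproduces every field of the input.
#'
#' @param peaks a `GRanges` as returned by [read_narrowpeak()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  if (length(peaks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mc <- mcols(peaks)
  strand_chr <- as.character(GenomicRanges::strand(peaks))
  strand_chr[strand_chr == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                   as.character(seqnames(peaks)),
                   start(peaks) - 1L, end(peaks),
                   mc$name, mc$score, strand_chr,
                   format_num(mc$signalValue), format_num(mc$pValue),
                   format_num(mc$qValue), mc$peak)
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals to BED6
#'
#' @param gr a `GRanges`; `name` and `score` metadata columns are used when
#'   present.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  if (length(gr) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mc <- mcols(gr)
  name <- if (!is.null(mc$name)) mc$name else paste0("region_", seq_along(gr))
  score <- if (!is.null(mc$score)) mc$score else 0L
  strand_chr <- as.character(GenomicRanges::strand(gr))
  strand_chr[strand_chr == "*"] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     name, as.integer(score), strand_chr), path)
  invisible(path)
}
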