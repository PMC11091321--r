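#' Construct a peak set
#'
#' A peak set is the container for one source of called ChIP-seq peaks (a
#' transcription factor or histone mark). Peaks are 0-based half-open
#' intervals with stable ids; the set is sorted by (chrom, start, end) on
#' construction and every chromosome must exist in the attached genome.
#' Duplicate identical intervals are retained: they are distinct peaks with
#' distinct ids. Peaks are unstranded.
#'
#' @param chrom,start,end Parallel vectors describing the intervals; `start`
#'   is 0-based inclusive, `end` exclusive, `end > start`, `start >= 0`.
#' @param genome A [genome_info()] object.
#' @param name Source label (e.g. `"WT1"`, `"AR"`, `"H3K4me3"`).
#' @param id Optional peak ids, unique within the set; auto-generated as
#'   `name_<ordinal>` (in sorted order) when missing.
#' @param score Optional numeric enrichment values.
#' @return An object of class `peak_set`: a list with `name`, `genome` and a
#'   data frame `peaks` (columns `chrom`, `start`, `end`, `id`, `score`).
#' @examples
#' g <- genome_info(c(chr1 = 1e6), "toy")
#' peak_set(c("chr1", "chr1"), c(100, 50), c(200, 80), g, name = "TF")
#' @export
peak_set <- function(chrom, start, end, genome, name = "peaks",
                     id = NULL, score = NULL) {
  stopifnot(inherits(genome, "genome_info"))
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n) {
    stop("chrom, start, end must have equal length")
  }
  if (n > 0L) {
    if (any(!is.finite(start)) || any(!is.finite(end))) {
      stop("non-finite coordinates")
    }
    if (any(start < 0)) stop("start must be >= 0")
    if (any(end <= start)) {
      bad <- which(end <= start)[1L]
      stop(sprintf("empty or inverted interval at record %d: [%s, %s)",
                   bad, format(start[bad]), format(end[bad])))
    }
    unknown <- setdiff(unique(chrom), names(genome$chrom_sizes))
    if (length(unknown)) {
      stop("chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "))
    }
    over <- end > genome$chrom_sizes[chrom]
    if (any(over)) {
      stop("interval(s) extend past chromosome end: record(s) ",
           paste(head(which(over), 5L), collapse = ", "))
    }
  }
  if (is.null(score)) score <- rep(NA_real_, n)
  ord <- order(match(chrom, names(genome$chrom_sizes)), start, end)
  peaks <- data.frame(chrom = chrom[ord], start = start[ord], end = end[ord],
                      id = rep(NA_character_, n),
                      score = as.numeric(score)[ord],
                      stringsAsFactors = FALSE)
  if (is.null(id)) {
    peaks$id <- if (n > 0L) sprintf("%s_%d", name, seq_len(n)) else character(0)
  } else {
    id <- as.character(id)
    if (length(id) != n) stop("id must match the number of peaks")
    if (anyDuplicated(id)) stop("peak ids must be unique within a set")
    peaks$id <- id[ord]
  }
  structure(list(name = name, genome = genome, peaks = peaks),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s: %d peak(s) on %d chromosome(s) [%s]\n",
              x$name, nrow(x$peaks), length(unique(x$peaks$chrom)),
              x$genome$assembly))
  invisible(x)
}

#' Number of peaks in a set
#' @param x A `peak_set`.
#' @return Integer count.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "peak_set"))
  nrow(x$peaks)
}

#' Peak lengths in bp
#' @param x A `peak_set`.
#' @return Numeric vector `end - start`, named by peak id.
#' @export
peak_lengths <- function(x) {
  stopifnot(inherits(x, "peak_set"))
  setNames(x$peaks$end - x$peaks$start, x$peaks$id)
}

# subset a peak_set by logical/integer index, preserving ids and order
.subset_peaks <- function(x, i) {
  out <- x
  out$peaks <- x$peaks[i, , drop = FALSE]
  rownames(out$peaks) <- NULL
  out
}

.check_same_genome <- function(a, b) {
  if (!identical(names(a$genome$chrom_sizes), names(b$genome$chrom_sizes)) ||
      !identical(unname(a$genome$chrom_sizes), unname(b$genome$chrom_sizes))) {
    stop("peak sets are on different genomes")
  }
}

# GRanges view of a peak_set / interval data frame (1-based closed inside)
.as_granges <- function(chrom, start, end, genome, id = NULL) {
  gr <- GRanges(seqnames = chrom,
                ranges = IRanges(start = start + 1, end = end),
                seqinfo = .seqinfo_of(genome))
  if (!is.null(id)) mcols(gr)$id <- id
  gr
}

.peaks_gr <- function(x) {
  .as_granges(x$peaks$chrom, x$peaks$start, x$peaks$end, x$genome,
              id = x$peaks$id)
}

#' Read a BED3/BED5 file into a peak set
#'
#' Tab-separated, 0-based half-open intervals; lines starting with `#` or
#' `track`/`browser` are skipped. Column 4, when present, supplies the peak
#' id; column 5 the score. Missing ids are auto-generated as
#' `name_<ordinal>`.
#'
#' @param path BED file path.
#' @param genome A [genome_info()]; every chromosome in the file must exist
#'   in it.
#' @param name Source label for the resulting set.
#' @return A sorted [peak_set()].
#' @export
read_bed <- function(path, genome, name = "peaks") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(peak_set(character(0), numeric(0), numeric(0), genome, name))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                 lineno[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 lineno[bad[1L]]))
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: end <= start (empty interval)",
                 lineno[bad[1L]]))
  }
  id <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  if (!is.null(id) && (anyDuplicated(id) || any(!nzchar(id)))) id <- NULL
  score <- if (all(nf >= 5L)) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  } else NULL
  peak_set(chrom, start, end, genome, name = name, id = id, score = score)
}

#' Write a peak set as BED
#'
#' Emits BED5 when any score is present, else BED4 (chrom, start, end, id).
#'
#' @param x A `peak_set`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "peak_set"))
  p <- x$peaks
  cols <- data.frame(chrom = p$chrom,
                     start = format(p$start, scientific = FALSE, trim = TRUE),
                     end = format(p$end, scientific = FALSE, trim = TRUE),
                     id = p$id)
  if (any(!is.na(p$score))) {
    cols$score <- ifelse(is.na(p$score), 0,
                         format(p$score, scientific = FALSE, trim = TRUE))
  }
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
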