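#' Genome description: chromosome names and lengths
#'
#' A minimal genome container: a named vector of chromosome lengths plus an
#' assembly label. All interval containers in the package carry one of these
#' so that chromosome names can be validated and the genome can be tiled into
#' bins for the co-localization test.
#'
#' @param chrom_sizes Named numeric vector, chromosome name -> length in bp.
#'   All lengths must be positive.
#' @param assembly Assembly label, e.g. `"GRCh38"` or `"synthetic"`.
#' @return An object of class `genome_info`.
#' @examples
#' genome_info(c(chr1 = 248956422L), "GRCh38")
#' @export
genome_info <- function(chrom_sizes, assembly = "unknown") {
  if (length(chrom_sizes) == 0L) stop("chrom_sizes must be non-empty")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(chrom_sizes))) stop("duplicate chromosome names")
  sizes <- as.numeric(chrom_sizes)
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  structure(
    list(chrom_sizes = setNames(sizes, names(chrom_sizes)),
         assembly = as.character(assembly)),
    class = "genome_info"
  )
}

#' @export
print.genome_info <- function(x, ...) {
  cat(sprintf("<genome_info> %s: %d chromosome(s), %.0f bp total\n",
              x$assembly, length(x$chrom_sizes), sum(x$chrom_sizes)))
  invisible(x)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with columns chromosome name and length (no
#'   header), the conventional `chrom.sizes` layout.
#' @param assembly Assembly label to attach.
#' @return A [genome_info()] object.
#' @export
read_chrom_sizes <- function(path, assembly = "unknown") {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  genome_info(setNames(tab$length, tab$chrom), assembly)
}

#' Write a chrom.sizes file
#'
#' @param genome A [genome_info()] object.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_info"))
  write.table(
    data.frame(chrom = names(genome$chrom_sizes),
               length = format(genome$chrom_sizes, scientific = FALSE,
                               trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

.seqinfo_of <- function(genome) {
  Seqinfo(seqnames = names(genome$chrom_sizes),
          seqlengths = as.integer(genome$chrom_sizes),
          genome = genome$assembly)
}

#' Tile a genome into fixed-width bins
#'
#' Each chromosome is tiled from position 0 in consecutive windows of
#' `width` bp; the final, possibly shorter, partial bin is kept, so the bins
#' partition each chromosome exactly and the per-chromosome bin count is
#' `ceiling(length / width)`. The grid is stored implicitly (genome + width);
#' use [bin_ranges()] to materialize bin intervals.
#'
#' @param genome A [genome_info()] object.
#' @param width Bin width in bp (positive integer).
#' @return An object of class `bin_grid` with fields `genome`, `width`,
#'   `n_bins` (named per-chromosome bin counts) and `n_total`.
#' @examples
#' g <- genome_info(c(chr1 = 10), "toy")
#' tile_genome(g, 4)  # 3 bins: [0,4) [4,8) [8,10)
#' @export
tile_genome <- function(genome, width) {
  stopifnot(inherits(genome, "genome_info"))
  width <- as.numeric(width)
  if (length(width) != 1L || !is.finite(width) || width < 1 ||
      width != floor(width)) {
    stop("width must be a positive integer number of bp")
  }
  n_bins <- ceiling(genome$chrom_sizes / width)
  structure(
    list(genome = genome, width = width,
         n_bins = n_bins, n_total = sum(n_bins)),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> width %d bp, %.0f bins over %d chromosome(s)\n",
              x$width, x$n_total, length(x$n_bins)))
  invisible(x)
}

#' Materialize the bins of a grid as intervals
#'
#' @param grid A [tile_genome()] grid.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `bin` (1-based global bin index).
#' @export
bin_ranges <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  chroms <- names(grid$n_bins)
  out <- lapply(chroms, function(ch) {
    n <- grid$n_bins[[ch]]
    s <- (seq_len(n) - 1) * grid$width
    data.frame(chrom = ch, start = s,
               end = pmin(s + grid$width, grid$genome$chrom_sizes[[ch]]))
  })
  out <- do.call(rbind, out)
  out$bin <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# global 1-based bin index offset per chromosome
.bin_offsets <- function(grid) {
  offs <- cumsum(c(0, unname(grid$n_bins)))
  setNames(offs[seq_along(grid$n_bins)], names(grid$n_bins))
}

# distinct global bin indices touched by >=1 bp of any of the intervals
.occupied_bins <- function(grid, chrom, start, end) {
  if (length(chrom) == 0L) return(numeric(0))
  offs <- .bin_offsets(grid)
  first <- floor(start / grid$width)          # 0-based within-chrom bin
  last <- floor((end - 1) / grid$width)
  nsp <- last - first + 1
  bins <- rep(offs[chrom] + first + 1, nsp) + (sequence(nsp) - 1)
  sort(unique(bins))
}
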