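#' Do two intervals share at least one base?
#'
#' Overlap means sharing at least one genomic coordinate. Under 0-based
#' half-open coordinates that is `a.start < b.end && b.start < a.end` on the
#' same chromosome; book-ended intervals (one ending exactly where the other
#' starts) do not overlap. Vectorized with recycling.
#'
#' @param chrom_a,start_a,end_a First interval(s), 0-based half-open.
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Logical vector.
#' @examples
#' intervals_overlap("chr1", 100, 200, "chr1", 199, 250)  # TRUE
#' intervals_overlap("chr1", 100, 200, "chr1", 200, 250)  # FALSE
#' @export
intervals_overlap <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

#' All overlapping peak pairs between two sets
#'
#' Every (A-peak, B-peak) pair sharing at least one base, each distinct pair
#' reported once. Both sets must be on the same genome.
#'
#' @param set_a,set_b [peak_set()] objects on the same genome.
#' @return Data frame with columns `id_a`, `id_b`.
#' @export
find_overlap_pairs <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "peak_set"), inherits(set_b, "peak_set"))
  .check_same_genome(set_a, set_b)
  hits <- findOverlaps(.peaks_gr(set_a), .peaks_gr(set_b))
  out <- data.frame(id_a = set_a$peaks$id[queryHits(hits)],
                    id_b = set_b$peaks$id[subjectHits(hits)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge co-bound peaks from two sets into connected components
#'
#' Builds the overlap graph over the union of the two peak sets and keeps
#' every connected component that contains at least one peak from each set.
#' Two peaks of set A bridged by a single peak of set B (or vice versa) fall
#' in one component and yield a single merged peak. The merged span is the
#' tightest interval covering all members; spans of distinct merged peaks
#' never overlap.
#'
#' @param set_a,set_b [peak_set()] objects on the same genome.
#' @return Data frame with one row per merged peak: `chrom`, `start`, `end`
#'   (component span, 0-based half-open), `n_a`, `n_b` (member counts) and
#'   comma-separated member id lists `members_a`, `members_b`.
#' @export
merge_cobound <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "peak_set"), inherits(set_b, "peak_set"))
  .check_same_genome(set_a, set_b)
  na <- n_peaks(set_a)
  nb <- n_peaks(set_b)
  if (na == 0L || nb == 0L) return(.empty_merged())
  all_gr <- c(.peaks_gr(set_a), .peaks_gr(set_b))
  src <- rep(c("a", "b"), c(na, nb))
  # components of the overlap graph = intervals falling in the same
  # reduced (overlap-merged, not book-ended) region
  comp_regions <- reduce(all_gr, min.gapwidth = 0L)
  hits <- findOverlaps(all_gr, comp_regions)
  comp <- integer(na + nb)
  comp[queryHits(hits)] <- subjectHits(hits)
  has_a <- tapply(src == "a", comp, any)
  has_b <- tapply(src == "b", comp, any)
  keep_comp <- as.integer(names(which(has_a & has_b)))
  if (length(keep_comp) == 0L) return(.empty_merged())
  rows <- lapply(keep_comp, function(ci) {
    m <- which(comp == ci)
    ids <- mcols(all_gr)$id[m]
    data.frame(
      chrom = as.character(seqnames(comp_regions))[ci],
      start = start(comp_regions)[ci] - 1,
      end = end(comp_regions)[ci],
      n_a = sum(src[m] == "a"),
      n_b = sum(src[m] == "b"),
      members_a = paste(ids[src[m] == "a"], collapse = ","),
      members_b = paste(ids[src[m] == "b"], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$chrom, seqlevels(comp_regions)), out$start), ]
  rownames(out) <- NULL
  out
}

.empty_merged <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             n_a = integer(0), n_b = integer(0),
             members_a = character(0), members_b = character(0),
             stringsAsFactors = FALSE)
}

#' Merged peaks as a peak set
#'
#' Convenience wrapper turning [merge_cobound()] output into a [peak_set()]
#' (ids `merged_<ordinal>`) so merged peaks can flow through annotation and
#' stratification like any other set.
#'
#' @param merged Output of [merge_cobound()].
#' @param genome The shared [genome_info()].
#' @param name Label for the new set.
#' @return A [peak_set()].
#' @export
merged_peak_set <- function(merged, genome, name = "merged") {
  peak_set(merged$chrom, merged$start, merged$end, genome, name = name,
           id = if (nrow(merged)) sprintf("%s_%d", name, seq_len(nrow(merged)))
                else character(0))
}

#' Distance from each query peak to its nearest subject peak
#'
#' The gap in bp between each query peak and the nearest subject peak on the
#' same chromosome: 0 when they overlap (or abut), otherwise the number of
#' bases strictly between them. Query peaks on chromosomes carrying no
#' subject peak get `NA` (they are excluded from distance histograms rather
#' than set to infinity).
#'
#' @param query,subject [peak_set()] objects on the same genome.
#' @return Numeric vector named by query peak id, in query (sorted) order.
#' @export
nearest_distance <- function(query, subject) {
  stopifnot(inherits(query, "peak_set"), inherits(subject, "peak_set"))
  .check_same_genome(query, subject)
  if (n_peaks(subject) == 0L) {
    stop("subject peak set is empty: nearest distances undefined")
  }
  d <- rep(NA_real_, n_peaks(query))
  hits <- distanceToNearest(.peaks_gr(query), .peaks_gr(subject))
  d[queryHits(hits)] <- mcols(hits)$distance
  setNames(d, query$peaks$id)
}

#' Mean peak length of two pooled peak sets
#'
#' Arithmetic mean of the lengths of the pooled multiset of peaks from both
#' sets, rounded half-up to the nearest integer bp. This is the default bin
#' width of the binned co-localization test. Set `pooled = FALSE` to average
#' the two per-set means instead.
#'
#' @param set_a,set_b Non-empty [peak_set()] objects.
#' @param pooled Pool all peaks (default) or average the two per-set means.
#' @return Integer bin width in bp.
#' @examples
#' g <- genome_info(c(chr1 = 1e4), "toy")
#' a <- peak_set("chr1", 0, 100, g)
#' b <- peak_set("chr1", 0, 101, g)
#' mean_peak_length(a, b)  # 101: 100.5 rounds half-up
#' @export
mean_peak_length <- function(set_a, set_b, pooled = TRUE) {
  stopifnot(inherits(set_a, "peak_set"), inherits(set_b, "peak_set"))
  if (n_peaks(set_a) == 0L || n_peaks(set_b) == 0L) {
    stop("mean peak length requires two non-empty peak sets")
  }
  m <- if (pooled) {
    mean(c(peak_lengths(set_a), peak_lengths(set_b)))
  } else {
    mean(c(mean(peak_lengths(set_a)), mean(peak_lengths(set_b))))
  }
  as.integer(floor(m + 0.5))
}
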