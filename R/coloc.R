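#' 2x2 bin-occupancy contingency table
#'
#' Construct the contingency table of the binned co-localization test. A bin
#' "contains" a set's peak iff at least one base of some peak of that set
#' lies in the bin. Cells: `n00` bins with no peaks, `n10` bins with only
#' set-A peaks, `n01` bins with only set-B peaks, `n11` bins with peaks from
#' both sets; the four cells always sum to the grid's total bin count.
#'
#' @param grid A [tile_genome()] grid.
#' @param set_a,set_b [peak_set()] objects on the grid's genome.
#' @return An object of class `contingency_2x2`.
#' @export
bin_occupancy_table <- function(grid, set_a, set_b) {
  stopifnot(inherits(grid, "bin_grid"),
            inherits(set_a, "peak_set"), inherits(set_b, "peak_set"))
  .check_same_genome(set_a, list(genome = grid$genome))
  .check_same_genome(set_b, list(genome = grid$genome))
  bins_a <- .occupied_bins(grid, set_a$peaks$chrom, set_a$peaks$start,
                           set_a$peaks$end)
  bins_b <- .occupied_bins(grid, set_b$peaks$chrom, set_b$peaks$start,
                           set_b$peaks$end)
  n11 <- length(intersect(bins_a, bins_b))
  n10 <- length(bins_a) - n11
  n01 <- length(bins_b) - n11
  n00 <- grid$n_total - n11 - n10 - n01
  contingency_2x2(n00, n10, n01, n11)
}

#' @rdname bin_occupancy_table
#' @param n00,n10,n01,n11 Non-negative cell counts (no peaks / A only /
#'   B only / both).
#' @export
contingency_2x2 <- function(n00, n10, n01, n11) {
  cells <- c(n00 = n00, n10 = n10, n01 = n01, n11 = n11)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$n00, x$n01, x$n10, x$n11), 2, 2, byrow = TRUE,
              dimnames = list(c("A absent", "A present"),
                              c("B absent", "B present")))
  print(m)
  invisible(x)
}

# Upper-tail hypergeometric P[X >= k] with X ~ Hyper(N, K, n), vectorized
# over tables. Terms are exp(lchoose sums); the modal log-term is factored
# out before summation so the tail is accurate in log space.
.hyper_upper_tail <- function(k, K, n, N) {
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), m); K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m); N <- rep_len(as.numeric(N), m)
  if (any(K > N | n > N | k < 0 | K < 0 | n < 0 | N < 0)) {
    stop("inconsistent hypergeometric parameters")
  }
  kmin <- pmax(0, K + n - N)
  kmax <- pmin(K, n)
  k <- pmax(k, kmin)                      # P[X >= k] = 1 below the support
  len <- kmax - k + 1
  if (any(len < 1)) stop("k exceeds the hypergeometric support")
  grp <- rep(seq_len(m), len)
  i <- sequence(len) - 1 + rep(k, len)
  lt <- lchoose(rep(K, len), i) +
    lchoose(rep(N - K, len), rep(n, len) - i) -
    lchoose(rep(N, len), rep(n, len))
  # modal term of the pmf, clamped into [k, kmax], anchors the log-sum
  mode_i <- pmin(pmax(floor((K + 1) * (n + 1) / (N + 2)), k), kmax)
  lmax <- lchoose(K, mode_i) + lchoose(N - K, n - mode_i) - lchoose(N, n)
  p <- exp(lmax) * as.numeric(rowsum(exp(lt - lmax[grp]), grp))
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' One-sided (enrichment) Fisher's exact test on a 2x2 table
#'
#' The exact enrichment p-value of the joint-occupancy cell: with `N` total
#' bins, `K = n11 + n10` bins holding set-A peaks, `n = n11 + n01` bins
#' holding set-B peaks and `k = n11` jointly occupied bins,
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. The tail is summed in
#' log space via log-gamma (the modal term factored out), so extreme tables
#' do not underflow prematurely; results below the smallest positive double
#' are floored there and never reported as exactly zero.
#'
#' @param table A [contingency_2x2()].
#' @return The p-value in (0, 1].
#' @examples
#' fisher_exact_one_sided(contingency_2x2(5, 2, 2, 0))  # k = 0 => p = 1
#' @export
fisher_exact_one_sided <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  N <- table$n00 + table$n10 + table$n01 + table$n11
  if (N == 0) return(1)
  .hyper_upper_tail(table$n11, table$n11 + table$n10,
                    table$n11 + table$n01, N)
}

#' Exact-rational hypergeometric upper tail (small N reference)
#'
#' Reference enumeration of `P[X >= k]`, `X ~ Hypergeometric(N, K, n)`,
#' computed with exact 128-bit integer arithmetic (Pascal-triangle binomial
#' coefficients, exact numerator and denominator; a single final division).
#' Exact for `N <= 120`; intended for validating the log-space
#' implementation on small tables, not for genome-scale grids.
#'
#' @param k,K,n,N Vectors (recycled) of tail start, successes in the
#'   population, draws, and population size.
#' @return Numeric vector of tail probabilities.
#' @export
hyper_tail_exact <- function(k, K, n, N) {
  m <- max(length(k), length(K), length(n), length(N))
  hyper_tail_exact_cpp(as.integer(rep_len(k, m)), as.integer(rep_len(K, m)),
                       as.integer(rep_len(n, m)), as.integer(rep_len(N, m)))
}

#' Binned-genome co-localization test between two peak sets
#'
#' The full co-localization procedure: tile the genome into bins whose width
#' defaults to the pooled mean peak length of the two sets, build the
#' bin-occupancy contingency table, and test joint occupancy for enrichment
#' with the one-sided exact test. Symmetric in the two sets up to
#' transposing the off-diagonal cells.
#'
#' @param set_a,set_b Non-empty [peak_set()] objects on the same genome.
#' @param width Bin width in bp; `NULL` (default) uses
#'   [mean_peak_length()].
#' @param restrict_to_peak_chroms Drop chromosomes bearing no peak of
#'   either set from the empty-bin count. Off by default: the whole genome
#'   is binned.
#' @return List of class `overlap_test_result`: `table`
#'   (a [contingency_2x2()]), `p_value`, `odds_ratio`
#'   (`n00*n11 / (n10*n01)`, `NA` on zero denominator), `bin_width`,
#'   `set_a`, `set_b`, `genome`.
#' @export
colocalization_test <- function(set_a, set_b, width = NULL,
                                restrict_to_peak_chroms = FALSE) {
  stopifnot(inherits(set_a, "peak_set"), inherits(set_b, "peak_set"))
  .check_same_genome(set_a, set_b)
  if (n_peaks(set_a) == 0L || n_peaks(set_b) == 0L) {
    stop("colocalization test requires two non-empty peak sets")
  }
  if (is.null(width)) width <- mean_peak_length(set_a, set_b)
  genome <- set_a$genome
  if (restrict_to_peak_chroms) {
    used <- union(set_a$peaks$chrom, set_b$peaks$chrom)
    genome <- genome_info(genome$chrom_sizes[used], genome$assembly)
    set_a <- peak_set(set_a$peaks$chrom, set_a$peaks$start, set_a$peaks$end,
                      genome, set_a$name, id = set_a$peaks$id)
    set_b <- peak_set(set_b$peaks$chrom, set_b$peaks$start, set_b$peaks$end,
                      genome, set_b$name, id = set_b$peaks$id)
  }
  grid <- tile_genome(genome, width)
  tab <- bin_occupancy_table(grid, set_a, set_b)
  denom <- tab$n10 * tab$n01
  structure(
    list(table = tab,
         p_value = fisher_exact_one_sided(tab),
         odds_ratio = if (denom > 0) (tab$n00 * tab$n11) / denom else NA_real_,
         bin_width = width,
         set_a = set_a$name, set_b = set_b$name,
         genome = genome$assembly),
    class = "overlap_test_result"
  )
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat(sprintf("<overlap_test_result> %s vs %s (%s), bin width %d bp\n",
              x$set_a, x$set_b, x$genome, x$bin_width))
  print(x$table)
  cat(sprintf("odds ratio %.3g, one-sided Fisher p = %.3g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Serialize an overlap test result
#'
#' @param x An `overlap_test_result`.
#' @param path Output path; format from extension (`.json` or `.tsv`).
#' @export
write_overlap_result <- function(x, path) {
  stopifnot(inherits(x, "overlap_test_result"))
  rec <- list(set_a = x$set_a, set_b = x$set_b, genome = x$genome,
              bin_width = x$bin_width,
              n00 = x$table$n00, n10 = x$table$n10,
              n01 = x$table$n01, n11 = x$table$n11,
              odds_ratio = x$odds_ratio, p_value = x$p_value)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    write.table(as.data.frame(rec), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Fraction of one peak set overlapping another
#'
#' The fraction of A-peaks sharing at least one base with at least one
#' B-peak.
#'
#' @param set_a Non-empty [peak_set()] (the numerator's denominator set).
#' @param set_b [peak_set()] on the same genome.
#' @return List with `fraction`, `count` (overlapping A-peaks) and `total`.
#' @export
overlap_fraction <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "peak_set"))
  if (n_peaks(set_a) == 0L) stop("set_a is empty: fraction undefined")
  pairs <- find_overlap_pairs(set_a, set_b)
  k <- length(unique(pairs$id_a))
  list(fraction = k / n_peaks(set_a), count = k, total = n_peaks(set_a))
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail p-value for observing at least `|A intersect B|` shared genes
#' when drawing `|B|` genes from a universe containing `|A|` marked genes.
#'
#' @param list_a,list_b Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector, the gene universe.
#' @return List with `p_value`, `overlap`, `n_a`, `n_b`, `n_universe`.
#' @export
gene_overlap_test <- function(list_a, list_b, universe) {
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  universe <- unique(as.character(universe))
  bad_a <- setdiff(list_a, universe)
  bad_b <- setdiff(list_b, universe)
  if (length(bad_a) || length(bad_b)) {
    stop("gene lists must be subsets of the universe; offenders: ",
         paste(head(c(bad_a, bad_b), 10L), collapse = ", "))
  }
  k <- length(intersect(list_a, list_b))
  list(p_value = .hyper_upper_tail(k, length(list_a), length(list_b),
                                   length(universe)),
       overlap = k, n_a = length(list_a), n_b = length(list_b),
       n_universe = length(universe))
}
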