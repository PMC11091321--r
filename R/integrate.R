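#' Read an enhancer annotation table
#'
#' Expected TSV header: `chrom`, `start`, `end`, `enhancer_id`,
#' `target_gene`, `interaction_score` (0-based half-open intervals; one row
#' per enhancer-target pair, so an enhancer targeting several genes spans
#' several rows sharing coordinates and id).
#'
#' @param path TSV path.
#' @param genome Optional [genome_info()] for chromosome validation.
#' @return Data frame of class `enhancer_table`.
#' @export
read_enhancers <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("enhancer file not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "enhancer_id", "target_gene",
            "interaction_score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("enhancer TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  enhancer_table(tab$chrom, as.numeric(tab$start), as.numeric(tab$end),
                 tab$enhancer_id, tab$target_gene,
                 as.numeric(tab$interaction_score), genome = genome)
}

#' @rdname read_enhancers
#' @param chrom,start,end Enhancer intervals (0-based half-open).
#' @param enhancer_id,target_gene,interaction_score Parallel annotation
#'   vectors; `interaction_score` must be non-negative and each
#'   (`enhancer_id`, `target_gene`) pair unique.
#' @export
enhancer_table <- function(chrom, start, end, enhancer_id, target_gene,
                           interaction_score, genome = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  interaction_score <- as.numeric(interaction_score)
  if (any(end <= start)) stop("enhancer intervals must have end > start")
  if (any(!is.finite(interaction_score)) || any(interaction_score < 0)) {
    stop("interaction scores must be non-negative")
  }
  key <- paste(enhancer_id, target_gene, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (enhancer_id, target_gene) pair(s): ",
         paste(head(sub("\r", "/", key[duplicated(key)]), 5L),
               collapse = ", "))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome$chrom_sizes))
    if (length(unknown)) {
      stop("enhancer chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "))
    }
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    enhancer_id = as.character(enhancer_id),
                    target_gene = as.character(target_gene),
                    interaction_score = interaction_score,
                    stringsAsFactors = FALSE)
  class(out) <- c("enhancer_table", "data.frame")
  out
}

#' Write an enhancer TSV
#' @param enhancers An [enhancer_table()].
#' @param path Output path.
#' @export
write_enhancers <- function(enhancers, path) {
  tab <- as.data.frame(enhancers)
  tab$start <- format(tab$start, scientific = FALSE, trim = TRUE)
  tab$end <- format(tab$end, scientific = FALSE, trim = TRUE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression results table
#'
#' Expected TSV header: `gene_id`, `log2FoldChange`, `padj` (extra columns
#' ignored). One row per gene; duplicate gene ids are an error. `padj` must
#' lie in \[0, 1\] (NA allowed, treated as untested downstream).
#'
#' @param path TSV path.
#' @return Data frame of class `de_table` with columns `gene_id`,
#'   `log2_fold_change`, `adjusted_p`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2FoldChange", "padj")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("DE TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  de_table(tab$gene_id, as.numeric(tab$log2FoldChange), as.numeric(tab$padj))
}

#' @rdname read_de_table
#' @param gene_id,log2_fold_change,adjusted_p Parallel vectors (fold change
#'   is secretory vs proliferative in the study design this emulates).
#' @export
de_table <- function(gene_id, log2_fold_change, adjusted_p) {
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in DE table: ",
         paste(head(unique(gene_id[duplicated(gene_id)]), 5L),
               collapse = ", "))
  }
  adjusted_p <- as.numeric(adjusted_p)
  ok <- is.na(adjusted_p) | (adjusted_p >= 0 & adjusted_p <= 1)
  if (!all(ok)) stop("adjusted_p outside [0, 1]")
  out <- data.frame(gene_id = as.character(gene_id),
                    log2_fold_change = as.numeric(log2_fold_change),
                    adjusted_p = adjusted_p, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write a DE TSV
#' @param de A [de_table()].
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  tab <- data.frame(gene_id = de$gene_id,
                    log2FoldChange = de$log2_fold_change,
                    padj = de$adjusted_p)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stratify a peak set by a histone-mark region set
#'
#' Splits peaks into those sharing at least one base with any mark region
#' (`in_mark`) and the rest (`out_of_mark`); the two subsets partition the
#' input.
#'
#' @param peaks A [peak_set()].
#' @param mark_regions A [peak_set()] of histone-mark domains on the same
#'   genome.
#' @return List of class `stratified_peaks`: `in_mark`, `out_of_mark`
#'   (peak sets), `mark_name`, `fraction_in`, `n_in`, `n_total`.
#' @export
stratify_by_mark <- function(peaks, mark_regions) {
  stopifnot(inherits(peaks, "peak_set"), inherits(mark_regions, "peak_set"))
  .check_same_genome(peaks, mark_regions)
  hit <- if (n_peaks(mark_regions) == 0L || n_peaks(peaks) == 0L) {
    rep(FALSE, n_peaks(peaks))
  } else {
    IRanges::overlapsAny(.peaks_gr(peaks), .peaks_gr(mark_regions))
  }
  structure(
    list(in_mark = .subset_peaks(peaks, hit),
         out_of_mark = .subset_peaks(peaks, !hit),
         mark_name = mark_regions$name,
         fraction_in = if (n_peaks(peaks) > 0L) mean(hit) else 0,
         n_in = sum(hit), n_total = n_peaks(peaks)),
    class = "stratified_peaks"
  )
}

#' @export
print.stratified_peaks <- function(x, ...) {
  cat(sprintf("<stratified_peaks> %d/%d (%.1f%%) in %s regions\n",
              x$n_in, x$n_total, 100 * x$fraction_in, x$mark_name))
  invisible(x)
}

#' Join distal peaks against an enhancer annotation
#'
#' Splits a (distal-intergenic) peak set into peaks overlapping at least
#' one annotated enhancer interval (`annotated`) and candidate novel
#' enhancer sites (`novel`); collects the distinct target genes of the
#' overlapped enhancers whose interaction score is strictly greater than
#' `min_score`.
#'
#' @param distal_peaks A [peak_set()], typically pre-filtered to the
#'   distal-intergenic category.
#' @param enhancers An [enhancer_table()].
#' @param min_score Strict lower bound on the interaction score for a
#'   target gene to count as regulated (default 10).
#' @return List of class `enhancer_join`: `annotated`, `novel` (peak
#'   sets partitioning the input), `regulated_genes` (character),
#'   `map` (data frame `peak_id`, `enhancer_id`, `target_gene`,
#'   `interaction_score`).
#' @export
enhancer_join <- function(distal_peaks, enhancers, min_score = 10) {
  stopifnot(inherits(distal_peaks, "peak_set"),
            inherits(enhancers, "enhancer_table"))
  egr <- .as_granges(enhancers$chrom, enhancers$start, enhancers$end,
                     distal_peaks$genome)
  hits <- if (nrow(enhancers) && n_peaks(distal_peaks)) {
    findOverlaps(.peaks_gr(distal_peaks), egr)
  } else NULL
  map <- if (!is.null(hits) && length(hits)) {
    data.frame(peak_id = distal_peaks$peaks$id[queryHits(hits)],
               enhancer_id = enhancers$enhancer_id[subjectHits(hits)],
               target_gene = enhancers$target_gene[subjectHits(hits)],
               interaction_score = enhancers$interaction_score[subjectHits(hits)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(peak_id = character(0), enhancer_id = character(0),
               target_gene = character(0), interaction_score = numeric(0),
               stringsAsFactors = FALSE)
  }
  annotated_ids <- unique(map$peak_id)
  is_annot <- distal_peaks$peaks$id %in% annotated_ids
  structure(
    list(annotated = .subset_peaks(distal_peaks, is_annot),
         novel = .subset_peaks(distal_peaks, !is_annot),
         regulated_genes =
           sort(unique(map$target_gene[map$interaction_score > min_score])),
         map = map, min_score = min_score),
    class = "enhancer_join"
  )
}

#' @export
print.enhancer_join <- function(x, ...) {
  cat(sprintf(paste0("<enhancer_join> %d annotated, %d novel peak(s); ",
                     "%d regulated gene(s) at score > %g\n"),
              n_peaks(x$annotated), n_peaks(x$novel),
              length(x$regulated_genes), x$min_score))
  invisible(x)
}

#' Classify peak-target genes by differential expression
#'
#' Over the distinct genes of a peak-to-gene multimap, classifies each gene
#' as `up` (adjusted p strictly below `fdr` and positive log2 fold change),
#' `down` (below `fdr`, negative fold change), `ns` (tested, not
#' significant — including a fold change of exactly zero or an `NA`
#' adjusted p), or `untested` (absent from the DE table). Classification is
#' per distinct gene, not per peak.
#'
#' @param peak_gene_map Data frame with columns `peak_id`, `gene_id` (e.g.
#'   from [peaks_in_promoters()] or [genes_near_peaks()]).
#' @param de A [de_table()].
#' @param fdr Strict significance threshold in (0, 1), default 0.05.
#' @return List of class `deg_join`: `classes` (data frame `gene_id`,
#'   `class`), `counts` (named vector over up/down/ns/untested),
#'   `fdr`.
#' @export
deg_join <- function(peak_gene_map, de, fdr = 0.05) {
  stopifnot(inherits(de, "de_table"))
  if (!all(c("peak_id", "gene_id") %in% names(peak_gene_map))) {
    stop("peak_gene_map needs columns peak_id and gene_id")
  }
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  genes <- sort(unique(peak_gene_map$gene_id))
  ix <- match(genes, de$gene_id)
  padj <- de$adjusted_p[ix]
  lfc <- de$log2_fold_change[ix]
  cls <- ifelse(is.na(ix), "untested",
         ifelse(!is.na(padj) & padj < fdr & lfc > 0, "up",
         ifelse(!is.na(padj) & padj < fdr & lfc < 0, "down", "ns")))
  classes <- data.frame(gene_id = genes,
                        class = factor(cls, levels = c("up", "down", "ns",
                                                       "untested")),
                        stringsAsFactors = FALSE)
  structure(list(classes = classes, counts = table(classes$class), fdr = fdr),
            class = "deg_join")
}

#' @export
print.deg_join <- function(x, ...) {
  cat(sprintf("<deg_join> FDR < %g: %d up, %d down, %d ns, %d untested\n",
              x$fdr, x$counts[["up"]], x$counts[["down"]], x$counts[["ns"]],
              x$counts[["untested"]]))
  invisible(x)
}
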