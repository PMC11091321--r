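#' Construct a gene-model table
#'
#' Gene models drive all peak annotation: the strand-aware TSS, the gene
#' body span and the exon structure. Coordinates are 0-based half-open;
#' exons are supplied in genomic (ascending) order and are re-read 5'->3'
#' internally for minus-strand genes. The TSS is `start` for `+` genes and
#' `end - 1` for `-` genes.
#'
#' @param gene_id,chrom,strand,start,end Parallel vectors; `strand` is `"+"`
#'   or `"-"`.
#' @param exon_starts,exon_ends Comma-separated coordinate lists per gene
#'   (ascending genomic order, within the gene span, non-overlapping).
#' @param gene_name,biotype Optional annotation columns (biotype e.g.
#'   `"mRNA"`, `"lncRNA"`, `"miRNA"`).
#' @param genome Optional [genome_info()] for chromosome validation.
#' @return Data frame of class `gene_models` with a computed `tss` column.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        exon_starts, exon_ends,
                        gene_name = NULL, biotype = NULL, genome = NULL) {
  n <- length(gene_id)
  strand <- as.character(strand)
  if (any(!strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'; offending gene(s): ",
         paste(head(gene_id[!strand %in% c("+", "-")], 5L), collapse = ", "))
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(end <= start)) stop("gene span must have end > start")
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome$chrom_sizes))
    if (length(unknown)) {
      stop("gene chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "))
    }
  }
  es <- .parse_coord_list(exon_starts)
  ee <- .parse_coord_list(exon_ends)
  for (i in seq_len(n)) {
    if (length(es[[i]]) != length(ee[[i]]) || length(es[[i]]) == 0L) {
      stop("exon_starts/exon_ends mismatch for gene ", gene_id[i])
    }
    if (any(es[[i]] < start[i]) || any(ee[[i]] > end[i]) ||
        any(ee[[i]] <= es[[i]])) {
      stop("exons outside span or empty for gene ", gene_id[i])
    }
    if (is.unsorted(es[[i]], strictly = TRUE) ||
        any(es[[i]][-1] < ee[[i]][-length(ee[[i]])])) {
      stop("exons must be ascending and non-overlapping for gene ", gene_id[i])
    }
  }
  out <- data.frame(
    gene_id = as.character(gene_id),
    gene_name = if (is.null(gene_name)) as.character(gene_id)
                else as.character(gene_name),
    chrom = as.character(chrom), strand = strand,
    start = start, end = end,
    exon_starts = vapply(es, paste, "", collapse = ","),
    exon_ends = vapply(ee, paste, "", collapse = ","),
    biotype = if (is.null(biotype)) rep("mRNA", n) else as.character(biotype),
    stringsAsFactors = FALSE
  )
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1)
  class(out) <- c("gene_models", "data.frame")
  out
}

.parse_coord_list <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE),
         function(v) as.numeric(v[nzchar(v)]))
}

#' Read a gene-model TSV
#'
#' Expected header: `gene_id`, `gene_name`, `chrom`, `strand`, `start`,
#' `end`, `exon_starts`, `exon_ends`, `biotype` (0-based half-open
#' coordinates, comma-separated exon lists).
#'
#' @param path TSV path.
#' @param genome Optional [genome_info()] for validation.
#' @return A [gene_models()] table.
#' @export
read_gene_models <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("gene-model file not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("gene_id", "chrom", "strand", "start", "end",
            "exon_starts", "exon_ends")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene-model TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  gene_models(tab$gene_id, tab$chrom, tab$strand,
              as.numeric(tab$start), as.numeric(tab$end),
              tab$exon_starts, tab$exon_ends,
              gene_name = tab$gene_name, biotype = tab$biotype,
              genome = genome)
}

#' Write a gene-model TSV
#' @param genes A [gene_models()] table.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  cols <- c("gene_id", "gene_name", "chrom", "strand", "start", "end",
            "exon_starts", "exon_ends", "biotype")
  tab <- as.data.frame(genes)[, cols]
  tab$start <- format(tab$start, scientific = FALSE, trim = TRUE)
  tab$end <- format(tab$end, scientific = FALSE, trim = TRUE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Groups `exon` features by `gene_id` (via rtracklayer), derives the gene
#' span as the exon envelope and converts GTF 1-based closed coordinates to
#' the package's 0-based half-open convention.
#'
#' @param path GTF path.
#' @param genome Optional [genome_info()] for validation.
#' @return A [gene_models()] table.
#' @export
read_gtf_gene_models <- function(path, genome = NULL) {
  gtf <- rtracklayer::import(path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features")
  ids <- as.character(ex$gene_id)
  sp <- split(seq_along(ex), ids)
  rows <- lapply(sp, function(ix) {
    e <- ex[ix]
    e <- e[order(start(e))]
    # collapse overlapping transcript exons into a flattened exon chain
    red <- reduce(e, min.gapwidth = 0L)
    nm <- if (!is.null(e$gene_name)) as.character(e$gene_name)[1] else NA
    bt <- if (!is.null(e$gene_biotype)) as.character(e$gene_biotype)[1] else NA
    list(chrom = as.character(seqnames(e))[1],
         strand = as.character(strand(e))[1],
         start = min(start(e)) - 1, end = max(end(e)),
         exon_starts = paste(start(red) - 1, collapse = ","),
         exon_ends = paste(end(red), collapse = ","),
         gene_name = nm, biotype = bt)
  })
  gene_models(
    gene_id = names(sp),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    exon_starts = vapply(rows, `[[`, "", "exon_starts"),
    exon_ends = vapply(rows, `[[`, "", "exon_ends"),
    gene_name = vapply(rows, function(r) as.character(r$gene_name), ""),
    biotype = vapply(rows, function(r) as.character(r$biotype), ""),
    genome = genome
  )
}

#' Promoter windows around gene TSSs
#'
#' A fixed strand-aware window around each TSS: for a `+` gene
#' `[tss - upstream, tss + downstream)`, for a `-` gene the mirror image
#' `[tss - downstream + 1, tss + upstream + 1)`, clipped to chromosome
#' bounds. Defaults (4 kb upstream, 1 kb downstream) are the promoter
#' definition used for promoter-peak sets and all downstream joins.
#'
#' @param genes A [gene_models()] table.
#' @param upstream,downstream Window extents in bp (non-negative, not both
#'   zero).
#' @param genome Optional [genome_info()]; when given, windows are clipped
#'   to chromosome lengths.
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
promoter_windows <- function(genes, upstream = 4000, downstream = 1000,
                             genome = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  if (upstream < 0 || downstream < 0) stop("window extents must be >= 0")
  if (upstream == 0 && downstream == 0) stop("window cannot be empty")
  plus <- genes$strand == "+"
  s <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  e <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  s <- pmax(s, 0)
  if (!is.null(genome)) e <- pmin(e, genome$chrom_sizes[genes$chrom])
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.numeric(s), end = as.numeric(e),
             stringsAsFactors = FALSE)
}

#' Peaks overlapping gene promoter windows
#'
#' A peak is a promoter peak iff it shares at least one base with at least
#' one promoter window. A promoter may contain several peaks and a peak may
#' hit several promoters; the full multimap is returned alongside the
#' promoter peak subset.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_models()] table.
#' @param upstream,downstream Promoter window extents (bp).
#' @return List with `promoter_peaks` (a [peak_set()] subset),
#'   `nonpromoter_peaks` (the complement) and `map` (data frame `peak_id`,
#'   `gene_id`, one row per peak-window overlap).
#' @export
peaks_in_promoters <- function(peaks, genes, upstream = 4000,
                               downstream = 1000) {
  stopifnot(inherits(peaks, "peak_set"))
  win <- promoter_windows(genes, upstream, downstream, genome = peaks$genome)
  wgr <- .as_granges(win$chrom, win$start, win$end, peaks$genome)
  hits <- findOverlaps(.peaks_gr(peaks), wgr)
  map <- data.frame(peak_id = peaks$peaks$id[queryHits(hits)],
                    gene_id = win$gene_id[subjectHits(hits)],
                    stringsAsFactors = FALSE)
  map <- unique(map)
  rownames(map) <- NULL
  in_prom <- peaks$peaks$id %in% map$peak_id
  list(promoter_peaks = .subset_peaks(peaks, in_prom),
       nonpromoter_peaks = .subset_peaks(peaks, !in_prom),
       map = map)
}

# category precedence, highest first
.feature_categories <- c("promoter_0_1kb", "promoter_1_2kb", "promoter_2_3kb",
                         "five_utr", "three_utr", "exon_1", "other_exon",
                         "intron_1", "other_intron", "downstream",
                         "distal_intergenic")

#' Assign each peak a genomic feature category
#'
#' Each peak receives exactly one category, the highest-precedence one it
#' qualifies for across all genes. Precedence (highest first): promoter
#' distance bands (0-1, 1-2, 2-3 kb), 5'/3' UTR (only when the annotation
#' supplies UTRs; never inferred), exon 1, other exons, intron 1, other
#' introns, downstream (within `downstream_bp` past the gene 3' end), then
#' distal intergenic (no associated gene). Promoter banding uses the peak
#' midpoint's strand-aware upstream distance to the TSS; all other
#' categories use >= 1 bp overlap between the peak interval and the feature
#' interval. Exon/intron ordinals follow the gene's 5'->3' order. Ties
#' between genes at equal precedence go to the gene with the nearest TSS,
#' then to the lexicographically smallest `gene_id`.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_models()] table.
#' @param promoter_bands Upstream band edges in bp (default 1, 2, 3 kb).
#' @param downstream_bp Extent of the downstream category past the 3' end.
#' @return Data frame of class `feature_assignments`: `peak_id`, `category`
#'   (factor over all categories), `gene_id` (`NA` iff distal intergenic).
#' @export
assign_feature <- function(peaks, genes, promoter_bands = c(1000, 2000, 3000),
                           downstream_bp = 3000) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_models"))
  p <- peaks$peaks
  np <- nrow(p)
  mid <- floor((p$start + p$end) / 2)
  cand <- list()

  # promoter bands: strand-aware upstream distance of the midpoint to a TSS
  if (nrow(genes) > 0L && np > 0L) {
    bands <- sort(promoter_bands)
    gmax <- max(bands)
    # pair peaks with genes on the same chromosome whose TSS is within gmax
    for (ci in unique(p$chrom)) {
      pi <- which(p$chrom == ci)
      gi <- which(genes$chrom == ci)
      if (!length(gi)) next
      dm <- outer(mid[pi], genes$tss[gi], function(m, t) m - t)
      up <- sweep(dm, 2, ifelse(genes$strand[gi] == "+", -1, 1), `*`)
      sel <- which(up >= 0 & up <= gmax, arr.ind = TRUE)
      if (nrow(sel)) {
        d <- up[sel]
        band <- findInterval(d, c(0, bands), rightmost.closed = FALSE,
                             left.open = TRUE)
        band[d == 0] <- 1L
        cand[[length(cand) + 1L]] <- data.frame(
          peak = pi[sel[, 1]],
          gene = gi[sel[, 2]],
          category = .feature_categories[band],
          tssdist = abs(dm[sel]),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  # overlap-based gene-body / downstream candidates
  feat <- .gene_feature_intervals(genes, downstream_bp)
  if (nrow(feat) > 0L && np > 0L) {
    fgr <- .as_granges(feat$chrom, pmax(feat$start, 0), feat$end,
                       peaks$genome)
    hits <- findOverlaps(.peaks_gr(peaks), fgr)
    if (length(hits)) {
      qi <- queryHits(hits)
      fi <- subjectHits(hits)
      cand[[length(cand) + 1L]] <- data.frame(
        peak = qi, gene = feat$gene_row[fi], category = feat$category[fi],
        tssdist = abs(mid[qi] - genes$tss[feat$gene_row[fi]]),
        stringsAsFactors = FALSE
      )
    }
  }

  category <- rep("distal_intergenic", np)
  gene_id <- rep(NA_character_, np)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand$rank <- match(cand$category, .feature_categories)
    cand$gid <- genes$gene_id[cand$gene]
    ord <- order(cand$peak, cand$rank, cand$tssdist, cand$gid)
    cand <- cand[ord, ]
    best <- cand[!duplicated(cand$peak), ]
    category[best$peak] <- best$category
    gene_id[best$peak] <- best$gid
  }
  out <- data.frame(
    peak_id = p$id,
    category = factor(category, levels = .feature_categories),
    gene_id = gene_id,
    stringsAsFactors = FALSE
  )
  class(out) <- c("feature_assignments", "data.frame")
  out
}

# exon_k / intron_k / downstream intervals per gene, 5'->3' ordinals
.gene_feature_intervals <- function(genes, downstream_bp) {
  if (nrow(genes) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), category = character(0),
                      gene_row = integer(0), stringsAsFactors = FALSE))
  }
  es <- .parse_coord_list(genes$exon_starts)
  ee <- .parse_coord_list(genes$exon_ends)
  rows <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    s <- es[[g]]; e <- ee[[g]]
    k <- length(s)
    ord <- if (genes$strand[g] == "+") seq_len(k) else rev(seq_len(k))
    exon_cat <- ifelse(ord == 1L, "exon_1", "other_exon")
    ist <- e[-k]; ien <- s[-1]            # introns in genomic order
    ikeep <- which(ien > ist)
    iord <- if (genes$strand[g] == "+") seq_len(k - 1) else rev(seq_len(k - 1))
    intron_cat <- ifelse(iord == 1L, "intron_1", "other_intron")
    if (genes$strand[g] == "+") {
      ds <- c(genes$end[g], genes$end[g] + downstream_bp)
    } else {
      ds <- c(genes$start[g] - downstream_bp, genes$start[g])
    }
    rows[[g]] <- data.frame(
      chrom = genes$chrom[g],
      start = c(s, ist[ikeep], ds[1]),
      end = c(e, ien[ikeep], ds[2]),
      category = c(exon_cat, intron_cat[ikeep], "downstream"),
      gene_row = g, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out[out$end > pmax(out$start, 0), , drop = FALSE]
}

#' Percentage of peaks per feature category
#'
#' @param assignments A [assign_feature()] result (non-empty).
#' @return Named numeric vector over all categories, summing to 100.
#' @export
feature_distribution <- function(assignments) {
  stopifnot(inherits(assignments, "feature_assignments"))
  if (nrow(assignments) == 0L) stop("no assignments: distribution undefined")
  100 * table(assignments$category) / nrow(assignments)
}

#' Genes within a maximum distance of each peak
#'
#' Associates a gene with a peak when the gap between the peak interval and
#' the gene body span is at most `max_dist` bp (gap 0 when they overlap or
#' abut).
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_models()] table.
#' @param max_dist Maximum gap in bp (default 5000).
#' @return Data frame multimap `peak_id`, `gene_id`.
#' @export
genes_near_peaks <- function(peaks, genes, max_dist = 5000) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_models"))
  if (max_dist < 0) stop("max_dist must be >= 0")
  ggr <- .as_granges(genes$chrom, genes$start, genes$end, peaks$genome)
  hits <- findOverlaps(.peaks_gr(peaks), ggr, maxgap = max_dist)
  out <- unique(data.frame(peak_id = peaks$peaks$id[queryHits(hits)],
                           gene_id = genes$gene_id[subjectHits(hits)],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Peak occupancy profile around gene TSSs
#'
#' Tiles the window `[-flank, +flank)` around every TSS into `step`-bp
#' offset bins, oriented 5'->3' (upstream offsets are negative for both
#' strands), and reports for each offset bin the fraction of TSSs whose bin
#' is covered by at least one peak.
#'
#' @param peaks A [peak_set()].
#' @param genes A [gene_models()] table.
#' @param flank Half-window in bp (> 0, divisible by `step`).
#' @param step Offset bin width in bp.
#' @return Data frame with `offset` (bin lower edge, bp relative to TSS),
#'   `count` (TSSs covered) and `fraction`; `2 * flank / step` rows.
#' @export
tss_profile <- function(peaks, genes, flank = 3000, step = 50) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_models"))
  if (flank <= 0 || step < 1 || flank %% step != 0) {
    stop("flank must be positive and divisible by step")
  }
  offs <- seq(-flank, flank - step, by = step)
  nb <- length(offs)
  ng <- nrow(genes)
  counts <- integer(nb)
  if (ng > 0L && n_peaks(peaks) > 0L) {
    # genomic interval of offset bin [lo, lo+step) at each TSS
    lo <- rep(offs, each = ng)
    tss <- rep(genes$tss, nb)
    plus <- rep(genes$strand == "+", nb)
    gstart <- ifelse(plus, tss + lo, tss - (lo + step) + 1)
    gend <- gstart + step
    keep <- gstart >= 0
    bgr <- GRanges(rep(genes$chrom, nb)[keep],
                   IRanges(start = gstart[keep] + 1, end = gend[keep]))
    pgr <- .peaks_gr(peaks)
    GenomeInfoDb::seqlevels(bgr) <- GenomeInfoDb::seqlevels(pgr)
    cov <- IRanges::overlapsAny(bgr, pgr)
    covered <- logical(nb * ng)
    covered[keep] <- cov
    counts <- vapply(seq_len(nb), function(j) {
      sum(covered[((j - 1) * ng + 1):(j * ng)])
    }, 0L)
  }
  data.frame(offset = offs, count = counts,
             fraction = if (ng > 0L) counts / ng else rep(0, nb))
}
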