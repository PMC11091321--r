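# Synthetic data generators. Every generator takes an explicit seed, runs in
# a locally scoped RNG (withr::with_seed) and records enough ground truth for
# exact recovery tests downstream. Defaults emulate the statistical regime of
# a two-factor co-occupancy study: ~7% cross-set peak overlap, 654 bp mean
# peak length, a third of peaks targeted at promoters, promoter-mark coverage
# ~78%, distal-mark coverage ~16%, and ~11%/16% of peak-target genes up/down
# regulated.

#' Simulate a genome with non-overlapping gene models
#'
#' Chromosomes of equal length; genes are spread evenly across chromosomes
#' and placed uniformly with at least 10 kb spacing, random strand, and 2-8
#' exons each. Deterministic given the seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Total gene count; an error is raised when the requested
#'   density cannot honour the 10 kb spacing.
#' @param seed Integer seed.
#' @param gene_length_range Span lengths drawn uniformly from this range.
#' @return List with `genome` (a [genome_info()]) and `genes`
#'   (a [gene_models()] table).
#' @export
simulate_genome <- function(n_chrom = 1, chrom_length = 1e7, n_genes = 200,
                            seed = 1, gene_length_range = c(2000, 20000)) {
  stopifnot(n_chrom >= 1, chrom_length > 0, n_genes >= 1)
  spacing <- 10000
  genome <- genome_info(
    setNames(rep(chrom_length, n_chrom), paste0("chr", seq_len(n_chrom))),
    assembly = "synthetic"
  )
  per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1)))
  if (any(per_chrom * (max(gene_length_range) + spacing) + spacing >
          chrom_length)) {
    stop("gene density infeasible: cannot place ", n_genes, " genes with ",
         spacing, " bp spacing; enlarge the genome or reduce n_genes")
  }
  withr::with_seed(seed, {
    rows <- list()
    gid <- 0L
    for (ci in seq_len(n_chrom)) {
      nc <- per_chrom[ci]
      if (nc == 0L) next
      len <- round(runif(nc, gene_length_range[1], gene_length_range[2]))
      free <- chrom_length - sum(len) - spacing * (nc + 1)
      if (free < 0) {
        stop("gene density infeasible on chr", ci,
             ": reduce n_genes or gene lengths")
      }
      # split the slack uniformly over the nc + 1 inter-gene gaps
      cuts <- sort(runif(nc, 0, free))
      gaps <- diff(c(0, cuts, free)) + spacing
      starts <- floor(cumsum(gaps)[seq_len(nc)] + cumsum(c(0, len[-nc])))
      for (g in seq_len(nc)) {
        gid <- gid + 1L
        n_ex <- sample(2:8, 1L)
        # partition the span into alternating exons/introns
        inner <- sort(sample(seq(200, len[g] - 200, by = 50),
                             2L * n_ex - 2L, replace = FALSE))
        bounds <- c(0, inner, len[g])
        ex_s <- starts[g] + bounds[seq(1, length(bounds) - 1, by = 2)]
        ex_e <- starts[g] + bounds[seq(2, length(bounds), by = 2)]
        rows[[gid]] <- data.frame(
          gene_id = sprintf("G%04d", gid),
          chrom = paste0("chr", ci),
          strand = sample(c("+", "-"), 1L),
          start = starts[g], end = starts[g] + len[g],
          exon_starts = paste(ex_s, collapse = ","),
          exon_ends = paste(ex_e, collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
    tab <- do.call(rbind, rows)
    biotype <- sample(c("mRNA", "lncRNA", "miRNA"), nrow(tab),
                      replace = TRUE, prob = c(0.8, 0.15, 0.05))
    genes <- gene_models(tab$gene_id, tab$chrom, tab$strand, tab$start,
                         tab$end, tab$exon_starts, tab$exon_ends,
                         biotype = biotype, genome = genome)
    list(genome = genome, genes = genes)
  })
}

# TRUE for each candidate interval overlapping >= 1 interval of a reference
# set (per-chromosome sorted starts + running max of ends)
.overlaps_reference <- function(chrom, start, end, ref) {
  idx <- split(seq_along(ref$chrom), ref$chrom)
  pre <- lapply(idx, function(i) {
    o <- order(ref$start[i])
    s <- ref$start[i][o]
    list(starts = s, maxend = cummax(ref$end[i][o]))
  })
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    p <- pre[[ch]]
    ci <- which(chrom == ch)
    if (is.null(p)) next
    j <- findInterval(end[ci] - 1, p$starts)   # refs with start < end
    hit <- j > 0
    hit[hit] <- p$maxend[j[hit]] > start[ci][hit]
    out[ci] <- hit
  }
  out
}

#' Simulate two co-bound ChIP-seq peak sets with planted overlap
#'
#' Set A peaks are placed with a controlled promoter bias (a fraction of
#' midpoints drawn inside 4 kb/1 kb promoter windows, the rest uniform on
#' the genome). Exactly `round(rho * n_b)` set-B peaks are planted to
#' overlap a randomly chosen A peak by at least one base; the remaining B
#' peaks are rejection-sampled to avoid every A peak, so the fraction of B
#' peaks overlapping A equals `round(rho * n_b) / n_b` exactly by
#' construction. Peak lengths are truncated-normal with a 50 bp floor.
#'
#' @param genome A [genome_info()].
#' @param genes A [gene_models()] table (for promoter placement bias).
#' @param n_a,n_b Peak counts for the two sets.
#' @param rho Intended fraction of B peaks overlapping A, in \[0, 1\].
#' @param peak_length_mean,peak_length_sd Peak length distribution (bp).
#' @param promoter_bias Fraction of A peaks targeted at promoter windows.
#' @param seed Integer seed.
#' @param set_names Labels for the two sets.
#' @param max_tries Rejection-sampling cap per non-overlapping B peak.
#' @return List with `set_a`, `set_b` ([peak_set()]s) and `truth` (the
#'   parameters plus `n_planted_overlap` and the per-B-peak
#'   `planted_overlap` ledger).
#' @export
simulate_cobound_peaks <- function(genome, genes, n_a = 1000, n_b = 1000,
                                   rho = 0.07, peak_length_mean = 654,
                                   peak_length_sd = 250, promoter_bias = 0.34,
                                   seed = 1,
                                   set_names = c("WT1_like", "AR_like"),
                                   max_tries = 200) {
  stopifnot(inherits(genome, "genome_info"), inherits(genes, "gene_models"),
            rho >= 0, rho <= 1, promoter_bias >= 0, promoter_bias <= 1,
            n_a >= 1, n_b >= 1)
  chroms <- names(genome$chrom_sizes)
  sizes <- genome$chrom_sizes
  rlen <- function(n) pmax(50, round(rnorm(n, peak_length_mean,
                                           peak_length_sd)))
  withr::with_seed(seed, {
    # --- set A ---
    len_a <- rlen(n_a)
    n_prom <- round(promoter_bias * n_a)
    win <- promoter_windows(genes, 4000, 1000, genome = genome)
    mid <- numeric(n_a)
    chr_a <- character(n_a)
    if (n_prom > 0 && nrow(win) > 0) {
      wi <- sample(nrow(win), n_prom, replace = TRUE)
      mid[seq_len(n_prom)] <- floor(runif(n_prom, win$start[wi],
                                          win$end[wi]))
      chr_a[seq_len(n_prom)] <- win$chrom[wi]
    } else n_prom <- 0L
    rest <- setdiff(seq_len(n_a), seq_len(n_prom))
    if (length(rest)) {
      ci <- sample(length(chroms), length(rest), replace = TRUE,
                   prob = sizes / sum(sizes))
      chr_a[rest] <- chroms[ci]
      mid[rest] <- floor(runif(length(rest), 0, sizes[ci]))
    }
    start_a <- pmax(0, pmin(mid - floor(len_a / 2),
                            sizes[chr_a] - len_a))
    a <- data.frame(chrom = chr_a, start = start_a, end = start_a + len_a)

    # --- set B: planted overlaps first ---
    n_ov <- round(rho * n_b)
    len_b <- rlen(n_b)
    chr_b <- character(n_b)
    start_b <- numeric(n_b)
    if (n_ov > 0) {
      ai <- sample(n_a, n_ov, replace = TRUE)
      ov <- floor(runif(n_ov, 1, pmin(len_a[ai], len_b[seq_len(n_ov)]) + 1))
      s <- a$end[ai] - ov
      s <- pmax(0, pmin(s, sizes[a$chrom[ai]] - len_b[seq_len(n_ov)]))
      # clamping near chromosome ends can break the planted overlap; fall
      # back to anchoring at the A start, which always intersects
      e <- s + len_b[seq_len(n_ov)]
      broken <- !(s < a$end[ai] & a$start[ai] < e)
      if (any(broken)) {
        s[broken] <- pmax(0, pmin(a$start[ai][broken],
                                  sizes[a$chrom[ai]][broken] -
                                    len_b[seq_len(n_ov)][broken]))
      }
      chr_b[seq_len(n_ov)] <- a$chrom[ai]
      start_b[seq_len(n_ov)] <- s
    }
    # --- set B: rejection-sampled non-overlappers ---
    rest <- setdiff(seq_len(n_b), seq_len(n_ov))
    todo <- rest
    tries <- 0L
    while (length(todo)) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("rejection sampling exhausted after ", max_tries,
             " rounds; peak density too high for rho = ", rho)
      }
      ci <- sample(length(chroms), length(todo), replace = TRUE,
                   prob = sizes / sum(sizes))
      cand_chr <- chroms[ci]
      cand_s <- floor(runif(length(todo), 0, sizes[ci] - len_b[todo]))
      bad <- .overlaps_reference(cand_chr, cand_s, cand_s + len_b[todo], a)
      ok <- which(!bad)
      chr_b[todo[ok]] <- cand_chr[ok]
      start_b[todo[ok]] <- cand_s[ok]
      todo <- todo[bad]
    }
    set_a <- peak_set(a$chrom, a$start, a$end, genome, name = set_names[1])
    set_b <- peak_set(chr_b, start_b, start_b + len_b, genome,
                      name = set_names[2])
    # ids were assigned in sorted order; recover planted status by position
    ord_b <- order(match(chr_b, chroms), start_b, start_b + len_b)
    planted <- logical(n_b)
    planted[seq_len(n_ov)] <- TRUE
    truth <- list(rho = rho, n_a = n_a, n_b = n_b,
                  n_planted_overlap = n_ov,
                  peak_length_mean = peak_length_mean,
                  peak_length_sd = peak_length_sd,
                  promoter_bias = promoter_bias, seed = seed,
                  planted_overlap = setNames(planted[ord_b],
                                             set_b$peaks$id))
    list(set_a = set_a, set_b = set_b, truth = truth)
  })
}

#' Simulate promoter- and enhancer-type histone-mark domain sets
#'
#' Promoter-mark (H3K4me3-like) domains blanket a `mark_promoter_cov`
#' fraction of the gene promoter windows (each selected window is covered
#' end to end, so any peak overlapping a selected window overlaps the
#' mark). Distal-mark (H3K27ac-like) domains of 500-5000 bp are placed in
#' intergenic space (outside gene bodies and promoter windows) until they
#' cover a `mark_distal_cov` fraction of it.
#'
#' @param genome A [genome_info()].
#' @param genes A [gene_models()] table.
#' @param mark_promoter_cov,mark_distal_cov Coverage fractions in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `promoter_marks`, `distal_marks` ([peak_set()]s,
#'   named `H3K4me3_like` / `H3K27ac_like`) and `truth` (parameters plus
#'   the ids of the marked promoter windows' genes).
#' @export
simulate_marks <- function(genome, genes, mark_promoter_cov = 0.776,
                           mark_distal_cov = 0.161, seed = 1) {
  stopifnot(mark_promoter_cov >= 0, mark_promoter_cov <= 1,
            mark_distal_cov >= 0, mark_distal_cov <= 0.8)
  win <- promoter_windows(genes, 4000, 1000, genome = genome)
  withr::with_seed(seed, {
    n_sel <- round(mark_promoter_cov * nrow(win))
    sel <- if (n_sel > 0) sort(sample(nrow(win), n_sel)) else integer(0)
    prom <- peak_set(win$chrom[sel], win$start[sel], win$end[sel], genome,
                     name = "H3K4me3_like")

    # intergenic space: complement of gene spans and promoter windows
    occ_gr <- reduce(c(
      .as_granges(genes$chrom, genes$start, genes$end, genome),
      .as_granges(win$chrom, win$start, win$end, genome)
    ))
    gaps_gr <- GenomicRanges::gaps(occ_gr)
    gaps_gr <- gaps_gr[strand(gaps_gr) == "*"]
    seg <- data.frame(chrom = as.character(seqnames(gaps_gr)),
                      start = start(gaps_gr) - 1, end = end(gaps_gr))
    seg <- seg[seg$end - seg$start >= 500, , drop = FALSE]
    total <- sum(seg$end - seg$start)
    target <- mark_distal_cov * total
    placed <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
    covered <- 0
    tries <- 0L
    while (covered < target && tries < 50000L) {
      tries <- tries + 1L
      si <- sample(nrow(seg), 1L, prob = seg$end - seg$start)
      dlen <- round(runif(1, 500, 5000))
      dlen <- min(dlen, seg$end[si] - seg$start[si])
      ds <- floor(runif(1, seg$start[si], seg$end[si] - dlen + 1))
      if (nrow(placed) &&
          any(.overlaps_reference(seg$chrom[si], ds, ds + dlen, placed))) {
        next
      }
      placed <- rbind(placed, data.frame(chrom = seg$chrom[si], start = ds,
                                         end = ds + dlen))
      covered <- covered + dlen
    }
    distal <- peak_set(placed$chrom, placed$start, placed$end, genome,
                       name = "H3K27ac_like")
    truth <- list(mark_promoter_cov = mark_promoter_cov,
                  mark_distal_cov = mark_distal_cov, seed = seed,
                  marked_promoter_genes = win$gene_id[sel],
                  realized_distal_cov = covered / total)
    list(promoter_marks = prom, distal_marks = distal, truth = truth)
  })
}

#' Simulate an enhancer annotation table
#'
#' Enhancer intervals of 200-2000 bp: a fraction anchored to overlap given
#' peaks (so the enhancer join has annotated hits), the rest placed
#' uniformly. Each enhancer targets 1-3 random genes with log-normal
#' interaction scores centred near 10, so a strict `> 10` filter retains
#' roughly half the links.
#'
#' @param genome A [genome_info()].
#' @param genes A [gene_models()] table (target-gene pool).
#' @param anchor_peaks Optional [peak_set()] whose peaks a fraction of
#'   enhancers are placed to overlap.
#' @param n_enhancers Number of distinct enhancer intervals.
#' @param frac_on_peaks Fraction anchored on `anchor_peaks`.
#' @param seed Integer seed.
#' @return An [enhancer_table()].
#' @export
simulate_enhancers <- function(genome, genes, anchor_peaks = NULL,
                               n_enhancers = 400, frac_on_peaks = 0.3,
                               seed = 1) {
  chroms <- names(genome$chrom_sizes)
  sizes <- genome$chrom_sizes
  withr::with_seed(seed, {
    len <- round(runif(n_enhancers, 200, 2000))
    chr <- character(n_enhancers)
    s <- numeric(n_enhancers)
    n_anch <- if (is.null(anchor_peaks) || n_peaks(anchor_peaks) == 0L) 0L
              else round(frac_on_peaks * n_enhancers)
    if (n_anch > 0L) {
      pi <- sample(n_peaks(anchor_peaks), n_anch, replace = TRUE)
      pk <- anchor_peaks$peaks[pi, ]
      chr[seq_len(n_anch)] <- pk$chrom
      s[seq_len(n_anch)] <- pmax(0, pmin(pk$end - 1,
                                         sizes[pk$chrom] - len[seq_len(n_anch)]))
    }
    rest <- setdiff(seq_len(n_enhancers), seq_len(n_anch))
    if (length(rest)) {
      ci <- sample(length(chroms), length(rest), replace = TRUE,
                   prob = sizes / sum(sizes))
      chr[rest] <- chroms[ci]
      s[rest] <- floor(runif(length(rest), 0, sizes[ci] - len[rest]))
    }
    n_targets <- sample(1:3, n_enhancers, replace = TRUE)
    rows <- data.frame(
      chrom = rep(chr, n_targets), start = rep(s, n_targets),
      end = rep(s + len, n_targets),
      enhancer_id = rep(sprintf("ENH%04d", seq_len(n_enhancers)), n_targets),
      target_gene = sample(genes$gene_id, sum(n_targets), replace = TRUE),
      interaction_score = round(exp(rnorm(sum(n_targets), log(10), 0.6)), 2),
      stringsAsFactors = FALSE
    )
    key <- paste(rows$enhancer_id, rows$target_gene)
    rows <- rows[!duplicated(key), ]
    enhancer_table(rows$chrom, rows$start, rows$end, rows$enhancer_id,
                   rows$target_gene, rows$interaction_score, genome = genome)
  })
}

#' Simulate a differential-expression table with planted labels
#'
#' Every gene gets a row. Among `target_genes`, fractions `up_frac` and
#' `down_frac` are planted as significantly up-/down-regulated (adjusted p
#' uniform on (0, fdr), |log2 fold change| ~ |N(1.5, 0.5)|); all other
#' genes are non-significant (adjusted p uniform on (fdr, 1), fold change
#' ~ N(0, 0.5)). Planted labels are returned for exact recovery checks.
#'
#' @param genes A [gene_models()] table.
#' @param target_genes Character vector of gene ids the fractions apply to.
#' @param up_frac,down_frac Planted fractions (sum must be <= 1).
#' @param fdr Significance boundary used for the planted p-values.
#' @param seed Integer seed.
#' @return List with `de` (a [de_table()]) and `truth` (planted label per
#'   target gene plus the planted up/down counts).
#' @export
simulate_de <- function(genes, target_genes, up_frac = 0.11,
                        down_frac = 0.16, fdr = 0.05, seed = 1) {
  stopifnot(up_frac >= 0, down_frac >= 0, up_frac + down_frac <= 1)
  target_genes <- unique(as.character(target_genes))
  if (!all(target_genes %in% genes$gene_id)) {
    stop("target_genes must be drawn from the gene models")
  }
  withr::with_seed(seed, {
    nt <- length(target_genes)
    n_up <- round(up_frac * nt)
    n_down <- round(down_frac * nt)
    lab <- rep("ns", nt)
    pick <- sample(nt, n_up + n_down)
    lab[pick[seq_len(n_up)]] <- "up"
    lab[pick[seq_len(n_down) + n_up]] <- "down"
    all_ids <- genes$gene_id
    lfc <- rnorm(length(all_ids), 0, 0.5)
    padj <- runif(length(all_ids), fdr, 1)
    ix <- match(target_genes, all_ids)
    up_i <- ix[lab == "up"]
    down_i <- ix[lab == "down"]
    lfc[up_i] <- abs(rnorm(length(up_i), 1.5, 0.5))
    lfc[down_i] <- -abs(rnorm(length(down_i), 1.5, 0.5))
    padj[c(up_i, down_i)] <- runif(length(up_i) + length(down_i), 0,
                                   fdr * 0.999)
    list(de = de_table(all_ids, lfc, padj),
         truth = list(up_frac = up_frac, down_frac = down_frac,
                      n_targets = nt, n_up = n_up, n_down = n_down,
                      seed = seed,
                      planted_label = setNames(lab, target_genes)))
  })
}

#' Generate a complete synthetic input bundle
#'
#' Composes all generators with sub-seeds derived from one master seed:
#' genome and gene models, two co-bound TF-like peak sets, promoter and
#' distal histone-mark domains, an enhancer table anchored partly on the
#' distal A peaks, and a DE table whose planted fractions apply to the
#' promoter-peak target genes of set A. When `dir` is given, writes every
#' input file the pipeline reads (chrom.sizes, gene TSV, four BED files,
#' enhancer TSV, DE TSV) plus `truth.json` and a ready-to-run
#' `config.yaml`.
#'
#' @param dir Output directory, or `NULL` to skip writing.
#' @param seed Master seed.
#' @param n_chrom,chrom_length,n_genes Genome scale.
#' @param n_a,n_b,rho,peak_length_mean,peak_length_sd,promoter_bias Peak
#'   generation parameters (see [simulate_cobound_peaks()]).
#' @param mark_promoter_cov,mark_distal_cov Mark coverage fractions.
#' @param de_target_up_frac,de_target_down_frac Planted DE fractions.
#' @param n_enhancers Enhancer interval count.
#' @return List with all generated objects, the merged `truth` record and
#'   (when written) `paths`.
#' @export
simulate_bundle <- function(dir = NULL, seed = 1,
                            n_chrom = 1, chrom_length = 1e7, n_genes = 200,
                            n_a = 1000, n_b = 1000, rho = 0.07,
                            peak_length_mean = 654, peak_length_sd = 250,
                            promoter_bias = 0.34,
                            mark_promoter_cov = 0.776,
                            mark_distal_cov = 0.161,
                            de_target_up_frac = 0.11,
                            de_target_down_frac = 0.16,
                            n_enhancers = 400) {
  seed <- as.integer(seed)
  gn <- simulate_genome(n_chrom, chrom_length, n_genes, seed = seed)
  pk <- simulate_cobound_peaks(gn$genome, gn$genes, n_a, n_b, rho,
                               peak_length_mean, peak_length_sd,
                               promoter_bias, seed = seed + 1L)
  mk <- simulate_marks(gn$genome, gn$genes, mark_promoter_cov,
                       mark_distal_cov, seed = seed + 2L)
  distal_a <- assign_feature(pk$set_a, gn$genes)
  distal_set <- .subset_peaks(pk$set_a,
                              distal_a$category == "distal_intergenic")
  enh <- simulate_enhancers(gn$genome, gn$genes, anchor_peaks = distal_set,
                            n_enhancers = n_enhancers, seed = seed + 3L)
  prom <- peaks_in_promoters(pk$set_a, gn$genes)
  de <- simulate_de(gn$genes, unique(prom$map$gene_id),
                    de_target_up_frac, de_target_down_frac,
                    seed = seed + 4L)
  pk$truth$seed <- NULL
  mk$truth$seed <- NULL
  de$truth$seed <- NULL
  truth <- c(pk$truth, mk$truth, de$truth,
             list(master_seed = seed, n_chrom = n_chrom,
                  chrom_length = chrom_length, n_genes = n_genes))
  out <- list(genome = gn$genome, genes = gn$genes,
              set_a = pk$set_a, set_b = pk$set_b,
              promoter_marks = mk$promoter_marks,
              distal_marks = mk$distal_marks,
              enhancers = enh, de = de$de, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.chrom.sizes"),
      genes = file.path(dir, "genes.tsv"),
      peaks_a = file.path(dir, "peaks_a.bed"),
      peaks_b = file.path(dir, "peaks_b.bed"),
      promoter_marks = file.path(dir, "h3k4me3_like.bed"),
      distal_marks = file.path(dir, "h3k27ac_like.bed"),
      enhancers = file.path(dir, "enhancers.tsv"),
      de = file.path(dir, "de.tsv"),
      truth = file.path(dir, "truth.json"),
      config = file.path(dir, "config.yaml")
    )
    write_chrom_sizes(gn$genome, paths$genome)
    write_gene_models(gn$genes, paths$genes)
    write_bed(pk$set_a, paths$peaks_a)
    write_bed(pk$set_b, paths$peaks_b)
    write_bed(mk$promoter_marks, paths$promoter_marks)
    write_bed(mk$distal_marks, paths$distal_marks)
    write_enhancers(enh, paths$enhancers)
    write_de_table(de$de, paths$de)
    jsonlite::write_json(
      lapply(truth, function(v) if (is.numeric(v) || is.logical(v) ||
                                    is.character(v)) v else unclass(v)),
      paths$truth, auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(list(
      genome = paths$genome, genes = paths$genes,
      peaks_a = paths$peaks_a, peaks_b = paths$peaks_b,
      promoter_marks = paths$promoter_marks,
      distal_marks = paths$distal_marks,
      enhancers = paths$enhancers, de = paths$de,
      assembly = gn$genome$assembly,
      set_a_name = pk$set_a$name, set_b_name = pk$set_b$name,
      promoter_upstream = 4000, promoter_downstream = 1000,
      gene_max_dist = 5000, enhancer_min_score = 10, deg_fdr = 0.05
    ), paths$config)
    out$paths <- paths
  }
  out
}
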