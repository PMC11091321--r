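ann_genome <- genome_info(c(chr1 = 1e6), "toy")

test_that("promoter windows are strand-aware and clipped", {
  g <- gene_models("G1", "chr1", "+", 10000, 20000, "10000", "20000",
                   genome = ann_genome)
  w <- promoter_windows(g, 4000, 1000, genome = ann_genome)
  expect_equal(c(w$start, w$end), c(6000, 11000))
  gm <- gene_models("G1", "chr1", "-", 1, 10001, "1", "10001",
                    genome = ann_genome)  # tss = 10000
  wm <- promoter_windows(gm, 4000, 1000, genome = ann_genome)
  expect_equal(c(wm$start, wm$end), c(9001, 14001))
  gc <- gene_models("G1", "chr1", "+", 500, 5000, "500", "5000",
                    genome = ann_genome)
  wc <- promoter_windows(gc, 4000, 1000, genome = ann_genome)
  expect_equal(c(wc$start, wc$end), c(0, 1500))
  expect_error(gene_models("G1", "chr1", "*", 0, 10, "0", "10"), "strand")
})

test_that("promoter membership is >=1 bp window overlap, matching brute force", {
  genes <- toy_genes(ann_genome)
  w <- promoter_windows(genes, 4000, 1000, genome = ann_genome)
  p1 <- peak_set("chr1", w$start[1] + 100, w$start[1] + 200, ann_genome, "P")
  r <- peaks_in_promoters(p1, genes)
  expect_equal(n_peaks(r$promoter_peaks), 1L)
  expect_equal(r$map$gene_id, genes$gene_id[1])
  # book-ended peak is not a promoter peak
  p2 <- peak_set("chr1", w$end[1], w$end[1] + 100, ann_genome, "P")
  expect_equal(n_peaks(peaks_in_promoters(p2, genes)$promoter_peaks), 0L)
  # random instances vs all-pairs window scan
  for (seed in 31:33) {
    withr::with_seed(seed, rp <- random_peak_set(ann_genome, 300, "rp"))
    got <- peaks_in_promoters(rp, genes)
    want <- do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
      hit <- rp$peaks$start < w$end[i] & w$start[i] < rp$peaks$end
      if (!any(hit)) return(NULL)
      data.frame(peak_id = rp$peaks$id[hit], gene_id = w$gene_id[i])
    }))
    expect_setequal(paste(got$map$peak_id, got$map$gene_id),
                    paste(want$peak_id, want$gene_id))
    expect_setequal(got$promoter_peaks$peaks$id, unique(want$peak_id))
    expect_equal(n_peaks(got$promoter_peaks) + n_peaks(got$nonpromoter_peaks),
                 n_peaks(rp))
  }
})

# deterministic placements with known intended category around one gene
planted_peaks_for_gene <- function(i, genes, jitter = 0) {
  S <- genes$start[i]; E <- genes$end[i]
  plus <- genes$strand[i] == "+"
  ex_s <- as.numeric(strsplit(genes$exon_starts[i], ",")[[1]])
  ex_e <- as.numeric(strsplit(genes$exon_ends[i], ",")[[1]])
  k <- length(ex_s)
  # exon ordinals in 5'->3' order
  first_exon <- if (plus) 1L else k
  other_exon <- if (plus) k else 1L
  intron <- c(ex_e[1] + 10 + jitter, ex_s[2] - 10)  # the only intron
  intron_cat <- "intron_1"                          # 2 exons: intron 1 always
  band <- function(d) if (plus) c(S - d - 60 + jitter, S - d + 40 + jitter)
                      else c(E - 1 + d - 40 - jitter, E - 1 + d + 60 - jitter)
  down <- if (plus) c(E + 100 + jitter, E + 300) else c(S - 300, S - 100 - jitter)
  rows <- rbind(
    data.frame(start = band(100)[1], end = band(100)[2],
               category = "promoter_0_1kb"),
    data.frame(start = band(1500)[1], end = band(1500)[2],
               category = "promoter_1_2kb"),
    data.frame(start = band(2500)[1], end = band(2500)[2],
               category = "promoter_2_3kb"),
    data.frame(start = ex_s[first_exon] + 10 + jitter,
               end = ex_s[first_exon] + 110 + jitter, category = "exon_1"),
    data.frame(start = ex_e[other_exon] - 110 - jitter,
               end = ex_e[other_exon] - 10 - jitter, category = "other_exon"),
    data.frame(start = intron[1], end = intron[2], category = intron_cat),
    data.frame(start = down[1], end = down[2], category = "downstream")
  )
  rows
}

test_that("feature assignment recovers planted categories and precedence", {
  # genes spaced 100 kb apart so plantings never collide across genes
  genes <- toy_genes(ann_genome,
                     tss = c(50000, 150000, 250000, 350000, 450000,
                             550000, 650000),
                     strand = c("+", "-", "+", "-", "+", "-", "+"))
  placed <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    do.call(rbind, lapply(c(0, 7, 13), function(j) {
      cbind(planted_peaks_for_gene(i, genes, jitter = j), gene = i)
    }))
  }))
  # plus far-from-everything distal peaks
  distal <- data.frame(start = c(705000, 905000), end = c(705400, 905400),
                       category = "distal_intergenic", gene = NA)
  placed <- rbind(placed, distal)
  ps <- peak_set(rep("chr1", nrow(placed)), placed$start, placed$end,
                 ann_genome, "planted")
  fa <- assign_feature(ps, genes)
  # peak_set sorts; re-align planted truth by coordinates
  key <- paste(placed$start, placed$end)
  got <- as.character(fa$category[match(key, paste(ps$peaks$start,
                                                   ps$peaks$end))])
  expect_equal(got, placed$category)
  # gene id is null exactly for distal intergenic
  expect_identical(is.na(fa$gene_id), fa$category == "distal_intergenic")
  # every peak has exactly one category and percentages sum to 100
  expect_equal(nrow(fa), n_peaks(ps))
  expect_equal(sum(feature_distribution(fa)), 100, tolerance = 1e-9)
})

test_that("promoter bands outrank gene-body features", {
  # peak overlapping exon 1 of one gene while its midpoint sits 500 bp
  # upstream of a neighbouring gene's TSS -> promoter_0_1kb wins
  genes <- gene_models(c("GA", "GB"), c("chr1", "chr1"), c("+", "+"),
                       c(10000, 21000), c(20500, 31000),
                       c("10000", "21000"), c("20500", "31000"),
                       genome = ann_genome)
  pk <- peak_set("chr1", 20400, 20600, ann_genome, "P")  # midpoint 20500
  fa <- assign_feature(pk, genes)
  expect_equal(as.character(fa$category), "promoter_0_1kb")
  expect_equal(fa$gene_id, "GB")
})

test_that("introns beyond the first are classified as other_intron", {
  # 3 exons; intron ordinals follow the 5'->3' direction of each strand
  genes <- gene_models(c("GP", "GM"), c("chr1", "chr1"), c("+", "-"),
                       c(100000, 300000), c(110000, 310000),
                       c("100000,102000,105000", "300000,302000,305000"),
                       c("101000,103000,110000", "301000,303000,310000"),
                       genome = ann_genome)
  # genomic introns: [+1000,+2000) and [+3000,+5000) past each gene start
  pk <- peak_set(rep("chr1", 4),
                 c(101100, 103100, 301100, 303100),
                 c(101200, 103200, 301200, 303200), ann_genome, "P")
  fa <- assign_feature(pk, genes)
  got <- as.character(fa$category[match(c(101100, 103100, 301100, 303100),
                                        pk$peaks$start)])
  # plus strand: first genomic intron is intron 1; minus strand: reversed
  expect_equal(got, c("intron_1", "other_intron",
                      "other_intron", "intron_1"))
})

test_that("feature distribution is a percentage tally", {
  fa <- structure(
    data.frame(peak_id = sprintf("p%d", 1:4),
               category = factor(c("promoter_0_1kb", "promoter_0_1kb",
                                   "promoter_1_2kb", "distal_intergenic"),
                                 levels = levels(assign_feature(
                                   peak_set("chr1", 1, 2, ann_genome),
                                   toy_genes(ann_genome))$category)),
               gene_id = c("g", "g", "g", NA)),
    class = c("feature_assignments", "data.frame"))
  d <- feature_distribution(fa)
  expect_equal(unname(d[["promoter_0_1kb"]]), 50)
  expect_equal(unname(d[["distal_intergenic"]]), 25)
  expect_equal(sum(d), 100)
  expect_error(feature_distribution(fa[0, ]), "empty|undefined")
})

test_that("gene association respects the maximum gap, matching brute force", {
  genes <- gene_models("G1", "chr1", "+", 5100, 6000, "5100", "6000",
                       genome = ann_genome)
  near <- peak_set("chr1", 0, 100, ann_genome, "P")
  expect_equal(nrow(genes_near_peaks(near, genes, 5000)), 1L)
  genes2 <- gene_models("G1", "chr1", "+", 5101, 6000, "5101", "6000",
                        genome = ann_genome)
  expect_equal(nrow(genes_near_peaks(near, genes2, 5000)), 0L)
  big_genes <- toy_genes(ann_genome)
  for (seed in 41:43) {
    withr::with_seed(seed, rp <- random_peak_set(ann_genome, 250, "rp"))
    got <- genes_near_peaks(rp, big_genes, 5000)
    want <- do.call(rbind, lapply(seq_len(nrow(big_genes)), function(i) {
      gap <- pmax(big_genes$start[i] - rp$peaks$end,
                  rp$peaks$start - big_genes$end[i])
      hit <- pmax(gap, 0) <= 5000
      if (!any(hit)) return(NULL)
      data.frame(peak_id = rp$peaks$id[hit],
                 gene_id = big_genes$gene_id[i])
    }))
    expect_setequal(paste(got$peak_id, got$gene_id),
                    paste(want$peak_id, want$gene_id))
  }
})

test_that("TSS profile marks covered offset bins and scans like brute force", {
  g <- gene_models("G1", "chr1", "+", 10000, 20000, "10000", "20000",
                   genome = ann_genome)
  pk <- peak_set("chr1", 9975, 10025, ann_genome, "P")
  pr <- tss_profile(pk, g, flank = 3000, step = 50)
  expect_equal(nrow(pr), 120)
  expect_equal(pr$count[pr$offset %in% c(-50, 0)], c(1, 1))
  expect_equal(sum(pr$count), 2)
  empty <- peak_set(character(0), numeric(0), numeric(0), ann_genome, "E")
  expect_true(all(tss_profile(empty, g)$count == 0))

  genes <- toy_genes(ann_genome)
  withr::with_seed(51, rp <- random_peak_set(ann_genome, 150, "rp"))
  pr <- tss_profile(rp, genes, flank = 1000, step = 50)
  # independent per-gene scan
  want <- integer(nrow(pr))
  for (j in seq_len(nrow(pr))) {
    lo <- pr$offset[j]
    for (i in seq_len(nrow(genes))) {
      span <- if (genes$strand[i] == "+") {
        c(genes$tss[i] + lo, genes$tss[i] + lo + 50)
      } else {
        c(genes$tss[i] - lo - 50 + 1, genes$tss[i] - lo + 1)
      }
      if (any(rp$peaks$start < span[2] & span[1] < rp$peaks$end)) {
        want[j] <- want[j] + 1L
      }
    }
  }
  expect_equal(pr$count, want)
})

test_that("reversing gene strands mirrors the single-base TSS profile", {
  genes <- toy_genes(ann_genome)
  withr::with_seed(52, rp <- random_peak_set(ann_genome, 100, "rp"))
  fwd <- tss_profile(rp, genes, flank = 200, step = 1)
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  flipped$tss <- genes$tss   # same anchor base, opposite orientation
  rev_pr <- tss_profile(rp, flipped, flank = 200, step = 1)
  # the bin at offset x of the flipped profile covers the base the forward
  # profile sees at offset -x (offset +200 is outside the half-open grid)
  j <- match(-rev_pr$offset, fwd$offset)
  expect_equal(rev_pr$count[!is.na(j)], fwd$count[j[!is.na(j)]])
})

test_that("uniformly placed peaks give a flat TSS profile", {
  genes <- toy_genes(ann_genome, tss = seq(50000, 950000, by = 10000),
                     strand = rep(c("+", "-"), length.out = 91))
  withr::with_seed(53, rp <- random_peak_set(ann_genome, 400, "rp",
                                             min_len = 300, max_len = 900))
  pr <- tss_profile(rp, genes, flank = 3000, step = 100)
  n <- nrow(genes)
  p_hat <- mean(pr$count) / n
  band <- 3 * sqrt(n * p_hat * (1 - p_hat))
  outside <- abs(pr$count - n * p_hat) > band
  # allow a couple of 3-sigma excursions over 60 correlated bins
  expect_lte(sum(outside), 2)
})

test_that("GTF exon records collapse into the gene-model structure", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  # two transcripts of one gene with overlapping exons, 1-based closed
  writeLines(c(
    paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; gene_name "GENE1";'),
    paste0("chr1\tsrc\texon\t401\t500\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; gene_name "GENE1";'),
    paste0("chr1\tsrc\texon\t151\t250\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T2"; gene_name "GENE1";')
  ), gtf)
  gm <- read_gtf_gene_models(gtf, genome = ann_genome)
  expect_equal(gm$start, 100)
  expect_equal(gm$end, 500)
  expect_equal(gm$exon_starts, "100,400")  # overlapping exons flattened
  expect_equal(gm$exon_ends, "250,500")
  expect_equal(gm$tss, 100)
})
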