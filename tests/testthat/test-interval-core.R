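toy_genome <- genome_info(c(chr1 = 1e6, chr2 = 5e5), "toy")

test_that("interval overlap follows the shared-base rule", {
  expect_true(intervals_overlap("chr1", 100, 200, "chr1", 199, 250))
  expect_false(intervals_overlap("chr1", 100, 200, "chr1", 200, 250))
  expect_false(intervals_overlap("chr1", 100, 200, "chr2", 100, 200))
  # symmetry and book-ended falseness over random cases
  withr::with_seed(11, {
    s1 <- sample(1e5, 300); e1 <- s1 + sample(500, 300, replace = TRUE)
    s2 <- sample(1e5, 300); e2 <- s2 + sample(500, 300, replace = TRUE)
    expect_identical(intervals_overlap("chr1", s1, e1, "chr1", s2, e2),
                     intervals_overlap("chr1", s2, e2, "chr1", s1, e1))
    expect_false(any(intervals_overlap("chr1", s1, e1, "chr1", e1,
                                       e1 + 100)))
  })
})

test_that("peak_set validates, sorts and auto-ids", {
  ps <- peak_set(c("chr2", "chr1", "chr1"), c(10, 500, 100),
                 c(20, 600, 200), toy_genome, name = "TF")
  expect_equal(ps$peaks$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(ps$peaks$start, c(100, 500, 10))
  expect_equal(ps$peaks$id, c("TF_1", "TF_2", "TF_3"))
  expect_error(peak_set("chr1", 200, 200, toy_genome), "empty")
  expect_error(peak_set("chrX", 0, 10, toy_genome), "absent")
  expect_error(peak_set("chr1", -5, 10, toy_genome), ">= 0")
  expect_error(peak_set(c("chr1", "chr1"), c(0, 1), c(5, 6), toy_genome,
                        id = c("p", "p")), "unique")
})

test_that("BED files parse, reject malformed records, and round-trip", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment",
               "chr1\t100\t200", "chr1\t150\t250"), f)
  ps <- read_bed(f, toy_genome, name = "TF")
  expect_equal(n_peaks(ps), 2L)
  expect_equal(ps$peaks$start, c(100, 150))

  writeLines("chr1\t200\t200", f)
  expect_error(read_bed(f, toy_genome), "line 1")
  writeLines(c("chr1\t1\t2", "chr1\t5"), f)
  expect_error(read_bed(f, toy_genome), "line 2")
  writeLines("chr9\t1\t2", f)
  expect_error(read_bed(f, toy_genome), "chr9")

  # round-trip of 1000 random records preserves the interval multiset
  withr::with_seed(42, {
    orig <- random_peak_set(toy_genome, 1000, name = "RT")
  })
  write_bed(orig, f)
  back <- read_bed(f, toy_genome, name = "RT")
  key <- function(p) sort(paste(p$peaks$chrom, p$peaks$start, p$peaks$end,
                                p$peaks$id))
  expect_identical(key(back), key(orig))
})

test_that("overlap pairs match the quadratic oracle", {
  a <- peak_set("chr1", 100, 200, toy_genome, "A")
  b <- peak_set(c("chr1", "chr1"), c(150, 400), c(300, 500), toy_genome, "B")
  expect_equal(find_overlap_pairs(a, b),
               data.frame(id_a = "A_1", id_b = "B_1"))
  # self-comparison includes all reflexive pairs
  self <- find_overlap_pairs(b, b)
  expect_true(all(paste(b$peaks$id, b$peaks$id) %in%
                    paste(self$id_a, self$id_b)))
  # randomized instances
  for (seed in 1:4) {
    withr::with_seed(seed, {
      ra <- random_peak_set(toy_genome, 400, "ra")
      rb <- random_peak_set(toy_genome, 400, "rb")
    })
    got <- find_overlap_pairs(ra, rb)
    want <- oracle_pairs(ra, rb)
    expect_setequal(paste(got$id_a, got$id_b), paste(want$id_a, want$id_b))
  }
  g2 <- genome_info(c(chr1 = 1e6), "other")
  expect_error(find_overlap_pairs(a, peak_set("chr1", 1, 2, g2)),
               "different genomes")
})

test_that("co-bound merging equals union-find components over the overlap graph", {
  a <- peak_set(c("chr1", "chr1"), c(100, 300), c(200, 400), toy_genome, "A")
  b <- peak_set("chr1", 150, 350, toy_genome, "B")
  m <- merge_cobound(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100, 400))
  expect_equal(m$members_a, "A_1,A_2")
  expect_equal(m$members_b, "B_1")

  far <- peak_set("chr1", 500, 600, toy_genome, "B")
  expect_equal(nrow(merge_cobound(a, far)), 0L)

  for (seed in 5:8) {
    withr::with_seed(seed, {
      ra <- random_peak_set(toy_genome, 150, "ra", max_len = 4000)
      rb <- random_peak_set(toy_genome, 150, "rb", max_len = 4000)
    })
    m <- merge_cobound(ra, rb)
    got <- lapply(seq_len(nrow(m)), function(i) {
      sort(c(paste0("a:", strsplit(m$members_a[i], ",")[[1]]),
             paste0("b:", strsplit(m$members_b[i], ",")[[1]])))
    })
    want <- oracle_components(ra, rb)
    expect_setequal(vapply(got, paste, "", collapse = "|"),
                    vapply(want, paste, "", collapse = "|"))
    # spans pairwise non-overlapping; each member in exactly one component
    if (nrow(m) > 1) {
      for (ch in unique(m$chrom)) {
        mm <- m[m$chrom == ch, ]
        o <- order(mm$start)
        expect_true(all(mm$start[o][-1] >= mm$end[o][-nrow(mm)]))
      }
    }
    members <- unlist(strsplit(c(m$members_a, m$members_b), ","))
    expect_false(anyDuplicated(members) > 0)
    expect_lte(length(members), n_peaks(ra) + n_peaks(rb))
  }
})

test_that("merging ignores within-set overlaps without cross-set contact", {
  a <- peak_set(c("chr1", "chr1"), c(100, 150), c(200, 260), toy_genome, "A")
  b <- peak_set(c("chr1", "chr1"), c(1000, 1100), c(1200, 1300),
                toy_genome, "B")
  expect_equal(nrow(merge_cobound(a, b)), 0L)
})

test_that("nearest distances equal the exhaustive minimum and flag undefined", {
  q <- peak_set("chr1", 100, 200, toy_genome, "Q")
  s1 <- peak_set("chr1", 300, 400, toy_genome, "S")
  expect_equal(unname(nearest_distance(q, s1)), 100)
  s2 <- peak_set("chr1", 150, 300, toy_genome, "S")
  expect_equal(unname(nearest_distance(q, s2)), 0)
  # query on a chromosome with no subject peaks is undefined
  q2 <- peak_set(c("chr1", "chr2"), c(100, 100), c(200, 200), toy_genome, "Q")
  d <- nearest_distance(q2, s1)
  expect_true(is.na(d[q2$peaks$id[q2$peaks$chrom == "chr2"]]))
  for (seed in 9:12) {
    withr::with_seed(seed, {
      rq <- random_peak_set(toy_genome, 200, "q")
      rs <- random_peak_set(toy_genome, 200, "s")
    })
    expect_equal(unname(nearest_distance(rq, rs)), oracle_nearest(rq, rs))
  }
})

test_that("distance is zero exactly for overlapping or abutting peaks", {
  withr::with_seed(21, {
    rq <- random_peak_set(toy_genome, 300, "q")
    rs <- random_peak_set(toy_genome, 300, "s")
  })
  d <- nearest_distance(rq, rs)
  pairs <- find_overlap_pairs(rq, rs)
  overlaps <- rq$peaks$id %in% pairs$id_a
  abuts <- vapply(seq_len(n_peaks(rq)), function(i) {
    any(rs$peaks$chrom == rq$peaks$chrom[i] &
          (rs$peaks$start == rq$peaks$end[i] |
             rs$peaks$end == rq$peaks$start[i]))
  }, TRUE)
  expect_identical(unname(d == 0), overlaps | abuts)
})

test_that("pooled mean peak length rounds half-up", {
  g <- toy_genome
  a <- peak_set(c("chr1", "chr1"), c(0, 1000), c(100, 1200), g, "A")
  b <- peak_set("chr1", 0, 300, g, "B")
  expect_identical(mean_peak_length(a, b), 200L)
  a1 <- peak_set("chr1", 0, 100, g, "A")
  b1 <- peak_set("chr1", 0, 101, g, "B")
  expect_identical(mean_peak_length(a1, b1), 101L)
  withr::with_seed(13, {
    ra <- random_peak_set(g, 600, "ra")
    rb <- random_peak_set(g, 400, "rb")
  })
  lens <- c(ra$peaks$end - ra$peaks$start, rb$peaks$end - rb$peaks$start)
  expect_identical(mean_peak_length(ra, rb),
                   as.integer(floor(sum(lens) / length(lens) + 0.5)))
  # per-set-mean alternative
  m2 <- (mean(ra$peaks$end - ra$peaks$start) +
           mean(rb$peaks$end - rb$peaks$start)) / 2
  expect_identical(mean_peak_length(ra, rb, pooled = FALSE),
                   as.integer(floor(m2 + 0.5)))
  expect_error(mean_peak_length(peak_set(character(0), numeric(0),
                                         numeric(0), g), ra), "non-empty")
})

test_that("genome tiling partitions chromosomes with a ceil bin count", {
  g <- genome_info(c(chr1 = 10), "toy")
  expect_equal(bin_ranges(tile_genome(g, 5))$start, c(0, 5))
  b <- bin_ranges(tile_genome(g, 4))
  expect_equal(b$start, c(0, 4, 8))
  expect_equal(b$end, c(4, 8, 10))
  big <- genome_info(c(chr1 = 248956422), "hg38-scale")
  expect_equal(tile_genome(big, 654)$n_total,
               ceiling(248956422 / 654))
  expect_error(tile_genome(g, 0), "positive")
  # bins partition: disjoint, exhaustive
  g2 <- genome_info(c(chr1 = 103, chr2 = 50), "toy")
  b2 <- bin_ranges(tile_genome(g2, 25))
  expect_equal(sum(b2$end - b2$start), 153)
  for (ch in c("chr1", "chr2")) {
    bb <- b2[b2$chrom == ch, ]
    expect_equal(bb$start[-1], bb$end[-nrow(bb)])
  }
})
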