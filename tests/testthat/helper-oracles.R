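# Independent brute-force oracles. Everything here is deliberately naive
# (quadratic scans, union-find, per-bin membership tests) and shares no code
# with the package implementations it checks.

# all overlapping (a, b) id pairs by exhaustive all-pairs scan (one query
# peak against every subject peak at a time)
oracle_pairs <- function(set_a, set_b) {
  pa <- set_a$peaks
  pb <- set_b$peaks
  out <- lapply(seq_len(nrow(pa)), function(i) {
    j <- which(pa$chrom[i] == pb$chrom &
                 pa$start[i] < pb$end & pb$start < pa$end[i])
    if (!length(j)) return(NULL)
    data.frame(id_a = pa$id[i], id_b = pb$id[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(id_a = character(0), id_b = character(0)))
  }
  out
}

# connected components of the overlap graph over A union B via union-find
# on the brute-force pair list; returns a list of character membership
# vectors (ids tagged a:/b:), restricted to components with both sources
oracle_components <- function(set_a, set_b) {
  ids <- c(paste0("a:", set_a$peaks$id), paste0("b:", set_b$peaks$id))
  ivs <- rbind(set_a$peaks[, c("chrom", "start", "end")],
               set_b$peaks[, c("chrom", "start", "end")])
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <- parent[parent[x]]   # path halving
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n)) {
    js <- which(ivs$chrom == ivs$chrom[i] &
                  ivs$start[i] < ivs$end & ivs$start < ivs$end[i])
    for (j in js[js > i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(ids, roots)
  keep <- vapply(comps, function(m) {
    any(startsWith(m, "a:")) && any(startsWith(m, "b:"))
  }, TRUE)
  unname(lapply(comps[keep], sort))
}

# per-query minimum gap by exhaustive scan (NA when no same-chrom subject)
oracle_nearest <- function(query, subject) {
  pq <- query$peaks
  ps <- subject$peaks
  vapply(seq_len(nrow(pq)), function(i) {
    j <- which(ps$chrom == pq$chrom[i])
    if (!length(j)) return(NA_real_)
    gaps <- pmax(ps$start[j] - pq$end[i], pq$start[i] - ps$end[j])
    min(pmax(gaps, 0))
  }, 0)
}

# contingency table by scanning every materialized bin against every peak
oracle_bin_table <- function(grid, set_a, set_b) {
  bins <- bin_ranges(grid)
  hit <- function(set) {
    vapply(seq_len(nrow(bins)), function(i) {
      any(set$peaks$chrom == bins$chrom[i] &
            set$peaks$start < bins$end[i] &
            bins$start[i] < set$peaks$end)
    }, TRUE)
  }
  ha <- hit(set_a)
  hb <- hit(set_b)
  c(n00 = sum(!ha & !hb), n10 = sum(ha & !hb),
    n01 = sum(!ha & hb), n11 = sum(ha & hb))
}

# uniform random peak set (caller controls the RNG state)
random_peak_set <- function(genome, n, name = "rand", min_len = 50,
                            max_len = 1500) {
  chroms <- names(genome$chrom_sizes)
  ci <- sample(length(chroms), n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  s <- floor(runif(n, 0, genome$chrom_sizes[ci] - len))
  peak_set(chroms[ci], s, s + len, genome, name = name)
}

# small deterministic gene set for annotation tests
toy_genes <- function(genome, tss = c(50000, 150000, 250000),
                      strand = c("+", "-", "+")) {
  n <- length(tss)
  start <- ifelse(strand == "+", tss, tss - 9999)
  end <- start + 10000
  exon_starts <- paste(start, start + 4000, sep = ",")
  exon_ends <- paste(start + 1000, start + 10000, sep = ",")
  gene_models(sprintf("TG%02d", seq_len(n)), rep("chr1", n), strand,
              start, end, exon_starts, exon_ends, genome = genome)
}
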