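#' Resolve a pipeline configuration
#'
#' Accepts a YAML file path or a named list, fills in the default analysis
#' parameters (promoter window 4 kb upstream / 1 kb downstream, gene
#' association within 5 kb, enhancer interaction score strictly above 10,
#' DEG FDR strictly below 0.05, bin width defaulting to the pooled mean
#' peak length) and checks that every required input file exists. Missing
#' files abort before any computation, with the full manifest of what is
#' missing.
#'
#' @param config Path to a YAML file or a named list. Required entries:
#'   `genome`, `genes`, `peaks_a`, `peaks_b`, `promoter_marks`,
#'   `distal_marks`, `enhancers`, `de`. Optional: `set_a_name`,
#'   `set_b_name`, `promoter_upstream`, `promoter_downstream`,
#'   `gene_max_dist`, `enhancer_min_score`, `deg_fdr`, `bin_width`,
#'   `assembly`.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  defaults <- list(set_a_name = "setA", set_b_name = "setB",
                   promoter_upstream = 4000, promoter_downstream = 1000,
                   gene_max_dist = 5000, enhancer_min_score = 10,
                   deg_fdr = 0.05, bin_width = NULL, assembly = "unknown")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  }
  required <- c("genome", "genes", "peaks_a", "peaks_b", "promoter_marks",
                "distal_marks", "enhancers", "de")
  missing_keys <- required[vapply(required, function(k)
    is.null(config[[k]]), TRUE)]
  if (length(missing_keys)) {
    stop("config missing required input entr",
         if (length(missing_keys) > 1) "ies: " else "y: ",
         paste(missing_keys, collapse = ", "))
  }
  missing_files <- unlist(config[required])[
    !file.exists(unlist(config[required]))]
  if (length(missing_files)) {
    stop("missing input file(s):\n  ",
         paste(missing_files, collapse = "\n  "))
  }
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the full co-occupancy analysis pipeline
#'
#' Executes, in order: feature annotation of each TF peak set; the co-bound
#' merge; nearest-peak distances of set B to set A; the binned
#' co-localization test; the promoter / non-promoter split of each set and
#' of the merged peaks; histone-mark stratification (promoter peaks against
#' the promoter mark, distal-intergenic peaks against the distal mark, and
#' the merged set against both); the enhancer join on distal set-A peaks;
#' and DEG joins of the set-A promoter target genes and of the merged-peak
#' promoter target genes. Writes per-stage TSV tables, a `summary.json`
#' with every headline count and fraction, and a `pipeline.log` recording
#' every resolved parameter. Fully deterministic: identical inputs and
#' config give byte-identical summaries.
#'
#' @param config A [pipeline_config()], YAML path, or named list.
#' @param out_dir Output directory (created if absent); `NULL` to skip
#'   writing files.
#' @return The report bundle, invisibly when writing: a list with all
#'   intermediate objects and the `summary` list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  log_lines <- c(sprintf("peakcoloc pipeline, package version %s",
                         as.character(utils::packageVersion("peakcoloc"))),
                 "resolved parameters:")
  for (nm in sort(names(cfg))) {
    log_lines <- c(log_lines, sprintf("  %s = %s", nm,
                                      if (is.null(cfg[[nm]])) "auto"
                                      else as.character(cfg[[nm]])))
  }

  genome <- read_chrom_sizes(cfg$genome, assembly = cfg$assembly)
  genes <- read_gene_models(cfg$genes, genome = genome)
  set_a <- read_bed(cfg$peaks_a, genome, name = cfg$set_a_name)
  set_b <- read_bed(cfg$peaks_b, genome, name = cfg$set_b_name)
  k4 <- read_bed(cfg$promoter_marks, genome, name = "promoter_mark")
  k27 <- read_bed(cfg$distal_marks, genome, name = "distal_mark")
  enh <- read_enhancers(cfg$enhancers, genome = genome)
  de <- read_de_table(cfg$de)

  # 1. feature annotation
  feat_a <- assign_feature(set_a, genes)
  feat_b <- assign_feature(set_b, genes)
  dist_a <- feature_distribution(feat_a)
  dist_b <- feature_distribution(feat_b)

  # 2. co-bound merge
  merged <- merge_cobound(set_a, set_b)
  merged_set <- merged_peak_set(merged, genome)

  # 3. nearest distances (B to nearest A)
  ndist <- nearest_distance(set_b, set_a)

  # 4. binned co-localization test
  coloc <- colocalization_test(set_a, set_b, width = cfg$bin_width)
  ovf <- overlap_fraction(set_b, set_a)

  # 5. promoter / distal splits
  prom_a <- peaks_in_promoters(set_a, genes, cfg$promoter_upstream,
                               cfg$promoter_downstream)
  prom_m <- peaks_in_promoters(merged_set, genes, cfg$promoter_upstream,
                               cfg$promoter_downstream)
  distal_a <- .subset_peaks(set_a, feat_a$category == "distal_intergenic")

  # 6. histone stratification
  strat_prom_a <- stratify_by_mark(prom_a$promoter_peaks, k4)
  strat_prom_m <- stratify_by_mark(prom_m$promoter_peaks, k4)
  strat_dist_a <- stratify_by_mark(distal_a, k27)
  strat_nonprom_m <- stratify_by_mark(prom_m$nonpromoter_peaks, k27)

  # 7. enhancer join on distal set-A peaks
  ej <- enhancer_join(distal_a, enh, min_score = cfg$enhancer_min_score)

  # 8. DEG joins
  deg_a <- deg_join(prom_a$map, de, fdr = cfg$deg_fdr)
  deg_m <- deg_join(prom_m$map, de, fdr = cfg$deg_fdr)

  summary <- list(
    set_a = set_a$name, set_b = set_b$name,
    n_peaks_a = n_peaks(set_a), n_peaks_b = n_peaks(set_b),
    feature_pct_a = as.list(round(as.numeric(dist_a), 4) |>
                              setNames(names(dist_a))),
    feature_pct_b = as.list(round(as.numeric(dist_b), 4) |>
                              setNames(names(dist_b))),
    n_merged_peaks = nrow(merged),
    overlap_fraction_b_in_a = ovf$fraction,
    n_overlap_b = ovf$count,
    bin_width = coloc$bin_width,
    contingency = list(n00 = coloc$table$n00, n10 = coloc$table$n10,
                       n01 = coloc$table$n01, n11 = coloc$table$n11),
    coloc_odds_ratio = coloc$odds_ratio,
    coloc_p_value = coloc$p_value,
    n_promoter_peaks_a = n_peaks(prom_a$promoter_peaks),
    n_promoter_genes_a = length(unique(prom_a$map$gene_id)),
    n_merged_promoter_peaks = n_peaks(prom_m$promoter_peaks),
    n_merged_nonpromoter_peaks = n_peaks(prom_m$nonpromoter_peaks),
    merged_promoter_pct =
      if (nrow(merged)) 100 * n_peaks(prom_m$promoter_peaks) / nrow(merged)
      else NA_real_,
    promoter_mark_fraction_a = strat_prom_a$fraction_in,
    promoter_mark_fraction_merged = strat_prom_m$fraction_in,
    distal_mark_fraction_a = strat_dist_a$fraction_in,
    distal_mark_fraction_merged_nonpromoter = strat_nonprom_m$fraction_in,
    n_distal_peaks_a = n_peaks(distal_a),
    n_enhancer_annotated = n_peaks(ej$annotated),
    n_enhancer_novel = n_peaks(ej$novel),
    n_regulated_genes = length(ej$regulated_genes),
    deg_a = as.list(setNames(as.integer(deg_a$counts), names(deg_a$counts))),
    deg_merged = as.list(setNames(as.integer(deg_m$counts),
                                  names(deg_m$counts)))
  )

  report <- list(config = cfg, genome = genome, genes = genes,
                 set_a = set_a, set_b = set_b,
                 features_a = feat_a, features_b = feat_b,
                 merged = merged, merged_set = merged_set,
                 nearest = ndist, coloc = coloc,
                 promoters_a = prom_a, promoters_merged = prom_m,
                 distal_a = distal_a,
                 strat_promoter_a = strat_prom_a,
                 strat_promoter_merged = strat_prom_m,
                 strat_distal_a = strat_dist_a,
                 strat_nonpromoter_merged = strat_nonprom_m,
                 enhancers = ej, deg_a = deg_a, deg_merged = deg_m,
                 summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    write.table(cbind(feat_a, set = set_a$name),
                file.path(out_dir, "features_a.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cbind(feat_b, set = set_b$name),
                file.path(out_dir, "features_b.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(merged, file.path(out_dir, "merged_peaks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(peak_id = names(ndist), distance = ndist),
                file.path(out_dir, "nearest_distance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_overlap_result(coloc, file.path(out_dir, "colocalization.tsv"))
    write.table(prom_a$map, file.path(out_dir, "promoter_gene_map_a.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ej$map, file.path(out_dir, "enhancer_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(deg_a$classes, file.path(out_dir, "deg_classes_a.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(deg_m$classes, file.path(out_dir, "deg_classes_merged.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    return(invisible(report))
  }
  report
}
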