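#' Validate a pipeline run configuration
#'
#' @param fasta,gff3 reference genome paths.
#' @param vcfs named list (condition -> character vector of per-replicate
#'   VCF paths).
#' @param depths named list (condition -> per-replicate depth TSV paths,
#'   same order as `vcfs`).
#' @param classification read-classification TSV path (optional; `NULL`
#'   skips the sample-metrics stage).
#' @param min_support concordance threshold (default 2).
#' @param min_depth coverage threshold (default 1).
#' @param kaks_upper,kaks_lower,kaks_syn_dense,kaks_min_conditions
#'   gene-of-interest selection thresholds (defaults 1, 1, 0.2, 2).
#' @param iterations continuum-randomization iterations (default 1e5;
#'   the full-scale analysis uses 1e6).
#' @param seed RNG seed for all stochastic stages.
#' @param target_genus on-target taxon label (default `"Nostoc"`).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(fasta, gff3, vcfs, depths, classification = NULL,
                       min_support = 2, min_depth = 1,
                       kaks_upper = 1, kaks_lower = 1, kaks_syn_dense = 0.2,
                       kaks_min_conditions = 2,
                       iterations = 1e5, seed = 1, target_genus = "Nostoc") {
  paths <- c(fasta, gff3, unlist(vcfs), unlist(depths), classification)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  stopifnot(is.list(vcfs), is.list(depths),
            identical(sort(names(vcfs)), sort(names(depths))))
  if (any(vapply(vcfs, length, integer(1)) < 1L)) {
    stopf("every condition needs at least one replicate VCF")
  }
  structure(list(fasta = fasta, gff3 = gff3, vcfs = vcfs, depths = depths,
                 classification = classification,
                 min_support = min_support, min_depth = min_depth,
                 kaks_upper = kaks_upper, kaks_lower = kaks_lower,
                 kaks_syn_dense = kaks_syn_dense,
                 kaks_min_conditions = kaks_min_conditions,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 target_genus = target_genus),
            class = "run_config")
}

#' Run the whole analysis pipeline
#'
#' Stages: ingest reference and per-replicate VCFs; effect-annotate;
#' concordance-merge per condition; genome-wide and per-gene Ka/Ks;
#' gene-of-interest selection; Pascal and continuum-randomization null
#' tests; noncoding characterization; sample purity/coverage metrics with
#' group comparisons. Writes a TSV/JSON report bundle and a run log
#' (content is timestamp-free, so two runs with the same config are
#' byte-identical).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report list.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(is(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("kakscan run log",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("kakscan"))),
                 sprintf("R version: %s.%s", R.version$major, R.version$minor),
                 sprintf("seed: %d; iterations: %d; min_support: %d",
                         config$seed, config$iterations, config$min_support))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  genome <- stage("ingest-genome", read_genome(config$fasta, config$gff3))
  conds <- names(config$vcfs)

  merged <- list()
  tracks <- list()
  all_tracks <- list()
  n_raw <- setNames(integer(length(conds)), conds)
  for (cn in conds) {
    reps <- stage("ingest-vcf", lapply(config$vcfs[[cn]], read_vcf_variants,
                                       condition = cn))
    ann <- stage("annotate", lapply(reps, function(r)
      classify_variants(genome, r)))
    n_raw[cn] <- sum(vapply(ann, nrow, integer(1)))
    merged[[cn]] <- stage("merge",
                          merge_replicates(ann, condition = cn,
                                           min_support = config$min_support))
    tracks[[cn]] <- stage("ingest-depth", lapply(config$depths[[cn]],
                                                 read_depth_track))
    for (tr in tracks[[cn]]) all_tracks[[tr$replicate_id]] <- tr
    write_annotated_tsv(merged[[cn]]$variants,
                        file.path(out_dir, sprintf("merged_%s.tsv", cn)))
  }

  # --- Ka/Ks ------------------------------------------------------------
  gw <- lapply(merged, genome_wide_kaks)
  gw_tab <- data.frame(
    condition = conds,
    ka = vapply(gw, function(x) x$ka_total, integer(1)),
    ks = vapply(gw, function(x) x$ks_total, integer(1)),
    ratio = vapply(gw, function(x) x$ratio_reported, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  write.table(gw_tab, file.path(out_dir, "genome_kaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  per_gene <- lapply(setNames(conds, conds), function(cn) {
    per_gene_kaks(genome, merged[[cn]], tracks[[cn]],
                  min_depth = config$min_depth,
                  min_covered_replicates = config$min_support)
  })
  write.table(kaks_table(per_gene), file.path(out_dir, "gene_kaks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  goi <- select_genes_of_interest(per_gene, upper = config$kaks_upper,
                                  lower = config$kaks_lower,
                                  syn_dense = config$kaks_syn_dense,
                                  min_conditions = config$kaks_min_conditions)
  jsonlite::write_json(goi[goi$direction != "none", , drop = FALSE],
                       file.path(out_dir, "genes_of_interest.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- null models ------------------------------------------------------
  obs <- lapply(merged, function(m)
    m$variants[!duplicated(variant_key(m$variants)),
               c("contig", "pos"), drop = FALSE])
  nt <- continuum_randomization(genome, obs, statistic = "shared_genes",
                                iterations = config$iterations,
                                seed = config$seed)
  jsonlite::write_json(null_result_summary(nt),
                       file.path(out_dir, "null_test.json"),
                       auto_unbox = TRUE, digits = NA)

  goi_ids <- goi$gene_id[goi$direction != "none"]
  pascal <- NULL
  if (length(goi_ids)) {
    g <- genome$genes[match(goi_ids, genome$genes$gene_id), , drop = FALSE]
    lens <- setNames(g$end - g$start + 1, g$gene_id)
    shared_counts <- vapply(goi_ids, function(gid) {
      keys <- lapply(merged, function(m) {
        v <- m$variants
        unique(variant_key(v[v$gene_id %in% gid, , drop = FALSE]))
      })
      pool <- unlist(keys)
      sum(table(pool) >= 2)  # variants recurring in >= 2 conditions
    }, numeric(1))
    pascal <- pascal_gene_table(lens, shared_counts)
    write.table(pascal, file.path(out_dir, "pascal_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # Friedman/Nemenyi across conditions on per-gene variant burdens of the
  # genes of interest (needs >= 2 such genes)
  friedman <- nemenyi <- NULL
  if (length(goi_ids) >= 2L) {
    mat <- vapply(conds, function(cn) {
      d <- per_gene[[cn]]
      cnt <- setNames(d$ka_count + d$ks_count, d$gene_id)
      out <- cnt[goi_ids]
      out[is.na(out)] <- 0
      out
    }, numeric(length(goi_ids)))
    mat <- matrix(mat, ncol = length(conds),
                  dimnames = list(goi_ids, conds))
    friedman <- friedman_test(mat)
    nemenyi <- nemenyi_posthoc(mat)
    fr_tab <- data.frame(statistic = friedman$statistic, df = friedman$df,
                         p_value = friedman$p_value)
    write.table(fr_tab, file.path(out_dir, "friedman.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (isTRUE(nemenyi$applicable)) {
      write.table(nemenyi$pairs, file.path(out_dir, "nemenyi.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- noncoding --------------------------------------------------------
  nc <- noncoding_summary(merged, genome)
  write.table(nc$counts, file.path(out_dir, "noncoding_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  spectra <- lapply(merged, function(m) substitution_spectrum(m$variants))
  write.table(spectrum_matrix(spectra),
              file.path(out_dir, "spectrum.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dist_tabs <- lapply(setNames(conds, conds), function(cn) {
    v <- merged[[cn]]$variants
    distance_distribution(v[v$effect == "intergenic", , drop = FALSE], genome)
  })
  dist_tab <- data.frame(
    condition = conds,
    n_intergenic = vapply(dist_tabs, function(d) d$n, integer(1)),
    n_within_10kb = vapply(dist_tabs, function(d) d$n_within, integer(1)),
    fraction_within = vapply(dist_tabs, function(d) d$fraction_within,
                             numeric(1)),
    max_distance = vapply(dist_tabs, function(d)
      if (is.null(d$max_distance) || !length(d$max_distance)) NA_real_
      else as.numeric(d$max_distance), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  write.table(dist_tab, file.path(out_dir, "intergenic_distance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # per-condition variant BED tracks (0-based half-open, name = effect)
  for (cn in conds) {
    v <- merged[[cn]]$variants
    bed <- data.frame(v$contig, v$pos - 1L, v$pos - 1L + nchar(v$ref),
                      v$effect)
    write.table(bed, file.path(out_dir, sprintf("variants_%s.bed", cn)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }

  # --- sample metrics ---------------------------------------------------
  metrics <- comparisons <- NULL
  if (!is.null(config$classification)) {
    cls <- read_classification(config$classification)
    metrics <- compute_sample_metrics(cls, all_tracks, genome,
                                      target_genus = config$target_genus,
                                      min_depth = config$min_depth)
    write.table(metrics, file.path(out_dir, "sample_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    comparisons <- tryCatch(group_comparisons(metrics, "condition"),
                            warning = function(w) NULL,
                            error = function(e) NULL)
    if (!is.null(comparisons)) {
      write.table(comparisons, file.path(out_dir, "group_comparisons.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- report -----------------------------------------------------------
  merged_counts <- vapply(merged, function(m)
    length(unique(variant_key(m$variants))), integer(1))
  effect_counts <- lapply(merged, function(m) {
    v <- m$variants[!duplicated(paste(variant_key(m$variants),
                                      m$variants$effect)), , drop = FALSE]
    as.list(table(v$effect))
  })
  report <- list(
    parameters = list(seed = config$seed, iterations = config$iterations,
                      min_support = config$min_support,
                      min_depth = config$min_depth),
    raw_call_counts = as.list(n_raw),
    merged_counts = as.list(merged_counts),
    effect_counts = effect_counts,
    genome_kaks = gw_tab,
    genes_of_interest = goi_ids,
    null_test = null_result_summary(nt),
    pascal = pascal,
    friedman = if (!is.null(friedman))
      list(statistic = friedman$statistic, df = friedman$df,
           p_value = friedman$p_value) else NULL,
    noncoding_counts = nc$counts,
    intergenic_distance = dist_tab,
    sample_metrics = metrics
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_lines <- c(log_lines,
                 sprintf("condition %s: %d raw calls, %d merged variants",
                         conds, n_raw, merged_counts),
                 "completed")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  message(paste(log_lines, collapse = "\n"))
  invisible(report)
}
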