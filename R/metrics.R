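#' Read a taxonomic read-classification table
#'
#' @param path TSV with header columns `sample`, `taxon`, `reads`.
#' @return data.frame.
#' @export
read_classification <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "taxon", "reads") %in% names(tab)))
  tab
}

#' Per-sample purity and genome coverage
#'
#' Purity is the fraction of a sample's classified reads assigned to the
#' target genus; genome coverage is the breadth of coverage of the whole
#' reference at `min_depth`.
#'
#' @param classification data.frame (`sample`, `taxon`, `reads`).
#' @param tracks named list (sample id -> [depth_track()]).
#' @param genome an [annotated_genome()].
#' @param target_genus taxon counted as on-target (default `"Nostoc"`).
#' @param min_depth coverage threshold (default 1).
#' @return data.frame: `sample`, `condition`, `replicate` (parsed from
#'   `condition_replicate` sample ids where possible), `purity`,
#'   `genome_coverage`, `n_reads`. A sample with zero classified reads
#'   gets `NA` purity and a warning.
#' @export
compute_sample_metrics <- function(classification, tracks, genome,
                                   target_genus = "Nostoc", min_depth = 1) {
  stopifnot(is(genome, "annotated_genome"))
  samples <- unique(classification$sample)
  clens <- nchar(genome$contigs)
  rows <- lapply(samples, function(s) {
    sub <- classification[classification$sample == s, , drop = FALSE]
    total <- sum(sub$reads)
    purity <- if (total == 0) {
      warnf("sample '%s' has zero classified reads; purity undefined", s)
      NA_real_
    } else {
      sum(sub$reads[sub$taxon == target_genus]) / total
    }
    cov <- NA_real_
    if (s %in% names(tracks)) {
      tr <- tracks[[s]]
      covered_bp <- sum(vapply(names(clens), function(cn) {
        breadth_of_coverage(tr, cn, 1L, clens[[cn]], min_depth) * clens[[cn]]
      }, numeric(1)))
      cov <- covered_bp / genome$total_length
    }
    has_us <- grepl("_", s)
    data.frame(sample = s,
               condition = if (has_us) sub("_[^_]*$", "", s) else NA_character_,
               replicate = if (has_us) sub("^.*_", "", s) else NA_character_,
               purity = purity, genome_coverage = cov, n_reads = total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise group comparisons of sample metrics
#'
#' Student's t-tests (pooled variance by default) of each response
#' between every pair of groups.
#'
#' @param metrics data.frame from [compute_sample_metrics()].
#' @param group_col grouping column name (e.g. `"condition"`).
#' @param response_cols responses to compare (default purity and genome
#'   coverage).
#' @param equal_variance passed to [two_sample_t()].
#' @return data.frame with one row per (response, group pair): group
#'   means, SDs, sizes, `t`, `df`, `p_value`. Pairs with a group of
#'   fewer than 2 usable samples are skipped with a warning.
#' @export
group_comparisons <- function(metrics, group_col = "condition",
                              response_cols = c("purity", "genome_coverage"),
                              equal_variance = TRUE) {
  groups <- unique(metrics[[group_col]])
  groups <- groups[!is.na(groups)]
  if (length(groups) < 2L) stopf("need >= 2 groups in '%s'", group_col)
  cmb <- combn(length(groups), 2L)
  rows <- list()
  for (resp in response_cols) {
    for (j in seq_len(ncol(cmb))) {
      g1 <- groups[cmb[1, j]]
      g2 <- groups[cmb[2, j]]
      a <- metrics[[resp]][metrics[[group_col]] == g1]
      b <- metrics[[resp]][metrics[[group_col]] == g2]
      a <- a[!is.na(a)]
      b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) {
        warnf("skipping %s %s vs %s: group with < 2 usable samples",
              resp, g1, g2)
        next
      }
      tt <- two_sample_t(a, b, equal_variance = equal_variance)
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, group1 = g1, group2 = g2,
        mean1 = mean(a), mean2 = mean(b), sd1 = sd(a), sd2 = sd(b),
        n1 = length(a), n2 = length(b),
        t = tt$t, df = tt$df, p_value = tt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(response = character(0), group1 = character(0),
                      group2 = character(0), mean1 = numeric(0),
                      mean2 = numeric(0), sd1 = numeric(0), sd2 = numeric(0),
                      n1 = integer(0), n2 = integer(0), t = numeric(0),
                      df = numeric(0), p_value = numeric(0))
  }
  rownames(out) <- NULL
  out
}
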