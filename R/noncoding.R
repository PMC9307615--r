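#' Summarize noncoding variants across conditions
#'
#' Tallies intragenic-noncoding and intergenic variants per condition,
#' computes cross-condition sharing of noncoding variants (exact keys and
#' allele-agnostic positions, pairwise and across all conditions), and
#' runs a descriptive sliding-window scan for positional clusters shared
#' by every condition.
#'
#' @param merged_list named list (condition -> [merge_replicates()]
#'   result with effect-annotated variants).
#' @param genome an [annotated_genome()].
#' @param window sliding window width in bp for the hotspot scan
#'   (default 35000).
#' @param step window step (default `window / 5`).
#' @return list with `counts` (data.frame: condition,
#'   `intragenic_noncoding`, `intergenic`), `shared_exact` /
#'   `shared_position` (data.frames of pairwise shared noncoding counts,
#'   plus an `all_conditions` row), and `windows` (data.frame of window
#'   start/end with per-condition variant counts and a
#'   `shared_all` flag; purely descriptive, no inference attached).
#' @export
noncoding_summary <- function(merged_list, genome, window = 35000,
                              step = max(1, window %/% 5)) {
  stopifnot(is.list(merged_list), length(merged_list) >= 1L)
  conds <- names(merged_list) %||% vapply(merged_list, function(m)
    m$condition, character(1))
  nonc <- lapply(merged_list, function(m) {
    v <- if (is(m, "condition_variant_set")) m$variants else m
    v[v$effect %in% c("intragenic_noncoding", "intergenic"), , drop = FALSE]
  })
  names(nonc) <- conds
  counts <- data.frame(
    condition = conds,
    intragenic_noncoding = vapply(nonc, function(v)
      sum(!duplicated(variant_key(v)) & v$effect == "intragenic_noncoding"),
      integer(1)),
    intergenic = vapply(nonc, function(v)
      sum(!duplicated(variant_key(v)) & v$effect == "intergenic"), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  pair_share <- function(keyfun) {
    keysets <- lapply(nonc, function(v) unique(keyfun(v)))
    cmb <- if (length(conds) >= 2) combn(length(conds), 2L) else
      matrix(integer(0), 2, 0)
    rows <- lapply(seq_len(ncol(cmb)), function(j) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      data.frame(a = conds[i1], b = conds[i2],
                 shared = length(intersect(keysets[[i1]], keysets[[i2]])),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    all_row <- data.frame(a = "all", b = "all",
                          shared = length(Reduce(intersect, keysets)),
                          stringsAsFactors = FALSE)
    rbind(out, all_row)
  }

  # window scan over all merged variants (coding and noncoding alike):
  # hotspot structure is positional, not effect-specific
  starts <- seq(1, max(1, genome$total_length - window + 1L), by = step)
  win <- data.frame(start = starts, end = pmin(starts + window - 1L,
                                               genome$total_length))
  for (ci in seq_along(conds)) {
    m <- merged_list[[ci]]
    v <- if (is(m, "condition_variant_set")) m$variants else m
    v <- v[!duplicated(variant_key(v)), , drop = FALSE]
    gp <- if (nrow(v)) global_positions(genome, v$contig, v$pos) else numeric(0)
    win[[conds[ci]]] <- vapply(seq_len(nrow(win)), function(i)
      sum(gp >= win$start[i] & gp <= win$end[i]), integer(1))
  }
  win$shared_all <- rowSums(as.matrix(win[, conds, drop = FALSE]) > 0) ==
    length(conds)

  list(counts = counts,
       shared_exact = pair_share(variant_key),
       shared_position = pair_share(position_key),
       windows = win)
}

#' Distance-to-gene distribution of intergenic variants
#'
#' @param variants data.frame of intergenic variants (`contig`, `pos`;
#'   distances are recomputed from the genome, not trusted from input).
#' @param genome an [annotated_genome()].
#' @param threshold_bp reporting threshold (default 10000).
#' @return list with `distances` (per-variant bp), `fraction_within`
#'   (share of variants with distance <= threshold; `NA` for empty
#'   input), `n_within`, `n`, `max_distance`, `threshold_bp`.
#' @export
distance_distribution <- function(variants, genome, threshold_bp = 10000) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!nrow(v)) {
    return(list(distances = numeric(0), fraction_within = NA_real_,
                n_within = 0L, n = 0L, max_distance = NA_real_,
                threshold_bp = threshold_bp))
  }
  v <- v[!duplicated(variant_key(v)), , drop = FALSE]
  d <- unlist(lapply(split(seq_len(nrow(v)), v$contig), function(idx) {
    distance_to_nearest_gene(genome, v$contig[idx[1]], v$pos[idx])
  }), use.names = FALSE)
  list(distances = d,
       fraction_within = mean(d <= threshold_bp, na.rm = TRUE),
       n_within = sum(d <= threshold_bp, na.rm = TRUE),
       n = length(d),
       max_distance = max(d, na.rm = TRUE),
       threshold_bp = threshold_bp)
}

.PAIR_LEVELS <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                  "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Substitution spectrum of a variant set
#'
#' Twelve ordered reference>alternate pair counts for SNVs, a
#' GC-direction rollup (see [gc_direction()]), and a separate tally of
#' multi-base substitutions.
#'
#' @param variants data.frame with `ref`, `alt` (and optionally
#'   `contig`/`pos` for key-deduplication).
#' @param condition optional label stored on the result.
#' @return object of class `spectrum_table`: list with `condition`,
#'   `counts` (named integer vector over the 12 pairs), `gc_increase`,
#'   `gc_decrease`, `gc_neutral`, `mnv_count`, `n_snv`.
#' @export
substitution_spectrum <- function(variants, condition = NULL) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(v) && all(c("contig", "pos") %in% names(v))) {
    v <- v[!duplicated(variant_key(v)), , drop = FALSE]
  }
  snv <- v[nchar(v$ref) == 1L & nchar(v$alt) == 1L, , drop = FALSE]
  mnv_count <- nrow(v) - nrow(snv)
  pairs <- factor(paste0(snv$ref, ">", snv$alt), levels = .PAIR_LEVELS)
  counts <- table(pairs)
  gc <- gc_direction(snv$ref, snv$alt)
  structure(list(condition = condition %||%
                   (if (nrow(v) && "condition" %in% names(v)) v$condition[1]
                    else NA_character_),
                 counts = setNames(as.integer(counts), names(counts)),
                 gc_increase = sum(gc == "increase", na.rm = TRUE),
                 gc_decrease = sum(gc == "decrease", na.rm = TRUE),
                 gc_neutral = sum(gc == "neutral", na.rm = TRUE),
                 mnv_count = mnv_count,
                 n_snv = nrow(snv)),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("spectrum_table [%s]: %d SNV(s), %d MNV(s)\n",
              x$condition, x$n_snv, x$mnv_count))
  print(x$counts)
  cat(sprintf("GC: +%d / -%d / =%d\n",
              x$gc_increase, x$gc_decrease, x$gc_neutral))
  invisible(x)
}

#' Multi-condition spectrum table as a data.frame (rows = 12 pairs + MNV)
#' @param spectra named list of [substitution_spectrum()] results.
#' @return data.frame with a `pair` column and one count column per
#'   condition.
#' @export
spectrum_matrix <- function(spectra) {
  conds <- names(spectra) %||% vapply(spectra, function(s)
    as.character(s$condition), character(1))
  out <- data.frame(pair = c(.PAIR_LEVELS, "MNV"), stringsAsFactors = FALSE)
  for (i in seq_along(spectra)) {
    out[[conds[i]]] <- c(unname(spectra[[i]]$counts), spectra[[i]]$mnv_count)
  }
  out
}
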