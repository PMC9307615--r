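#' Genome-wide Ka/Ks ratio from raw effect counts
#'
#' Ka is the number of non-synonymous variants, Ks the number of
#' synonymous variants, over the whole merged set of a condition; the
#' ratio is taken on raw counts (no site normalization at genome scale).
#'
#' @param merged a [merge_replicates()] result whose variants carry an
#'   `effect` column, or a plain data.frame of annotated variants.
#' @param condition optional label override.
#' @return object of class `genome_kaks`: list with `condition`,
#'   `ka_total`, `ks_total`, `ratio` (full precision), `ratio_reported`
#'   (truncated to 2 decimals, the convention of published genome-wide
#'   Ka/Ks tables: 64/117 = 0.547 is reported as 0.54), and a logical
#'   `infinite` flag (set when `ks_total == 0` and `ka_total > 0`).
#' @export
genome_wide_kaks <- function(merged, condition = NULL) {
  v <- if (is(merged, "condition_variant_set")) merged$variants else
    as.data.frame(merged, stringsAsFactors = FALSE)
  if (!"effect" %in% names(v)) stopf("variants must be effect-annotated")
  condition <- condition %||%
    (if (is(merged, "condition_variant_set")) merged$condition else NA_character_)
  # a variant spanning overlapping genes appears once per gene in the
  # annotation table; count distinct keys per class
  v <- v[!duplicated(paste(variant_key(v), v$effect)), , drop = FALSE]
  ka <- sum(v$effect == "non_synonymous")
  ks <- sum(v$effect == "synonymous")
  inf <- ks == 0L && ka > 0L
  ratio <- if (ks > 0L) ka / ks else if (ka == 0L) NA_real_ else Inf
  structure(list(condition = condition, ka_total = ka, ks_total = ks,
                 ratio = ratio, ratio_reported = trunc_decimals(ratio, 2),
                 infinite = inf),
            class = "genome_kaks")
}

#' Truncate values to a number of decimal places (toward zero)
#'
#' The table-reporting convention for Ka/Ks ratios: 0.547 prints as 0.54.
#' Full precision is always kept internally.
#'
#' @param x numeric vector.
#' @param digits decimal places kept (default 2).
#' @return truncated numeric vector.
#' @export
trunc_decimals <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' @export
print.genome_kaks <- function(x, ...) {
  cat(sprintf("genome_kaks [%s]: Ka = %d, Ks = %d, Ka/Ks = %s\n",
              x$condition, x$ka_total, x$ks_total,
              if (is.na(x$ratio)) "undefined" else
                format(x$ratio_reported, nsmall = 2)))
  invisible(x)
}

#' Synonymous and non-synonymous site opportunity of a gene
#'
#' Nei-Gojobori-style site counting restricted to covered positions: for
#' each covered CDS position, the fraction of the 3 possible single-base
#' substitutions that preserve the amino acid contributes to the
#' synonymous site count, the remainder to the non-synonymous count.
#' Thus `syn_sites + nonsyn_sites` equals the number of covered positions
#' (positions in codons containing N are excluded and tallied).
#'
#' @param genome an [annotated_genome()].
#' @param gene gene id or record row (`kind == "CDS"`).
#' @param covered logical vector over the gene's positions in genomic
#'   order (`NULL` = fully covered).
#' @return list with `syn_sites`, `nonsyn_sites`, `n_covered`,
#'   `n_unknown`.
#' @export
potential_sites <- function(genome, gene, covered = NULL) {
  gr <- .get_gene(genome, gene)
  if (gr$kind != "CDS") stopf("gene '%s' is not a CDS", gr$gene_id)
  L <- gr$end - gr$start + 1L
  if (isFALSE(gr$frame_ok %||% TRUE)) {
    stopf("gene '%s' is out of frame", gr$gene_id)
  }
  if (is.null(covered)) covered <- rep(TRUE, L)
  stopifnot(length(covered) == L)
  if (!any(covered)) {
    return(list(syn_sites = 0, nonsyn_sites = 0, n_covered = 0L,
                n_unknown = 0L))
  }
  seq <- substring(genome$contigs[[gr$contig]], gr$start, gr$end)
  coding <- if (gr$strand == "+") seq else revcomp_chr(seq)
  codons <- substring(coding, seq(1L, L, 3L), seq(3L, L, 3L))
  M <- syn_fraction_matrix()
  known <- codons %in% rownames(M)
  # per coding position: synonymous fraction (NA inside N-codons)
  frac <- rep(NA_real_, L)
  idx <- which(known)
  for (o in 0:2) {
    frac[3L * (idx - 1L) + o + 1L] <- M[codons[idx], o + 1L]
  }
  # map genomic-order coverage onto coding order
  cov_coding <- if (gr$strand == "+") covered else rev(covered)
  use <- cov_coding & !is.na(frac)
  n_unknown <- sum(cov_coding & is.na(frac))
  list(syn_sites = sum(frac[use]),
       nonsyn_sites = sum(1 - frac[use]),
       n_covered = sum(cov_coding),
       n_unknown = n_unknown)
}

#' Per-gene Ka/Ks with breadth-of-coverage normalization
#'
#' For each in-frame CDS gene, variant counts from the condition's merged
#' set are converted to rates per covered potential site. A position is
#' "covered" for a condition when at least `min_covered_replicates`
#' replicate depth tracks reach `min_depth` there, mirroring the
#' concordance rule: only such positions could have produced a retained
#' variant.
#'
#' @param genome an [annotated_genome()].
#' @param merged a [merge_replicates()] result (effect-annotated).
#' @param tracks list of [depth_track()]s for the condition's replicates.
#' @param condition optional label (defaults to `merged$condition`).
#' @param min_depth per-position depth threshold (default 1).
#' @param min_covered_replicates replicates that must cover a position
#'   (default 2, matching the default concordance `min_support`).
#' @return data.frame with one row per evaluable gene: `gene_id`,
#'   `product`, `condition`, `ka_count`, `ks_count`, `covered_fraction`,
#'   `syn_sites`, `nonsyn_sites`, `ka_rate`, `ks_rate`, `ratio`
#'   (`Inf` when `ks_rate == 0 < ka_rate`, `NA` when the gene has no
#'   variants). Genes with zero covered positions are excluded and listed
#'   in the `"excluded_genes"` attribute.
#' @export
per_gene_kaks <- function(genome, merged, tracks, condition = NULL,
                          min_depth = 1, min_covered_replicates = 2) {
  stopifnot(is(genome, "annotated_genome"))
  condition <- condition %||%
    (if (is(merged, "condition_variant_set")) merged$condition else NA_character_)
  v <- if (is(merged, "condition_variant_set")) merged$variants else
    as.data.frame(merged, stringsAsFactors = FALSE)
  if (nrow(v) && !"effect" %in% names(v)) {
    stopf("merged variants must be effect-annotated")
  }
  genes <- genome$genes
  genes <- genes[genes$kind == "CDS" & !isFALSE(genes$frame_ok), , drop = FALSE]
  out <- vector("list", nrow(genes))
  excluded <- character(0)
  for (i in seq_len(nrow(genes))) {
    gr <- genes[i, , drop = FALSE]
    cnt <- coverage_counts(tracks, gr$contig, gr$start, gr$end, min_depth)
    covered <- cnt >= min_covered_replicates
    if (!any(covered)) {
      excluded <- c(excluded, gr$gene_id)
      next
    }
    sites <- potential_sites(genome, gr, covered)
    in_gene <- nrow(v) > 0 && any(sel <- (v$gene_id %in% gr$gene_id))
    ka <- if (in_gene) sum(v$effect[sel] == "non_synonymous") else 0L
    ks <- if (in_gene) sum(v$effect[sel] == "synonymous") else 0L
    ka_rate <- if (sites$nonsyn_sites > 0) ka / sites$nonsyn_sites else NA_real_
    ks_rate <- if (sites$syn_sites > 0) ks / sites$syn_sites else NA_real_
    ratio <- if (!is.na(ks_rate) && ks_rate > 0) {
      ka_rate / ks_rate
    } else if (ka > 0L) {
      Inf
    } else {
      NA_real_
    }
    out[[i]] <- data.frame(
      gene_id = gr$gene_id, product = gr$product, condition = condition,
      ka_count = ka, ks_count = ks,
      covered_fraction = mean(covered),
      syn_sites = sites$syn_sites, nonsyn_sites = sites$nonsyn_sites,
      ka_rate = ka_rate, ks_rate = ks_rate, ratio = ratio,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), product = character(0),
                      condition = character(0), ka_count = integer(0),
                      ks_count = integer(0), covered_fraction = numeric(0),
                      syn_sites = numeric(0), nonsyn_sites = numeric(0),
                      ka_rate = numeric(0), ks_rate = numeric(0),
                      ratio = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "excluded_genes") <- excluded
  res
}

#' Wide gene-by-condition Ka/Ks ratio table
#'
#' @param per_gene_list named list (condition -> [per_gene_kaks()]
#'   data.frame).
#' @param digits round ratios for reporting (default 2; set `NULL` to
#'   keep full precision).
#' @return data.frame: `gene_id`, `product`, one ratio column per
#'   condition, `n_variants` (total Ka+Ks over conditions).
#' @export
kaks_table <- function(per_gene_list, digits = 2) {
  stopifnot(is.list(per_gene_list), length(per_gene_list) >= 1L)
  conds <- names(per_gene_list) %||%
    vapply(per_gene_list, function(d) d$condition[1], character(1))
  base <- unique(do.call(rbind, lapply(per_gene_list, function(d)
    d[, c("gene_id", "product")])))
  tab <- base[order(base$gene_id), , drop = FALSE]
  total <- setNames(numeric(nrow(tab)), tab$gene_id)
  for (i in seq_along(per_gene_list)) {
    d <- per_gene_list[[i]]
    r <- setNames(d$ratio, d$gene_id)
    if (!is.null(digits)) r <- round(r, digits)
    tab[[conds[i]]] <- unname(r[tab$gene_id])
    n <- setNames(d$ka_count + d$ks_count, d$gene_id)
    hit <- tab$gene_id %in% names(n)
    total[tab$gene_id[hit]] <- total[tab$gene_id[hit]] + n[tab$gene_id[hit]]
  }
  tab$n_variants <- unname(total[tab$gene_id])
  rownames(tab) <- NULL
  tab
}

#' Select genes of interest across conditions
#'
#' A gene qualifies as *synonymous-dense* when its normalized Ka/Ks ratio
#' is strictly below `syn_dense` in at least `min_conditions` conditions
#' in which it carries at least one variant, and *non-synonymous
#' enriched* when the ratio is strictly above `upper` in at least
#' `min_conditions` such conditions. Ties at a threshold are excluded
#' (strict inequalities).
#'
#' @param per_gene_list named list (condition -> [per_gene_kaks()]
#'   data.frame) over the same gene universe.
#' @param upper non-synonymous enrichment threshold (default 1).
#' @param lower synonymous-leaning threshold (default 1); genes below it
#'   are labeled in the `syn_biased_conditions` count for reporting.
#' @param syn_dense synonymous-density threshold (default 0.2).
#' @param min_conditions minimum qualifying conditions (default 2).
#' @return data.frame sorted by total variant count (descending):
#'   `gene_id`, `product`, `n_variants`, per-class qualifying-condition
#'   counts, and `direction` (`"synonymous_dense"`,
#'   `"non_synonymous_enriched"`, or `"none"`).
#' @export
select_genes_of_interest <- function(per_gene_list, upper = 1.0, lower = 1.0,
                                     syn_dense = 0.2, min_conditions = 2) {
  stopifnot(is.list(per_gene_list), length(per_gene_list) >= 1L)
  all_ids <- unique(unlist(lapply(per_gene_list, function(d) d$gene_id),
                           use.names = FALSE))
  products <- character(0)
  for (d in per_gene_list) products[d$gene_id] <- d$product
  syn_dense_n <- syn_biased_n <- nonsyn_n <- nvar <-
    setNames(numeric(length(all_ids)), all_ids)
  for (d in per_gene_list) {
    has_var <- (d$ka_count + d$ks_count) >= 1L
    ratio <- d$ratio
    sd_hit <- has_var & !is.na(ratio) & ratio < syn_dense
    sb_hit <- has_var & !is.na(ratio) & ratio < lower
    ns_hit <- has_var & ((!is.na(ratio) & ratio > upper) | is.infinite(ratio))
    syn_dense_n[d$gene_id] <- syn_dense_n[d$gene_id] + sd_hit
    syn_biased_n[d$gene_id] <- syn_biased_n[d$gene_id] + sb_hit
    nonsyn_n[d$gene_id] <- nonsyn_n[d$gene_id] + ns_hit
    nvar[d$gene_id] <- nvar[d$gene_id] + d$ka_count + d$ks_count
  }
  direction <- rep("none", length(all_ids))
  direction[nonsyn_n >= min_conditions] <- "non_synonymous_enriched"
  direction[syn_dense_n >= min_conditions] <- "synonymous_dense"
  out <- data.frame(
    gene_id = all_ids,
    product = unname(products[all_ids]),
    n_variants = unname(nvar),
    syn_dense_conditions = unname(syn_dense_n),
    syn_biased_conditions = unname(syn_biased_n),
    nonsyn_conditions = unname(nonsyn_n),
    direction = direction,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_variants, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
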