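#' Merge per-replicate variant calls into a per-condition consensus
#'
#' Single-cell whole-genome amplification produces abundant spurious
#' calls unique to one cell. The concordance filter retains a variant
#' only if the exact same call -- identical `(contig, pos, ref, alt)`
#' key -- appears in at least `min_support` distinct replicates of the
#' condition.
#'
#' @param replicate_sets list of per-replicate variant data.frames
#'   (annotated or raw; columns `contig`, `pos`, `ref`, `alt` required).
#' @param condition condition label; defaults to the `condition` column
#'   of the first non-empty replicate.
#' @param min_support minimum number of distinct supporting replicates
#'   (default 2).
#' @return object of class `condition_variant_set`: list with
#'   `condition`, `variants` (one row per retained key, annotation
#'   columns taken from the first supporting replicate; overlapping-gene
#'   duplicates retained as one row per `(key, gene_id)`), and `support`
#'   (named integer vector, key -> replicate count, over all keys seen).
#' @details Duplicate keys within one replicate are counted once, with a
#'   warning. A condition with fewer than 2 replicates yields an empty
#'   consensus and a loud warning rather than an error (study designs may
#'   have 1-4 cells per condition).
#' @export
merge_replicates <- function(replicate_sets, condition = NULL,
                             min_support = 2) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 1L)
  reps <- lapply(replicate_sets, as.data.frame, stringsAsFactors = FALSE)
  if (is.null(condition)) {
    for (r in reps) {
      if (nrow(r) && "condition" %in% names(r)) {
        condition <- r$condition[1]
        break
      }
    }
    condition <- condition %||% NA_character_
  }
  if (length(reps) < min_support) {
    warnf(paste("condition '%s' has %d replicate(s), fewer than",
                "min_support = %d: consensus is empty"),
          condition, length(reps), min_support)
  }

  keys_by_rep <- lapply(reps, function(r) {
    if (!nrow(r)) return(character(0))
    k <- variant_key(r)
    if (anyDuplicated(k)) {
      warnf("duplicate variant key(s) within one replicate; counted once")
      k <- unique(k)
    }
    k
  })
  all_keys <- unlist(keys_by_rep, use.names = FALSE)
  support <- if (length(all_keys)) table(all_keys) else table(character(0))
  support <- setNames(as.integer(support), names(support))
  retained <- names(support)[support >= min_support]

  pooled <- do.call(rbind, lapply(reps, function(r) {
    if (nrow(r)) r else NULL
  }))
  if (is.null(pooled) || !length(retained)) {
    variants <- if (!is.null(pooled)) pooled[0, , drop = FALSE] else
      data.frame(contig = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))
  } else {
    pk <- variant_key(pooled)
    keep <- pk %in% retained
    sub <- pooled[keep, , drop = FALSE]
    gid <- if ("gene_id" %in% names(sub)) sub$gene_id else ""
    dedup_key <- paste(variant_key(sub), gid, sep = "|")
    variants <- sub[!duplicated(dedup_key), , drop = FALSE]
    variants <- variants[order(variants$contig, variants$pos, variants$alt), ,
                         drop = FALSE]
    rownames(variants) <- NULL
  }
  if ("replicate" %in% names(variants)) variants$replicate <- NULL
  if ("condition" %in% names(variants) && nrow(variants)) {
    variants$condition <- condition
  }
  structure(list(condition = condition, variants = variants,
                 support = support, min_support = min_support),
            class = "condition_variant_set")
}

#' @export
print.condition_variant_set <- function(x, ...) {
  n_keys <- length(unique(variant_key(x$variants)))
  cat(sprintf(
    "condition_variant_set '%s': %d variant(s) retained (support >= %d) of %d seen\n",
    x$condition, n_keys, x$min_support, length(x$support)))
  invisible(x)
}

#' Histogram of replicate support over all variant keys seen
#' @param cvs a [merge_replicates()] result.
#' @return table: support count -> number of keys.
#' @export
support_histogram <- function(cvs) {
  stopifnot(is(cvs, "condition_variant_set"))
  table(cvs$support)
}

#' Exact variants shared between two conditions
#'
#' Intersection on the full `(contig, pos, ref, alt)` key.
#'
#' @param a,b [merge_replicates()] results.
#' @return character vector of shared keys.
#' @export
shared_variants <- function(a, b) {
  intersect(unique(variant_key(a$variants)), unique(variant_key(b$variants)))
}

#' Positions shared between two conditions regardless of allele
#'
#' Intersects on `(contig, pos)` only, capturing loci hit in both
#' conditions even when the substituted base differs.
#'
#' @param a,b [merge_replicates()] results.
#' @return character vector of shared `contig:pos` keys.
#' @export
shared_positions <- function(a, b) {
  intersect(unique(position_key(a$variants)), unique(position_key(b$variants)))
}
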