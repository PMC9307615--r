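#' GC-content direction of a substitution
#'
#' A substitution from a weak base (A/T) to a strong base (G/C) increases
#' genomic GC content; the reverse decreases it; weak->weak and
#' strong->strong are neutral.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return character vector with values `"increase"`, `"decrease"`,
#'   `"neutral"`, or `NA` for non-ACGT input.
#' @export
gc_direction <- function(ref, alt) {
  strong <- c("G", "C")
  weak <- c("A", "T")
  out <- rep(NA_character_, length(ref))
  ok <- ref %in% .BASES & alt %in% .BASES
  out[ok & ref %in% weak & alt %in% strong] <- "increase"
  out[ok & ref %in% strong & alt %in% weak] <- "decrease"
  out[ok & is.na(out)] <- "neutral"
  out
}

#' Distance from a position to the nearest annotated gene
#'
#' Gap-style distance: the number of bases strictly between the position
#' and the nearest gene edge, plus one (so a position immediately
#' adjacent to a gene has distance 1). Positions inside a gene have
#' distance 0. Distances are never computed across contigs.
#'
#' @param genome an [annotated_genome()].
#' @param contig contig id.
#' @param pos 1-based position(s) on `contig`.
#' @return numeric vector of distances; `NA` (with a warning) for a
#'   contig that carries no annotated genes.
#' @export
distance_to_nearest_gene <- function(genome, contig, pos) {
  g <- genome$genes[genome$genes$contig == contig, , drop = FALSE]
  if (!nrow(g)) {
    warnf("contig '%s' has no annotated genes; distance undefined", contig)
    return(rep(NA_real_, length(pos)))
  }
  vapply(pos, function(p) {
    d <- pmax(g$start - p, p - g$end, 0)
    min(d)
  }, numeric(1))
}

# nearest gene id (ties broken toward the lower-coordinate gene)
nearest_gene_id <- function(genome, contig, pos) {
  g <- genome$genes[genome$genes$contig == contig, , drop = FALSE]
  if (!nrow(g)) return(rep(NA_character_, length(pos)))
  vapply(pos, function(p) {
    d <- pmax(g$start - p, p - g$end, 0)
    g$gene_id[which.min(d)]  # genes sorted by start; which.min takes first
  }, character(1))
}

#' Annotate variant calls with codon-level effect classes
#'
#' Classifies each substitution from first principles by rebuilding the
#' affected codon on the coding strand and translating reference and
#' mutated codons with the bacterial genetic code (table 11).
#'
#' Effect classes (mutually exclusive per gene context):
#' * `synonymous` -- SNV in a CDS, amino acid unchanged;
#' * `non_synonymous` -- SNV in a CDS, amino acid changed (including
#'   stop gain/loss);
#' * `intragenic_noncoding` -- SNV inside an annotated non-CDS feature
#'   (e.g. rRNA);
#' * `intergenic` -- SNV in no annotated feature; distance to the
#'   nearest gene is computed;
#' * `multi_bp` -- multi-base substitution (not decomposed);
#' * `unknown` -- codon contains N.
#'
#' @param genome an [annotated_genome()].
#' @param variants data.frame with columns `contig`, `pos` (1-based
#'   position of the first changed base), `ref`, `alt` (equal-length
#'   strings; indels are rejected with a warning), and optionally
#'   `condition`, `replicate`.
#' @return data.frame of annotated variants: input columns plus `effect`,
#'   `gene_id`, `aa_ref`, `aa_pos`, `aa_alt`, `distance_to_gene`,
#'   `gc_direction`. A variant inside overlapping genes yields one row
#'   per containing gene (the Ka/Ks stage counts it once per gene).
#' @details The reference allele is checked against the genome sequence;
#'   a mismatch is a hard error naming the position, guarding against
#'   coordinate drift between the VCF and the reference.
#' @export
classify_variants <- function(genome, variants) {
  stopifnot(is(genome, "annotated_genome"))
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!nrow(v)) {
    return(cbind(v, data.frame(effect = character(0), gene_id = character(0),
                               aa_ref = character(0), aa_pos = integer(0),
                               aa_alt = character(0),
                               distance_to_gene = numeric(0),
                               gc_direction = character(0))))
  }
  if (!"condition" %in% names(v)) v$condition <- NA_character_
  if (!"replicate" %in% names(v)) v$replicate <- NA_character_

  indel <- nchar(v$ref) != nchar(v$alt)
  if (any(indel)) {
    warnf("rejecting %d indel record(s) at ingest (substitutions only)",
          sum(indel))
    v <- v[!indel, , drop = FALSE]
  }
  if (!nrow(v)) return(classify_variants(genome, v[0, ]))
  if (any(v$ref == v$alt)) stopf("ref and alt must differ")

  # reference consistency check
  obs <- substring(genome$contigs[v$contig], v$pos, v$pos + nchar(v$ref) - 1L)
  bad <- which(obs != v$ref)
  if (length(bad)) {
    stopf("reference mismatch at %s:%d (VCF says %s, genome has %s)",
          v$contig[bad[1]], v$pos[bad[1]], v$ref[bad[1]], obs[bad[1]])
  }

  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    vi <- v[i, , drop = FALSE]
    base <- data.frame(
      vi,
      effect = NA_character_, gene_id = NA_character_,
      aa_ref = NA_character_, aa_pos = NA_integer_, aa_alt = NA_character_,
      distance_to_gene = NA_real_, gc_direction = NA_character_,
      stringsAsFactors = FALSE
    )
    if (nchar(vi$ref) > 1L) {
      hits <- gene_at(genome, vi$contig, vi$pos)
      base$effect <- "multi_bp"
      base$gene_id <- if (nrow(hits)) hits$gene_id[1] else NA_character_
      rows[[i]] <- base
      next
    }
    base$gc_direction <- gc_direction(vi$ref, vi$alt)
    hits <- gene_at(genome, vi$contig, vi$pos)
    if (!nrow(hits)) {
      base$effect <- "intergenic"
      base$distance_to_gene <-
        distance_to_nearest_gene(genome, vi$contig, vi$pos)
      rows[[i]] <- base
      next
    }
    per_gene <- lapply(seq_len(nrow(hits)), function(j) {
      gr <- hits[j, , drop = FALSE]
      out <- base
      out$gene_id <- gr$gene_id
      if (gr$kind != "CDS" || isFALSE(gr$frame_ok)) {
        out$effect <- "intragenic_noncoding"
        return(out)
      }
      cc <- codon_context(genome, gr, vi$pos)
      alt_coding <- if (gr$strand == "+") vi$alt else comp_base(vi$alt)
      mut <- cc$codon
      substring(mut, cc$offset_in_codon + 1L, cc$offset_in_codon + 1L) <-
        alt_coding
      aa1 <- cc$aa
      aa2 <- translate_codon(mut)
      if (is.na(aa1) || is.na(aa2)) {
        out$effect <- "unknown"
        return(out)
      }
      out$effect <- if (aa1 == aa2) "synonymous" else "non_synonymous"
      out$aa_ref <- aa1
      out$aa_pos <- cc$codon_index
      out$aa_alt <- aa2
      out
    })
    rows[[i]] <- do.call(rbind, per_gene)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write annotated variants as TSV (1-based positions)
#' @param variants data.frame from [classify_variants()].
#' @param path output path.
#' @return invisibly, `variants`.
#' @export
write_annotated_tsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(variants)
}
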