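#' Construct an annotated genome
#'
#' Bundles contig sequences with gene annotation into the coordinate
#' authority used by every downstream stage. Coordinates are 1-based
#' inclusive. Genes are single-interval features (bacterial model: no
#' introns/joins); overlapping genes are permitted by the data model.
#'
#' @param contigs named character vector of uppercase A/C/G/T/N sequences,
#'   one element per contig.
#' @param genes data.frame with columns `gene_id`, `contig`, `start`,
#'   `end` (1-based inclusive), `strand` (`"+"`/`"-"`), `kind` (`"CDS"`,
#'   `"rRNA"` or `"other"`), and optionally `product`.
#' @return object of class `annotated_genome` with elements `contigs`,
#'   `genes` (sorted by contig then start, with a logical `frame_ok`
#'   column flagging CDS whose length is a positive multiple of 3) and
#'   `total_length`.
#' @details A CDS whose length is not a multiple of 3 is flagged
#'   (`frame_ok = FALSE`) with a warning, never silently dropped; such
#'   genes are excluded from codon arithmetic but still occupy their
#'   interval for positional queries.
#' @export
annotated_genome <- function(contigs, genes) {
  if (is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == "")) {
    stopf("all contigs must be named")
  }
  if (anyDuplicated(names(contigs))) stopf("duplicate contig ids")
  contigs <- toupper(contigs)

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  needed <- c("gene_id", "contig", "start", "end", "strand", "kind")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols)) stopf("genes is missing columns: %s",
                                  paste(missing_cols, collapse = ", "))
  if (!"product" %in% names(genes)) genes$product <- ""
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id)) stopf("gene ids are not unique")
    bad_contig <- setdiff(unique(genes$contig), names(contigs))
    if (length(bad_contig)) {
      stopf("gene annotation references unknown contig(s): %s",
            paste(bad_contig, collapse = ", "))
    }
    if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
    if (!all(genes$kind %in% c("CDS", "rRNA", "other"))) {
      stopf("kind must be one of CDS, rRNA, other")
    }
    if (any(genes$start < 1L) || any(genes$start > genes$end)) {
      stopf("gene intervals must satisfy 1 <= start <= end")
    }
    clen <- nchar(contigs)[genes$contig]
    oob <- genes$end > clen
    if (any(oob)) {
      stopf("gene(s) extend beyond contig end: %s",
            paste(genes$gene_id[oob], collapse = ", "))
    }
    len <- genes$end - genes$start + 1L
    genes$frame_ok <- ifelse(genes$kind == "CDS", len %% 3L == 0L, NA)
    bad_frame <- which(genes$kind == "CDS" & !genes$frame_ok)
    if (length(bad_frame)) {
      warnf("CDS length not a multiple of 3 for: %s (flagged, kept)",
            paste(genes$gene_id[bad_frame], collapse = ", "))
    }
    genes <- genes[order(genes$contig, genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes$frame_ok <- logical(0)
  }

  structure(
    list(contigs = contigs, genes = genes,
         total_length = sum(nchar(contigs))),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d contig(s), %s bp, %d gene(s) (%d CDS)\n",
              length(x$contigs), format(x$total_length, big.mark = ","),
              nrow(x$genes), sum(x$genes$kind == "CDS")))
  invisible(x)
}

#' Read a reference genome from FASTA + GFF3
#'
#' @param fasta_path multi-contig FASTA file.
#' @param gff3_path GFF3 annotation (1-based inclusive coordinates);
#'   feature attributes should carry `ID` and `product`. Features of type
#'   `CDS` map to kind `"CDS"`, `rRNA` to `"rRNA"`, any other feature
#'   type (except region/chromosome/contig containers) to `"other"`.
#' @return an [annotated_genome()].
#' @details A GFF3 record referencing a contig absent from the FASTA, or
#'   extending past its contig end, is a hard error naming the offender.
#' @export
read_genome <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gff$type)
  keep <- !(type %in% c("region", "chromosome", "contig"))
  gff <- gff[keep]
  type <- type[keep]
  kind <- ifelse(type == "CDS", "CDS", ifelse(type == "rRNA", "rRNA", "other"))
  ids <- gff$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gff))
  fallback <- paste0("feature_", seq_along(gff))
  ids <- ifelse(is.na(ids) | ids == "", fallback, ids)
  product <- gff$product
  if (is.null(product)) product <- rep("", length(gff))
  product[is.na(product)] <- ""
  genes <- data.frame(
    gene_id = ids,
    contig = as.character(GenomeInfoDb::seqnames(gff)),
    start = BiocGenerics::start(gff),
    end = BiocGenerics::end(gff),
    strand = as.character(BiocGenerics::strand(gff)),
    kind = kind,
    product = product,
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  bad <- setdiff(unique(genes$contig), names(seqs))
  if (length(bad)) {
    stopf("GFF3 references contig(s) missing from FASTA: %s",
          paste(bad, collapse = ", "))
  }
  annotated_genome(as.character(seqs), genes)
}

#' Write an annotated genome to FASTA + GFF3
#'
#' Inverse of [read_genome()]; round-trips sequences and intervals.
#'
#' @param genome an [annotated_genome()].
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, `genome`.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  stopifnot(is(genome, "annotated_genome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs),
                              fasta_path)
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$contigs),
                     nchar(genome$contigs)))
  if (nrow(g)) {
    type <- ifelse(g$kind == "CDS", "CDS", ifelse(g$kind == "rRNA", "rRNA", "gene"))
    phase <- ifelse(g$kind == "CDS", "0", ".")
    attrs <- sprintf("ID=%s;product=%s", g$gene_id, g$product)
    lines <- c(lines, sprintf("%s\tkakscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                              g$contig, type, g$start, g$end, g$strand,
                              phase, attrs))
  }
  writeLines(lines, gff3_path)
  invisible(genome)
}

#' Genes containing a position
#'
#' @param genome an [annotated_genome()].
#' @param contig contig id.
#' @param pos 1-based position within the contig.
#' @return data.frame of gene records whose interval contains `pos`, in
#'   coordinate order; zero rows iff the position is intergenic.
#' @export
gene_at <- function(genome, contig, pos) {
  stopifnot(is(genome, "annotated_genome"), length(pos) == 1L)
  if (!contig %in% names(genome$contigs)) stopf("unknown contig '%s'", contig)
  if (pos < 1L || pos > nchar(genome$contigs[[contig]])) {
    stopf("position %d outside contig '%s' (length %d)",
          pos, contig, nchar(genome$contigs[[contig]]))
  }
  g <- genome$genes
  hit <- g$contig == contig & g$start <= pos & g$end >= pos
  out <- g[hit, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

.get_gene <- function(genome, gene) {
  if (is.character(gene) && length(gene) == 1L) {
    i <- match(gene, genome$genes$gene_id)
    if (is.na(i)) stopf("unknown gene '%s'", gene)
    return(genome$genes[i, , drop = FALSE])
  }
  as.data.frame(gene, stringsAsFactors = FALSE)
}

#' Codon context of a position within a CDS
#'
#' @param genome an [annotated_genome()].
#' @param gene gene id or a gene record row (`kind` must be `"CDS"` with
#'   in-frame length).
#' @param pos 1-based genomic position inside the gene.
#' @return list with `codon` (3-mer read 5'->3' on the coding strand;
#'   reverse-complemented for `-` strand genes), `offset_in_codon`
#'   (0..2 along the coding direction), `codon_index` (1-based codon
#'   number = amino-acid position), and `aa` (single-letter amino acid,
#'   `*` for stop, `NA` if the codon contains N). Translation uses the
#'   bacterial/archaeal genetic code (NCBI table 11).
#' @export
codon_context <- function(genome, gene, pos) {
  gr <- .get_gene(genome, gene)
  if (gr$kind != "CDS") stopf("gene '%s' is not a CDS", gr$gene_id)
  if (isFALSE(gr$frame_ok %||% TRUE)) {
    stopf("gene '%s' is out of frame (length not multiple of 3)", gr$gene_id)
  }
  if (pos < gr$start || pos > gr$end) {
    stopf("position %d outside gene '%s' [%d, %d]",
          pos, gr$gene_id, gr$start, gr$end)
  }
  seq <- genome$contigs[[gr$contig]]
  if (gr$strand == "+") {
    cds_off <- pos - gr$start            # 0-based offset along coding strand
  } else {
    cds_off <- gr$end - pos
  }
  codon_index <- cds_off %/% 3L
  offset <- cds_off %% 3L
  if (gr$strand == "+") {
    cstart <- gr$start + 3L * codon_index
    codon <- substring(seq, cstart, cstart + 2L)
  } else {
    cend <- gr$end - 3L * codon_index
    codon <- revcomp_chr(substring(seq, cend - 2L, cend))
  }
  list(codon = codon, offset_in_codon = offset,
       codon_index = codon_index + 1L, aa = translate_codon(codon))
}

#' Translate codons with the bacterial genetic code (table 11)
#'
#' @param codons character vector of 3-mers.
#' @return character vector of single-letter amino acids (`*` = stop);
#'   `NA` for codons containing non-ACGT characters.
#' @export
translate_codon <- function(codons) {
  code <- codon_table()
  out <- unname(code[codons])
  out
}

codon_table <- function() {
  if (is.null(.kakscan_env$code11)) {
    code <- Biostrings::getGeneticCode("11")
    .kakscan_env$code11 <- setNames(as.character(code), names(code))
  }
  .kakscan_env$code11
}

# 64 x 3 matrix: fraction of the 3 possible substitutions at each codon
# offset that are synonymous (Nei-Gojobori style site opportunity)
syn_fraction_matrix <- function() {
  if (!is.null(.kakscan_env$synfrac)) return(.kakscan_env$synfrac)
  code <- codon_table()
  codons <- names(code)
  M <- matrix(0, nrow = length(codons), ncol = 3,
              dimnames = list(codons, NULL))
  for (cd in codons) {
    for (o in 1:3) {
      refb <- substring(cd, o, o)
      alts <- setdiff(.BASES, refb)
      same <- vapply(alts, function(b) {
        mut <- cd
        substring(mut, o, o) <- b
        code[[mut]] == code[[cd]]
      }, logical(1))
      M[cd, o] <- mean(same)
    }
  }
  .kakscan_env$synfrac <- M
  M
}

# ---------------------------------------------------------------------------
# depth tracks

#' Construct a per-replicate depth track
#'
#' Run-length encoded per-base depth for one sequencing replicate.
#'
#' @param replicate_id sample/replicate label.
#' @param runs data.frame with columns `contig`, `start`, `end` (1-based
#'   inclusive) and `depth` (>= 0). Runs must be sorted and
#'   non-overlapping within each contig; positions not covered by any run
#'   have depth 0.
#' @return object of class `depth_track`.
#' @export
depth_track <- function(replicate_id, runs) {
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "start", "end", "depth") %in% names(runs)))
  if (nrow(runs)) {
    if (any(runs$start < 1L) || any(runs$start > runs$end)) {
      stopf("depth runs must satisfy 1 <= start <= end")
    }
    if (any(runs$depth < 0)) stopf("depth must be >= 0")
    runs <- runs[order(runs$contig, runs$start), , drop = FALSE]
    by_contig <- split(seq_len(nrow(runs)), runs$contig)
    for (idx in by_contig) {
      if (length(idx) > 1L &&
          any(runs$start[idx][-1] <= runs$end[idx][-length(idx)])) {
        stopf("overlapping depth runs in track '%s'", replicate_id)
      }
    }
    rownames(runs) <- NULL
  }
  structure(list(replicate_id = replicate_id, runs = runs),
            class = "depth_track")
}

#' Read a depth track from a 4-column BED-like TSV
#'
#' Columns: contig, start (0-based), end (exclusive), depth. Converted to
#' internal 1-based inclusive runs.
#'
#' @param path TSV file.
#' @param replicate_id label; default is the file name without extension.
#' @return a [depth_track()].
#' @export
read_depth_track <- function(path, replicate_id = NULL) {
  replicate_id <- replicate_id %||% sub("\\.[^.]*$", "", basename(path))
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("contig", "start", "end", "depth"),
                    colClasses = c("character", "integer", "integer", "numeric"))
  tab$start <- tab$start + 1L
  depth_track(replicate_id, tab)
}

#' Write a depth track as a 4-column BED-like TSV (0-based half-open)
#' @param track a [depth_track()].
#' @param path output path.
#' @return invisibly, `track`.
#' @export
write_depth_track <- function(track, path) {
  stopifnot(is(track, "depth_track"))
  out <- track$runs
  out$start <- out$start - 1L
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(track)
}

#' Breadth of coverage over an interval
#'
#' Fraction of interval positions with depth >= `min_depth`; the
#' normalizer behind coverage-adjusted Ka/Ks rates and the genome
#' coverage axis of the sample-metrics stage.
#'
#' @param track a [depth_track()].
#' @param contig contig id.
#' @param start,end 1-based inclusive interval bounds (`start <= end`).
#' @param min_depth a position counts as covered if its depth is at least
#'   this value (default 1: covered by any read).
#' @return fraction in `[0, 1]`.
#' @export
breadth_of_coverage <- function(track, contig, start, end, min_depth = 1) {
  stopifnot(is(track, "depth_track"))
  if (length(start) != 1L || length(end) != 1L || end < start) {
    stopf("empty or invalid interval [%s, %s]", start, end)
  }
  r <- track$runs
  r <- r[r$contig == contig & r$depth >= min_depth &
           r$end >= start & r$start <= end, , drop = FALSE]
  if (!nrow(r)) return(0)
  covered <- sum(pmin(r$end, end) - pmax(r$start, start) + 1L)
  covered / (end - start + 1L)
}

# per-position count of replicates covering [start, end] at >= min_depth
coverage_counts <- function(tracks, contig, start, end, min_depth = 1) {
  n <- end - start + 1L
  cnt <- integer(n)
  for (tr in tracks) {
    r <- tr$runs
    r <- r[r$contig == contig & r$depth >= min_depth &
             r$end >= start & r$start <= end, , drop = FALSE]
    if (nrow(r)) {
      for (i in seq_len(nrow(r))) {
        a <- max(r$start[i], start) - start + 1L
        b <- min(r$end[i], end) - start + 1L
        cnt[a:b] <- cnt[a:b] + 1L
      }
    }
  }
  cnt
}

# ---------------------------------------------------------------------------
# global (concatenated) coordinates used by the continuum null

contig_offsets <- function(genome) {
  len <- nchar(genome$contigs)
  off <- cumsum(c(0, len[-length(len)]))
  names(off) <- names(genome$contigs)
  off
}

global_positions <- function(genome, contig, pos) {
  off <- contig_offsets(genome)
  unname(off[contig]) + pos
}
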