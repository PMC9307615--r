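#' Read one replicate's variant calls from a VCF 4.2 file
#'
#' Multi-allelic records are split into one row per alternate allele at
#' ingest, so the concordance stage counts replicate support per exact
#' allele.
#'
#' @param path VCF file (haploid substitution calls).
#' @param condition,replicate labels attached to every record; by default
#'   parsed from the VCF sample name, expected as `condition_replicate`
#'   (last underscore separates the replicate).
#' @return data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `condition`, `replicate`.
#' @export
read_vcf_variants <- function(path, condition = NULL, replicate = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "ref")
  sample_name <- colnames(vcf)[1] %||% NA_character_
  if (is.null(condition) || is.null(replicate)) {
    if (!is.na(sample_name) && grepl("_", sample_name)) {
      condition <- condition %||% sub("_[^_]*$", "", sample_name)
      replicate <- replicate %||% sub("^.*_", "", sample_name)
    } else {
      condition <- condition %||% NA_character_
      replicate <- replicate %||% (sample_name %||% NA_character_)
    }
  }
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (!length(rr)) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      condition = character(0), replicate = character(0)))
  }
  data.frame(
    contig = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    condition = condition,
    replicate = replicate,
    stringsAsFactors = FALSE
  )
}

#' Write variant calls as a minimal VCF 4.2 file
#'
#' One sample column with haploid genotype `1` per record; used by the
#' synthetic-data generator.
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param path output path.
#' @param sample_name VCF sample column name (convention:
#'   `condition_replicate`).
#' @param contig_lengths named integer vector for `##contig` header lines.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, path, sample_name, contig_lengths) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  v <- v[order(v$contig, v$pos, v$alt), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kakscan",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)
  )
  body <- if (nrow(v)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t1",
            v$contig, v$pos, v$ref, v$alt)
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
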