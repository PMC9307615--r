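# Fixtures are built in code; no binary test data.

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Independent translation oracle: full-sequence Biostrings translate with
# the bacterial code, no initiator special-casing.
oracle_translate <- function(dna) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE))
}

# Hand-built miniature genome: two CDS (one per strand), one rRNA gene,
# and a second contig with no genes at all.
tiny_genome <- function() {
  geneA <- "ATGGGAGAATTTTGCTAA"         # '+' CDS, 11..28
  geneB_coding <- "ATGCCTGGGAAATGGTAA"  # '-' CDS, 41..58
  rrna <- paste(rep("ACGT", 8), collapse = "")  # 70..101
  c1 <- paste0("ACGTACGTAC",            # 1..10
               geneA,
               "GGGGCCCCAAAA",          # 29..40
               rc(geneB_coding),
               paste(rep("T", 11), collapse = ""),  # 59..69
               rrna,
               paste(rep("GA", 10), collapse = "")) # 102..121
  c2 <- paste(rep("ACGGT", 12), collapse = "")      # 60 bp, geneless
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "rrna1"),
    contig = "c1",
    start = c(11L, 41L, 70L),
    end = c(28L, 58L, 101L),
    strand = c("+", "-", "+"),
    kind = c("CDS", "CDS", "rRNA"),
    product = c("protein A", "protein B", "ribosomal RNA"),
    stringsAsFactors = FALSE)
  annotated_genome(c(c1 = c1, c2 = c2), genes)
}

# one-row variant data.frame
v1 <- function(contig, pos, ref, alt, condition = "c", replicate = "r1") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             condition = condition, replicate = replicate,
             stringsAsFactors = FALSE)
}

# small sim config for fast tests; any argument can be overridden
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_contigs = 1L, contig_length = 40000L,
               n_genes = 25L, mean_gene_length = 600L, n_rrna_genes = 1L,
               rrna_length = 800L, hotspot_genes = 4L,
               hotspot_variants_per_gene = 5L, n_intergenic_variants = 8L,
               n_intragenic_noncoding = 2L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# --------------------------------------------------------------------------
# exact big-integer binomial oracle (limb arithmetic, base 1e7):
# C(N, K) = prod(N - i, i = 0..K-1) / K!, returned as log(C).

big_mul_small <- function(limbs, m) {
  carry <- 0
  out <- numeric(0)
  for (l in limbs) {
    p <- l * m + carry
    out <- c(out, p %% 1e7)
    carry <- p %/% 1e7
  }
  while (carry > 0) {
    out <- c(out, carry %% 1e7)
    carry <- carry %/% 1e7
  }
  out
}

big_div_small <- function(limbs, d) {
  rem <- 0
  out <- numeric(length(limbs))
  for (i in rev(seq_along(limbs))) {
    cur <- rem * 1e7 + limbs[i]
    out[i] <- cur %/% d
    rem <- cur %% d
  }
  stopifnot(rem == 0)  # binomial coefficients are integers
  while (length(out) > 1 && out[length(out)] == 0) {
    out <- out[-length(out)]
  }
  out
}

big_log <- function(limbs) {
  n <- length(limbs)
  top <- limbs[n]
  if (n >= 2) top <- top + limbs[n - 1] * 1e-7
  if (n >= 3) top <- top + limbs[n - 2] * 1e-14
  log(top) + (n - 1) * log(1e7)
}

oracle_log_choose <- function(N, K) {
  if (K == 0) return(0)
  limbs <- 1
  for (i in 0:(K - 1)) limbs <- big_mul_small(limbs, N - i)
  limbs <- big_div_small(limbs, factorial(K))
  big_log(limbs)
}
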