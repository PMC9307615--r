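#' Configuration for the synthetic single-cell variant dataset
#'
#' The defaults state a scaled-down but structurally faithful world: a
#' multi-contig bacterial genome with non-overlapping CDS on both
#' strands, three exposure conditions with four single-cell replicates
#' each, hotspot variants recurring at identical positions across
#' replicates and (mostly) conditions, replicate-unique singleton noise
#' emulating amplification artifacts, partial uneven breadth of coverage,
#' a transition-enriched substitution spectrum, occasional adjacent
#' 2-bp substitutions, and a contaminant read fraction.
#'
#' @param seed RNG seed; identical configs give byte-identical outputs.
#' @param n_contigs,contig_length genome shape (default 2 x 120 kb).
#' @param n_genes number of protein-coding genes (default 120).
#' @param mean_gene_length mean CDS length in bp (default 900).
#' @param n_rrna_genes non-CDS (rRNA) genes so intragenic-noncoding
#'   variants have somewhere to live (default 2).
#' @param rrna_length rRNA gene length (default 1500).
#' @param conditions condition ids (default Ground_UV, ISS_UV, ISS_Dark).
#' @param replicates_per_condition single cells per condition (default 4).
#' @param hotspot_genes,hotspot_variants_per_gene planted hotspot
#'   structure (default 8 genes x 6 variants).
#' @param hotspot_nonsyn_fraction fraction of each hotspot gene's planted
#'   variants that are non-synonymous (default 0.2, i.e. synonymous-dense
#'   hotspots).
#' @param shared_across_conditions probability that a planted variant
#'   recurs in every condition rather than one (default 0.8).
#' @param n_intergenic_variants shared intergenic variants planted
#'   genome-wide (default 25).
#' @param n_intragenic_noncoding variants planted inside rRNA genes
#'   (default 3).
#' @param singleton_noise_rate spurious replicate-unique variants per Mb
#'   per replicate (default 50).
#' @param replicate_detection_prob probability that a replicate detects
#'   each true variant of its condition (default 0.9; models allele
#'   dropout).
#' @param breadth_mean expected per-replicate breadth of coverage
#'   (default 0.8).
#' @param covered_run_mean mean covered run length in bp (default 2000).
#' @param spectrum_weights named weights over the 12 ref>alt pairs;
#'   default enriches the four transitions (A>G, G>A, C>T, T>C) 4:1 over
#'   transversions.
#' @param mnv_rate fraction of planted intergenic and noise variants
#'   emitted as adjacent 2-bp substitutions (default 0.05).
#' @param contamination_fraction non-target-genus read fraction
#'   (default 0.1).
#' @param reads_per_sample mean classified reads per replicate
#'   (default 1e6).
#' @param min_intergenic_gap minimum gap between genes (default 50 bp,
#'   so intergenic analyses have support).
#' @param target_genus taxon label for on-target reads (default
#'   `"Nostoc"`).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 120000L,
                       n_genes = 120L,
                       mean_gene_length = 900L,
                       n_rrna_genes = 2L,
                       rrna_length = 1500L,
                       conditions = c("Ground_UV", "ISS_UV", "ISS_Dark"),
                       replicates_per_condition = 4L,
                       hotspot_genes = 8L,
                       hotspot_variants_per_gene = 6L,
                       hotspot_nonsyn_fraction = 0.2,
                       shared_across_conditions = 0.8,
                       n_intergenic_variants = 25L,
                       n_intragenic_noncoding = 3L,
                       singleton_noise_rate = 50,
                       replicate_detection_prob = 0.9,
                       breadth_mean = 0.8,
                       covered_run_mean = 2000,
                       spectrum_weights = NULL,
                       mnv_rate = 0.05,
                       contamination_fraction = 0.1,
                       reads_per_sample = 1e6,
                       min_intergenic_gap = 50L,
                       target_genus = "Nostoc") {
  if (is.null(spectrum_weights)) {
    spectrum_weights <- setNames(rep(1, 12), .PAIR_LEVELS)
    spectrum_weights[c("A>G", "G>A", "C>T", "T>C")] <- 4
  }
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes),
              mean_gene_length = as.integer(mean_gene_length),
              n_rrna_genes = as.integer(n_rrna_genes),
              rrna_length = as.integer(rrna_length),
              conditions = conditions,
              replicates_per_condition = as.integer(replicates_per_condition),
              hotspot_genes = as.integer(hotspot_genes),
              hotspot_variants_per_gene = as.integer(hotspot_variants_per_gene),
              hotspot_nonsyn_fraction = hotspot_nonsyn_fraction,
              shared_across_conditions = shared_across_conditions,
              n_intergenic_variants = as.integer(n_intergenic_variants),
              n_intragenic_noncoding = as.integer(n_intragenic_noncoding),
              singleton_noise_rate = singleton_noise_rate,
              replicate_detection_prob = replicate_detection_prob,
              breadth_mean = breadth_mean,
              covered_run_mean = covered_run_mean,
              spectrum_weights = spectrum_weights,
              mnv_rate = mnv_rate,
              contamination_fraction = contamination_fraction,
              reads_per_sample = reads_per_sample,
              min_intergenic_gap = as.integer(min_intergenic_gap),
              target_genus = target_genus)
  probs <- c(cfg$hotspot_nonsyn_fraction, cfg$shared_across_conditions,
             cfg$replicate_detection_prob, cfg$breadth_mean, cfg$mnv_rate,
             cfg$contamination_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    stopf("all probability parameters must lie in [0, 1]")
  }
  counts <- c(cfg$n_contigs, cfg$contig_length, cfg$n_genes,
              cfg$hotspot_genes, cfg$hotspot_variants_per_gene,
              cfg$n_intergenic_variants, cfg$n_intragenic_noncoding)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (cfg$hotspot_genes > cfg$n_genes) {
    stopf("more hotspot genes (%d) than genes (%d)",
          cfg$hotspot_genes, cfg$n_genes)
  }
  if (!all(names(cfg$spectrum_weights) %in% .PAIR_LEVELS)) {
    stopf("spectrum_weights names must be ref>alt pairs like 'A>G'")
  }
  structure(cfg, class = "sim_config")
}

.NONSTOP_CODONS <- NULL  # computed lazily

nonstop_codons <- function() {
  if (is.null(.kakscan_env$nonstop)) {
    code <- codon_table()
    .kakscan_env$nonstop <- names(code)[code != "*"]
  }
  .kakscan_env$nonstop
}

.PRODUCT_VOCAB <- c("mobile element protein",
                    "transposase",
                    "photosystem II D1 protein",
                    "vitamin B12 ABC transporter ATP-binding protein",
                    "high light inducible protein",
                    "filamentous hemagglutinin family protein")

# generate the synthetic genome: non-overlapping genes on both strands,
# stop-free CDS ending in a stop codon, >= min_gap intergenic spacing
sim_genome <- function(cfg) {
  n_feat <- cfg$n_genes + cfg$n_rrna_genes
  is_rrna <- c(rep(FALSE, cfg$n_genes), rep(TRUE, cfg$n_rrna_genes))
  is_rrna <- sample(is_rrna)
  feat_len <- integer(n_feat)
  feat_seq <- character(n_feat)
  for (i in seq_len(n_feat)) {
    if (is_rrna[i]) {
      feat_len[i] <- cfg$rrna_length
      feat_seq[i] <- paste(sample(.BASES, cfg$rrna_length, replace = TRUE),
                           collapse = "")
    } else {
      ncod <- max(30L, as.integer(round(rnorm(1, cfg$mean_gene_length / 3,
                                              cfg$mean_gene_length / 9))))
      feat_len[i] <- 3L * ncod
      feat_seq[i] <- paste(c("ATG",
                             sample(nonstop_codons(), ncod - 2L, replace = TRUE),
                             sample(c("TAA", "TAG", "TGA"), 1L)),
                           collapse = "")
    }
  }
  need <- sum(feat_len) + n_feat * (cfg$min_intergenic_gap + 50L)
  if (need > cfg$n_contigs * cfg$contig_length) {
    stopf("infeasible config: features need ~%d bp but genome has %d bp",
          need, cfg$n_contigs * cfg$contig_length)
  }

  contig_names <- sprintf("contig_%02d", seq_len(cfg$n_contigs))
  pieces <- setNames(vector("list", cfg$n_contigs), contig_names)
  cursor <- setNames(rep(1L, cfg$n_contigs), contig_names)
  genes <- vector("list", n_feat)
  ci <- 1L
  gi <- 0L
  for (i in seq_len(n_feat)) {
    gap <- cfg$min_intergenic_gap + rgeom(1, 1 / 50)
    placed <- FALSE
    for (try in seq_len(cfg$n_contigs)) {
      cname <- contig_names[ci]
      start <- cursor[cname] + gap
      end <- start + feat_len[i] - 1L
      if (end <= cfg$contig_length - cfg$min_intergenic_gap) {
        strand <- sample(c("+", "-"), 1L)
        seq_fwd <- if (strand == "+") feat_seq[i] else revcomp_chr(feat_seq[i])
        pieces[[cname]] <- c(pieces[[cname]],
                             paste(sample(.BASES, gap, replace = TRUE),
                                   collapse = ""),
                             seq_fwd)
        gi <- gi + 1L
        genes[[gi]] <- data.frame(
          gene_id = sprintf("gene_%04d", gi),
          contig = cname, start = as.integer(start), end = as.integer(end),
          strand = strand,
          kind = if (is_rrna[i]) "rRNA" else "CDS",
          product = if (is_rrna[i]) "ribosomal RNA" else "hypothetical protein",
          stringsAsFactors = FALSE
        )
        cursor[cname] <- end + 1L
        placed <- TRUE
        break
      }
      ci <- ci %% cfg$n_contigs + 1L
    }
    if (!placed) stopf("infeasible config: ran out of genome space at feature %d", i)
    ci <- ci %% cfg$n_contigs + 1L
  }
  contigs <- vapply(contig_names, function(cname) {
    tail_len <- cfg$contig_length - cursor[cname] + 1L
    paste(c(pieces[[cname]],
            paste(sample(.BASES, tail_len, replace = TRUE), collapse = "")),
          collapse = "")
  }, character(1))
  annotated_genome(contigs, do.call(rbind, genes))
}

# sample an alternate base for `ref` from the spectrum weights
sample_alt <- function(ref, weights) {
  alts <- setdiff(.BASES, ref)
  w <- weights[paste0(ref, ">", alts)]
  w[is.na(w)] <- 1
  sample(alts, 1L, prob = w)
}

# enumerate all single-base substitutions in a CDS with their effect
# (vectorized: 3 alternate alleles per coding position)
.gene_substitutions <- function(genome, gr) {
  L <- gr$end - gr$start + 1L
  seq <- substring(genome$contigs[[gr$contig]], gr$start, gr$end)
  coding <- if (gr$strand == "+") seq else revcomp_chr(seq)
  code <- codon_table()
  ncod <- L %/% 3L
  codons <- substring(coding, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  aa1 <- unname(code[codons])
  cp <- seq_len(L)
  ci <- (cp - 1L) %/% 3L + 1L
  off <- (cp - 1L) %% 3L
  refb <- substring(coding, cp, cp)
  alt_map <- lapply(setNames(.BASES, .BASES), function(b) setdiff(.BASES, b))
  alts <- unlist(alt_map[refb], use.names = FALSE)
  cod3 <- rep(codons[ci], each = 3L)
  off3 <- rep(off, each = 3L)
  mut <- paste0(substring(cod3, 1L, off3), alts,
                substring(cod3, off3 + 2L, 3L))
  syn <- unname(code[mut]) == rep(aa1[ci], each = 3L)
  gpos <- if (gr$strand == "+") gr$start + cp - 1L else gr$end - cp + 1L
  data.frame(
    pos = rep(gpos, each = 3L),
    ref = if (gr$strand == "+") rep(refb, each = 3L) else
      comp_base(rep(refb, each = 3L)),
    alt = if (gr$strand == "+") alts else comp_base(alts),
    synonymous = syn,
    stringsAsFactors = FALSE
  )
}

.site_mutation <- function(genome, gene, synonymous, exclude_pos = NULL,
                           spectrum_weights = NULL) {
  gr <- .get_gene(genome, gene)
  if (gr$kind != "CDS") stopf("gene '%s' is not a CDS", gr$gene_id)
  cand <- .gene_substitutions(genome, gr)
  cand <- cand[cand$synonymous == synonymous, , drop = FALSE]
  if (!is.null(exclude_pos)) {
    cand <- cand[!cand$pos %in% exclude_pos, , drop = FALSE]
  }
  if (!nrow(cand)) {
    stopf("gene '%s' has no feasible %s site",
          gr$gene_id, if (synonymous) "synonymous" else "non-synonymous")
  }
  w <- if (is.null(spectrum_weights)) rep(1, nrow(cand)) else {
    ww <- spectrum_weights[paste0(cand$ref, ">", cand$alt)]
    ww[is.na(ww)] <- 1
    ww
  }
  pick <- cand[sample(nrow(cand), 1L, prob = w), , drop = FALSE]
  data.frame(contig = gr$contig, pos = pick$pos, ref = pick$ref,
             alt = pick$alt, stringsAsFactors = FALSE)
}

#' Draw a guaranteed-synonymous (or non-synonymous) SNV in a gene
#'
#' Enumerates every single-base substitution in the CDS, keeps those of
#' the requested effect (by codon comparison under genetic code 11) and
#' samples one, optionally weighting by the substitution spectrum. Used
#' by the generator to plant Ka/Ks ground truth.
#'
#' @param genome an [annotated_genome()].
#' @param gene gene id or record row (CDS).
#' @param exclude_pos genomic positions to avoid (already used).
#' @param spectrum_weights optional named ref>alt weights.
#' @return one-row data.frame: `contig`, `pos`, `ref`, `alt`.
#' @details A gene whose codons admit no synonymous change (e.g. only
#'   ATG/TGG) raises an error rather than looping forever.
#' @export
synonymous_site_mutation <- function(genome, gene, exclude_pos = NULL,
                                     spectrum_weights = NULL) {
  .site_mutation(genome, gene, TRUE, exclude_pos, spectrum_weights)
}

#' @rdname synonymous_site_mutation
#' @export
nonsynonymous_site_mutation <- function(genome, gene, exclude_pos = NULL,
                                        spectrum_weights = NULL) {
  .site_mutation(genome, gene, FALSE, exclude_pos, spectrum_weights)
}

# draw a fresh position avoiding `used`: intergenic by default,
# anywhere in the genome (`anywhere = TRUE`), or inside a gene of a kind
.draw_position <- function(genome, lookup, used, want_gene_kind = NULL,
                           width = 1L, max_tries = 10000L, anywhere = FALSE) {
  g <- genome$genes
  for (t in seq_len(max_tries)) {
    if (is.null(want_gene_kind)) {
      gp <- floor(runif(1) * (genome$total_length - width)) + 1
      if (!anywhere) {
        idx <- locate_genes(gp, lookup)
        idx2 <- locate_genes(gp + width - 1L, lookup)
        if (idx != 0L || idx2 != 0L) next
      }
      # map back to contig coordinates
      off <- contig_offsets(genome)
      cidx <- findInterval(gp, off + 1)
      cname <- names(off)[cidx]
      pos <- gp - off[cidx]
      if (pos + width - 1L > nchar(genome$contigs[[cname]])) next
    } else {
      rr <- g[g$kind == want_gene_kind, , drop = FALSE]
      if (!nrow(rr)) stopf("no gene of kind '%s' to place variant in",
                           want_gene_kind)
      row <- rr[sample(nrow(rr), 1L), , drop = FALSE]
      pos <- row$start + floor(runif(1) * (row$end - row$start - width + 1L))
      cname <- row$contig
    }
    key <- paste(cname, pos)
    keys <- paste(cname, pos:(pos + width - 1L))
    if (!any(keys %in% used)) {
      return(list(contig = unname(cname), pos = as.integer(pos), keys = keys))
    }
  }
  stopf("could not place a variant after %d tries (genome too dense?)",
        max_tries)
}

.substitute_at <- function(genome, contig, pos, width, weights) {
  ref <- substring(genome$contigs[[contig]], pos, pos + width - 1L)
  alt_chars <- vapply(strsplit(ref, "")[[1]], sample_alt, character(1),
                      weights = weights)
  list(ref = ref, alt = paste(alt_chars, collapse = ""))
}

#' Simulate a complete synthetic single-cell variant dataset
#'
#' Generates the genome, plants hotspot / intergenic / intragenic
#' ground-truth variants, emits per-replicate variant calls with allele
#' dropout and replicate-unique singleton noise, builds depth tracks and
#' a read-classification table, and optionally writes everything to disk
#' (FASTA, GFF3, one VCF 4.2 per replicate, depth TSVs, classification
#' TSV, ground-truth JSON).
#'
#' @param config a [sim_config()].
#' @param out_dir if non-NULL, directory to write all artifacts into
#'   (created if needed).
#' @return list with `config`, `genome`, `truth` (list: `hotspot_genes`,
#'   `variants` data.frame with construction-derived `effect` and
#'   `conditions`, `noise` data.frame, `by_condition` split of true
#'   variants), `replicates` (condition -> replicate -> call data.frame),
#'   `tracks` (condition -> replicate -> [depth_track()]),
#'   `classification` (sample/taxon/reads data.frame), and `paths` when
#'   `out_dir` is given.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(is(config, "sim_config"))
  cfg <- config
  local_seed(cfg$seed, {
    genome <- sim_genome(cfg)
    lookup <- gene_lookup(genome)
    used <- character(0)
    weights <- cfg$spectrum_weights

    # --- hotspot variants in CDS genes ----------------------------------
    cds_ids <- genome$genes$gene_id[genome$genes$kind == "CDS"]
    hot_ids <- if (cfg$hotspot_genes > 0L) {
      sort(sample(cds_ids, cfg$hotspot_genes))
    } else {
      character(0)
    }
    if (length(hot_ids)) {
      gi <- match(hot_ids, genome$genes$gene_id)
      genome$genes$product[gi] <-
        .PRODUCT_VOCAB[(seq_along(gi) - 1L) %% length(.PRODUCT_VOCAB) + 1L]
    }
    truth_rows <- list()
    n_ns <- round(cfg$hotspot_nonsyn_fraction * cfg$hotspot_variants_per_gene)
    n_syn <- cfg$hotspot_variants_per_gene - n_ns
    for (gid in hot_ids) {
      gene_used <- integer(0)
      for (j in seq_len(n_syn)) {
        mv <- synonymous_site_mutation(genome, gid, exclude_pos = gene_used,
                                       spectrum_weights = weights)
        gene_used <- c(gene_used, mv$pos)
        truth_rows[[length(truth_rows) + 1L]] <-
          cbind(mv, effect = "synonymous", gene_id = gid,
                category = "hotspot", stringsAsFactors = FALSE)
      }
      for (j in seq_len(n_ns)) {
        mv <- nonsynonymous_site_mutation(genome, gid, exclude_pos = gene_used,
                                          spectrum_weights = weights)
        gene_used <- c(gene_used, mv$pos)
        truth_rows[[length(truth_rows) + 1L]] <-
          cbind(mv, effect = "non_synonymous", gene_id = gid,
                category = "hotspot", stringsAsFactors = FALSE)
      }
      used <- c(used, paste(genome$genes$contig[match(gid, genome$genes$gene_id)],
                            gene_used))
    }

    # --- intergenic and intragenic-noncoding variants -------------------
    for (j in seq_len(cfg$n_intergenic_variants)) {
      width <- if (runif(1) < cfg$mnv_rate) 2L else 1L
      spot <- .draw_position(genome, lookup, used, NULL, width)
      used <- c(used, spot$keys)
      sub <- .substitute_at(genome, spot$contig, spot$pos, width, weights)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        contig = spot$contig, pos = spot$pos, ref = sub$ref, alt = sub$alt,
        effect = if (width > 1L) "multi_bp" else "intergenic",
        gene_id = NA_character_, category = "intergenic",
        stringsAsFactors = FALSE)
    }
    for (j in seq_len(cfg$n_intragenic_noncoding)) {
      spot <- .draw_position(genome, lookup, used, "rRNA", 1L)
      used <- c(used, spot$keys)
      sub <- .substitute_at(genome, spot$contig, spot$pos, 1L, weights)
      hits <- gene_at(genome, spot$contig, spot$pos)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        contig = spot$contig, pos = spot$pos, ref = sub$ref, alt = sub$alt,
        effect = "intragenic_noncoding", gene_id = hits$gene_id[1],
        category = "intragenic_noncoding", stringsAsFactors = FALSE)
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(contig = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), effect = character(0),
                 gene_id = character(0), category = character(0))

    # --- assign conditions ---------------------------------------------
    if (nrow(truth)) {
      shared <- runif(nrow(truth)) < cfg$shared_across_conditions
      cond_of <- sample(cfg$conditions, nrow(truth), replace = TRUE)
      truth$shared <- shared
      truth$conditions <- ifelse(shared,
                                 paste(cfg$conditions, collapse = ";"),
                                 cond_of)
    } else {
      truth$shared <- logical(0)
      truth$conditions <- character(0)
    }
    by_condition <- lapply(setNames(cfg$conditions, cfg$conditions),
                           function(cn) {
      sel <- vapply(strsplit(truth$conditions, ";"), function(x)
        cn %in% x, logical(1))
      truth[sel, , drop = FALSE]
    })

    # --- per-replicate emission ----------------------------------------
    rep_ids <- sprintf("rep%d", seq_len(cfg$replicates_per_condition))
    replicates <- list()
    noise_rows <- list()
    mb <- genome$total_length / 1e6
    for (cn in cfg$conditions) {
      tv <- by_condition[[cn]]
      replicates[[cn]] <- list()
      for (rid in rep_ids) {
        det <- if (nrow(tv)) runif(nrow(tv)) < cfg$replicate_detection_prob
               else logical(0)
        calls <- tv[det, c("contig", "pos", "ref", "alt"), drop = FALSE]
        n_noise <- rpois(1, cfg$singleton_noise_rate * mb)
        for (j in seq_len(n_noise)) {
          width <- if (runif(1) < cfg$mnv_rate) 2L else 1L
          spot <- tryCatch(
            .draw_position(genome, lookup, used, NULL, width, anywhere = TRUE),
            error = function(e) NULL)
          if (is.null(spot)) next
          used <- c(used, spot$keys)
          sub <- .substitute_at(genome, spot$contig, spot$pos, width, weights)
          nr <- data.frame(contig = spot$contig, pos = spot$pos,
                           ref = sub$ref, alt = sub$alt,
                           stringsAsFactors = FALSE)
          calls <- rbind(calls, nr)
          noise_rows[[length(noise_rows) + 1L]] <-
            cbind(nr, condition = cn, replicate = rid,
                  stringsAsFactors = FALSE)
        }
        if (nrow(calls)) {
          calls$condition <- cn
          calls$replicate <- rid
          calls <- calls[order(calls$contig, calls$pos, calls$alt), ,
                         drop = FALSE]
          rownames(calls) <- NULL
        } else {
          calls <- data.frame(contig = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              condition = character(0),
                              replicate = character(0))
        }
        replicates[[cn]][[rid]] <- calls
      }
    }
    noise <- if (length(noise_rows)) do.call(rbind, noise_rows) else
      data.frame(contig = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), condition = character(0),
                 replicate = character(0))

    # --- depth tracks ---------------------------------------------------
    tracks <- list()
    uncov_mean <- max(1, cfg$covered_run_mean *
                        (1 - cfg$breadth_mean) / max(cfg$breadth_mean, 1e-6))
    for (cn in cfg$conditions) {
      tracks[[cn]] <- list()
      for (rid in rep_ids) {
        runs <- list()
        for (cname in names(genome$contigs)) {
          clen <- nchar(genome$contigs[[cname]])
          pos <- 1L
          covered <- runif(1) < cfg$breadth_mean
          starts <- ends <- integer(0)
          while (pos <= clen) {
            len <- 1L + rgeom(1, 1 / (if (covered) cfg$covered_run_mean
                                      else uncov_mean))
            to <- min(clen, pos + len - 1L)
            if (covered) {
              starts <- c(starts, pos)
              ends <- c(ends, to)
            }
            pos <- to + 1L
            covered <- !covered
          }
          # force coverage around this replicate's emitted calls
          calls <- replicates[[cn]][[rid]]
          cp <- calls$pos[calls$contig == cname]
          if (length(cp)) {
            starts <- c(starts, pmax(1L, cp - 50L))
            ends <- c(ends, pmin(clen, cp + 51L))
          }
          if (length(starts)) {
            ir <- IRanges::reduce(IRanges::IRanges(starts, ends))
            runs[[cname]] <- data.frame(
              contig = cname,
              start = BiocGenerics::start(ir),
              end = BiocGenerics::end(ir),
              depth = 10 + rpois(length(ir), 5),
              stringsAsFactors = FALSE)
          }
        }
        tracks[[cn]][[rid]] <- depth_track(paste(cn, rid, sep = "_"),
                                           do.call(rbind, runs))
      }
    }

    # --- read classification -------------------------------------------
    contaminants <- c("Pseudomonas", "Ralstonia", "Cutibacterium")
    class_rows <- list()
    for (cn in cfg$conditions) {
      for (rid in rep_ids) {
        total <- round(cfg$reads_per_sample * runif(1, 0.5, 1.5))
        target <- round((1 - cfg$contamination_fraction) * total)
        rest <- total - target
        split3 <- as.integer(rmultinom(1, rest, rep(1 / 3, 3)))
        class_rows[[length(class_rows) + 1L]] <- data.frame(
          sample = paste(cn, rid, sep = "_"),
          taxon = c(cfg$target_genus, contaminants),
          reads = c(target, split3),
          stringsAsFactors = FALSE)
      }
    }
    classification <- do.call(rbind, class_rows)

    result <- list(config = cfg, genome = genome,
                   truth = list(hotspot_genes = hot_ids, variants = truth,
                                noise = noise, by_condition = by_condition),
                   replicates = replicates, tracks = tracks,
                   classification = classification)

    if (!is.null(out_dir)) {
      result$paths <- write_dataset(result, out_dir)
    }
    result
  })
}

# write all artifacts of a simulated dataset; returns the path manifest
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE)
  genome <- sim$genome
  fasta <- file.path(out_dir, "genome.fasta")
  gff3 <- file.path(out_dir, "genome.gff3")
  write_genome(genome, fasta, gff3)
  clen <- setNames(nchar(genome$contigs), names(genome$contigs))
  vcfs <- list()
  depths <- list()
  for (cn in names(sim$replicates)) {
    vcfs[[cn]] <- character(0)
    depths[[cn]] <- character(0)
    for (rid in names(sim$replicates[[cn]])) {
      sample_name <- paste(cn, rid, sep = "_")
      vp <- file.path(out_dir, "vcf", paste0(sample_name, ".vcf"))
      write_vcf(sim$replicates[[cn]][[rid]], vp, sample_name, clen)
      vcfs[[cn]] <- c(vcfs[[cn]], vp)
      dp <- file.path(out_dir, "depth", paste0(sample_name, ".tsv"))
      write_depth_track(sim$tracks[[cn]][[rid]], dp)
      depths[[cn]] <- c(depths[[cn]], dp)
    }
  }
  class_path <- file.path(out_dir, "classification.tsv")
  write.table(sim$classification, class_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(hotspot_genes = sim$truth$hotspot_genes,
         variants = sim$truth$variants,
         noise = sim$truth$noise),
    truth_path, auto_unbox = TRUE, digits = NA)
  list(fasta = fasta, gff3 = gff3, vcf = vcfs, depth = depths,
       classification = class_path, ground_truth = truth_path)
}
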