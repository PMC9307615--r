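test_that("sim_config validates parameters", {
  expect_error(sim_config(replicate_detection_prob = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(hotspot_genes = 500, n_genes = 10), "hotspot")
  expect_error(sim_config(n_genes = -1), "non-negative")
  # infeasible: features cannot fit in the genome
  expect_error(simulate_dataset(sim_config(n_contigs = 1L,
                                           contig_length = 5000L,
                                           n_genes = 50L,
                                           mean_gene_length = 900L)),
               "infeasible")
})

test_that("identical seeds give byte-identical artifacts", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(small_config(seed = 99), out_dir = d1)
  simulate_dataset(small_config(seed = 99), out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed changes the variant calls
  sim3 <- simulate_dataset(small_config(seed = 100))
  sim1 <- simulate_dataset(small_config(seed = 99))
  expect_false(identical(sim1$truth$variants, sim3$truth$variants))
})

test_that("degenerate parameters give identical replicates within condition", {
  sim <- simulate_dataset(small_config(seed = 2, singleton_noise_rate = 0,
                                       replicate_detection_prob = 1))
  for (cn in names(sim$replicates)) {
    reps <- sim$replicates[[cn]]
    for (r in reps[-1]) {
      expect_identical(r[, c("contig", "pos", "ref", "alt")],
                       reps[[1]][, c("contig", "pos", "ref", "alt")])
    }
  }
})

test_that("planted labels survive independent re-annotation (label honesty)", {
  sim <- simulate_dataset(small_config(seed = 51))
  tv <- sim$truth$variants
  ann <- classify_variants(sim$genome, tv[, c("contig", "pos", "ref", "alt")])
  # non-overlapping genes: one row per variant
  expect_equal(nrow(ann), nrow(tv))
  expect_equal(ann$effect, tv$effect)
  expect_equal(ann$gene_id[!is.na(tv$gene_id)], tv$gene_id[!is.na(tv$gene_id)])
})

test_that("noise-free pipeline recovers planted per-gene counts exactly", {
  sim <- simulate_dataset(small_config(seed = 53,
                                       replicate_detection_prob = 1,
                                       singleton_noise_rate = 0,
                                       shared_across_conditions = 1))
  gen <- sim$genome
  truth <- sim$truth$variants
  for (cn in names(sim$replicates)) {
    ann <- lapply(sim$replicates[[cn]], function(r) classify_variants(gen, r))
    m <- merge_replicates(ann, condition = cn)
    for (gid in sim$truth$hotspot_genes) {
      v <- m$variants[m$variants$gene_id %in% gid, ]
      tv <- truth[truth$gene_id %in% gid, ]
      expect_equal(sum(v$effect == "synonymous"),
                   sum(tv$effect == "synonymous"))
      expect_equal(sum(v$effect == "non_synonymous"),
                   sum(tv$effect == "non_synonymous"))
    }
  }
})

test_that("site mutation ops plant the requested effect and detect infeasibility", {
  g <- tiny_genome()
  set.seed(12)
  for (i in 1:20) {
    mv <- synonymous_site_mutation(g, "geneA")
    ann <- classify_variants(g, cbind(mv, condition = "c", replicate = "r"))
    expect_equal(ann$effect, "synonymous")
    mv2 <- nonsynonymous_site_mutation(g, "geneB")
    ann2 <- classify_variants(g, cbind(mv2, condition = "c", replicate = "r"))
    expect_equal(ann2$effect, "non_synonymous")
  }
  # GGA offset 2: all three alternates stay glycine
  gga <- annotated_genome(
    c(c1 = "GGAGGAGGA"),
    data.frame(gene_id = "g", contig = "c1", start = 1L, end = 9L,
               strand = "+", kind = "CDS"))
  for (i in 1:10) {
    mv <- synonymous_site_mutation(gga, "g")
    expect_equal(mv$pos %% 3, 0)  # only offset-2 sites are degenerate here
  }
  # Met/Trp-only gene admits no synonymous change
  mw <- annotated_genome(
    c(c1 = "ATGTGGATGTGG"),
    data.frame(gene_id = "g", contig = "c1", start = 1L, end = 12L,
               strand = "+", kind = "CDS"))
  expect_error(synonymous_site_mutation(mw, "g"), "no feasible synonymous")
})

test_that("substitution spectrum of emitted variants follows the weights", {
  # concentrated spectrum: every A-reference SNV must become G
  w <- setNames(rep(1e-9, 12), kakscan:::.PAIR_LEVELS)
  w["A>G"] <- 1
  w["T>C"] <- 1
  sim <- simulate_dataset(small_config(seed = 61, spectrum_weights = w,
                                       singleton_noise_rate = 200,
                                       mnv_rate = 0))
  calls <- do.call(rbind, unlist(sim$replicates, recursive = FALSE))
  snv <- calls[nchar(calls$ref) == 1, ]
  expect_true(all(snv$alt[snv$ref == "A"] == "G"))
  expect_true(all(snv$alt[snv$ref == "T"] == "C"))

  # default transition-rich weights: chi-square goodness of fit on the
  # alt distribution conditional on each reference base
  cfg <- small_config(seed = 63, singleton_noise_rate = 1500, mnv_rate = 0,
                      hotspot_genes = 0L, n_intergenic_variants = 0L,
                      n_intragenic_noncoding = 0L)
  sim2 <- simulate_dataset(cfg)
  noise <- sim2$truth$noise
  expect_gt(nrow(noise), 500)
  for (ref in c("A", "C")) {
    sub <- noise[noise$ref == ref & nchar(noise$ref) == 1, ]
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    wts <- cfg$spectrum_weights[paste0(ref, ">", alts)]
    obs <- table(factor(sub$alt, levels = alts))
    p <- suppressWarnings(stats::chisq.test(obs, p = wts / sum(wts))$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("multi-base substitutions are emitted as single adjacent records", {
  sim <- simulate_dataset(small_config(seed = 67, mnv_rate = 1,
                                       n_intergenic_variants = 10L))
  tv <- sim$truth$variants
  mnv <- tv[tv$effect == "multi_bp", ]
  expect_gt(nrow(mnv), 0)
  expect_true(all(nchar(mnv$ref) == 2))
  expect_true(all(nchar(mnv$alt) == 2))
  # the reference really is the genome's 2-mer at that spot
  for (i in seq_len(nrow(mnv))) {
    expect_equal(substring(sim$genome$contigs[[mnv$contig[i]]],
                           mnv$pos[i], mnv$pos[i] + 1), mnv$ref[i])
  }
})

test_that("VCF files round-trip through the reader", {
  sim <- simulate_dataset(small_config(seed = 71))
  dir <- withr::local_tempdir()
  kakscan:::write_dataset(sim, dir)
  cn <- names(sim$replicates)[2]
  path <- file.path(dir, "vcf", paste0(cn, "_rep1.vcf"))
  back <- read_vcf_variants(path)
  orig <- sim$replicates[[cn]][["rep1"]]
  expect_equal(back$pos, orig$pos)
  expect_equal(back$ref, orig$ref)
  expect_equal(back$alt, orig$alt)
  expect_equal(unique(back$condition), cn)
  expect_equal(unique(back$replicate), "rep1")
})

test_that("depth tracks hit the requested breadth and cover emitted calls", {
  sim <- simulate_dataset(small_config(seed = 73, breadth_mean = 0.7))
  gen <- sim$genome
  cn <- names(sim$tracks)[1]
  breadths <- vapply(names(sim$tracks), function(cn) {
    mean(vapply(sim$tracks[[cn]], function(tr) {
      breadth_of_coverage(tr, names(gen$contigs)[1], 1,
                          nchar(gen$contigs[[1]]))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(abs(breadths - 0.7) < 0.15))
  # every emitted call position is covered in its own replicate
  for (cn in names(sim$replicates)) {
    for (rid in names(sim$replicates[[cn]])) {
      calls <- sim$replicates[[cn]][[rid]]
      tr <- sim$tracks[[cn]][[rid]]
      if (!nrow(calls)) next
      covered <- vapply(seq_len(nrow(calls)), function(i)
        breadth_of_coverage(tr, calls$contig[i], calls$pos[i],
                            calls$pos[i]), numeric(1))
      expect_true(all(covered == 1))
    }
  }
})
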