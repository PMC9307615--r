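#' Combinatorial probability of K shared variant positions in a gene
#'
#' Probability that K variant positions drawn uniformly without
#' replacement from a gene of length N coincide with K fixed positions:
#' `1 / choose(N, K)`, computed in log space so large genes do not
#' overflow.
#'
#' @param gene_length_bp N, gene length in bp.
#' @param shared_variants K, number of observed shared variants
#'   (`0 <= K <= N`); `K = 0` returns probability 1.
#' @return probability in `(0, 1]` (vectorized over both arguments).
#' @export
pascal_probability <- function(gene_length_bp, shared_variants) {
  N <- gene_length_bp
  K <- shared_variants
  if (any(K < 0) || any(N < 0)) stopf("N and K must be non-negative")
  if (any(K > N)) stopf("K cannot exceed gene length N")
  exp(-lchoose(N, K))
}

#' Per-gene Pascal probabilities with BH adjustment
#'
#' Raw `1/choose(N, K)` probabilities for a set of genes plus
#' Benjamini-Hochberg adjusted values (multiple testing across genes; the
#' adjustment is an addition beyond the raw combinatorial probability and
#' is reported alongside, never substituted).
#'
#' @param gene_lengths named numeric vector (gene id -> length in bp).
#' @param shared_counts named numeric vector (gene id -> observed shared
#'   variant count); names must match `gene_lengths`.
#' @return data.frame: `gene_id`, `N`, `K`, `p_pascal`, `p_bh`.
#' @export
pascal_gene_table <- function(gene_lengths, shared_counts) {
  ids <- names(gene_lengths)
  stopifnot(!is.null(ids), all(ids %in% names(shared_counts)))
  K <- shared_counts[ids]
  p <- pascal_probability(gene_lengths, K)
  data.frame(gene_id = ids, N = unname(gene_lengths), K = unname(K),
             p_pascal = unname(p),
             p_bh = p.adjust(unname(p), method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---------------------------------------------------------------------------
# continuum randomization

# sorted global gene intervals for fast position -> gene lookup;
# assumes non-overlapping genes (checked) for the Monte Carlo fast path
gene_lookup <- function(genome, kinds = NULL) {
  g <- genome$genes
  if (!is.null(kinds)) g <- g[g$kind %in% kinds, , drop = FALSE]
  off <- contig_offsets(genome)
  gstart <- unname(off[g$contig]) + g$start
  gend <- unname(off[g$contig]) + g$end
  o <- order(gstart)
  gstart <- gstart[o]
  gend <- gend[o]
  if (length(gstart) > 1L && any(gstart[-1] <= gend[-length(gend)])) {
    warnf("overlapping genes: continuum null assigns each position to one gene")
    gend <- pmin(gend, c(gstart[-1] - 1L, Inf))
  }
  list(gstart = gstart, gend = gend, gene_id = g$gene_id[o],
       G = length(gstart), L = genome$total_length)
}

# gene index (0 = intergenic) for global positions
locate_genes <- function(pos, lookup) {
  idx <- findInterval(pos, lookup$gstart)
  hit <- idx > 0L & pos <= lookup$gend[pmax(idx, 1L)]
  idx[!hit] <- 0L
  idx
}

# distance from global positions to nearest gene (0 inside)
gene_distances <- function(pos, lookup) {
  idx <- findInterval(pos, lookup$gstart)
  inside <- idx > 0L & pos <= lookup$gend[pmax(idx, 1L)]
  dleft <- ifelse(idx > 0L, pos - lookup$gend[pmax(idx, 1L)], Inf)
  dright <- ifelse(idx < lookup$G, lookup$gstart[pmin(idx + 1L, lookup$G)] - pos,
                   Inf)
  d <- pmin(dleft, dright)
  d[inside] <- 0
  d
}

.observed_stat <- function(statistic, pos_by_cond, lookup) {
  if (is.function(statistic)) return(statistic(pos_by_cond, lookup))
  switch(statistic,
    shared_genes = {
      sets <- lapply(pos_by_cond, function(p) {
        unique(locate_genes(p, lookup))
      })
      sets <- lapply(sets, setdiff, y = 0L)
      length(Reduce(intersect, sets))
    },
    max_gene_hits = {
      hits <- unlist(lapply(pos_by_cond, function(p) {
        setdiff(locate_genes(p, lookup), 0L)
      }))
      if (!length(hits)) 0 else max(tabulate(hits, lookup$G))
    },
    mean_gene_distance = {
      mean(gene_distances(unlist(pos_by_cond), lookup))
    },
    stopf("unknown statistic '%s'", statistic)
  )
}

#' Monte Carlo continuum randomization of variant positions
#'
#' Treats the genome as a single continuum of `total_length` positions.
#' Under the null, each iteration re-places every condition's observed
#' number of variants uniformly (with replacement, at bp resolution) and
#' recomputes a clustering statistic; the empirical p-value is
#' `(1 + #\{null >= observed\}) / (iterations + 1)`, which can never be
#' exactly zero from a finite simulation.
#'
#' @param genome an [annotated_genome()].
#' @param observed named list (condition -> data.frame with `contig`,
#'   `pos`, or a numeric vector of global positions) of merged variant
#'   sets.
#' @param statistic `"shared_genes"` (default; the number of genes
#'   containing at least one variant in every condition simultaneously),
#'   `"max_gene_hits"` (largest per-gene variant count pooled over
#'   conditions), `"mean_gene_distance"` (mean distance of variants to
#'   the nearest gene; continuous, used for calibration), or a function
#'   `(pos_by_condition, lookup) -> scalar` (slow path).
#' @param iterations Monte Carlo iterations (default 10000; the
#'   full-scale analysis uses 1e6).
#' @param seed RNG seed; recorded in the result.
#' @param chunk_size iterations simulated per vectorized block.
#' @return object of class `null_test_result`: `statistic_name`,
#'   `observed`, `null_mean`, `null_sd`, `iterations`, `seed`,
#'   `p_empirical`, `p_combined` (for `"shared_genes"` only: the product
#'   over conditions of each condition's single-run empirical probability
#'   of hitting every gene of the observed shared-gene set; an
#'   independence approximation, reported separately and never
#'   substituted for `p_empirical`), `n_observed` (variants per
#'   condition) and the full `null` sample.
#' @export
continuum_randomization <- function(genome, observed,
                                    statistic = "shared_genes",
                                    iterations = 10000, seed = 1,
                                    chunk_size = 5000) {
  stopifnot(is(genome, "annotated_genome"), iterations >= 1)
  lookup <- gene_lookup(genome)
  pos_by_cond <- lapply(observed, function(o) {
    if (is.numeric(o)) return(as.numeric(o))
    global_positions(genome, o$contig, o$pos)
  })
  n_c <- vapply(pos_by_cond, length, integer(1))
  ncond <- length(pos_by_cond)
  stat_name <- if (is.function(statistic)) "custom" else statistic
  if (any(n_c == 0L)) {
    warnf("condition(s) with zero observed variants: statistic is trivial")
  }
  obs <- .observed_stat(statistic, pos_by_cond, lookup)

  target <- integer(0)
  if (identical(statistic, "shared_genes") && all(n_c > 0L)) {
    sets <- lapply(pos_by_cond, function(p) setdiff(unique(locate_genes(p, lookup)), 0L))
    target <- Reduce(intersect, sets)
  }

  null_vals <- numeric(iterations)
  target_hits <- numeric(ncond)  # per condition: iterations hitting all target genes
  local_seed(seed, {
    done <- 0L
    while (done < iterations) {
      B <- min(chunk_size, iterations - done)
      if (is.function(statistic)) {
        for (b in seq_len(B)) {
          sim <- lapply(n_c, function(n) floor(runif(n) * lookup$L) + 1)
          null_vals[done + b] <- statistic(sim, lookup)
        }
      } else if (identical(statistic, "mean_gene_distance")) {
        n_tot <- sum(n_c)
        pos <- floor(runif(B * n_tot) * lookup$L) + 1
        d <- gene_distances(pos, lookup)
        null_vals[done + seq_len(B)] <- colMeans(matrix(d, nrow = n_tot))
      } else {
        G <- lookup$G
        keys_by_cond <- vector("list", ncond)
        for (ci in seq_len(ncond)) {
          n <- n_c[ci]
          if (n == 0L) {
            keys_by_cond[[ci]] <- numeric(0)
            next
          }
          pos <- floor(runif(B * n) * lookup$L) + 1
          gid <- locate_genes(pos, lookup)
          iter <- rep(seq_len(B), each = n)
          hit <- gid > 0L
          keys <- unique((iter[hit] - 1) * G + gid[hit])
          keys_by_cond[[ci]] <- keys
          if (length(target)) {
            tk <- keys[((keys - 1) %% G) + 1 %in% target]
            cnt <- tabulate(((tk - 1) %/% G) + 1, B)
            target_hits[ci] <- target_hits[ci] + sum(cnt == length(target))
          }
        }
        if (identical(statistic, "shared_genes")) {
          pool <- sort(unlist(keys_by_cond))
          r <- rle(pool)
          full <- r$values[r$lengths == ncond]
          S <- tabulate(((full - 1) %/% G) + 1, B)
          null_vals[done + seq_len(B)] <- S
        } else { # max_gene_hits
          for (b in seq_len(B)) null_vals[done + b] <- NA_real_
          pos_all <- floor(runif(B * sum(n_c)) * lookup$L) + 1
          gid <- locate_genes(pos_all, lookup)
          iter <- rep(seq_len(B), each = sum(n_c))
          hit <- gid > 0L
          if (any(hit)) {
            key <- (iter[hit] - 1) * G + gid[hit]
            tb <- sort(key)
            rr <- rle(tb)
            it <- ((rr$values - 1) %/% G) + 1
            mx <- rep(0, B)
            agg <- tapply(rr$lengths, it, max)
            mx[as.integer(names(agg))] <- agg
            null_vals[done + seq_len(B)] <- mx
          } else {
            null_vals[done + seq_len(B)] <- 0
          }
        }
      }
      done <- done + B
    }
  })

  p_emp <- (1 + sum(null_vals >= obs)) / (iterations + 1)
  p_comb <- NULL
  if (identical(statistic, "shared_genes") && length(target)) {
    p_c <- (1 + target_hits) / (iterations + 1)
    p_comb <- prod(p_c)
  }
  structure(list(statistic_name = stat_name, observed = obs,
                 null_mean = mean(null_vals), null_sd = sd(null_vals),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 p_empirical = p_emp, p_combined = p_comb,
                 n_observed = n_c, target_genes = lookup$gene_id[target],
                 null = null_vals),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf("null_test_result [%s]\n", x$statistic_name))
  cat(sprintf("  observed = %.4g; null mean = %.4g (sd %.4g) over %d iterations (seed %d)\n",
              x$observed, x$null_mean, x$null_sd, x$iterations, x$seed))
  cat(sprintf("  p_empirical = %.4g", x$p_empirical))
  if (!is.null(x$p_combined)) {
    cat(sprintf("; p_combined (independence product) = %.4g", x$p_combined))
  }
  cat("\n")
  invisible(x)
}

#' Null test result as a JSON-ready list
#' @param x a [continuum_randomization()] result.
#' @return plain list without the raw null sample.
#' @export
null_result_summary <- function(x) {
  stopifnot(is(x, "null_test_result"))
  list(statistic = x$statistic_name, observed = x$observed,
       null_mean = x$null_mean, null_sd = x$null_sd,
       iterations = x$iterations, seed = x$seed,
       p_empirical = x$p_empirical,
       p_combined = x$p_combined %||% NA_real_,
       n_observed = as.list(x$n_observed))
}

# ---------------------------------------------------------------------------
# Friedman / Nemenyi / t-test

# all k! permutations of 1..k as a matrix
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  row <- 1L
  for (pos in seq_len(k)) {
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[i, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

.friedman_stat <- function(r, n, k) {
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) return(0)
  num / den
}

#' Friedman rank test across conditions
#'
#' Blocks are rows (e.g. genes), treatments are columns (conditions).
#' Values are ranked within each block with average ranks for ties; the
#' tie-corrected chi-square statistic is referred to a chi-square
#' distribution with `k - 1` degrees of freedom, or to the exact
#' within-block permutation distribution when `exact = TRUE`.
#'
#' @param x numeric matrix, `n` blocks x `k >= 2` conditions.
#' @param exact compute the exact permutation p-value by enumerating all
#'   `(k!)^n` within-block rearrangements (guarded at 1e6 combinations).
#' @return list with `statistic` (chi-square), `df`, `p_value`, `method`,
#'   `mean_ranks`, and for `exact = TRUE` also `n_permutations`.
#' @details A matrix of entirely constant rows has statistic 0 and
#'   p-value 1.
#' @export
friedman_test <- function(x, exact = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2L || n < 2L) stopf("need >= 2 conditions and >= 2 blocks")
  r <- t(apply(x, 1L, rank))
  stat <- .friedman_stat(r, n, k)
  mean_ranks <- colMeans(r)
  if (!exact) {
    p <- if (stat == 0) 1 else pchisq(stat, df = k - 1L, lower.tail = FALSE)
    return(list(statistic = stat, df = k - 1L, p_value = min(p, 1),
                method = "chi-square approximation",
                mean_ranks = mean_ranks))
  }
  P <- .permutations(k)
  m <- nrow(P)
  total <- m^n
  if (total > 1e6) stopf("exact enumeration infeasible: (k!)^n = %g", total)
  ge <- 0L
  digits <- integer(n)
  for (t in seq_len(total)) {
    rp <- matrix(0, n, k)
    for (i in seq_len(n)) rp[i, ] <- r[i, P[digits[i] + 1L, ]]
    if (.friedman_stat(rp, n, k) >= stat - 1e-9) ge <- ge + 1L
    # increment mixed-radix counter
    for (i in seq_len(n)) {
      digits[i] <- digits[i] + 1L
      if (digits[i] < m) break
      digits[i] <- 0L
    }
  }
  list(statistic = stat, df = k - 1L, p_value = ge / total,
       method = "exact permutation", mean_ranks = mean_ranks,
       n_permutations = total)
}

#' Nemenyi post-hoc test after Friedman
#'
#' All-pairs comparison of mean ranks. The critical difference is
#' `CD = q_alpha * sqrt(k (k + 1) / (6 n))` with `q_alpha` the
#' studentized-range quantile at infinite df divided by `sqrt(2)`; pairs
#' whose mean-rank difference exceeds CD are flagged.
#'
#' @param x numeric matrix, blocks x conditions (ranked within blocks).
#' @param alpha significance level (default 0.05).
#' @return list with `applicable` (FALSE for `k < 3`), `mean_ranks`,
#'   `critical_difference`, and `pairs` (data.frame: condition pair,
#'   `rank_diff`, `p_value`, `significant`).
#' @export
nemenyi_posthoc <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (k < 3L) {
    return(list(applicable = FALSE, reason = "Nemenyi requires k >= 3",
                mean_ranks = NULL, critical_difference = NA_real_,
                pairs = NULL))
  }
  r <- t(apply(x, 1L, rank))
  mean_ranks <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  q_alpha <- qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  cd <- q_alpha * se
  cmb <- combn(k, 2L)
  labels <- colnames(x) %||% paste0("cond", seq_len(k))
  diffs <- abs(mean_ranks[cmb[1, ]] - mean_ranks[cmb[2, ]])
  pvals <- ptukey(diffs / se * sqrt(2), nmeans = k, df = Inf,
                  lower.tail = FALSE)
  list(applicable = TRUE, mean_ranks = setNames(mean_ranks, labels),
       critical_difference = cd, alpha = alpha,
       pairs = data.frame(a = labels[cmb[1, ]], b = labels[cmb[2, ]],
                          rank_diff = unname(diffs), p_value = unname(pvals),
                          significant = unname(diffs > cd),
                          stringsAsFactors = FALSE))
}

#' Two-sample Student's t-test
#'
#' Pooled-variance Student's t by default (the form used for purity /
#' coverage group comparisons); Welch's unequal-variance form by flag.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param equal_variance pooled-variance Student's t (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return list with `t`, `df`, `p_value` (two-sided).
#' @details When both groups have zero variance and equal means the
#'   result is `t = 0, p = 1`; zero variance with unequal means gives
#'   infinite `t` and `p = 0`.
#' @export
two_sample_t <- function(a, b, equal_variance = TRUE) {
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) stopf("each group needs n >= 2")
  ma <- mean(a)
  mb <- mean(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (equal_variance) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- if (se == 0) na + nb - 2 else
      (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (ma == mb) return(list(t = 0, df = df, p_value = 1))
    return(list(t = sign(ma - mb) * Inf, df = df, p_value = 0))
  }
  t <- (ma - mb) / se
  list(t = t, df = df, p_value = 2 * pt(abs(t), df, lower.tail = FALSE))
}
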