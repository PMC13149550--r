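#' Quantify shared-promoter transcript variants from unique regions
#'
#' Variant-level signal comes only from variant-disjoint regions: reads in
#' exons shared by the variants carry no variant information and are
#' discarded.  Each variant's count is the coverage overlapping its
#' `unique_regions`, normalized to counts per kb of unique region per
#' million library reads.
#'
#' @param coverage Data frame of read/region counts per sample: `chrom`,
#'   `start`, `end`, `count`.
#' @param gene A [gene_model()] with >= 2 variants, all with nonempty
#'   `unique_regions` (checked via [validate_variants()]).
#' @param libsize Library size (total reads) of the sample.
#' @return Data frame per variant: `gene_id`, `variant_id`,
#'   `unique_region_count`, `unique_kb`, `norm_expr`.
#' @export
quantify_variants <- function(coverage, gene, libsize) {
  if (length(gene$variants) < 2)
    stop("gene ", gene$gene_id, " needs >= 2 variants")
  validate_variants(gene)
  out <- NULL
  cov_iv <- genomic_intervals(coverage$chrom, coverage$start, coverage$end)
  for (v in gene$variants) {
    fl <- overlap_flags(cov_iv, v$unique_regions)
    cnt <- sum(coverage$count[fl$a])
    kb <- sum(v$unique_regions$end - v$unique_regions$start) / 1000
    out <- rbind(out, data.frame(
      gene_id = gene$gene_id, variant_id = v$variant_id,
      unique_region_count = cnt, unique_kb = kb,
      norm_expr = cnt / kb / (libsize / 1e6),
      stringsAsFactors = FALSE))
  }
  out
}

#' Differential test of variant expression between groups
#'
#' Runs the package's negative-binomial Wald engine on the variants'
#' unique-region counts.
#'
#' @param quants Data frame with one row per variant per sample: columns
#'   `variant_id`, `sample_id`, `unique_region_count`.
#' @param meta Sample metadata (`sample_id`, `group`, `replicate`).
#' @param libsizes Optional named per-sample library sizes used as size
#'   factors; a two-feature matrix cannot self-normalize by
#'   median-of-ratios without absorbing the effect under test.
#' @param group_ref,group_alt Group labels contrasted as in
#'   [nb_wald_test()].
#' @return [nb_wald_test()] result, one row per variant.
#' @export
variant_wald_test <- function(quants, meta, libsizes = NULL,
                              group_ref = "young", group_alt = "old") {
  wide <- stats::reshape(
    quants[c("variant_id", "sample_id", "unique_region_count")],
    idvar = "variant_id", timevar = "sample_id", direction = "wide")
  counts <- as.matrix(wide[, -1, drop = FALSE])
  colnames(counts) <- sub("^unique_region_count\\.", "", colnames(counts))
  rownames(counts) <- wide$variant_id
  sf <- if (is.null(libsizes)) NULL else libsizes[colnames(counts)]
  nb_wald_test(count_matrix(counts, meta), group_ref, group_alt,
               size_factors = sf)
}

#' Preranked gene-set enrichment score with permutation p-value
#'
#' Classical weighted Kolmogorov-Smirnov running sum: genes are ranked by
#' score (descending); hits increment the sum proportionally to
#' `|score|^weight` (normalized to 1 over hits), misses decrement by
#' `1/(N - Nh)`; the enrichment score is the extremum.  The p-value is a
#' gene-label permutation test with add-one correction:
#' `p = (1 + #{|ES_perm| >= |ES|}) / (n_perm + 1)`.
#'
#' @param scores Named numeric vector of ranking scores (names = gene
#'   ids); ties broken by input order.
#' @param gene_set Character vector of gene ids; must intersect the
#'   ranked list.
#' @param weight Score weight exponent (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return List with `es`, `p`, `direction` (`"top"`/`"bottom"`),
#'   `running` (the running sum), `n_hits`.
#' @export
gsea_preranked <- function(scores, gene_set, weight = 1, n_perm = 1000,
                           seed = 1) {
  stopifnot(all(is.finite(scores)))
  o <- order(scores, decreasing = TRUE)
  scores <- scores[o]
  hit <- names(scores) %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene_set does not intersect the ranked list")
  if (nh == length(scores)) stop("gene_set covers the whole ranked list")
  es_of <- function(hit) {
    w <- abs(scores)^weight
    inc <- numeric(length(scores))
    inc[hit] <- w[hit] / sum(w[hit])
    inc[!hit] <- -1 / (length(scores) - sum(hit))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  run_w <- abs(scores)^weight
  inc <- ifelse(hit, run_w / sum(run_w[hit]), 0)
  inc[!hit] <- -1 / (length(scores) - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  set.seed(seed)
  n_ge <- 0
  for (b in seq_len(n_perm)) {
    ph <- logical(length(scores))
    ph[sample(length(scores), nh)] <- TRUE
    if (abs(es_of(ph)) >= abs(es)) n_ge <- n_ge + 1
  }
  list(es = es, p = (1 + n_ge) / (n_perm + 1),
       direction = if (es >= 0) "top" else "bottom",
       running = running, n_hits = nh)
}

#' Transcriptome reversal score for a knockdown experiment
#'
#' For the aging-up and aging-down gene sets, examines the distribution of
#' knockdown-vs-control log2 fold changes.  Reversal is declared when the
#' aging-up set shifts negative and the aging-down set shifts positive,
#' both with a two-sided one-sample t-test significant at `alpha`.  Sets
#' smaller than 3 report the shift but skip the test (flagged).
#'
#' @param aging_up,aging_down Character vectors of aging DEG ids.
#' @param kd_log2fc Named numeric vector of knockdown/control log2 fold
#'   changes per gene.
#' @param alpha Significance level (default 0.05).
#' @return List with per-set `mean_shift`, `p`, `tested`, and `reversal`
#'   (logical).
#' @export
reversal_score <- function(aging_up, aging_down, kd_log2fc, alpha = 0.05) {
  one <- function(set) {
    x <- kd_log2fc[names(kd_log2fc) %in% set]
    if (length(x) < 3 || stats::sd(x) == 0)
      return(list(mean_shift = mean(x), p = NA_real_, tested = FALSE,
                  n = length(x)))
    t <- stats::t.test(x)
    list(mean_shift = mean(x), p = t$p.value, tested = TRUE,
         n = length(x))
  }
  up <- one(aging_up)
  dn <- one(aging_down)
  rev_up <- up$tested && up$mean_shift < 0 && up$p < alpha
  rev_dn <- dn$tested && dn$mean_shift > 0 && dn$p < alpha
  list(up_set = up, down_set = dn, reversal = rev_up && rev_dn)
}
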