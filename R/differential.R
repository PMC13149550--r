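#' Median-of-ratios size factors and CPM
#'
#' Size factors use the median-of-ratios scheme: each sample's factor is
#' the median, over features nonzero in every sample, of the ratio of its
#' count to the feature's geometric mean.  CPM is counts scaled to a
#' library size of one million.
#'
#' @param m A [count_matrix()].
#' @return List with `size_factors` (named), `cpm` (matrix) and
#'   `norm_counts` (counts divided by size factors).
#' @export
normalize_counts <- function(m) {
  k <- m$counts
  libsize <- colSums(k)
  if (any(libsize == 0))
    stop("sample with all-zero counts: ",
         colnames(k)[which(libsize == 0)[1]])
  ok <- rowSums(k == 0) == 0
  if (!any(ok)) stop("no feature is nonzero in every sample")
  lg <- log(k[ok, , drop = FALSE])
  ref <- rowMeans(lg)                       # log geometric mean
  sf <- apply(exp(lg - ref), 2, stats::median)
  list(size_factors = sf,
       cpm = sweep(k, 2, libsize / 1e6, "/"),
       norm_counts = sweep(k, 2, sf, "/"))
}

# method-of-moments NB dispersion per feature with shrinkage toward a
# loess mean-dispersion trend; variance pooled within groups so true fold
# changes do not inflate dispersion
estimate_dispersion <- function(norm_counts, groups) {
  gl <- unique(groups)
  n <- ncol(norm_counts)
  mu <- rowMeans(norm_counts)
  wvar <- rowSums(vapply(gl, function(g) {
    x <- norm_counts[, groups == g, drop = FALSE]
    rowSums((x - rowMeans(x))^2)
  }, numeric(nrow(norm_counts)))) / (n - length(gl))
  raw <- (wvar - mu) / mu^2
  raw[!is.finite(raw)] <- 0
  floor_disp <- 1e-4
  # mean-dispersion trend on the mean scale: running mean of the (signed)
  # moment estimates over abundance rank.  Averaging on the mean scale
  # (not log) and keeping non-positive estimates avoids the downward /
  # selection biases a log-scale fit of positive-only values carries.
  use <- mu > 0
  trend <- rep(floor_disp, length(mu))
  if (sum(use) >= 50) {
    o <- order(mu[use])
    r <- raw[use][o]
    win <- max(50, round(0.1 * length(r)))
    cs <- cumsum(c(0, r))
    lo <- pmax(1, seq_along(r) - win %/% 2)
    hi <- pmin(length(r), seq_along(r) + win %/% 2)
    tr <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    trend[use][o] <- tr
  } else if (any(use)) {
    trend <- rep(mean(raw[use]), length(mu))
  }
  trend <- pmax(trend, floor_disp)
  # shrink the per-feature estimates toward the trend on the log scale;
  # the trend is estimated from many features, so it carries a large
  # prior weight relative to the few residual df per feature
  w_trend <- 40
  w_raw <- n - length(gl)
  shr <- exp((w_raw * log(pmax(raw, floor_disp)) +
                w_trend * log(trend)) / (w_raw + w_trend))
  shr <- pmax(shr, floor_disp)
  attr(shr, "prior_df") <- w_trend
  shr
}

#' Negative-binomial Wald test between two groups
#'
#' Per feature: group abundances are estimated as size-factor-weighted
#' means, the NB dispersion by method-of-moments with shrinkage toward a
#' loess mean-dispersion trend, and the log2 fold change is tested with a
#' Wald statistic using the delta-method standard error
#' `Var(log q) = sum(s_j^2 (mu_j + phi mu_j^2)) / (sum s_j)^2 / q^2`.
#' P-values are two-sided normal; FDR is Benjamini-Hochberg across tested
#' features.
#'
#' @param m A [count_matrix()].
#' @param group_ref,group_alt Group labels; the reported `log2fc` is
#'   `log2(alt / ref)` (old vs young by convention).
#' @param size_factors Optional externally supplied size factors (e.g.
#'   library sizes rescaled to geometric mean 1) for feature sets too
#'   small for median-of-ratios self-normalization.
#' @return Data frame with `feature_id`, `log2fc`, `mean_cpm`,
#'   `base_mean`, `p_value`, `fdr`.
#' @export
nb_wald_test <- function(m, group_ref = "young", group_alt = "old",
                         size_factors = NULL) {
  groups <- m$meta$group
  if (sum(groups == group_ref) < 2 || sum(groups == group_alt) < 2)
    stop("need >= 2 replicates per group")
  if (is.null(size_factors)) {
    nz <- normalize_counts(m)
    sf <- nz$size_factors
  } else {
    stopifnot(length(size_factors) == ncol(m$counts),
              all(size_factors > 0))
    sf <- size_factors / exp(mean(log(size_factors)))
    nz <- list(size_factors = sf,
               cpm = sweep(m$counts, 2, colSums(m$counts) / 1e6, "/"))
  }
  keep <- groups %in% c(group_ref, group_alt)
  k <- m$counts[, keep, drop = FALSE]
  sf <- sf[keep]
  grp <- groups[keep]
  nc <- sweep(k, 2, sf, "/")
  disp <- estimate_dispersion(nc, grp)

  qhat <- function(g) rowSums(k[, grp == g, drop = FALSE]) /
    sum(sf[grp == g])
  q_ref <- qhat(group_ref)
  q_alt <- qhat(group_alt)
  # Var(qhat) = sum_j Var(K_j) / (sum_j s_j)^2 with K_j ~ NB(s_j q, phi);
  # delta method then gives se of log(qhat)
  se_log <- function(q, g) {
    s <- sf[grp == g]
    vq <- numeric(length(q))
    for (j in seq_along(s)) {
      muj <- q * s[j]
      vq <- vq + (muj + disp * muj^2)
    }
    vq <- vq / sum(s)^2
    sqrt(vq) / pmax(q, 1e-12)
  }
  pseudo_q <- 0.5 / mean(sf)                # continuity for zero groups
  q_ref_p <- pmax(q_ref, pseudo_q)
  q_alt_p <- pmax(q_alt, pseudo_q)
  log2fc <- log2(q_alt_p / q_ref_p)
  se <- sqrt(se_log(q_ref_p, group_ref)^2 + se_log(q_alt_p, group_alt)^2) /
    log(2)
  z <- log2fc / se
  # moderated-t reference: residual df plus the dispersion trend's prior
  # df; with desk-scale replicate numbers a plain normal reference is too
  # light-tailed while a pure residual-df t is far too heavy
  mod_df <- max(1, ncol(k) - 2) + attr(disp, "prior_df")
  p <- 2 * stats::pt(-abs(z), df = mod_df)
  expressed <- q_ref + q_alt > 0
  p[!expressed] <- 1
  log2fc[!expressed] <- 0
  fdr <- rep(NA_real_, length(p))
  fdr[expressed] <- stats::p.adjust(p[expressed], method = "BH")
  fdr[!expressed] <- 1
  data.frame(feature_id = rownames(m$counts),
             log2fc = log2fc,
             mean_cpm = rowMeans(nz$cpm[, keep, drop = FALSE]),
             base_mean = rowMeans(nc),
             p_value = p, fdr = fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially accessible regions
#'
#' Applies the DAR rule: up if `log2fc > log2(fc_min)`, `mean_cpm >
#' cpm_min` and `fdr < fdr_max`; down symmetric.  All thresholds strict.
#'
#' @param results Output of [nb_wald_test()].
#' @param fc_min Linear fold-change threshold (default 1.5).
#' @param cpm_min Mean-CPM threshold (default 1.5).
#' @param fdr_max FDR threshold (default 0.01).
#' @return `results` with an added `call` column in
#'   `{"up", "down", "unchanged"}`.
#' @export
call_dars <- function(results, fc_min = 1.5, cpm_min = 1.5,
                      fdr_max = 0.01) {
  up <- results$log2fc > log2(fc_min) & results$mean_cpm > cpm_min &
    results$fdr < fdr_max
  dn <- results$log2fc < -log2(fc_min) & results$mean_cpm > cpm_min &
    results$fdr < fdr_max
  results$call <- ifelse(up, "up", ifelse(dn, "down", "unchanged"))
  results
}

#' Replicate-consistent histone peak change calls
#'
#' A peak is called increased iff the merged (replicate-mean) old/young
#' height ratio exceeds `fc_merged_min` *and* every (old replicate, young
#' replicate) pairwise ratio is at least `fc_rep_min`; decreased symmetric.
#' A pseudocount guards zero heights.
#'
#' @param heights Data frame with one row per peak: columns matching
#'   `young_rep*` and `old_rep*` hold normalized heights.
#' @param fc_merged_min Merged fold-change threshold (default 1.5).
#' @param fc_rep_min Per-replicate-pair fold-change threshold (default
#'   1.2).
#' @param pseudocount Added to every height before ratio computation
#'   (default 1).
#' @return Input with added `merged_fc` (old/young) and `call` columns.
#' @export
replicate_consistent_peak_changes <- function(heights, fc_merged_min = 1.5,
                                              fc_rep_min = 1.2,
                                              pseudocount = 1) {
  yc <- grep("^young_rep", names(heights), value = TRUE)
  oc <- grep("^old_rep", names(heights), value = TRUE)
  if (length(yc) < 2 || length(oc) < 2)
    stop("need >= 2 replicates per group")
  y <- as.matrix(heights[yc]) + pseudocount
  o <- as.matrix(heights[oc]) + pseudocount
  merged_fc <- rowMeans(o) / rowMeans(y)
  up <- merged_fc > fc_merged_min
  dn <- 1 / merged_fc > fc_merged_min
  for (a in seq_along(oc)) {
    for (b in seq_along(yc)) {
      r <- o[, a] / y[, b]
      up <- up & r >= fc_rep_min
      dn <- dn & (1 / r) >= fc_rep_min
    }
  }
  heights$merged_fc <- merged_fc
  heights$call <- ifelse(up, "increased", ifelse(dn, "decreased",
                                                 "unchanged"))
  heights
}

#' Expand broad-peak seeds against a Poisson background
#'
#' From each seed segment, the peak is grown bin-by-bin left and right
#' while (a) the candidate bin's Poisson upper-tail p-value against the
#' genome-wide mean bin signal is below `p_max` and (b) the running mean
#' height of the extended peak stays above `height_min`.  Seeds whose own
#' mean height fails the height clause are dropped; touching peaks are
#' merged.
#'
#' @param track A [binned_track()] (1 kb bins, normalized signal).
#' @param seeds Interval data frame of candidate segments on the track's
#'   chromosome (coordinates are snapped to bin boundaries).
#' @param height_min Running-mean height threshold (default 0.3).
#' @param p_max Poisson upper-tail threshold (default 1e-4).
#' @param lambda Background rate; defaults to the mean bin signal of the
#'   track.
#' @return Interval data frame of broad peaks with `mean_height`.
#' @export
expand_broad_peaks <- function(track, seeds, height_min = 0.3,
                               p_max = 1e-4, lambda = NULL) {
  v <- track$values
  if (is.null(lambda)) lambda <- mean(v)
  if (lambda == 0) stop("empty track: background rate is zero")
  bs <- track$bin_size
  nb <- length(v)
  sig_bin <- function(x) stats::ppois(ceiling(x) - 1, lambda,
                                      lower.tail = FALSE) < p_max
  res <- NULL
  for (k in seq_len(nrow(seeds))) {
    lo <- floor(seeds$start[k] / bs) + 1
    hi <- ceiling(seeds$end[k] / bs)
    lo <- max(1, lo); hi <- min(nb, hi)
    if (mean(v[lo:hi]) <= height_min) next
    tot <- sum(v[lo:hi]); n <- hi - lo + 1
    repeat {
      grew <- FALSE
      if (lo > 1 && sig_bin(v[lo - 1]) &&
          (tot + v[lo - 1]) / (n + 1) > height_min) {
        lo <- lo - 1; tot <- tot + v[lo]; n <- n + 1; grew <- TRUE
      }
      if (hi < nb && sig_bin(v[hi + 1]) &&
          (tot + v[hi + 1]) / (n + 1) > height_min) {
        hi <- hi + 1; tot <- tot + v[hi]; n <- n + 1; grew <- TRUE
      }
      if (!grew) break
    }
    res <- rbind(res, data.frame(start = (lo - 1) * bs, end = hi * bs))
  }
  if (is.null(res))
    return(genomic_intervals(character(0), numeric(0), numeric(0),
                             mean_height = numeric(0)))
  res <- res[order(res$start), , drop = FALSE]
  merged <- res[1, , drop = FALSE]
  for (k in seq_len(nrow(res))[-1]) {
    if (res$start[k] <= merged$end[nrow(merged)]) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], res$end[k])
    } else merged <- rbind(merged, res[k, ])
  }
  mh <- vapply(seq_len(nrow(merged)), function(k)
    mean(v[(merged$start[k] / bs + 1):(merged$end[k] / bs)]), 0)
  genomic_intervals(track$chrom, merged$start, merged$end,
                    mean_height = mh)
}

#' Composite (metagene) signal profile
#'
#' TSS-centered mode averages signal in native-resolution bins across
#' `+/- flank` around each anchor's TSS; scaled mode resamples each gene
#' body to `body_bins` bins by mean pooling with flanks in native bins.
#' Minus-strand anchors are reversed so profiles read 5' to 3'.
#'
#' @param tracks Named list (per chromosome) of [binned_track()].
#' @param anchors For TSS mode, a data frame with `chrom`, `tss`,
#'   `strand`; for scaled mode additionally `start`, `end`.
#' @param mode `"tss"` or `"scaled"`.
#' @param flank Flank size in bp (default 2000).
#' @param body_bins Number of body bins in scaled mode (default 100).
#' @return List with `profile` (mean signal per bin), `n_used`,
#'   `n_skipped`, `mode`.
#' @export
composite_profile <- function(tracks, anchors, mode = c("tss", "scaled"),
                              flank = 2000, body_bins = 100) {
  mode <- match.arg(mode)
  bs <- tracks[[1]]$bin_size
  fl_bins <- round(flank / bs)
  acc <- NULL
  n_used <- 0; n_skipped <- 0
  for (k in seq_len(nrow(anchors))) {
    tr <- tracks[[anchors$chrom[k]]]
    if (is.null(tr)) { n_skipped <- n_skipped + 1; next }
    v <- tr$values
    if (mode == "tss") {
      c_bin <- floor(anchors$tss[k] / bs) + 1
      idx <- (c_bin - fl_bins):(c_bin + fl_bins)
      if (any(idx < 1 | idx > length(v))) { n_skipped <- n_skipped + 1; next }
      prof <- v[idx]
    } else {
      s_bin <- floor(anchors$start[k] / bs) + 1
      e_bin <- ceiling(anchors$end[k] / bs)
      if (e_bin - s_bin + 1 < 1 ||
          (anchors$end[k] - anchors$start[k]) < bs) {
        n_skipped <- n_skipped + 1; next
      }
      body <- v[s_bin:e_bin]
      # mean pooling onto body_bins
      map <- floor((seq_along(body) - 1) * body_bins / length(body)) + 1
      pooled <- as.numeric(tapply(body, map, mean))
      if (length(pooled) < body_bins) { n_skipped <- n_skipped + 1; next }
      left <- (s_bin - fl_bins):(s_bin - 1)
      right <- (e_bin + 1):(e_bin + fl_bins)
      if (any(left < 1) || any(right > length(v))) {
        n_skipped <- n_skipped + 1; next
      }
      prof <- c(v[left], pooled, v[right])
    }
    if (anchors$strand[k] == "-") prof <- rev(prof)
    acc <- if (is.null(acc)) prof else acc + prof
    n_used <- n_used + 1
  }
  if (n_used == 0) stop("no usable anchors")
  list(profile = acc / n_used, n_used = n_used, n_skipped = n_skipped,
       mode = mode)
}
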