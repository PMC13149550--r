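#' Two-sided Fisher exact test on a 2x2 table by hypergeometric enumeration
#'
#' Enumerates the full support of the hypergeometric distribution fixed by
#' the table's margins and sums the probabilities of all tables at most as
#' probable as the observed one (with a relative tolerance for ties), the
#' conventional two-sided definition.
#'
#' @param tab 2x2 integer matrix or vector `c(a, b, c, d)` (row-wise).
#' @return List with `p`, `odds_ratio` (sample OR, `Inf` allowed) and the
#'   observed table.
#' @export
fisher_exact_2x2 <- function(tab) {
  x <- as.integer(tab)
  stopifnot(length(x) == 4, all(x >= 0))
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  m <- a + b            # row 1 margin
  n <- c_ + d           # row 2 margin
  k <- a + c_           # column 1 margin
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  # mid-p: halves the observed outcome's own mass; the exact p of a
  # discrete test is conservative by construction, the mid-p is the
  # (approximately) uniform-calibrated version
  mid_p <- p - 0.5 * sum(exp(logp[abs(logp - obs) <= 1e-7]))
  or <- (a * d) / (b * c_)
  if (b == 0 || c_ == 0) or <- if (a == 0 || d == 0) NaN else Inf
  list(p = min(1, p), mid_p = max(0, min(1, mid_p)), odds_ratio = or,
       table = matrix(x, 2, 2, byrow = TRUE))
}

# dense symmetric matrix from a contact_map (counts mirrored below the
# diagonal)
dense_map <- function(map) {
  m <- matrix(0, map$n_bins, map$n_bins)
  idx <- cbind(map$df$bin_i + 1L, map$df$bin_j + 1L)
  m[idx] <- map$df$count
  m[idx[, 2:1, drop = FALSE]] <- map$df$count
  m
}

#' Contact frequency vs genomic distance with a short/long split
#'
#' Counts are pooled over chromosomes into log-spaced distance bins and
#' normalized by the library's total pairs; the short/long mass fractions
#' below and above `range_split` are normalized to sum to one over the
#' intra-chromosomal contacts considered.
#'
#' @param maps Named list of [contact_map()] (one library).
#' @param range_split Distance split in bp (default 5 Mb).
#' @param n_dist_bins Number of log-spaced distance bins (default 50).
#' @return List with `curve` (data frame: distance, frequency) and
#'   `fractions = c(short, long)`.
#' @export
distance_profile <- function(maps, range_split = 5e6, n_dist_bins = 50) {
  res <- unique(vapply(maps, function(m) m$resolution, 0))
  stopifnot(length(res) == 1)
  tp <- maps[[1]]$total_pairs
  d_all <- NULL; c_all <- NULL
  for (m in maps) {
    d <- (m$df$bin_j - m$df$bin_i) * m$resolution
    keep <- d > 0
    d_all <- c(d_all, d[keep]); c_all <- c(c_all, m$df$count[keep])
  }
  breaks <- exp(seq(log(res), log(max(d_all) + 1), length.out =
                      n_dist_bins + 1))
  bin <- findInterval(d_all, breaks, rightmost.closed = TRUE)
  bin[bin == 0] <- 1
  freq <- tapply(c_all, bin, sum) / tp
  mids <- sqrt(breaks[-1] * breaks[-length(breaks)])
  curve <- data.frame(distance = mids[as.integer(names(freq))],
                      frequency = as.numeric(freq))
  short <- sum(c_all[d_all < range_split])
  long <- sum(c_all[d_all >= range_split])
  list(curve = curve,
       fractions = c(short = short / (short + long),
                     long = long / (short + long)))
}

#' A/B compartment eigenvector from a contact map
#'
#' Observed/expected by distance, Pearson correlation over informative
#' bins, first eigenvector of the correlation matrix, sign oriented so
#' that positive bins have the higher mean activity (A = positive).
#' Maximal runs of equal sign become compartment blocks.
#'
#' @param map A [contact_map()] at the compartment resolution.
#' @param activity Numeric vector of per-bin activity (e.g. gene density
#'   or H3K4me3 coverage) used for sign orientation.
#' @param min_bins Minimum informative bins; chromosomes below this are
#'   skipped with a warning (default 20).
#' @return List with `eigen` (per-bin value, `NA` for empty bins) and
#'   `blocks` (interval data frame with `label`, `mean_eigen`), or `NULL`
#'   if skipped.
#' @export
compartment_eigen <- function(map, activity, min_bins = 20) {
  m <- dense_map(map)
  n <- nrow(m)
  stopifnot(length(activity) == n)
  info <- colSums(m) > 0
  if (sum(info) < min_bins) {
    warning("chromosome ", map$chrom, " has < ", min_bins,
            " informative bins; skipped")
    return(NULL)
  }
  mi <- m[info, info]
  ni <- nrow(mi)
  # expected value per |i-j| from the mean of each diagonal
  pos <- which(info)
  dmat <- abs(outer(pos, pos, "-"))
  exp_d <- tapply(mi, dmat, mean)
  e <- matrix(exp_d[as.character(dmat)], ni, ni)
  oe <- mi / pmax(e, .Machine$double.eps)
  cc <- suppressWarnings(stats::cor(oe))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  # orient: positive side has the higher mean activity
  act <- activity[info]
  if (mean(act[ev > 0]) < mean(act[ev <= 0])) ev <- -ev
  full <- rep(NA_real_, n)
  full[info] <- ev
  # blocks: maximal same-sign runs over informative bins
  sgn <- ifelse(full > 0, "A", "B")
  blocks <- NULL
  r <- rle(ifelse(is.na(sgn), "NA", sgn))
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  for (k in seq_along(r$values)) {
    if (r$values[k] == "NA") next
    idx <- starts[k]:ends[k]
    blocks <- rbind(blocks, data.frame(
      chrom = map$chrom,
      start = (starts[k] - 1) * map$resolution,
      end = ends[k] * map$resolution,
      label = r$values[k],
      mean_eigen = mean(full[idx], na.rm = TRUE),
      stringsAsFactors = FALSE))
  }
  list(eigen = full, blocks = blocks)
}

#' Gene-density activity track for eigenvector orientation
#'
#' @param genes List of [gene_model()].
#' @param chrom Chromosome name.
#' @param chrom_len Chromosome length in bp.
#' @param resolution Bin size in bp.
#' @return Numeric vector: number of gene TSSs per bin.
#' @export
gene_density_activity <- function(genes, chrom, chrom_len, resolution) {
  n <- ceiling(chrom_len / resolution)
  v <- numeric(n)
  for (g in genes) {
    if (g$chrom != chrom) next
    b <- floor(g$tss / resolution) + 1
    v[b] <- v[b] + 1
  }
  v
}

# all distinct block pairs (within chromosomes) with summed counts
block_pair_counts <- function(maps, blocks) {
  out <- NULL
  for (ch in unique(blocks$chrom)) {
    map <- maps[[ch]]
    if (is.null(map)) next
    b <- blocks[blocks$chrom == ch, ]
    if (nrow(b) < 2) next
    m <- dense_map(map)
    lo <- b$start / map$resolution + 1
    hi <- b$end / map$resolution
    for (i in seq_len(nrow(b) - 1)) {
      for (j in (i + 1):nrow(b)) {
        cnt <- sum(m[lo[i]:hi[i], lo[j]:hi[j]])
        out <- rbind(out, data.frame(
          chrom = ch, i = i, j = j,
          label_i = b$label[i], label_j = b$label[j],
          len_i = b$end[i] - b$start[i], len_j = b$end[j] - b$start[j],
          dist = abs((b$start[j] + b$end[j]) -
                       (b$start[i] + b$end[i])) / 2,
          count = cnt, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Block-pair contact density (RPMM) and per-class age comparison
#'
#' RPMM of a block pair is `contacts / (len_i/1e6 * len_j/1e6) /
#' (total_pairs/1e6)` — reads per million base pairs per million reads.
#' Blocks are filtered to size > `min_block` and must carry the same label
#' in both ages (pass the filtered set in `blocks`).  Self-pairs are
#' excluded.  For each pair class (A-A, A-B, B-B) a paired two-sided
#' t-test on log2 per-pair RPMM ratios compares the ages.  The per-class
#' location test is restricted to long-range pairs (block midpoints
#' separated by more than `range_split`): the question it answers is
#' whether a compartment class loses long-range contact, and short-range
#' pairs are dominated by domain-scale (TAD) intensity, a separate
#' phenomenon quantified by [tad_compactness()].
#'
#' @param maps_young,maps_old Named per-chromosome [contact_map()] lists.
#' @param blocks Interval data frame with `label`, filtered to blocks
#'   shared in sign between ages and larger than `min_block`.
#' @param min_block Minimum block size in bp (default 1e6).
#' @param range_split Midpoint-distance cutoff separating short- from
#'   long-range pairs (default 5e6); only pairs beyond it enter the
#'   per-class tests.  All pairs are always returned in `pairs`.
#' @return List with `pairs` (per-pair RPMM both ages, class, delta) and
#'   `tests` (per class: long-range pair count n, mean log2 ratio, p).
#' @export
compartment_pair_rpmm <- function(maps_young, maps_old, blocks,
                                  min_block = 1e6, range_split = 5e6) {
  blocks <- blocks[blocks$end - blocks$start > min_block, , drop = FALSE]
  if (nrow(blocks) < 2) stop("no qualifying blocks (size > min_block)")
  tp_y <- maps_young[[1]]$total_pairs
  tp_o <- maps_old[[1]]$total_pairs
  py <- block_pair_counts(maps_young, blocks)
  po <- block_pair_counts(maps_old, blocks)
  stopifnot(nrow(py) == nrow(po))
  rpmm <- function(count, li, lj, tp)
    count / (li / 1e6 * lj / 1e6) / (tp / 1e6)
  cls <- ifelse(py$label_i == py$label_j,
                paste0(py$label_i, "-", py$label_j), "A-B")
  pairs <- data.frame(py[c("chrom", "i", "j", "dist")], class = cls,
                      rpmm_young = rpmm(py$count, py$len_i, py$len_j, tp_y),
                      rpmm_old = rpmm(po$count, po$len_i, po$len_j, tp_o))
  pairs$delta <- pairs$rpmm_old - pairs$rpmm_young
  pairs$log2_ratio <- log2((pairs$rpmm_old + 1e-9) /
                             (pairs$rpmm_young + 1e-9))
  # depth-normalized maps are compositional: a change confined to one
  # class shifts every other pair's normalized value slightly.  Centering
  # the per-pair log ratios on their genome-wide median removes that
  # global shift so the per-class test asks whether a class moves
  # relative to the typical pair.
  pairs$log2_ratio_centered <- pairs$log2_ratio -
    stats::median(pairs$log2_ratio)
  long <- pairs[pairs$dist > range_split, , drop = FALSE]
  tests <- lapply(split(long, long$class), function(d) {
    p <- if (nrow(d) >= 3 && stats::sd(d$log2_ratio_centered) > 0)
      stats::t.test(d$log2_ratio_centered)$p.value else NA_real_
    data.frame(class = d$class[1], n = nrow(d),
               mean_log2_ratio = mean(d$log2_ratio),
               mean_log2_ratio_centered = mean(d$log2_ratio_centered),
               p = p)
  })
  list(pairs = pairs, tests = do.call(rbind, c(tests,
                                               make.row.names = FALSE)))
}

#' Enrichment of pair classes among the top-N most-decreased interactions
#'
#' Pairs are ranked ascending by their depth-centered log2 old/young
#' ratio (the most decreased first); `rank_by = "delta"` ranks by the raw
#' RPMM difference instead.  Ties at rank N are broken by stable pair
#' order (chromosome, block indices).  The contingency table is
#' restricted to same-type pairs (A-A, B-B); the A-B count inside the top
#' N is reported separately.
#'
#' @param pairs Pair table from [compartment_pair_rpmm()].
#' @param n_top Number of most-decreased pairs (default 200, capped at
#'   the pair count).
#' @param rank_by `"ratio"` (centered log2 ratio, default) or `"delta"`
#'   (raw RPMM difference).
#' @return List with `contingency` (2x2: in/out of top-N x A-A/B-B),
#'   `fisher` ([fisher_exact_2x2()] result), `ab_in_top`,
#'   `top_frac_bb`.
#' @export
topN_enrichment <- function(pairs, n_top = 200,
                            rank_by = c("ratio", "delta")) {
  rank_by <- match.arg(rank_by)
  n_top <- min(n_top, nrow(pairs))
  key <- if (rank_by == "ratio") pairs$log2_ratio_centered else pairs$delta
  o <- order(key, pairs$chrom, pairs$i, pairs$j)
  in_top <- logical(nrow(pairs))
  in_top[o[seq_len(n_top)]] <- TRUE
  same <- pairs$class %in% c("A-A", "B-B")
  tab <- matrix(c(sum(in_top & same & pairs$class == "B-B"),
                  sum(in_top & same & pairs$class == "A-A"),
                  sum(!in_top & same & pairs$class == "B-B"),
                  sum(!in_top & same & pairs$class == "A-A")),
                2, 2, byrow = TRUE,
                dimnames = list(c("top", "rest"), c("B-B", "A-A")))
  list(contingency = tab, fisher = fisher_exact_2x2(tab),
       ab_in_top = sum(in_top & pairs$class == "A-B"),
       top_frac_bb = sum(in_top & pairs$class == "B-B") / n_top)
}

#' Per-TAD compactness
#'
#' Compactness = sum of intra-TAD counts (diagonal excluded) / number of
#' intra-TAD bin pairs / (total_pairs / 1e6): depth- and size-normalized
#' mean internal pair intensity.  TADs smaller than two bins are skipped.
#'
#' @param maps Named per-chromosome [contact_map()] list.
#' @param tads Interval data frame (`chrom`, `start`, `end`, `tad_id`).
#' @return `tads` with an added `compactness` column (NA when skipped).
#' @export
tad_compactness <- function(maps, tads) {
  tp <- maps[[1]]$total_pairs
  tads$compactness <- NA_real_
  for (ch in unique(tads$chrom)) {
    map <- maps[[ch]]
    if (is.null(map)) next
    res <- map$resolution
    m <- dense_map(map)
    idx <- which(tads$chrom == ch)
    for (k in idx) {
      lo <- tads$start[k] / res + 1
      hi <- tads$end[k] / res
      nb <- hi - lo + 1
      if (nb < 2) next
      sub <- m[lo:hi, lo:hi]
      tot <- sum(sub[upper.tri(sub)])
      tads$compactness[k] <- tot / (nb * (nb - 1) / 2) / (tp / 1e6)
    }
  }
  tads
}

#' Call changed TADs with the replicate-derived threshold
#'
#' The threshold is the largest absolute log2 compactness ratio observed
#' between same-age replicate pairs across all TADs; a TAD is called
#' changed when the |log2| ratio of merged (replicate-mean) old vs young
#' compactness exceeds it.  Because the maps are depth-normalized, any
#' genuinely compacted set of TADs depresses every other TAD's normalized
#' compactness by a common factor; the merged log2 ratios are therefore
#' median-centered before thresholding so the call reflects TAD-specific
#' change rather than this global compositional shift (same-age replicate
#' ratios share their composition, so the threshold needs no centering).
#'
#' @param comp Data frame: one row per TAD, columns `young_rep*` and
#'   `old_rep*` of per-replicate compactness.
#' @param pseudocount Added to compactness before ratios (default 1e-3).
#' @return List with `tads` (input plus `delta` = log2 merged ratio and
#'   `call` in increased/decreased/unchanged) and `threshold`.
#' @export
call_changed_tads <- function(comp, pseudocount = 1e-3) {
  yc <- grep("^young_rep", names(comp), value = TRUE)
  oc <- grep("^old_rep", names(comp), value = TRUE)
  if (length(yc) < 2 || length(oc) < 2)
    stop("need >= 2 replicates per age")
  thr <- 0
  for (cols in list(yc, oc)) {
    cb <- utils::combn(cols, 2)
    for (k in seq_len(ncol(cb))) {
      r <- abs(log2((comp[[cb[1, k]]] + pseudocount) /
                      (comp[[cb[2, k]]] + pseudocount)))
      thr <- max(thr, max(r, na.rm = TRUE))
    }
  }
  merged_y <- rowMeans(as.matrix(comp[yc]))
  merged_o <- rowMeans(as.matrix(comp[oc]))
  comp$delta <- log2((merged_o + pseudocount) / (merged_y + pseudocount))
  comp$delta <- comp$delta - stats::median(comp$delta, na.rm = TRUE)
  comp$call <- ifelse(abs(comp$delta) > thr,
                      ifelse(comp$delta > 0, "increased", "decreased"),
                      "unchanged")
  list(tads = comp, threshold = thr)
}

#' Aggregate rescaled TAD windows
#'
#' Each TAD window (half-TAD flanks on both sides) is resampled to a
#' `grid x grid` matrix by mean pooling and averaged across TADs; maps are
#' normalized to their total pairs first.  Flanks truncated at chromosome
#' edges are averaged over the available bins.
#'
#' @param maps Named per-chromosome [contact_map()] list.
#' @param tads Interval data frame of TADs.
#' @param grid Output grid size (default 30).
#' @return `grid x grid` numeric matrix.
#' @export
tad_aggregate <- function(maps, tads, grid = 30) {
  stopifnot(nrow(tads) >= 1)
  tp <- maps[[1]]$total_pairs
  acc <- matrix(0, grid, grid)
  wt <- matrix(0, grid, grid)
  for (ch in unique(tads$chrom)) {
    map <- maps[[ch]]
    if (is.null(map)) next
    res <- map$resolution
    m <- dense_map(map) / (tp / 1e6)
    n <- nrow(m)
    idx <- which(tads$chrom == ch)
    for (k in idx) {
      w <- (tads$end[k] - tads$start[k]) / 2
      lo_bp <- tads$start[k] - w
      hi_bp <- tads$end[k] + w
      lo <- floor(lo_bp / res) + 1
      hi <- ceiling(hi_bp / res)
      span <- hi - lo + 1
      gi <- floor((seq_len(span) - 1) * grid / span) + 1   # bin -> cell
      ok <- (lo:hi) >= 1 & (lo:hi) <= n
      rows <- (lo:hi)[ok]
      sub <- m[rows, rows, drop = FALSE]
      gio <- gi[ok]
      for (a in seq_len(grid)) {
        ia <- which(gio == a)
        if (!length(ia)) next
        for (b in seq_len(grid)) {
          ib <- which(gio == b)
          if (!length(ib)) next
          acc[a, b] <- acc[a, b] + mean(sub[ia, ib, drop = FALSE])
          wt[a, b] <- wt[a, b] + 1
        }
      }
    }
  }
  acc / pmax(wt, 1)
}

#' Mean mark signal over TADs grouped by compactness-change rank
#'
#' TADs are sorted by `delta` descending (most compacted in old first) and
#' partitioned into consecutive groups of `bin_size`; the last partial
#' group is retained and flagged.  For each group the mean normalized
#' signal of each mark over the TAD spans is reported.
#'
#' @param tads Data frame with `chrom`, `start`, `end`, `delta`.
#' @param tracks Named list per mark of per-chromosome [binned_track()]
#'   lists.
#' @param bin_size TADs per group (default 100).
#' @return Data frame: `bin` index, `n_tads`, `partial`, one column per
#'   mark.
#' @export
tad_state_bins <- function(tads, tracks, bin_size = 100) {
  o <- order(-tads$delta)
  tads <- tads[o, ]
  grp <- (seq_len(nrow(tads)) - 1) %/% bin_size + 1
  mean_signal <- function(mark_tracks, d) {
    tot <- 0; nb <- 0
    for (k in seq_len(nrow(d))) {
      tr <- mark_tracks[[d$chrom[k]]]
      if (is.null(tr)) next
      lo <- d$start[k] / tr$bin_size + 1
      hi <- d$end[k] / tr$bin_size
      tot <- tot + sum(tr$values[lo:hi])
      nb <- nb + hi - lo + 1
    }
    tot / max(nb, 1)
  }
  out <- NULL
  for (g in unique(grp)) {
    d <- tads[grp == g, ]
    row <- data.frame(bin = g, n_tads = nrow(d),
                      partial = nrow(d) < bin_size)
    for (mk in names(tracks)) row[[mk]] <- mean_signal(tracks[[mk]], d)
    out <- rbind(out, row)
  }
  out
}

# majority-overlap block label per TAD; exact 50/50 ties go to the block
# with the larger |mean eigenvalue| when available
tad_block_labels <- function(tads, blocks) {
  lab <- character(nrow(tads))
  for (k in seq_len(nrow(tads))) {
    b <- blocks[blocks$chrom == tads$chrom[k], , drop = FALSE]
    ov <- pmax(0, pmin(b$end, tads$end[k]) - pmax(b$start, tads$start[k]))
    by_lab <- tapply(ov, b$label, sum)
    if (length(by_lab) == 1) { lab[k] <- names(by_lab); next }
    if (by_lab[["A"]] != by_lab[["B"]]) {
      lab[k] <- if (by_lab[["A"]] > by_lab[["B"]]) "A" else "B"
    } else if ("mean_eigen" %in% names(b)) {
      mag <- tapply(abs(b$mean_eigen) * ov, b$label, sum)
      lab[k] <- names(which.max(mag))
    } else lab[k] <- "A"
  }
  lab
}

#' Compartment enrichment of changed and top-N TADs
#'
#' Labels TADs A/B by majority overlap with compartment blocks, then
#' tests (a) changed vs unchanged TADs and (b) top-N most-increased vs
#' rest against the A/B label with two-sided Fisher tests.
#'
#' @param tads Data frame with `chrom`, `start`, `end`, `delta`, `call`.
#' @param blocks Compartment block interval data frame with `label`.
#' @param n_top Top-N size for the second table (default 200, capped).
#' @return List with `label` vector, `changed_table`, `changed_fisher`,
#'   `top_table`, `top_fisher`.
#' @export
tad_compartment_enrichment <- function(tads, blocks, n_top = 200) {
  lab <- tad_block_labels(tads, blocks)
  changed <- tads$call != "unchanged"
  t1 <- matrix(c(sum(changed & lab == "B"), sum(changed & lab == "A"),
                 sum(!changed & lab == "B"), sum(!changed & lab == "A")),
               2, 2, byrow = TRUE,
               dimnames = list(c("changed", "unchanged"), c("B", "A")))
  n_top <- min(n_top, nrow(tads))
  o <- order(-tads$delta, tads$chrom, tads$start)
  top <- logical(nrow(tads)); top[o[seq_len(n_top)]] <- TRUE
  t2 <- matrix(c(sum(top & lab == "B"), sum(top & lab == "A"),
                 sum(!top & lab == "B"), sum(!top & lab == "A")),
               2, 2, byrow = TRUE,
               dimnames = list(c("top", "rest"), c("B", "A")))
  list(label = lab,
       changed_table = t1, changed_fisher = fisher_exact_2x2(t1),
       top_table = t2, top_fisher = fisher_exact_2x2(t2))
}
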