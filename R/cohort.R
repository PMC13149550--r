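#' Effect specification for the synthetic cohort
#'
#' Encodes the age effects injected into the "old" arm of the synthetic
#' cohort.  Defaults mirror the qualitative structure of aged-HSC data:
#' asymmetric gain of accessibility, loss-dominated bivalency changes,
#' depleted long-range B-B contacts, a compacted-TAD set biased toward B
#' compartments, and a fold change confined to the short transcript
#' variant's unique 3'UTR.
#'
#' @param frac_dar_up,frac_dar_down Fractions of accessibility features
#'   with a true old/young fold change (defaults 0.05 / 0.012, preserving
#'   the observed up:down asymmetry direction).
#' @param dar_fc True linear fold change of differential features.
#' @param frac_bivalent Fraction of genes whose promoters are bivalent.
#' @param frac_bivalent_changed Fraction of bivalent promoters with an age
#'   change of at least one mark.
#' @param bivalency_change_probs Probability over the 8 change groups (see
#'   [classify_change()]) for changed bivalent promoters; loss groups
#'   dominate by default.
#' @param mark_fc Linear fold change applied to a changed mark's height.
#' @param tad_compaction_frac Fraction of TADs given increased internal
#'   contact intensity in the old maps.
#' @param tad_compaction_m Intensity multiplier for compacted TADs.
#' @param tad_compaction_b_bias Relative sampling weight of B-block TADs
#'   when choosing the compacted set.
#' @param bb_longrange_depletion Multiplier (< 1) on old-map contacts
#'   between B bins separated by more than `longrange_split` bp.
#' @param shortrange_gain Multiplier on old-map contacts below
#'   `longrange_split`.  Default 1: the short-range gain of the old maps is
#'   generated by the compacted-TAD set itself.
#' @param longrange_split Distance separating short- from long-range
#'   contacts (default 5 Mb).
#' @param variant_fc Old/young fold change of the short variant's unique
#'   3'UTR signal (canonical variant unchanged).
#' @param frac_deg_up,frac_deg_down Fractions of genes (outside the
#'   bivalency-driven set) with a direct expression change.
#' @param deg_fc Linear fold change of those genes.
#' @param nb_dispersion Negative-binomial dispersion of all counts.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(frac_dar_up = 0.05, frac_dar_down = 0.012,
                        dar_fc = 2.0,
                        frac_bivalent = 0.3, frac_bivalent_changed = 0.2,
                        bivalency_change_probs = c(0.02, 0.08, 0.02, 0.10,
                                                   0.02, 0.18, 0.18, 0.40),
                        mark_fc = 1.8,
                        tad_compaction_frac = 0.35, tad_compaction_m = 1.5,
                        tad_compaction_b_bias = 3,
                        bb_longrange_depletion = 0.5, shortrange_gain = 1.0,
                        longrange_split = 5e6,
                        variant_fc = 3.0,
                        frac_deg_up = 0.05, frac_deg_down = 0.05,
                        deg_fc = 2.0,
                        nb_dispersion = 0.03) {
  p <- as.numeric(bivalency_change_probs)
  stopifnot(length(p) == 8, all(p >= 0), abs(sum(p) - 1) < 1e-8,
            dar_fc > 0, mark_fc > 1, tad_compaction_m > 0,
            bb_longrange_depletion > 0, shortrange_gain > 0,
            variant_fc > 0, nb_dispersion > 0,
            frac_dar_up >= 0, frac_dar_up <= 1,
            frac_dar_down >= 0, frac_dar_down <= 1,
            frac_bivalent >= 0, frac_bivalent <= 1)
  structure(list(frac_dar_up = frac_dar_up, frac_dar_down = frac_dar_down,
                 dar_fc = dar_fc, frac_bivalent = frac_bivalent,
                 frac_bivalent_changed = frac_bivalent_changed,
                 bivalency_change_probs = p, mark_fc = mark_fc,
                 tad_compaction_frac = tad_compaction_frac,
                 tad_compaction_m = tad_compaction_m,
                 tad_compaction_b_bias = tad_compaction_b_bias,
                 bb_longrange_depletion = bb_longrange_depletion,
                 shortrange_gain = shortrange_gain,
                 longrange_split = longrange_split,
                 variant_fc = variant_fc,
                 frac_deg_up = frac_deg_up, frac_deg_down = frac_deg_down,
                 deg_fc = deg_fc, nb_dispersion = nb_dispersion),
            class = "effect_spec")
}

#' Null effect specification (global null)
#'
#' All multipliers 1 and all effect fractions 0: young and old arms differ
#' only by sampling noise.  Used for false-positive calibration.
#'
#' @return An `effect_spec`.
#' @export
null_effect_spec <- function() {
  effect_spec(frac_dar_up = 0, frac_dar_down = 0, dar_fc = 1,
              frac_bivalent = 0.3, frac_bivalent_changed = 0,
              tad_compaction_frac = 0, tad_compaction_m = 1,
              bb_longrange_depletion = 1, shortrange_gain = 1,
              variant_fc = 1, frac_deg_up = 0, frac_deg_down = 0,
              deg_fc = 1)
}

#' Cohort specification
#'
#' @param seed Integer master seed; every stochastic quantity in the cohort
#'   derives from it.
#' @param chroms Named numeric vector of chromosome lengths in bp; lengths
#'   must be divisible by both bin sizes.
#' @param n_genes Total number of genes across the genome.
#' @param n_acc_features Number of accessibility (ATAC) features.
#' @param bin_size_compartment Compartment analysis resolution (bp).
#' @param bin_size_tad TAD analysis resolution (bp).
#' @param n_replicates Replicates per age group (>= 2).
#' @param effects An [effect_spec()].
#' @param contact_scale Expected contact count at one-bin separation for a
#'   neutral pair at the TAD resolution; controls sequencing depth.
#' @param decay_alpha Power-law distance-decay exponent of P(s).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(seed, chroms = c(chr1 = 2e7, chr2 = 2e7),
                        n_genes = 400, n_acc_features = 2000,
                        bin_size_compartment = 1e5, bin_size_tad = 2.5e4,
                        n_replicates = 4, effects = effect_spec(),
                        contact_scale = 50, decay_alpha = 1.0) {
  stopifnot(n_replicates >= 2,
            all(chroms %% bin_size_compartment == 0),
            all(chroms %% bin_size_tad == 0))
  structure(list(seed = as.integer(seed), chroms = chroms,
                 n_genes = n_genes, n_acc_features = n_acc_features,
                 bin_size_compartment = bin_size_compartment,
                 bin_size_tad = bin_size_tad,
                 n_replicates = n_replicates, effects = effects,
                 contact_scale = contact_scale, decay_alpha = decay_alpha),
            class = "cohort_spec")
}

# deterministic sub-seed derived from the master seed and a context code,
# kept inside 32-bit integer range
derive_seed <- function(seed, code) {
  as.integer((as.numeric(seed) * 1009 + code) %% 2147483647)
}

group_code <- function(group) {
  match(group, c("young", "old", "ctrl", "kd")) * 100000
}

#' Generate the synthetic genome: genes, compartment blocks and TADs
#'
#' Each chromosome is tiled with alternating A/B blocks (each > 1 Mb,
#' aligned to the compartment bin size), blocks are tiled with TADs
#' (200 kb - 1 Mb, aligned to the TAD bin size), and genes are placed with
#' a 4:1 preference for A blocks.  Exactly one gene carries two transcript
#' variants sharing the promoter and first exons, the shorter one with a
#' variant-unique 3'UTR.  The compacted-TAD set is drawn here (biased
#' toward B blocks) and recorded in the truth tables.
#'
#' @param spec A [cohort_spec()].
#' @return A list (class `cohort_truth`) with elements `blocks`, `tads`,
#'   `genes` (list of [gene_model()]), `gene_table`, `acc_features`,
#'   `variant_gene_id`, and the `spec`.
#' @export
generate_genome <- function(spec) {
  set.seed(derive_seed(spec$seed, 1))
  eff <- spec$effects
  bsc <- spec$bin_size_compartment
  bst <- spec$bin_size_tad
  blocks <- NULL
  tads <- NULL
  for (ch in names(spec$chroms)) {
    len <- spec$chroms[[ch]]
    # alternating A/B blocks, lengths 1.2-2 Mb in compartment-bin units;
    # the fine tiling keeps a good share of same-label block pairs beyond
    # the 5 Mb long-range split on a 20 Mb chromosome
    pos <- 0
    lab <- sample(c("A", "B"), 1)
    while (pos < len) {
      bl <- sample(seq(12, 20))[1] * bsc
      if (len - pos - bl < 12 * bsc) bl <- len - pos
      blocks <- rbind(blocks,
                      data.frame(chrom = ch, start = pos, end = pos + bl,
                                 label = lab))
      pos <- pos + bl
      lab <- if (lab == "A") "B" else "A"
    }
    # TADs tile blocks: 200 kb - 1 Mb in TAD-bin units
    bch <- blocks[blocks$chrom == ch, ]
    for (k in seq_len(nrow(bch))) {
      tpos <- bch$start[k]
      while (tpos < bch$end[k]) {
        tl <- sample(seq(8, 40))[1] * bst
        if (bch$end[k] - tpos - tl < 8 * bst) tl <- bch$end[k] - tpos
        tads <- rbind(tads,
                      data.frame(chrom = ch, start = tpos, end = tpos + tl,
                                 block_label = bch$label[k]))
        tpos <- tpos + tl
      }
    }
  }
  blocks$block_id <- paste0(blocks$chrom, "_blk", ave(seq_len(nrow(blocks)),
                                                      blocks$chrom,
                                                      FUN = seq_along))
  tads$tad_id <- paste0(tads$chrom, "_tad", ave(seq_len(nrow(tads)),
                                                tads$chrom, FUN = seq_along))
  # compacted-TAD set, biased toward B blocks
  n_comp <- round(eff$tad_compaction_frac * nrow(tads))
  w <- ifelse(tads$block_label == "B", eff$tad_compaction_b_bias, 1)
  comp_idx <- if (n_comp > 0)
    sample(seq_len(nrow(tads)), n_comp, prob = w) else integer(0)
  tads$compacted <- seq_len(nrow(tads)) %in% comp_idx

  # genes: A-block preference 4:1 by length
  wblk <- (blocks$end - blocks$start) * ifelse(blocks$label == "A", 4, 1)
  gene_blk <- sample(seq_len(nrow(blocks)), spec$n_genes, replace = TRUE,
                     prob = wblk)
  genes <- vector("list", spec$n_genes)
  gene_tab <- NULL
  for (i in seq_len(spec$n_genes)) {
    b <- blocks[gene_blk[i], ]
    glen <- sample(5:30, 1) * 1000
    gstart <- b$start + sample.int(max(1, b$end - b$start - glen), 1)
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("gene%04d", i)
    n_ex <- sample(3:8, 1)
    # exon starts spread across the gene, 400 bp - 2 kb exons, no overlap
    cuts <- sort(sample(seq(0, glen - 2000, by = 200), n_ex))
    exl <- pmin(sample(seq(400, 2000, by = 100), n_ex, replace = TRUE),
                diff(c(cuts, glen)) - 100)
    exl <- pmax(exl, 200)
    ex <- genomic_intervals(b$chrom, gstart + cuts, gstart + cuts + exl,
                            strand = strand)
    genes[[i]] <- gene_model(gid, b$chrom, strand, ex)
    gene_tab <- rbind(gene_tab,
                      data.frame(gene_id = gid, chrom = b$chrom,
                                 strand = strand,
                                 start = gstart, end = gstart + glen,
                                 block_label = b$label,
                                 stringsAsFactors = FALSE))
  }
  # the two-variant gene: rebuilt with a fixed exon architecture on the
  # plus strand inside an A block (first A-block gene is replaced)
  vi <- which(gene_tab$block_label == "A")[1]
  b <- blocks[gene_blk[vi], ]
  gstart <- b$start + 10000
  gid <- gene_tab$gene_id[vi]
  shared <- genomic_intervals(b$chrom,
                              gstart + c(0, 3000, 6000, 9000, 12000),
                              gstart + c(1000, 4000, 7000, 10000, 12800),
                              strand = "+")
  short_utr <- genomic_intervals(b$chrom, gstart + 13000, gstart + 14000,
                                 strand = "+")
  canon_tail <- genomic_intervals(b$chrom, gstart + c(15000, 17000, 19000),
                                  gstart + c(16000, 18000, 20000),
                                  strand = "+")
  v_short <- transcript_variant(paste0(gid, ".short"),
                                rbind(shared, short_utr), short_utr)
  v_canon <- transcript_variant(paste0(gid, ".canonical"),
                                rbind(shared, canon_tail), canon_tail)
  genes[[vi]] <- gene_model(gid, b$chrom, "+",
                            rbind(shared, short_utr, canon_tail),
                            list(v_canon, v_short))
  validate_variants(genes[[vi]])
  gene_tab$strand[vi] <- "+"
  gene_tab$start[vi] <- gstart
  gene_tab$end[vi] <- gstart + 20000

  gene_tab$tss <- vapply(genes, function(g) g$tss, 0)

  # bivalency truth
  n_biv <- round(eff$frac_bivalent * spec$n_genes)
  biv_idx <- if (n_biv > 0) sample(seq_len(spec$n_genes), n_biv)
             else integer(0)
  gene_tab$bivalent <- seq_len(spec$n_genes) %in% biv_idx
  gene_tab$biv_group <- 0L
  if (n_biv > 0 && eff$frac_bivalent_changed > 0) {
    n_chg <- round(eff$frac_bivalent_changed * n_biv)
    chg <- sample(biv_idx, n_chg)
    gene_tab$biv_group[chg] <- sample(1:8, n_chg, replace = TRUE,
                                      prob = eff$bivalency_change_probs)
  }
  # expression truth: bivalency-linked changes first, then direct DEGs
  gene_tab$expr_base <- pmax(20, stats::rlnorm(spec$n_genes, log(200), 1))
  gene_tab$expr_change <- "none"
  gene_tab$expr_change[gene_tab$biv_group == 8] <- "up"      # K27me3 loss
  gene_tab$expr_change[gene_tab$biv_group %in% c(4, 6, 7)] <- "down"
  free <- which(gene_tab$expr_change == "none" &
                  seq_len(spec$n_genes) != vi)
  n_up <- round(eff$frac_deg_up * spec$n_genes)
  n_dn <- round(eff$frac_deg_down * spec$n_genes)
  if (n_up + n_dn > 0 && length(free) >= n_up + n_dn) {
    pick <- sample(free, n_up + n_dn)
    gene_tab$expr_change[pick[seq_len(n_up)]] <- "up"
    gene_tab$expr_change[pick[n_up + seq_len(n_dn)]] <- "down"
  }
  # the variant gene: moderately expressed, no gene-level change
  gene_tab$expr_change[vi] <- "none"
  gene_tab$expr_base[vi] <- 300

  # accessibility features and DAR truth (injected features get base means
  # >= 50 so power statements refer to a defined mean regime)
  n_acc <- spec$n_acc_features
  acc_chrom <- sample(names(spec$chroms), n_acc, replace = TRUE)
  acc_start <- vapply(acc_chrom, function(ch)
    sample.int(spec$chroms[[ch]] - 1000, 1), 0)
  acc <- data.frame(feature_id = sprintf("acc%05d", seq_len(n_acc)),
                    chrom = acc_chrom, start = acc_start,
                    end = acc_start + sample(300:1500, n_acc,
                                             replace = TRUE),
                    base_mean = pmax(20, stats::rlnorm(n_acc, log(120),
                                                       0.6)),
                    dar = "none", stringsAsFactors = FALSE)
  n_up <- round(eff$frac_dar_up * n_acc)
  n_dn <- round(eff$frac_dar_down * n_acc)
  if (n_up + n_dn > 0) {
    pick <- sample(n_acc, n_up + n_dn)
    acc$dar[pick[seq_len(n_up)]] <- "up"
    acc$dar[pick[n_up + seq_len(n_dn)]] <- "down"
    acc$base_mean[pick] <- pmax(acc$base_mean[pick], 50)
  }
  rownames(acc) <- NULL

  structure(list(spec = spec, blocks = blocks, tads = tads, genes = genes,
                 gene_table = gene_tab, acc_features = acc,
                 variant_gene_id = gene_tab$gene_id[vi]),
            class = "cohort_truth")
}

# per-bin block label / TAD index vectors at a given resolution
bin_labels <- function(truth, chrom, resolution) {
  len <- truth$spec$chroms[[chrom]]
  n <- len / resolution
  mids <- (seq_len(n) - 0.5) * resolution
  b <- truth$blocks[truth$blocks$chrom == chrom, ]
  lab <- b$label[findInterval(mids, b$start)]
  t <- truth$tads[truth$tads$chrom == chrom, ]
  tad <- findInterval(mids, t$start)
  list(n = n, label = lab, tad = tad,
       tad_compacted = t$compacted[tad])
}

#' Generate Hi-C contact maps for one sample
#'
#' The expected count of bin pair (i, j) is
#' `L * s^(-alpha) * c_ij * t_ij * a_ij` with `s` the separation in bins,
#' `c_ij` a same-compartment affinity boost, `t_ij` an intra-TAD boost and
#' `a_ij` the age-effect multipliers (old group only: B-B long-range
#' depletion, global short-range gain, compacted-TAD intensity).  Realized
#' counts are Poisson; each replicate carries a log-normal depth factor.
#'
#' @param spec A [cohort_spec()].
#' @param truth Output of [generate_genome()].
#' @param group `"young"` or `"old"`.
#' @param replicate Replicate index (1-based).
#' @param resolution Bin size in bp (defaults to the TAD resolution).
#' @return Named list of [contact_map()] per chromosome; all share the
#'   sample's `total_pairs`.
#' @export
generate_contacts <- function(spec, truth, group, replicate,
                              resolution = spec$bin_size_tad) {
  stopifnot(group %in% c("young", "old"))
  set.seed(derive_seed(spec$seed,
                       2 + group_code(group) + 1000 * replicate +
                         resolution / 1000))
  eff <- spec$effects
  depth <- stats::rlnorm(1, 0, 0.1)
  # the expected model is resolution-aware: one-bin separation carries
  # contact_scale counts at the TAD resolution, scaled by bin area
  L <- spec$contact_scale * (resolution / spec$bin_size_tad)^2 * depth
  maps <- list()
  for (ch in names(spec$chroms)) {
    bl <- bin_labels(truth, ch, resolution)
    n <- bl$n
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pairs[, 1]; j <- pairs[, 2]
    s <- (j - i)
    lambda <- L * s^(-spec$decay_alpha)
    same_lab <- bl$label[i] == bl$label[j]
    lambda <- lambda * ifelse(same_lab, 1.6, 1)
    same_tad <- bl$tad[i] == bl$tad[j]
    lambda <- lambda * ifelse(same_tad, 2.0, 1)
    if (group == "old") {
      dist_bp <- s * resolution
      bb_long <- bl$label[i] == "B" & bl$label[j] == "B" &
        dist_bp > eff$longrange_split
      lambda[bb_long] <- lambda[bb_long] * eff$bb_longrange_depletion
      short <- dist_bp < eff$longrange_split
      lambda[short] <- lambda[short] * eff$shortrange_gain
      comp <- same_tad & bl$tad_compacted[i]
      lambda[comp] <- lambda[comp] * eff$tad_compaction_m
    }
    cnt <- stats::rpois(length(lambda), lambda)
    keep <- cnt > 0
    maps[[ch]] <- contact_map(ch, resolution, n,
                              i[keep] - 1L, j[keep] - 1L, cnt[keep],
                              total_pairs = 1)  # patched below
  }
  tp <- sum(vapply(maps, function(m) sum(m$df$count), 0))
  for (ch in names(maps)) maps[[ch]]$total_pairs <- tp
  maps
}

# promoter peak geometry shared by the track generator and tests:
# K4me3 straddles the TSS, K27me3 overlaps the TSS and reaches downstream
promoter_peak <- function(g, mark) {
  if (mark == "H3K4me3") {
    if (g$strand == "+") c(g$tss - 500, g$tss + 500)
    else c(g$tss - 500, g$tss + 500)
  } else {                      # H3K27me3
    if (g$strand == "+") c(g$tss - 300, g$tss + 1500)
    else c(g$tss - 1500, g$tss + 300)
  }
}

# fold change applied to mark heights in the old group for a bivalency
# change group (pair = (K4me3 state, K27me3 state))
biv_group_states <- function(group_id) {
  tab <- list(c("up", "up"), c("up", "unchanged"), c("up", "down"),
              c("unchanged", "up"), c("down", "up"),
              c("down", "unchanged"), c("down", "down"),
              c("unchanged", "down"))
  if (group_id >= 1 && group_id <= 8) tab[[group_id]]
  else c("unchanged", "unchanged")
}

state_fc <- function(state, fc) switch(state, up = fc, down = 1 / fc, 1)

#' Generate peaks, tracks and count columns for one sample
#'
#' Produces promoter-anchored H3K4me3/H3K27ac peaks, H3K27me3 peaks at
#' bivalent promoters, gene-body H3K36me3, domain-scale H3K27me3/H3K9me3
#' over B blocks, 1 kb binned tracks per mark, and negative-binomial count
#' columns for accessibility features, gene expression, and the variant
#' gene's region-level coverage.  Old-group samples carry the injected age
#' effects from the cohort's [effect_spec()].
#'
#' @param spec A [cohort_spec()].
#' @param truth Output of [generate_genome()].
#' @param group `"young"` or `"old"`.
#' @param replicate Replicate index.
#' @return List with `peaks` (data frame: chrom, start, end, mark, sample,
#'   height), `tracks` (per mark, per chromosome [binned_track()]),
#'   `acc_counts`, `expr_counts` (named integer vectors),
#'   `variant_coverage` (region-level count data frame), `libsize`, and
#'   `sample_id`.
#' @export
generate_tracks_and_counts <- function(spec, truth, group, replicate) {
  stopifnot(group %in% c("young", "old"))
  set.seed(derive_seed(spec$seed,
                       3 + group_code(group) + 1000 * replicate))
  eff <- spec$effects
  gt <- truth$gene_table
  sample_id <- paste0(group, "_rep", replicate)
  old <- group == "old"
  repnoise <- function(n) stats::rlnorm(n, 0, 0.05)

  marks <- c("H3K4me3", "H3K27me3", "H3K27ac", "H3K36me3", "H3K9me3")
  peaks <- NULL
  for (i in seq_len(nrow(gt))) {
    g <- truth$genes[[i]]
    st <- biv_group_states(gt$biv_group[i])
    k4fc <- if (old) state_fc(st[1], eff$mark_fc) else 1
    k27fc <- if (old) state_fc(st[2], eff$mark_fc) else 1
    p4 <- promoter_peak(g, "H3K4me3")
    peaks <- rbind(peaks, data.frame(
      chrom = g$chrom, start = p4[1], end = p4[2], mark = "H3K4me3",
      sample = sample_id, gene_id = gt$gene_id[i],
      height = 8 * k4fc * repnoise(1), stringsAsFactors = FALSE))
    if (gt$bivalent[i]) {
      p27 <- promoter_peak(g, "H3K27me3")
      peaks <- rbind(peaks, data.frame(
        chrom = g$chrom, start = p27[1], end = p27[2], mark = "H3K27me3",
        sample = sample_id, gene_id = gt$gene_id[i],
        height = 4 * k27fc * repnoise(1), stringsAsFactors = FALSE))
    }
    peaks <- rbind(peaks, data.frame(
      chrom = g$chrom, start = g$tss - 400, end = g$tss + 600,
      mark = "H3K27ac", sample = sample_id, gene_id = gt$gene_id[i],
      height = 5 * repnoise(1), stringsAsFactors = FALSE))
    peaks <- rbind(peaks, data.frame(
      chrom = g$chrom, start = gt$start[i], end = gt$end[i],
      mark = "H3K36me3", sample = sample_id, gene_id = gt$gene_id[i],
      height = 3 * repnoise(1), stringsAsFactors = FALSE))
  }

  # 1 kb tracks: peak signal + B-block repressive domains + background
  tracks <- list()
  for (mk in marks) {
    tracks[[mk]] <- list()
    for (ch in names(spec$chroms)) {
      nb <- spec$chroms[[ch]] / 1000
      v <- stats::rexp(nb, rate = 20)          # background ~0.05
      bks <- truth$blocks[truth$blocks$chrom == ch, ]
      if (mk %in% c("H3K27me3", "H3K9me3")) {
        for (k in which(bks$label == "B")) {
          idx <- (bks$start[k] / 1000 + 1):(bks$end[k] / 1000)
          v[idx] <- v[idx] + 0.5 * repnoise(1)
        }
      }
      pk <- peaks[peaks$mark == mk & peaks$chrom == ch, ]
      for (k in seq_len(nrow(pk))) {
        lo <- max(1, floor(pk$start[k] / 1000) + 1)
        hi <- min(nb, ceiling(pk$end[k] / 1000))
        v[lo:hi] <- v[lo:hi] + pk$height[k]
      }
      tracks[[mk]][[ch]] <- binned_track(ch, 1000, v)
    }
  }

  nbv <- function(mu) stats::rnbinom(length(mu), mu = mu,
                                     size = 1 / eff$nb_dispersion)
  depth <- stats::rlnorm(1, 0, 0.05)
  acc_mu <- truth$acc_features$base_mean * depth
  if (old) {
    acc_mu <- acc_mu * ifelse(truth$acc_features$dar == "up", eff$dar_fc,
                              ifelse(truth$acc_features$dar == "down",
                                     1 / eff$dar_fc, 1))
  }
  acc_counts <- stats::setNames(nbv(acc_mu), truth$acc_features$feature_id)

  expr_mu <- gt$expr_base * depth
  if (old) {
    expr_mu <- expr_mu * ifelse(gt$expr_change == "up", eff$deg_fc,
                                ifelse(gt$expr_change == "down",
                                       1 / eff$deg_fc, 1))
  }
  expr_counts <- stats::setNames(nbv(expr_mu), gt$gene_id)

  # variant-gene region coverage: shared block, canonical-unique exons,
  # short-variant-unique 3'UTR; only the last responds to age
  vg <- truth$genes[[which(gt$gene_id == truth$variant_gene_id)]]
  v_can <- vg$variants[[1]]; v_sho <- vg$variants[[2]]
  shared_ex <- interval_setdiff(vg$exons,
                                rbind(v_can$unique_regions,
                                      v_sho$unique_regions))
  mk_cov <- function(regions, mu_each) {
    data.frame(chrom = regions$chrom, start = regions$start,
               end = regions$end,
               count = nbv(rep(mu_each, nrow(regions))),
               stringsAsFactors = FALSE)
  }
  sho_mu <- 150 * depth * if (old) eff$variant_fc else 1
  variant_coverage <- rbind(
    cbind(mk_cov(shared_ex, 300 * depth), region = "shared"),
    cbind(mk_cov(v_can$unique_regions, 200 * depth), region = "canonical"),
    cbind(mk_cov(v_sho$unique_regions, sho_mu), region = "short"))

  libsize <- sum(expr_counts) + sum(variant_coverage$count)
  list(peaks = peaks, tracks = tracks, acc_counts = acc_counts,
       expr_counts = expr_counts, variant_coverage = variant_coverage,
       libsize = libsize, sample_id = sample_id)
}

#' Generate a full young/old cohort
#'
#' Convenience wrapper: genome truth plus per-sample tracks/counts and
#' assembled [count_matrix()] objects for accessibility and expression.
#'
#' @param spec A [cohort_spec()].
#' @param contacts Logical; also generate contact maps at the TAD
#'   resolution (default FALSE, they are comparatively expensive).
#' @return List with `truth`, `samples` (list per sample), `acc` and
#'   `expr` count matrices, and optionally `contact_maps`.
#' @export
generate_cohort <- function(spec, contacts = FALSE) {
  truth <- generate_genome(spec)
  samples <- list()
  for (grp in c("young", "old"))
    for (r in seq_len(spec$n_replicates))
      samples[[paste0(grp, "_rep", r)]] <-
        generate_tracks_and_counts(spec, truth, grp, r)
  meta <- data.frame(
    sample_id = names(samples),
    group = sub("_rep.*", "", names(samples)),
    replicate = as.integer(sub(".*_rep", "", names(samples))))
  acc <- count_matrix(vapply(samples, function(s) s$acc_counts,
                             numeric(spec$n_acc_features)), meta)
  expr <- count_matrix(vapply(samples, function(s) s$expr_counts,
                              numeric(spec$n_genes)), meta)
  out <- list(truth = truth, samples = samples, acc = acc, expr = expr)
  if (contacts) {
    out$contact_maps <- list()
    for (nm in names(samples)) {
      grp <- sub("_rep.*", "", nm)
      r <- as.integer(sub(".*_rep", "", nm))
      out$contact_maps[[nm]] <- generate_contacts(spec, truth, grp, r)
    }
  }
  out
}

#' Generate a control/knockdown expression cohort with a reversal effect
#'
#' Both arms start from the old expression state; the knockdown arm
#' reverses the aging expression changes (aging-up genes return to
#' baseline, aging-down genes recover) and suppresses the short variant's
#' unique-region signal.  Used to exercise the reversal analysis.
#'
#' @param spec A [cohort_spec()].
#' @param truth Output of [generate_genome()].
#' @param n_replicates Replicates per arm (default `spec$n_replicates`).
#' @return List with `expr` (a [count_matrix()] with groups ctrl/kd) and
#'   `variant_coverage` per sample.
#' @export
generate_kd_cohort <- function(spec, truth, n_replicates = spec$n_replicates) {
  eff <- spec$effects
  gt <- truth$gene_table
  old_mu <- gt$expr_base * ifelse(gt$expr_change == "up", eff$deg_fc,
                                  ifelse(gt$expr_change == "down",
                                         1 / eff$deg_fc, 1))
  young_mu <- gt$expr_base
  counts <- NULL
  meta <- NULL
  for (grp in c("ctrl", "kd")) {
    for (r in seq_len(n_replicates)) {
      set.seed(derive_seed(spec$seed, 4 + group_code(grp) + 1000 * r))
      depth <- stats::rlnorm(1, 0, 0.05)
      mu <- if (grp == "ctrl") old_mu else young_mu
      cnt <- stats::rnbinom(length(mu), mu = mu * depth,
                            size = 1 / eff$nb_dispersion)
      counts <- cbind(counts, cnt)
      meta <- rbind(meta, data.frame(sample_id = paste0(grp, "_rep", r),
                                     group = grp, replicate = r))
    }
  }
  rownames(counts) <- gt$gene_id
  colnames(counts) <- meta$sample_id
  list(expr = count_matrix(counts, meta))
}

#' Write a cohort directory tree
#'
#' Emits the on-disk formats the readers consume (BED peaks, bedGraph
#' tracks, contact triplets, count TSVs, GTF-lite gene model) plus a
#' `truth/` subdirectory of TSV ground-truth tables for tests.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  truth <- cohort$truth
  write_gtf(truth$genes, file.path(dir, "genes.gtf"))
  write_counts(cohort$acc, file.path(dir, "acc_counts.tsv"))
  write_counts(cohort$expr, file.path(dir, "expr_counts.tsv"))
  for (nm in names(cohort$samples)) {
    s <- cohort$samples[[nm]]
    pk <- s$peaks
    write_bed(genomic_intervals(pk$chrom, pk$start, pk$end,
                                name = paste(pk$mark, pk$gene_id, sep = ":"),
                                score = pk$height),
              file.path(dir, paste0("peaks_", nm, ".bed")))
    for (mk in names(s$tracks))
      write_bedgraph(s$tracks[[mk]],
                     file.path(dir, paste0("track_", mk, "_", nm,
                                           ".bedgraph")))
  }
  if (!is.null(cohort$contact_maps))
    for (nm in names(cohort$contact_maps))
      write_contacts(cohort$contact_maps[[nm]],
                     file.path(dir, paste0("contacts_", nm, ".tsv")))
  tw <- function(x, f) utils::write.table(
    x, file.path(dir, "truth", f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tw(truth$blocks, "blocks.tsv")
  tw(truth$tads, "tads.tsv")
  tw(truth$gene_table, "genes.tsv")
  tw(truth$acc_features, "acc_features.tsv")
  invisible(dir)
}
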