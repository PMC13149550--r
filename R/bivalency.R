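#' Assign H3K4me3 and H3K27me3 peaks to gene promoters
#'
#' The assignment windows are deliberately asymmetric.  H3K4me3: a peak is
#' assigned when its gap to the TSS is at most 1 kb on either side (0 when
#' overlapping).  H3K27me3: a peak is assigned only when it overlaps the
#' TSS or lies entirely within the 2 kb immediately downstream of the TSS
#' in the gene's orientation, so repressive signal in intergenic regions
#' upstream of the promoter is never counted toward bivalency.
#'
#' @param k4_peaks,k27_peaks Interval data frames of merged peaks per mark.
#' @param genes List of [gene_model()]; all must be stranded.
#' @param k4_window H3K4me3 TSS gap limit in bp (default 1000).
#' @param k27_downstream H3K27me3 downstream window in bp (default 2000).
#' @return Data frame per gene: `gene_id`, `n_k4`, `n_k27`, `bivalent`.
#' @export
assign_marks_to_promoters <- function(k4_peaks, k27_peaks, genes,
                                      k4_window = 1000,
                                      k27_downstream = 2000) {
  out <- data.frame(gene_id = vapply(genes, function(g) g$gene_id, ""),
                    n_k4 = 0L, n_k27 = 0L, stringsAsFactors = FALSE)
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    if (!g$strand %in% c("+", "-"))
      stop("unstranded gene ", g$gene_id, ": downstream undefined")
    k4 <- k4_peaks[k4_peaks$chrom == g$chrom, , drop = FALSE]
    if (nrow(k4)) {
      d <- vapply(seq_len(nrow(k4)), function(r)
        abs(distance_to_tss(k4[r, ], g)), 0)
      out$n_k4[gi] <- sum(d <= k4_window)
    }
    k27 <- k27_peaks[k27_peaks$chrom == g$chrom, , drop = FALSE]
    if (nrow(k27)) {
      over <- k27$start <= g$tss & g$tss < k27$end
      if (g$strand == "+") {
        within_dn <- k27$start > g$tss & k27$end <= g$tss + k27_downstream
      } else {
        within_dn <- k27$end <= g$tss & k27$start >= g$tss - k27_downstream
      }
      out$n_k27[gi] <- sum(over | within_dn)
    }
  }
  out$bivalent <- out$n_k4 > 0 & out$n_k27 > 0
  out
}

#' Per-age bivalent gene sets and Venn partition
#'
#' @param assign_young,assign_old Outputs of
#'   [assign_marks_to_promoters()] on the merged per-age peak sets.
#' @return List with `young` and `old` bivalent gene-id vectors and
#'   `venn = c(young_only, old_only, shared)`; totals satisfy
#'   `young_total = young_only + shared`, `old_total = old_only + shared`.
#' @export
call_bivalent <- function(assign_young, assign_old) {
  ys <- assign_young$gene_id[assign_young$bivalent]
  os <- assign_old$gene_id[assign_old$bivalent]
  shared <- intersect(ys, os)
  list(young = ys, old = os,
       venn = c(young_only = length(setdiff(ys, os)),
                old_only = length(setdiff(os, ys)),
                shared = length(shared)),
       young_total = length(ys), old_total = length(os))
}

# canonical bivalency change-group table: pair = (K4me3 state, K27me3
# state); group 8 is K27me3-loss-only, the class the expression linkage
# anchors on
biv_group_table <- function() {
  data.frame(group_id = 1:8,
             k4_state = c("up", "up", "up", "unchanged", "down", "down",
                          "down", "unchanged"),
             k27_state = c("up", "unchanged", "down", "up", "up",
                           "unchanged", "down", "down"),
             stringsAsFactors = FALSE)
}

#' Classify a bivalent promoter's mark changes into the 8-group taxonomy
#'
#' Each mark's state is `up` if its old/young fold change exceeds
#' `fc_min`, `down` if below `1/fc_min`, otherwise `unchanged`.  The eight
#' non-null (state, state) pairs map to groups 1-8; promoters with both
#' marks unchanged are excluded (group `NA`).
#'
#' @param k4_fc,k27_fc Linear old/young fold changes (vectors).
#' @param fc_min Fold-change threshold (default 1.5).
#' @return Data frame with `k4_state`, `k27_state`, `group_id` (`NA` for
#'   the both-unchanged class).
#' @export
classify_change <- function(k4_fc, k27_fc, fc_min = 1.5) {
  if (any(k4_fc <= 0) || any(k27_fc <= 0))
    stop("fold changes must be positive")
  state <- function(fc) ifelse(fc > fc_min, "up",
                               ifelse(fc < 1 / fc_min, "down",
                                      "unchanged"))
  k4 <- state(k4_fc); k27 <- state(k27_fc)
  tab <- biv_group_table()
  key <- paste(tab$k4_state, tab$k27_state)
  gid <- tab$group_id[match(paste(k4, k27), key)]
  data.frame(k4_state = k4, k27_state = k27, group_id = gid,
             stringsAsFactors = FALSE)
}

#' Classify expression changes for the bivalency linkage
#'
#' `up`/`down` require fold change beyond `fc_min` at `fdr < fdr_max`;
#' everything else is `no_significant_change` (which deliberately pools
#' unexpressed genes, near-identical genes below `similar_fc`, and genes
#' that change but miss significance).
#'
#' @param results Output of [nb_wald_test()] on expression counts.
#' @param fc_min DEG fold-change threshold (default 1.5).
#' @param fdr_max DEG FDR threshold (default 0.05).
#' @param similar_fc Fold change below which expression counts as similar
#'   between ages (default 1.05); reported in the `similar` column.
#' @return Data frame `feature_id`, `expression_class`, `similar`.
#' @export
classify_expression <- function(results, fc_min = 1.5, fdr_max = 0.05,
                                similar_fc = 1.05) {
  up <- results$log2fc > log2(fc_min) & results$fdr < fdr_max
  dn <- results$log2fc < -log2(fc_min) & results$fdr < fdr_max
  data.frame(feature_id = results$feature_id,
             expression_class = ifelse(up, "up",
                                       ifelse(dn, "down",
                                              "no_significant_change")),
             similar = abs(results$log2fc) < log2(similar_fc),
             stringsAsFactors = FALSE)
}

#' Link bivalency change groups to expression classes
#'
#' @param changes Data frame with `gene_id` and `group_id` (1-8), e.g.
#'   built from [classify_change()].
#' @param expression Output of [classify_expression()] (joined on
#'   `gene_id` = `feature_id`; genes absent from the expression table fall
#'   in `no_significant_change`).
#' @return List with `contingency` (8 groups x 3 classes count matrix) and
#'   `per_class` (fraction of each expression class per group).
#' @export
link_expression <- function(changes, expression) {
  classes <- c("up", "down", "no_significant_change")
  cont <- matrix(0L, nrow = 8, ncol = 3,
                 dimnames = list(paste0("group", 1:8), classes))
  if (nrow(changes)) {
    cls <- expression$expression_class[
      match(changes$gene_id, expression$feature_id)]
    cls[is.na(cls)] <- "no_significant_change"
    tt <- table(factor(changes$group_id, levels = 1:8),
                factor(cls, levels = classes))
    cont[] <- as.integer(tt)
  }
  per_class <- sweep(cont, 2, pmax(colSums(cont), 1), "/")
  list(contingency = cont, per_class = per_class)
}
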