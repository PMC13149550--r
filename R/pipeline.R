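#' Default pipeline configuration
#'
#' A flat key/value list holding every threshold the analyses use; each
#' default equals the corresponding published rule where one exists.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @param ... Overrides for any default entry.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("chromage_run"),
                           ...) {
  cfg <- list(seed = seed, out_dir = out_dir,
              fc_min = 1.5, fdr_dar = 0.01, cpm_min = 1.5,
              fdr_deg = 0.05, similar_fc = 1.05, rep_fc = 1.2,
              range_split = 5e6, top_n = 200, tad_bin = 100,
              k4_window = 1000, k27_downstream = 2000,
              broad_height = 0.3, broad_p = 1e-4,
              n_replicates = 4, n_genes = 400, n_acc_features = 2000)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  bad <- vapply(cfg[c("fc_min", "cpm_min", "rep_fc", "range_split",
                      "top_n", "tad_bin", "k4_window", "k27_downstream",
                      "broad_height", "broad_p")], function(x) x <= 0,
                TRUE)
  if (any(bad)) stop("thresholds must be positive: ",
                     paste(names(bad)[bad], collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key/value configuration file
#'
#' @param path YAML (flat mapping) configuration file.
#' @return A `run_config` (unspecified keys take defaults).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

log_stage <- function(report, stage, msg, t0) {
  report$stages[[stage]] <- list(
    status = "ok", message = msg,
    seconds = round(as.numeric(Sys.time()) - t0, 2))
  message(sprintf("[%s] %s (%.1fs)", stage, msg,
                  as.numeric(Sys.time()) - t0))
  report
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a synthetic young/old cohort, then runs every stage in
#' dependency order: differential accessibility (DAR rule), histone peak
#' changes (replicate-consistency rule), bivalency calling and taxonomy
#' with expression linkage, Hi-C distance/compartment/TAD statistics, and
#' variant quantification with the knockdown reversal analysis.  Writes
#' TSV/BED outputs plus a machine-readable JSON run report.
#'
#' @param config A [default_config()] list (or path to a YAML file).
#' @return The run report list (also written to
#'   `<out_dir>/run_report.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = unclass(config), seed = config$seed,
                 package_version = as.character(
                   utils::packageVersion("chromage")),
                 stages = list(), manifest = character(0))
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report$manifest <<- c(report$manifest, name)
  }

  t0 <- as.numeric(Sys.time())
  spec <- cohort_spec(config$seed, n_genes = config$n_genes,
                      n_acc_features = config$n_acc_features,
                      n_replicates = config$n_replicates)
  cohort <- generate_cohort(spec)
  truth <- cohort$truth
  report <- log_stage(report, "simulate",
                      sprintf("%d genes, %d acc features, %d samples",
                              spec$n_genes, spec$n_acc_features,
                              length(cohort$samples)), t0)

  # differential accessibility
  t0 <- as.numeric(Sys.time())
  dar_res <- call_dars(nb_wald_test(cohort$acc), fc_min = config$fc_min,
                       cpm_min = config$cpm_min,
                       fdr_max = config$fdr_dar)
  emit(dar_res, "dar_results.tsv")
  report <- log_stage(report, "diff_counts",
                      sprintf("%d up, %d down of %d features",
                              sum(dar_res$call == "up"),
                              sum(dar_res$call == "down"),
                              nrow(dar_res)), t0)

  # replicate-consistent histone peak changes (promoter K4me3/K27me3)
  t0 <- as.numeric(Sys.time())
  ph <- peak_height_table(cohort)
  pk4 <- replicate_consistent_peak_changes(
    ph$k4, fc_merged_min = config$fc_min, fc_rep_min = config$rep_fc)
  pk27 <- replicate_consistent_peak_changes(
    ph$k27, fc_merged_min = config$fc_min, fc_rep_min = config$rep_fc)
  emit(pk4, "peak_changes_H3K4me3.tsv")
  emit(pk27, "peak_changes_H3K27me3.tsv")
  report <- log_stage(report, "diff_peaks",
                      sprintf("K4me3: %d changed; K27me3: %d changed",
                              sum(pk4$call != "unchanged"),
                              sum(pk27$call != "unchanged")), t0)

  # bivalency
  t0 <- as.numeric(Sys.time())
  biv <- bivalency_stage(cohort, config)
  emit(biv$per_gene, "bivalency_per_gene.tsv")
  emit(data.frame(t(biv$venn)), "bivalency_venn.tsv")
  emit(as.data.frame(biv$link$contingency), "bivalency_expression.tsv")
  report <- log_stage(report, "bivalency",
                      sprintf("venn %d/%d/%d, %d changed",
                              biv$venn[1], biv$venn[2], biv$venn[3],
                              biv$n_changed), t0)

  # Hi-C
  t0 <- as.numeric(Sys.time())
  hic <- hic_stage(spec, truth, config)
  emit(hic$pairs, "compartment_pairs.tsv")
  emit(hic$rpmm_tests, "compartment_tests.tsv")
  emit(hic$tads, "tad_calls.tsv")
  report <- log_stage(report, "hic",
                      sprintf("threshold %.3f, %d TADs increased",
                              hic$threshold,
                              sum(hic$tads$call == "increased")), t0)

  # variants + reversal
  t0 <- as.numeric(Sys.time())
  vr <- variant_stage(spec, truth, cohort, config)
  emit(vr$quants, "variant_quants.tsv")
  emit(vr$test, "variant_test.tsv")
  emit(data.frame(set = c("aging_up", "aging_down"),
                  mean_shift = c(vr$reversal$up_set$mean_shift,
                                 vr$reversal$down_set$mean_shift),
                  p = c(vr$reversal$up_set$p, vr$reversal$down_set$p)),
       "reversal.tsv")
  report <- log_stage(report, "variants",
                      sprintf("short-variant log2fc %.2f; reversal %s",
                              vr$test$log2fc[vr$short_idx],
                              vr$reversal$reversal), t0)

  report_path <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$manifest <- c(report$manifest, "run_report.json")
  report
}

# per-gene promoter peak heights in wide replicate layout
peak_height_table <- function(cohort) {
  build <- function(mark) {
    out <- NULL
    for (nm in names(cohort$samples)) {
      pk <- cohort$samples[[nm]]$peaks
      pk <- pk[pk$mark == mark, c("gene_id", "height")]
      names(pk)[2] <- nm
      out <- if (is.null(out)) pk else merge(out, pk, by = "gene_id")
    }
    out
  }
  list(k4 = build("H3K4me3"), k27 = build("H3K27me3"))
}

# merged per-age peak sets -> bivalency calls, taxonomy, expression link
bivalency_stage <- function(cohort, config) {
  truth <- cohort$truth
  merged_peaks <- function(group, mark) {
    pks <- NULL
    for (nm in names(cohort$samples)) {
      if (!startsWith(nm, group)) next
      pk <- cohort$samples[[nm]]$peaks
      pks <- rbind(pks, pk[pk$mark == mark, ])
    }
    agg <- stats::aggregate(height ~ chrom + start + end + gene_id, pks,
                            mean)
    genomic_intervals(agg$chrom, agg$start, agg$end,
                      gene_id = agg$gene_id, height = agg$height)
  }
  ay <- assign_marks_to_promoters(merged_peaks("young", "H3K4me3"),
                                  merged_peaks("young", "H3K27me3"),
                                  truth$genes,
                                  k4_window = config$k4_window,
                                  k27_downstream = config$k27_downstream)
  ao <- assign_marks_to_promoters(merged_peaks("old", "H3K4me3"),
                                  merged_peaks("old", "H3K27me3"),
                                  truth$genes,
                                  k4_window = config$k4_window,
                                  k27_downstream = config$k27_downstream)
  bv <- call_bivalent(ay, ao)
  both <- intersect(bv$young, bv$old)
  k4y <- merged_peaks("young", "H3K4me3")
  k4o <- merged_peaks("old", "H3K4me3")
  k27y <- merged_peaks("young", "H3K27me3")
  k27o <- merged_peaks("old", "H3K27me3")
  h <- function(pk, g) {
    v <- pk$height[pk$gene_id == g]
    if (length(v)) mean(v) else 0
  }
  k4_fc <- vapply(both, function(g) (h(k4o, g) + 1) / (h(k4y, g) + 1), 0)
  k27_fc <- vapply(both, function(g) (h(k27o, g) + 1) / (h(k27y, g) + 1),
                   0)
  cls <- classify_change(k4_fc, k27_fc, fc_min = config$fc_min)
  changes <- data.frame(gene_id = both, group_id = cls$group_id)
  changes <- changes[!is.na(changes$group_id), ]
  expr_res <- nb_wald_test(cohort$expr)
  expr_cls <- classify_expression(expr_res, fc_min = config$fc_min,
                                  fdr_max = config$fdr_deg,
                                  similar_fc = config$similar_fc)
  link <- link_expression(changes, expr_cls)
  per_gene <- data.frame(gene_id = ay$gene_id,
                         bivalent_young = ay$bivalent,
                         bivalent_old = ao$bivalent)
  per_gene$group_id <- changes$group_id[match(per_gene$gene_id,
                                              changes$gene_id)]
  list(per_gene = per_gene, venn = bv$venn, n_changed = nrow(changes),
       link = link, changes = changes)
}

# contact-map statistics at both resolutions
hic_stage <- function(spec, truth, config) {
  nrep <- spec$n_replicates
  maps_c <- list(); maps_t <- list()
  for (grp in c("young", "old")) {
    for (r in seq_len(nrep)) {
      nm <- paste0(grp, "_rep", r)
      maps_c[[nm]] <- generate_contacts(spec, truth, grp, r,
                                        spec$bin_size_compartment)
      maps_t[[nm]] <- generate_contacts(spec, truth, grp, r,
                                        spec$bin_size_tad)
    }
  }
  merge_maps <- function(lst) {
    out <- lst[[1]]
    for (k in seq_along(lst)[-1]) {
      for (ch in names(out)) {
        d <- rbind(out[[ch]]$df, lst[[k]][[ch]]$df)
        agg <- stats::aggregate(count ~ bin_i + bin_j, d, sum)
        out[[ch]]$df <- agg
        out[[ch]]$total_pairs <- out[[ch]]$total_pairs +
          lst[[k]][[ch]]$total_pairs
      }
    }
    out
  }
  ynames <- paste0("young_rep", seq_len(nrep))
  onames <- paste0("old_rep", seq_len(nrep))
  my <- merge_maps(maps_c[ynames])
  mo <- merge_maps(maps_c[onames])
  blocks <- NULL
  for (ch in names(my)) {
    act <- gene_density_activity(truth$genes, ch, spec$chroms[[ch]],
                                 spec$bin_size_compartment)
    ey <- compartment_eigen(my[[ch]], act)
    eo <- compartment_eigen(mo[[ch]], act)
    if (is.null(ey) || is.null(eo)) next
    shared <- shared_sign_blocks(ey, eo)
    blocks <- rbind(blocks, shared)
  }
  rp <- compartment_pair_rpmm(my, mo, blocks)
  top <- topN_enrichment(rp$pairs, n_top = config$top_n)
  tads <- truth$tads
  comp <- tads[c("chrom", "start", "end", "tad_id")]
  for (nm in c(ynames, onames))
    comp[[nm]] <- tad_compactness(maps_t[[nm]], tads)$compactness
  calls <- call_changed_tads(comp)
  enr <- tad_compartment_enrichment(calls$tads, blocks,
                                    n_top = config$top_n)
  calls$tads$compartment <- enr$label
  list(pairs = rp$pairs, rpmm_tests = rp$tests, top = top,
       tads = calls$tads, threshold = calls$threshold,
       enrichment = enr, blocks = blocks,
       maps_young = my, maps_old = mo)
}

#' Compartment blocks with age-consistent sign
#'
#' Takes the young-partition blocks and keeps those whose label the old
#' eigenvector confirms: the mean old eigenvalue over the block's bins
#' has the sign matching the young label.  This is the "shared in sign
#' between ages" filter expected by [compartment_pair_rpmm()].
#'
#' @param ey,eo [compartment_eigen()] results for the young and old map
#'   of the same chromosome.
#' @return The subset of `ey$blocks` confirmed by the old eigenvector.
#' @export
shared_sign_blocks <- function(ey, eo) {
  b <- ey$blocks
  binres <- max(b$end) / length(ey$eigen)
  out <- NULL
  for (k in seq_len(nrow(b))) {
    ib <- (b$start[k] / binres + 1):(b$end[k] / binres)
    mo <- mean(eo$eigen[ib], na.rm = TRUE)
    if (is.nan(mo)) next
    if ((b$label[k] == "A") == (mo > 0))
      out <- rbind(out, b[k, ])
  }
  out
}

# variant quantification + Wald + knockdown reversal
variant_stage <- function(spec, truth, cohort, config) {
  vg <- truth$genes[[which(truth$gene_table$gene_id ==
                             truth$variant_gene_id)]]
  quants <- NULL
  for (nm in names(cohort$samples)) {
    s <- cohort$samples[[nm]]
    q <- quantify_variants(s$variant_coverage, vg, s$libsize)
    q$sample_id <- nm
    quants <- rbind(quants, q)
  }
  meta <- cohort$acc$meta
  libsizes <- vapply(cohort$samples, function(s) s$libsize, 0)
  vtest <- variant_wald_test(quants, meta, libsizes = libsizes)
  short_idx <- grep("\\.short$", vtest$feature_id)

  kd <- generate_kd_cohort(spec, truth)
  kd_res <- nb_wald_test(kd$expr, group_ref = "ctrl", group_alt = "kd")
  kd_lfc <- stats::setNames(kd_res$log2fc, kd_res$feature_id)
  gt <- truth$gene_table
  rev <- reversal_score(gt$gene_id[gt$expr_change == "up"],
                        gt$gene_id[gt$expr_change == "down"],
                        kd_lfc)
  list(quants = quants, test = vtest, short_idx = short_idx,
       reversal = rev, kd_results = kd_res)
}
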