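# shared fixtures, built in code

# one + strand gene with three exons at [1000,1400), [2000,2600),
# [3000,3500); TSS = 1000, TES = 3500
simple_gene <- function(gene_id = "gA", chrom = "chr1", strand = "+") {
  ex <- genomic_intervals(chrom, c(1000, 2000, 3000),
                          c(1400, 2600, 3500), strand = strand)
  gene_model(gene_id, chrom, strand, ex)
}

# two-variant gene: shared exons [0,1000) and [2000,3000); the short
# variant adds its unique 3'UTR [3500,4500), the canonical adds exons
# [5000,6000) and [7000,8000) (its unique tail)
two_variant_gene <- function(chrom = "chr1") {
  shared <- genomic_intervals(chrom, c(0, 2000), c(1000, 3000),
                              strand = "+")
  sho_utr <- genomic_intervals(chrom, 3500, 4500, strand = "+")
  can_tail <- genomic_intervals(chrom, c(5000, 7000), c(6000, 8000),
                                strand = "+")
  v_can <- transcript_variant("v.canonical", rbind(shared, can_tail),
                              can_tail)
  v_sho <- transcript_variant("v.short", rbind(shared, sho_utr), sho_utr)
  gene_model("gV", chrom, "+", rbind(shared, sho_utr, can_tail),
             list(v_can, v_sho))
}

# random interval set on a toy chromosome
random_intervals <- function(n, chrom = "chr1", len = 1e6, seed = 1) {
  set.seed(seed)
  s <- sample.int(len - 2000, n, replace = TRUE)
  genomic_intervals(chrom, s, s + sample(50:1500, n, replace = TRUE))
}

# brute-force O(n^2) overlap scan (independent oracle for overlap_venn)
brute_overlap_flags <- function(a, b) {
  hit <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i)
      any(y$chrom == x$chrom[i] & y$start < x$end[i] &
            y$end > x$start[i]), TRUE)
  }
  list(a = hit(a, b), b = hit(b, a))
}

# small NB count matrix with optional fold change in "old"
nb_matrix <- function(n_feat, mu, disp, n_per_group = 4, fc = 1,
                      n_changed = 0, seed = 1) {
  set.seed(seed)
  groups <- rep(c("young", "old"), each = n_per_group)
  mu_mat <- matrix(mu, n_feat, 2 * n_per_group)
  if (n_changed > 0)
    mu_mat[seq_len(n_changed), groups == "old"] <-
      mu_mat[seq_len(n_changed), groups == "old"] * fc
  counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                  size = 1 / disp),
                   n_feat, 2 * n_per_group)
  rownames(counts) <- sprintf("f%04d", seq_len(n_feat))
  colnames(counts) <- paste0(groups, "_r", rep(seq_len(n_per_group), 2))
  count_matrix(counts, data.frame(sample_id = colnames(counts),
                                  group = groups,
                                  replicate = rep(seq_len(n_per_group),
                                                  2)))
}

# memoized small cohort (shared inside a test file)
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed = 11) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(cohort_spec(seed))
  .cohort_cache[[key]]
}
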