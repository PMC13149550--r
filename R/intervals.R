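#' Construct a set of genomic intervals
#'
#' Intervals are stored in a plain data frame using the 0-based half-open
#' convention (`start` inclusive, `end` exclusive), the native convention of
#' BED.  All package functions expect this convention internally; GTF-style
#' 1-based inclusive coordinates are converted at the I/O boundary.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer-like vector, 0-based inclusive start positions.
#' @param end Integer-like vector, exclusive end positions; must satisfy
#'   `start < end`.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param ... Further equal-length columns carried along (e.g. `name`,
#'   `score`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   and any extra columns supplied.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (any(!nzchar(chrom)) || anyNA(chrom))
    stop("chromosome names must be non-empty")
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  if (is.null(strand)) strand <- rep("*", n)
  strand <- as.character(strand)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# shared chromosome-naming check: refuse to compare interval sets whose
# chromosome conventions differ (e.g. "chr1" vs "1"); silent renaming hides
# upstream data bugs.
check_chrom_compat <- function(a, b) {
  ca <- unique(a$chrom)
  cb <- unique(b$chrom)
  pa <- grepl("^chr", ca)
  pb <- grepl("^chr", cb)
  if (length(ca) && length(cb) && any(pa) != any(pb) && !(all(pa) && all(pb))) {
    off <- if (any(pa) && !any(pb)) cb[!pb][1] else ca[!pa][1]
    stop("mixed chromosome naming conventions; offending chromosome: ", off)
  }
  invisible(NULL)
}

# per-chromosome overlap hits between two 0-based half-open interval frames;
# returns logical vectors: which rows of a / b overlap anything on the other
# side.  IRanges uses 1-based closed coordinates, so shift start by +1.
overlap_flags <- function(a, b) {
  hit_a <- logical(nrow(a))
  hit_b <- logical(nrow(b))
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    hit_a[ia[unique(S4Vectors::queryHits(ov))]] <- TRUE
    hit_b[ib[unique(S4Vectors::subjectHits(ov))]] <- TRUE
  }
  list(a = hit_a, b = hit_b)
}

#' Element-wise Venn overlap between two interval sets
#'
#' Counts elements (not merged regions): an element is *shared* iff it
#' overlaps at least one base pair of any element of the other set.  Because
#' several elements of one set can overlap a single element of the other,
#' the shared count can differ between perspectives; both are returned, with
#' `shared` reported from `set_a`'s perspective.
#'
#' @param set_a,set_b Interval data frames (see [genomic_intervals()]).
#'   Chromosome naming must agree between the two sets.
#' @return A list with `unique_a`, `unique_b`, `shared` (= `shared_a`),
#'   `shared_a`, `shared_b`.
#' @export
overlap_venn <- function(set_a, set_b) {
  check_chrom_compat(set_a, set_b)
  fl <- overlap_flags(set_a, set_b)
  list(unique_a = sum(!fl$a),
       unique_b = sum(!fl$b),
       shared = sum(fl$a),
       shared_a = sum(fl$a),
       shared_b = sum(fl$b))
}

#' Signed distance from an interval to a gene's TSS
#'
#' Returns 0 when the interval covers the TSS; otherwise the gap between the
#' interval's nearest edge and the TSS, signed positive when the interval
#' lies downstream of the TSS in the gene's orientation and negative when
#' upstream.
#'
#' @param interval A single-row interval data frame.
#' @param gene A [gene_model()] with defined `tss` and strand.
#' @return Signed distance in base pairs.
#' @export
distance_to_tss <- function(interval, gene) {
  if (!gene$strand %in% c("+", "-")) stop("gene must be stranded")
  tss <- gene$tss
  s <- interval$start[1]
  e <- interval$end[1]
  if (s <= tss && tss < e) return(0)
  if (e <= tss) {         # interval numerically left of the TSS
    d <- tss - e
    if (gene$strand == "+") -d else d
  } else {                # numerically right
    d <- s - tss
    if (gene$strand == "+") d else -d
  }
}

#' Classify an interval relative to a gene annotation
#'
#' Classes follow the precedence promoter > exonic > intronic > intergenic.
#' The promoter is the symmetric window `TSS +/- promoter_window`; exonic
#' means >= 1 bp overlap with any exon of any gene; intronic means overlap
#' with a gene span (TSS..TES) without exon or promoter overlap.
#'
#' @param interval Single-row interval data frame.
#' @param genes List of [gene_model()] objects.
#' @param promoter_window Half-width of the promoter window in bp
#'   (default 2000).
#' @return One of `"promoter"`, `"exonic"`, `"intronic"`, `"intergenic"`.
#' @export
annotate_feature <- function(interval, genes, promoter_window = 2000) {
  stopifnot(promoter_window > 0)
  s <- interval$start[1]; e <- interval$end[1]; ch <- interval$chrom[1]
  cls <- "intergenic"
  for (g in genes) {
    if (g$chrom != ch) next
    pw_lo <- g$tss - promoter_window
    pw_hi <- g$tss + promoter_window
    if (s < pw_hi && e > pw_lo) return("promoter")
    if (nrow(g$exons) &&
        any(s < g$exons$end & e > g$exons$start)) {
      cls <- "exonic"
      next
    }
    glo <- min(g$tss, g$tes); ghi <- max(g$tss, g$tes)
    if (cls != "exonic" && s < ghi && e > glo) cls <- "intronic"
  }
  cls
}

#' Construct a gene model
#'
#' A gene with TSS/TES, exons, and (optionally) transcript variants.  The
#' TSS is the 5'-most coordinate respecting strand: for `+` genes it is the
#' smallest exon start, for `-` genes the largest exon end.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Interval data frame of exons (non-overlapping).
#' @param variants Optional list of [transcript_variant()] objects.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, variants = list()) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons overlap within gene ", gene_id)
  tss <- if (strand == "+") min(exons$start) else max(exons$end)
  tes <- if (strand == "+") max(exons$end) else min(exons$start)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = tss, tes = tes, exons = exons, variants = variants),
            class = "gene_model")
}

#' Construct a transcript variant
#'
#' `unique_regions` are the intervals exclusive to this variant among all
#' variants of its gene (for a short 3'UTR variant, its variant-specific
#' 3'UTR).  They must lie within the variant's own exons; disjointness from
#' the sibling variants is checked by [validate_variants()].
#'
#' @param variant_id Variant identifier.
#' @param exons Interval data frame of the variant's exons.
#' @param unique_regions Interval data frame of variant-exclusive regions.
#' @return An object of class `transcript_variant`.
#' @export
transcript_variant <- function(variant_id, exons, unique_regions) {
  cov <- covered_width(unique_regions, exons)
  if (any(cov < unique_regions$end - unique_regions$start))
    stop("unique_regions of ", variant_id, " must lie within its exons")
  structure(list(variant_id = variant_id, exons = exons,
                 unique_regions = unique_regions),
            class = "transcript_variant")
}

# width of each row of `q` covered by the union of `s` (same chromosome set)
covered_width <- function(q, s) {
  out <- numeric(nrow(q))
  for (ch in unique(q$chrom)) {
    iq <- which(q$chrom == ch)
    is <- which(s$chrom == ch)
    if (!length(is)) next
    rs <- IRanges::reduce(IRanges::IRanges(s$start[is] + 1L, s$end[is]))
    rq <- IRanges::IRanges(q$start[iq] + 1L, q$end[iq])
    ov <- IRanges::findOverlaps(rq, rs)
    w <- IRanges::width(IRanges::pintersect(
      rq[S4Vectors::queryHits(ov)], rs[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[iq[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

#' Check that a gene's variants have mutually disjoint unique regions
#'
#' Each variant's `unique_regions` must be disjoint from every sibling
#' variant's exon union, so that variant-level quantification from those
#' regions is unambiguous.
#'
#' @param gene A [gene_model()] with >= 2 variants.
#' @return Invisibly `TRUE`; errors naming the offending variant otherwise.
#' @export
validate_variants <- function(gene) {
  vs <- gene$variants
  for (i in seq_along(vs)) {
    if (nrow(vs[[i]]$unique_regions) == 0)
      stop("variant ", vs[[i]]$variant_id, " has empty unique_regions")
    for (j in seq_along(vs)) {
      if (i == j) next
      fl <- overlap_flags(vs[[i]]$unique_regions, vs[[j]]$exons)
      if (any(fl$a))
        stop("unique_regions of ", vs[[i]]$variant_id,
             " overlap exons of ", vs[[j]]$variant_id)
    }
  }
  invisible(TRUE)
}
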