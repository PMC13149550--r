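#' Read a BED3+ file
#'
#' Columns beyond the first three are mapped to `name` (4), `score` (5) and
#' `strand` (6) when present.  BED is 0-based half-open, the package's
#' internal convention, so coordinates are taken as-is.
#'
#' @param path File path.
#' @return Interval data frame.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  out <- genomic_intervals(df[[1]], df[[2]], df[[3]],
                           strand = if (ncol(df) >= 6) df[[6]] else NULL)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (ncol(df) >= 5) out$score <- as.numeric(df[[5]])
  out
}

#' Write intervals as BED
#'
#' @param x Interval data frame; optional `name` and `score` columns are
#'   written as BED columns 4-5, strand as column 6.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) as.character(x$name) else "."
  score <- if ("score" %in% names(x)) x$score else 0
  df <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                   name, score, x$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Construct a binned signal track
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @param values Non-negative signal per bin, covering the chromosome
#'   (length = ceiling(chrom length / bin_size)).
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(chrom, bin_size, values) {
  stopifnot(bin_size > 0, all(values >= 0), all(is.finite(values)))
  structure(list(chrom = chrom, bin_size = bin_size,
                 values = as.numeric(values)),
            class = "binned_track")
}

#' Write binned tracks as bedGraph
#'
#' @param tracks A `binned_track` or list thereof.
#' @param path Output path.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "binned_track")) tracks <- list(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    n <- length(tr$values)
    start <- (seq_len(n) - 1L) * tr$bin_size
    df <- data.frame(tr$chrom, format_coord(start),
                     format_coord(start + tr$bin_size),
                     format_signal(tr$values))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

format_signal <- function(x) format(x, digits = 17, scientific = FALSE,
                                    trim = TRUE)

#' Read a bedGraph of uniform bins into binned tracks
#'
#' @param path File path.
#' @return Named list of `binned_track`, one per chromosome.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- c("chrom", "start", "end", "value")
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    bs <- unique(d$end - d$start)
    if (length(bs) != 1)
      stop("non-uniform bins in bedGraph for ", ch)
    vals <- numeric(max(d$end) / bs)
    vals[d$start / bs + 1] <- d$value
    out[[ch]] <- binned_track(ch, bs, vals)
  }
  out
}

#' Write gene models as GTF-lite
#'
#' Emits only `gene`, `transcript` and `exon` records with `gene_id` and
#' `transcript_id` attributes.  Internal 0-based half-open coordinates are
#' converted to GTF's 1-based inclusive on write.  A gene without explicit
#' variants is written as a single transcript `<gene_id>.t1`.
#'
#' @param genes List of [gene_model()].
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  rec <- function(chrom, feat, s, e, strand, gid, tid = NULL) {
    attr <- sprintf('gene_id "%s";', gid)
    if (!is.null(tid)) attr <- paste(attr, sprintf('transcript_id "%s";', tid))
    sprintf("%s\tchromage\t%s\t%s\t%s\t.\t%s\t.\t%s",
            chrom, feat, format_coord(s + 1), format_coord(e), strand, attr)
  }
  for (g in genes) {
    glo <- min(g$exons$start); ghi <- max(g$exons$end)
    vs <- g$variants
    if (!length(vs))
      vs <- list(list(variant_id = paste0(g$gene_id, ".t1"), exons = g$exons))
    for (v in vs) {
      glo <- min(glo, v$exons$start); ghi <- max(ghi, v$exons$end)
    }
    lines <- c(lines, rec(g$chrom, "gene", glo, ghi, g$strand, g$gene_id))
    for (v in vs) {
      lines <- c(lines,
                 rec(g$chrom, "transcript", min(v$exons$start),
                     max(v$exons$end), g$strand, g$gene_id, v$variant_id))
      for (k in seq_len(nrow(v$exons)))
        lines <- c(lines,
                   rec(g$chrom, "exon", v$exons$start[k], v$exons$end[k],
                       g$strand, g$gene_id, v$variant_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF-lite file into gene models
#'
#' Only `gene`/`transcript`/`exon` records are honoured.  For multi-variant
#' genes, each variant's `unique_regions` are recomputed as the parts of its
#' exons not covered by any sibling variant's exons.
#'
#' @param path File path.
#' @return List of [gene_model()].
#' @export
read_gtf <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "#")
  names(raw) <- c("chrom", "src", "feature", "start", "end", "score",
                  "strand", "frame", "attr")
  raw$start <- raw$start - 1   # to 0-based half-open
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  raw$gene_id <- get_attr(raw$attr, "gene_id")
  raw$transcript_id <- get_attr(raw$attr, "transcript_id")
  ex <- raw[raw$feature == "exon", ]
  genes <- list()
  for (gid in unique(raw$gene_id)) {
    gx <- ex[ex$gene_id == gid, ]
    tids <- unique(gx$transcript_id)
    vexons <- lapply(tids, function(t) {
      d <- gx[gx$transcript_id == t, ]
      genomic_intervals(d$chrom, d$start, d$end, strand = d$strand)
    })
    union_ex <- interval_union(do.call(rbind, vexons))
    variants <- list()
    if (length(tids) > 1) {
      variants <- lapply(seq_along(tids), function(i) {
        others <- interval_union(do.call(rbind, vexons[-i]))
        uniq <- interval_setdiff(vexons[[i]], others)
        transcript_variant(tids[i], vexons[[i]], uniq)
      })
    }
    genes[[gid]] <- gene_model(gid, gx$chrom[1], gx$strand[1],
                               union_ex, variants)
  }
  unname(genes)
}

# union of intervals as a sorted disjoint interval frame
interval_union <- function(x) {
  out <- NULL
  for (ch in unique(x$chrom)) {
    d <- x[x$chrom == ch, ]
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    out <- rbind(out, genomic_intervals(ch, IRanges::start(r) - 1L,
                                        IRanges::end(r)))
  }
  out
}

# parts of x not covered by y
interval_setdiff <- function(x, y) {
  out <- NULL
  for (ch in unique(x$chrom)) {
    dx <- x[x$chrom == ch, ]
    rx <- IRanges::reduce(IRanges::IRanges(dx$start + 1L, dx$end))
    iy <- which(y$chrom == ch)
    if (length(iy)) {
      ry <- IRanges::reduce(IRanges::IRanges(y$start[iy] + 1L, y$end[iy]))
      rx <- IRanges::setdiff(rx, ry)
    }
    if (length(rx))
      out <- rbind(out, genomic_intervals(ch, IRanges::start(rx) - 1L,
                                          IRanges::end(rx)))
  }
  if (is.null(out)) genomic_intervals(character(0), numeric(0), numeric(0))
  else out
}

#' Construct a per-chromosome contact map
#'
#' Upper-triangular binned contact counts.  `total_pairs` is the
#' library-wide valid pair count used for depth normalization and may exceed
#' the sum of the stored (per-chromosome, intra-chromosomal) counts.
#'
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @param n_bins Number of bins on the chromosome.
#' @param bin_i,bin_j 0-based bin indices with `bin_i <= bin_j`.
#' @param count Non-negative counts.
#' @param total_pairs Library-wide valid pair total.
#' @return Object of class `contact_map`.
#' @export
contact_map <- function(chrom, resolution, n_bins, bin_i, bin_j, count,
                        total_pairs) {
  stopifnot(all(bin_i <= bin_j), all(count >= 0),
            all(bin_j < n_bins), total_pairs > 0)
  structure(list(chrom = chrom, resolution = resolution, n_bins = n_bins,
                 df = data.frame(bin_i = as.integer(bin_i),
                                 bin_j = as.integer(bin_j),
                                 count = as.numeric(count)),
                 total_pairs = as.numeric(total_pairs)),
            class = "contact_map")
}

#' Write contact maps as triplet text
#'
#' Format: header line `# resolution=<bp> total_pairs=<int>`, a second
#' comment line recording bin counts per chromosome, then TSV records
#' `chrom bin_i bin_j count`.
#'
#' @param maps A `contact_map` or list thereof (one library).
#' @param path Output path.
#' @export
write_contacts <- function(maps, path) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  res <- unique(vapply(maps, function(m) m$resolution, 0))
  tp <- unique(vapply(maps, function(m) m$total_pairs, 0))
  stopifnot(length(res) == 1, length(tp) == 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution=%s total_pairs=%s",
                     format_coord(res), format_coord(tp)), con)
  writeLines(paste0("# chrom_bins=",
                    paste(vapply(maps, function(m)
                      paste0(m$chrom, ":", m$n_bins), ""), collapse = ",")),
             con)
  for (m in maps) {
    df <- data.frame(m$chrom, m$df$bin_i, m$df$bin_j,
                     format_coord(m$df$count))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read contact maps from triplet text
#'
#' @param path File path written by [write_contacts()].
#' @return Named list of `contact_map`, one per chromosome.
#' @export
read_contacts <- function(path) {
  lines <- readLines(path, n = 2)
  h <- regmatches(lines[1],
                  regexec("resolution=([0-9]+) total_pairs=([0-9]+)",
                          lines[1]))[[1]]
  if (length(h) != 3) stop("malformed contact header in ", path)
  res <- as.numeric(h[2]); tp <- as.numeric(h[3])
  nb <- NULL
  if (grepl("chrom_bins=", lines[2])) {
    toks <- strsplit(sub(".*chrom_bins=", "", lines[2]), ",")[[1]]
    kv <- strsplit(toks, ":")
    nb <- stats::setNames(as.integer(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- c("chrom", "bin_i", "bin_j", "count")
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    n_bins <- if (!is.null(nb) && ch %in% names(nb)) nb[[ch]]
              else max(d$bin_j) + 1L
    out[[ch]] <- contact_map(ch, res, n_bins, d$bin_i, d$bin_j, d$count, tp)
  }
  out
}

#' Construct a count matrix with sample metadata
#'
#' @param counts Non-negative integer matrix, features x samples, with
#'   feature ids as row names and sample ids as column names.
#' @param meta Data frame with columns `sample_id`, `group`, `replicate`;
#'   one row per column of `counts`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  stopifnot(all(counts >= 0), !is.null(rownames(counts)),
            !is.null(colnames(counts)),
            all(c("sample_id", "group", "replicate") %in% names(meta)),
            nrow(meta) == ncol(counts))
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' Write a count matrix and its metadata sidecar
#'
#' @param m A [count_matrix()].
#' @param path Counts TSV path (first column `feature_id`); the metadata
#'   sidecar is written to `<path>.meta.tsv`.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(feature_id = rownames(m$counts), m$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path Counts TSV path; `<path>.meta.tsv` must exist.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- utils::read.table(paste0(path, ".meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  count_matrix(counts, meta)
}
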