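# Comparative rRNA/rDNA analysis of paired OTU tables: rarefaction,
# OTU partitioning (shared / rDNA-only / phantom), activity ratios,
# ratio-abundance correlation, alpha diversity and Canberra distances.

#' Rarefy an OTU table to even depth
#'
#' Subsamples every retained column without replacement to exactly `depth`
#' reads (via [vegan::rrarefy()]), then drops OTU rows that become all-zero.
#' Columns whose total is below `depth` are either an error or dropped,
#' per `on_short`.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (>= 1).
#' @param seed optional integer seed; the draw is reproducible.
#' @param on_short `"error"` (default) or `"drop"` for columns with fewer
#'   than `depth` reads.
#' @return a rarefied [otu_table()]; every retained column sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL, on_short = c("error", "drop")) {
  stopifnot(inherits(table, "otu_table"))
  depth <- assert_count(depth, "depth", 1L)
  on_short <- match.arg(on_short)
  sums <- colSums(table$counts)
  short <- sums < depth
  if (any(short) && on_short == "error") {
    stop("sample(s) below rarefaction depth: ",
         paste(colnames(table$counts)[short], collapse = ", "), call. = FALSE)
  }
  keep <- !short
  if (!any(keep)) stop("rarefaction would drop every sample", call. = FALSE)
  counts <- table$counts[, keep, drop = FALSE]
  rarefied <- with_seed_or_current(seed, {
    # vegan warns on low-count matrices; subsampling small fixtures is fine
    suppressWarnings(t(vegan::rrarefy(t(counts), sample = depth)))
  })
  storage.mode(rarefied) <- "integer"
  nonzero <- rowSums(rarefied) > 0
  meta <- table$sample_meta[keep, , drop = FALSE]
  otu_table(rarefied[nonzero, , drop = FALSE], meta)
}

#' Partition-summary arithmetic
#'
#' Builds the shared / rDNA-only / rRNA-only (phantom) partition record from
#' the three counts, with percentages of the total rounded half away from
#' zero to one decimal.
#'
#' @param n_shared OTUs detected in both nucleic-acid classes.
#' @param n_rdna_only OTUs detected only in rDNA samples.
#' @param n_rrna_only OTUs detected only in rRNA samples (phantoms).
#' @return object of class `"partition_summary"`: counts, `n_total`, and
#'   `pct_shared`, `pct_rdna_only`, `pct_rrna_only`.
#' @examples
#' partition_summary(343, 424, 309)
#' @export
partition_summary <- function(n_shared, n_rdna_only, n_rrna_only) {
  n_shared <- assert_count(n_shared, "n_shared")
  n_rdna_only <- assert_count(n_rdna_only, "n_rdna_only")
  n_rrna_only <- assert_count(n_rrna_only, "n_rrna_only")
  n_total <- n_shared + n_rdna_only + n_rrna_only
  if (n_total == 0) stop("partition is empty: no detected OTUs", call. = FALSE)
  pct <- function(n) round_half_away(100 * n / n_total, 1)
  structure(list(n_shared = n_shared, n_rdna_only = n_rdna_only,
                 n_rrna_only = n_rrna_only, n_total = n_total,
                 pct_shared = pct(n_shared), pct_rdna_only = pct(n_rdna_only),
                 pct_rrna_only = pct(n_rrna_only)),
            class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat(sprintf("OTU partition (n = %d):\n", x$n_total))
  cat(sprintf("  shared rDNA+rRNA : %5d (%.1f%%)\n", x$n_shared, x$pct_shared))
  cat(sprintf("  rDNA only        : %5d (%.1f%%)\n", x$n_rdna_only, x$pct_rdna_only))
  cat(sprintf("  rRNA only        : %5d (%.1f%%)  <- phantom taxa\n",
              x$n_rrna_only, x$pct_rrna_only))
  invisible(x)
}

#' Partition OTUs into shared, rDNA-only and phantom sets
#'
#' An OTU is detected in a nucleic-acid class when any column of that class
#' has a count > 0 (`pooling = "pooled"`, the default, matching library-wide
#' totals); with `pooling = "per_sample"` one partition is computed per day
#' from that day's rDNA/rRNA column pair.
#'
#' @param table an [otu_table()] with at least one sample of each class.
#' @param pooling `"pooled"` or `"per_sample"`.
#' @return a [partition_summary()], or a named list of them (one per day)
#'   for `per_sample`.
#' @export
partition_otus <- function(table, pooling = c("pooled", "per_sample")) {
  stopifnot(inherits(table, "otu_table"))
  pooling <- match.arg(pooling)
  for (acid in c("rDNA", "rRNA")) {
    if (!any(table$sample_meta$nucleic_acid == acid)) {
      stop("OTU table has no ", acid, " samples", call. = FALSE)
    }
  }
  summarize <- function(rd, rr) {
    det_rd <- rowSums(rd) > 0
    det_rr <- rowSums(rr) > 0
    if (!any(det_rd)) stop("no OTUs detected in rDNA samples", call. = FALSE)
    if (!any(det_rr)) stop("no OTUs detected in rRNA samples", call. = FALSE)
    partition_summary(sum(det_rd & det_rr), sum(det_rd & !det_rr),
                      sum(!det_rd & det_rr))
  }
  if (pooling == "pooled") {
    return(summarize(class_columns(table, "rDNA"), class_columns(table, "rRNA")))
  }
  days <- unique(table$sample_meta$day)
  out <- lapply(days, function(d) {
    sel <- table$sample_meta$day %in% d
    sub <- otu_table(table$counts[, sel, drop = FALSE],
                     table$sample_meta[sel, , drop = FALSE])
    summarize(class_columns(sub, "rDNA"), class_columns(sub, "rRNA"))
  })
  stats::setNames(out, days)
}

#' Per-OTU rRNA:rDNA activity ratios
#'
#' Converts each column to relative abundances, averages them within each
#' nucleic-acid class, and reports the rRNA:rDNA ratio of the class means
#' for every shared OTU (both means > 0). Class means of relative
#' abundances (rather than summed counts) keep unequal library depths from
#' biasing the ratios.
#'
#' @param table an [otu_table()] with both classes present.
#' @return data.frame with columns `otu_id`, `mean_relabund_rdna`,
#'   `mean_relabund_rrna`, `ratio`, one row per shared OTU.
#' @export
rrna_rdna_ratios <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  sums <- colSums(table$counts)
  if (any(sums == 0)) {
    stop("zero-sum sample column(s): ",
         paste(colnames(table$counts)[sums == 0], collapse = ", "), call. = FALSE)
  }
  relab <- sweep(table$counts, 2, sums, "/")
  mean_rd <- rowMeans(relab[, table$sample_meta$nucleic_acid == "rDNA", drop = FALSE])
  mean_rr <- rowMeans(relab[, table$sample_meta$nucleic_acid == "rRNA", drop = FALSE])
  shared <- mean_rd > 0 & mean_rr > 0
  data.frame(otu_id = rownames(table$counts)[shared],
             mean_relabund_rdna = mean_rd[shared],
             mean_relabund_rrna = mean_rr[shared],
             ratio = mean_rr[shared] / mean_rd[shared],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between activity ratio and rDNA abundance
#'
#' Correlates each shared OTU's rRNA:rDNA ratio against its mean relative
#' abundance in the rDNA community. Both variables are log10-transformed by
#' default (both are strictly positive for shared OTUs); Kendall's
#' correlation is the tie-corrected tau-b, and p-values use the standard
#' asymptotic approximations.
#'
#' @param records output of [rrna_rdna_ratios()] (>= 3 rows).
#' @param method `"pearson"` or `"kendall_tau_b"`.
#' @param transform `"log10"` (default) or `"none"`.
#' @return list with `estimate`, `p_value`, `n`, `method`, `transform`.
#' @export
ratio_abundance_correlation <- function(records,
                                        method = c("pearson", "kendall_tau_b"),
                                        transform = c("log10", "none")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (!is.data.frame(records) ||
      !all(c("mean_relabund_rdna", "ratio") %in% names(records))) {
    stop("`records` must be the data.frame returned by rrna_rdna_ratios()",
         call. = FALSE)
  }
  if (nrow(records) < 3) stop("need at least 3 ratio records", call. = FALSE)
  x <- records$mean_relabund_rdna
  y <- records$ratio
  if (transform == "log10") {
    x <- log10(x)
    y <- log10(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in ratio or abundance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y,
                        method = if (method == "pearson") "pearson" else "kendall",
                        exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = nrow(records), method = method, transform = transform)
}

#' Per-sample alpha diversity
#'
#' Richness (OTUs with count > 0), Shannon entropy in nats, and Pielou
#' evenness `J = H / ln(richness)` (`NA` when richness < 2, where evenness
#' is undefined).
#'
#' @param table an [otu_table()] with nonzero columns.
#' @return data.frame with columns `sample_id`, `nucleic_acid`, `richness`,
#'   `shannon`, `pielou`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  sums <- colSums(table$counts)
  if (any(sums == 0)) stop("zero-sum sample column(s)", call. = FALSE)
  richness <- colSums(table$counts > 0)
  shannon <- vegan::diversity(t(table$counts), index = "shannon")
  pielou <- ifelse(richness >= 2, shannon / log(richness), NA_real_)
  data.frame(sample_id = colnames(table$counts),
             nucleic_acid = table$sample_meta$nucleic_acid,
             richness = as.integer(richness),
             shannon = as.numeric(shannon), pielou = as.numeric(pielou),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Canberra distance matrix between samples
#'
#' Classic Canberra distance `d(x, y) = sum |x_i - y_i| / (x_i + y_i)` over
#' coordinates with `x_i + y_i > 0`; the `"nonzero_normalized"` variant
#' divides by the number of such coordinates (the convention used by
#' [vegan::vegdist()]). Classic Canberra is a semimetric: only symmetry,
#' nonnegativity and zero self-distance are guaranteed.
#'
#' @param table an [otu_table()] with >= 2 samples.
#' @param variant `"classic"` or `"nonzero_normalized"`.
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
canberra_matrix <- function(table, variant = c("classic", "nonzero_normalized")) {
  stopifnot(inherits(table, "otu_table"))
  variant <- match.arg(variant)
  m <- table$counts
  if (ncol(m) < 2) stop("need at least 2 samples for a distance matrix", call. = FALSE)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- m[, i]
      y <- m[, j]
      nz <- (x + y) > 0
      val <- sum(abs(x[nz] - y[nz]) / (x[nz] + y[nz]))
      if (variant == "nonzero_normalized") val <- val / sum(nz)
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Core OTUs shared across all samples of one nucleic-acid class
#'
#' The core set is the OTUs detected in every sample of the class; each
#' sample's shared percentage is `100 * |core| / richness`, summarized as
#' mean and SD across samples.
#'
#' @param table an [otu_table()].
#' @param nucleic_acid `"rDNA"` or `"rRNA"`.
#' @return list with `mean_pct`, `sd_pct`, `core_size`, `n_samples`.
#' @export
shared_otu_percentage <- function(table, nucleic_acid = c("rDNA", "rRNA")) {
  stopifnot(inherits(table, "otu_table"))
  nucleic_acid <- match.arg(nucleic_acid)
  m <- class_columns(table, nucleic_acid)
  if (ncol(m) == 0) stop("OTU table has no ", nucleic_acid, " samples", call. = FALSE)
  if (ncol(m) < 2) {
    stop("need at least 2 ", nucleic_acid, " samples for a shared-OTU percentage",
         call. = FALSE)
  }
  det <- m > 0
  core <- rowSums(det) == ncol(m)
  pct <- 100 * sum(core) / colSums(det)
  list(mean_pct = mean(pct), sd_pct = stats::sd(pct),
       core_size = sum(core), n_samples = ncol(m))
}
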