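# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# OTU table from a counts matrix and per-column nucleic-acid labels
make_table <- function(counts, acids, days = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  }
  meta <- data.frame(sample_id = colnames(counts), nucleic_acid = acids,
                     stringsAsFactors = FALSE)
  if (!is.null(days)) meta$day <- days
  otu_table(counts, meta)
}

# columns of one nucleic-acid class
class_cols <- function(table, acid) {
  table$counts[, table$sample_meta$nucleic_acid == acid, drop = FALSE]
}

# small random community with N <= max_copies and R <= max_copies,
# suitable for exhaustive enumeration
random_small_community <- function(max_copies = 8) {
  s <- sample(1:3, 1)
  repeat {
    k <- sample(1:3, s, replace = TRUE)
    if (sum(k) <= max_copies) break
  }
  active <- sample(c(TRUE, FALSE), s, replace = TRUE)
  repeat {
    r <- ifelse(active, sample(1:3, s, replace = TRUE), 0L)
    if (sum(r) <= max_copies) break
  }
  community(sprintf("T%d", seq_len(s)), k, active, r)
}

# moderately sized random community realized from the community model
random_model_community <- function(n_taxa = 200, seed = NULL, mode = "bernoulli") {
  realize_community(
    abundance_distribution("negative_binomial", shape = 1, mean = 5),
    n_taxa,
    activity_profile(c(1, 3, 10), c(0.8, 0.5, 0.2)),
    intensity_function(c(1, 3, 10), c(20, 5, 1)),
    mode = mode, seed = seed
  )
}

# zero-truncated negative binomial pmf table (series oracle)
ztnb_pmf <- function(kmax, shape, mu) {
  p <- stats::dnbinom(seq_len(kmax), size = shape, mu = mu)
  p / (1 - stats::dnbinom(0, size = shape, mu = mu))
}
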