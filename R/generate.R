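# Synthetic paired rRNA/rDNA OTU tables: the finite-depth observation layer
# over a realized community, emulating paired daily amplicon libraries.

#' Generate paired rRNA/rDNA OTU count tables from a community
#'
#' For each of `n_sample_pairs` days, draws one rDNA library and one rRNA
#' library from the community's pools. Sequencing is modelled as multinomial
#' resampling of template molecules by default (`with_replacement`);
#' `without_replacement` draws a uniform subset of pool copies, matching the
#' analytic theory exactly, and then requires depths no larger than the
#' pools. All-zero OTU rows are retained so the table's row set equals the
#' community's taxa. Optionally, each day's pool proportions are perturbed
#' by lognormal noise (sd `day_noise_sd` on the log scale) and renormalized
#' before multinomial sampling.
#'
#' @param community a [community()].
#' @param n_sample_pairs number of day pairs (default 4, the study layout).
#' @param depth_rdna,depth_rrna reads per rDNA / rRNA library (>= 1).
#' @param scheme `"with_replacement"` (default) or `"without_replacement"`.
#' @param seed optional integer seed; fixed seed gives byte-identical
#'   written tables.
#' @param day_noise_sd nonnegative lognormal day-effect SD (default 0;
#'   only available with `with_replacement`).
#' @return an [otu_table()] with columns `rDNA_day<i>` and `rRNA_day<i>`.
#' @export
generate_paired_tables <- function(community, n_sample_pairs = 4,
                                   depth_rdna, depth_rrna,
                                   scheme = c("with_replacement", "without_replacement"),
                                   seed = NULL, day_noise_sd = 0) {
  stopifnot(inherits(community, "community"))
  scheme <- match.arg(scheme)
  n_sample_pairs <- assert_count(n_sample_pairs, "n_sample_pairs", 1L)
  depth_rdna <- assert_count(depth_rdna, "depth_rdna", 1L)
  depth_rrna <- assert_count(depth_rrna, "depth_rrna", 1L)
  if (day_noise_sd < 0) stop("`day_noise_sd` must be >= 0", call. = FALSE)
  if (day_noise_sd > 0 && scheme == "without_replacement") {
    stop("day-level noise perturbs pool proportions and requires with_replacement sampling",
         call. = FALSE)
  }
  if (scheme == "without_replacement") {
    if (depth_rdna > community$N) {
      stop("`depth_rdna` exceeds the rDNA pool size under without-replacement sampling",
           call. = FALSE)
    }
    if (depth_rrna > community$R) {
      stop("`depth_rrna` exceeds the rRNA pool size under without-replacement sampling",
           call. = FALSE)
    }
  }
  s <- community$S
  draw_column <- function(copies, depth) {
    if (sum(copies) == 0) return(integer(s))  # empty rRNA pool: all-zero column
    if (scheme == "without_replacement") {
      draw_pool_counts(copies, depth, scheme, 1L)[1, ]
    } else {
      w <- copies
      if (day_noise_sd > 0) {
        w <- w * stats::rlnorm(s, meanlog = 0, sdlog = day_noise_sd)
      }
      as.integer(stats::rmultinom(1, depth, prob = w / sum(w)))
    }
  }
  with_seed_or_current(seed, {
    cols <- vector("list", 2L * n_sample_pairs)
    ids <- character(2L * n_sample_pairs)
    acid <- character(2L * n_sample_pairs)
    day <- character(2L * n_sample_pairs)
    for (d in seq_len(n_sample_pairs)) {
      i <- 2L * d - 1L
      cols[[i]] <- draw_column(community$taxa$rdna_count, depth_rdna)
      cols[[i + 1L]] <- draw_column(community$taxa$rrna_count, depth_rrna)
      ids[c(i, i + 1L)] <- sprintf("%s_day%d", c("rDNA", "rRNA"), d)
      acid[c(i, i + 1L)] <- c("rDNA", "rRNA")
      day[c(i, i + 1L)] <- sprintf("day%d", d)
    }
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(community$taxa$taxon_id, ids)
    otu_table(counts, data.frame(sample_id = ids, nucleic_acid = acid,
                                 day = day, stringsAsFactors = FALSE))
  })
}

#' Latent ground truth behind a generated OTU table
#'
#' Pairs a generated table with the community it came from, exposing the
#' latent truth so that pipeline estimates (phantom fractions, the sign of
#' the ratio-abundance correlation) can be validated against it.
#'
#' @param community the generating [community()] (realized with a model, so
#'   that its activity profile and intensity are recorded).
#' @param table the [otu_table()] generated from it.
#' @return list with `active_ids` (the true active set),
#'   `phantom_eligible_ids` (identical to the active set: only active taxa
#'   can appear as phantoms) and `per_otu`, a data.frame with each OTU's
#'   true rDNA abundance `k`, rRNA copies `r`, activity state, abundance
#'   class (0-based), alpha and m values.
#' @export
ground_truth_report <- function(community, table) {
  stopifnot(inherits(community, "community"), inherits(table, "otu_table"))
  if (!setequal(rownames(table$counts), community$taxa$taxon_id)) {
    stop("OTU ids in the table do not match the community's taxa", call. = FALSE)
  }
  tx <- community$taxa[match(rownames(table$counts), community$taxa$taxon_id), ]
  per_otu <- data.frame(otu_id = tx$taxon_id, k = tx$rdna_count,
                        r = tx$rrna_count, active = tx$active,
                        stringsAsFactors = FALSE)
  if (!is.null(community$profile)) {
    per_otu$alpha_class <- classify_abundance(per_otu$k, community$profile$breakpoints)
    per_otu$alpha <- step_value(community$profile, per_otu$k)
  }
  if (!is.null(community$intensity)) {
    per_otu$m <- step_value(community$intensity, per_otu$k)
  }
  rownames(per_otu) <- NULL
  list(active_ids = tx$taxon_id[tx$active],
       phantom_eligible_ids = tx$taxon_id[tx$active],
       per_otu = per_otu)
}
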