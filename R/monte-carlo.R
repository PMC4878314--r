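# Monte-Carlo sampling of the community and simulation-based expectations.

# Draw per-taxon counts for `reps` independent samples of size n from a pool
# whose composition is `copies`. Without replacement this is a multivariate
# hypergeometric draw, realized as a chain of rhyper calls vectorized across
# replicates; with replacement it is multinomial over copy proportions.
# Returns a reps x length(copies) integer matrix.
draw_pool_counts <- function(copies, n, scheme, reps = 1L) {
  s <- length(copies)
  total <- sum(copies)
  out <- matrix(0L, nrow = reps, ncol = s)
  if (n == 0 || total == 0) return(out)
  if (scheme == "with_replacement") {
    return(t(stats::rmultinom(reps, size = n, prob = copies / total)))
  }
  if (n > total) {
    stop("sample size exceeds pool size under without-replacement sampling",
         call. = FALSE)
  }
  rem_draw <- rep.int(n, reps)
  rem_pool <- total
  for (i in seq_len(s)) {
    ci <- copies[i]
    rem_pool <- rem_pool - ci
    if (ci == 0L) next
    x <- if (rem_pool == 0L) rem_draw else stats::rhyper(reps, ci, rem_pool, rem_draw)
    out[, i] <- x
    rem_draw <- rem_draw - x
    if (all(rem_draw == 0L)) break
  }
  out
}

#' Draw one random sample from both pools and record detections
#'
#' Draws one sample of each pool under the design (the two pools are
#' sampled independently) and returns the sets of detected taxa together
#' with the derived phantom set (taxa detected in the rRNA sample but not
#' the rDNA sample). Phantoms are always a subset of the active taxa,
#' because inactive taxa hold no rRNA copies.
#'
#' @param community a [community()].
#' @param design a [sampling_design()].
#' @param seed optional integer seed.
#' @return object of class `"observed_detection"`: list with character
#'   vectors `rdna_detected`, `rrna_detected`, `phantoms`.
#' @export
monte_carlo_sample <- function(community, design, seed = NULL) {
  check_design(community, design)
  ids <- community$taxa$taxon_id
  with_seed_or_current(seed, {
    rd <- draw_pool_counts(community$taxa$rdna_count, design$n_rdna,
                           design$scheme, 1L)
    rr <- draw_pool_counts(community$taxa$rrna_count, design$n_rrna,
                           design$scheme, 1L)
    rdna_detected <- ids[rd[1, ] > 0L]
    rrna_detected <- ids[rr[1, ] > 0L]
    structure(list(rdna_detected = rdna_detected,
                   rrna_detected = rrna_detected,
                   phantoms = setdiff(rrna_detected, rdna_detected)),
              class = "observed_detection")
  })
}

#' @export
print.observed_detection <- function(x, ...) {
  cat(sprintf("Observed detection: %d rDNA taxa, %d rRNA taxa, %d phantoms\n",
              length(x$rdna_detected), length(x$rrna_detected), length(x$phantoms)))
  invisible(x)
}

#' Monte-Carlo estimates of richness and phantom expectations
#'
#' Simulates `replicates` independent samples of the community under the
#' design and reports the mean observed rDNA richness, rRNA richness and
#' phantom count with their standard errors (sample SD / sqrt(replicates);
#' `NA` when `replicates = 1`). Replicate draws are derived deterministically
#' from the master seed, so results are reproducible.
#'
#' @param community a [community()].
#' @param design a [sampling_design()].
#' @param replicates number of simulated samples (>= 1).
#' @param seed optional integer master seed.
#' @return list with elements `rdna_richness`, `rrna_richness`,
#'   `phantom_count` (each a list with `mean` and `se`) and `replicates`.
#' @export
monte_carlo_expectations <- function(community, design, replicates, seed = NULL) {
  check_design(community, design)
  replicates <- assert_count(replicates, "replicates", min = 1L)
  with_seed_or_current(seed, {
    rd <- draw_pool_counts(community$taxa$rdna_count, design$n_rdna,
                           design$scheme, replicates)
    rr <- draw_pool_counts(community$taxa$rrna_count, design$n_rrna,
                           design$scheme, replicates)
    rd_rich <- rowSums(rd > 0L)
    rr_rich <- rowSums(rr > 0L)
    phantom <- rowSums(rr > 0L & rd == 0L)
    se <- function(x) if (replicates == 1L) NA_real_ else stats::sd(x) / sqrt(replicates)
    list(rdna_richness = list(mean = mean(rd_rich), se = se(rd_rich)),
         rrna_richness = list(mean = mean(rr_rich), se = se(rr_rich)),
         phantom_count = list(mean = mean(phantom), se = se(phantom)),
         replicates = replicates)
  })
}

#' Exhaustive-enumeration expectations (exact oracle)
#'
#' Enumerates every equally likely without-replacement subset of each pool
#' and computes the exact expected rDNA richness, rRNA richness and phantom
#' count. Because the pools are sampled independently, the exact expectation
#' over all subset pairs factorizes into per-taxon detection frequencies
#' computed from each pool's enumeration. Intended as a test oracle; guarded
#' to small problems (`choose(N, n_rdna) * choose(R, n_rrna) <= 1e6`).
#'
#' @param community a [community()].
#' @param design a without-replacement [sampling_design()].
#' @return list with `rdna_richness`, `rrna_richness`, `phantom_count`.
#' @export
brute_force_expectations <- function(community, design) {
  check_design(community, design)
  if (design$scheme != "without_replacement") {
    stop("brute-force enumeration is defined for without-replacement sampling only",
         call. = FALSE)
  }
  n_pairs <- choose(community$N, design$n_rdna) * choose(community$R, design$n_rrna)
  if (n_pairs > 1e6) {
    stop("oracle infeasible: more than 1e6 subset pairs to enumerate", call. = FALSE)
  }
  s <- community$S
  # per-taxon detection frequency over all subsets of a pool
  detect_freq <- function(copies, n) {
    if (n == 0 || sum(copies) == 0) return(numeric(s))
    members <- rep.int(seq_len(s), copies)
    subs <- utils::combn(length(members), n)
    freq <- numeric(s)
    for (j in seq_len(ncol(subs))) {
      det <- unique(members[subs[, j]])
      freq[det] <- freq[det] + 1
    }
    freq / ncol(subs)
  }
  f_rd <- detect_freq(community$taxa$rdna_count, design$n_rdna)
  f_rr <- detect_freq(community$taxa$rrna_count, design$n_rrna)
  list(rdna_richness = sum(f_rd),
       rrna_richness = sum(f_rr),
       phantom_count = sum(f_rr * (1 - f_rd)))
}
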