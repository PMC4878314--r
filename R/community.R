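# The realized joint rDNA/rRNA community.

#' Construct a community from per-taxon counts
#'
#' A community is the realized population: for every taxon its rDNA copy
#' count (abundance k), whether it is metabolically active, and its rRNA
#' copy count. Derived totals are always recomputed from the taxa.
#'
#' @param taxon_id character vector of unique taxon identifiers.
#' @param rdna_count positive integer rDNA abundances.
#' @param active logical activity states.
#' @param rrna_count nonnegative integer rRNA copy counts; inactive taxa
#'   must have 0 and active taxa at least 1.
#' @param profile,intensity optional [activity_profile()] /
#'   [intensity_function()] recording the generating model (kept for
#'   ground-truth reports).
#' @return object of class `"community"`: a list with element `taxa`
#'   (data.frame) and derived totals `S` (taxon count), `S_active`,
#'   `N` (total rDNA copies) and `R` (total rRNA copies).
#' @examples
#' community(c("A", "B"), c(2, 1), c(TRUE, FALSE), c(4, 0))
#' @export
community <- function(taxon_id, rdna_count, active, rrna_count,
                      profile = NULL, intensity = NULL) {
  n <- length(taxon_id)
  if (anyDuplicated(taxon_id)) stop("taxon ids must be unique", call. = FALSE)
  if (length(rdna_count) != n || length(active) != n || length(rrna_count) != n) {
    stop("all per-taxon vectors must have equal length", call. = FALSE)
  }
  if (any(rdna_count < 1) || any(rdna_count != floor(rdna_count))) {
    stop("`rdna_count` must be integers >= 1", call. = FALSE)
  }
  if (any(rrna_count < 0) || any(rrna_count != floor(rrna_count))) {
    stop("`rrna_count` must be integers >= 0", call. = FALSE)
  }
  if (any(!active & rrna_count > 0)) {
    stop("inactive taxa must have rrna_count = 0", call. = FALSE)
  }
  if (any(active & rrna_count < 1)) {
    stop("active taxa must have rrna_count >= 1", call. = FALSE)
  }
  taxa <- data.frame(taxon_id = as.character(taxon_id),
                     rdna_count = as.integer(rdna_count),
                     active = as.logical(active),
                     rrna_count = as.integer(rrna_count),
                     stringsAsFactors = FALSE)
  structure(list(taxa = taxa,
                 S = nrow(taxa),
                 S_active = sum(taxa$active),
                 N = sum(taxa$rdna_count),
                 R = sum(taxa$rrna_count),
                 profile = profile,
                 intensity = intensity),
            class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("Joint rDNA/rRNA community: S = %d taxa (%d active), N = %d rDNA copies, R = %d rRNA copies\n",
              x$S, x$S_active, x$N, x$R))
  invisible(x)
}

#' @export
summary.community <- function(object, ...) {
  k <- object$taxa$rdna_count
  cat(sprintf("S = %d, S_active = %d (%.1f%%), N = %d, R = %d\n",
              object$S, object$S_active, 100 * object$S_active / object$S,
              object$N, object$R))
  cat("rDNA abundance: ")
  print(summary(k))
  invisible(object)
}

#' Realize a joint rDNA/rRNA community from a model configuration
#'
#' Composes [draw_abundances()], [assign_activity()] and [compute_rrna()]:
#' abundances are drawn from the SAD, each taxon's activity state from the
#' activity profile, and each active taxon's rRNA copies from the intensity
#' function. Fully reproducible for a fixed seed.
#'
#' @param dist an [abundance_distribution()].
#' @param n_taxa number of taxa (>= 1).
#' @param profile an [activity_profile()].
#' @param intensity an [intensity_function()].
#' @param mode activity assignment mode, see [assign_activity()].
#' @param seed optional integer seed.
#' @return a [community()].
#' @examples
#' realize_community(abundance_distribution("uniform", value = 2), 4,
#'                   activity_profile(1, 1), intensity_function(1, 1))
#' @export
realize_community <- function(dist, n_taxa, profile, intensity,
                              mode = c("bernoulli", "expected"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "activity_profile"),
            inherits(intensity, "intensity_function"))
  n_taxa <- assert_count(n_taxa, "n_taxa", min = 1L)
  with_seed_or_current(seed, {
    k <- draw_abundances(dist, n_taxa)
    active <- assign_activity(k, profile, mode = mode)
    m <- step_value(intensity, k)
    rrna <- compute_rrna(k, m, active)
    community(sprintf("OTU_%0*d", nchar(n_taxa), seq_len(n_taxa)),
              k, active, rrna, profile = profile, intensity = intensity)
  })
}
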