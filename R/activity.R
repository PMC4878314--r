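# Activity profile alpha(k) and activity intensity m(k).
#
# Both are step functions over abundance classes: class i is the half-open
# interval [breakpoints[i], breakpoints[i+1]), and the last class is
# open-ended so that every abundance k >= 1 belongs to exactly one class.

validate_breakpoints <- function(breakpoints) {
  if (length(breakpoints) == 0) {
    stop("`breakpoints` must be a nonempty ascending integer vector", call. = FALSE)
  }
  if (any(breakpoints != floor(breakpoints)) || any(breakpoints < 1)) {
    stop("`breakpoints` must be positive integers", call. = FALSE)
  }
  if (any(diff(breakpoints) <= 0)) {
    stop("`breakpoints` must be strictly ascending", call. = FALSE)
  }
  if (breakpoints[1] != 1) {
    stop("`breakpoints` must start at 1 so classes cover every abundance k >= 1",
         call. = FALSE)
  }
  as.integer(breakpoints)
}

new_step_function <- function(breakpoints, values, class) {
  breakpoints <- validate_breakpoints(breakpoints)
  if (length(values) != length(breakpoints)) {
    stop("`values` must have one entry per abundance class", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, values = as.numeric(values)),
            class = c(class, "abundance_step_function"))
}

#' Activity profile: fraction of active taxa per abundance class
#'
#' The activity profile alpha(k) gives, for each rDNA abundance class, the
#' fraction of taxa that are metabolically active (rRNA-producing).
#'
#' @param breakpoints strictly ascending positive integers starting at 1;
#'   class i covers abundances in `[breakpoints[i], breakpoints[i+1])` and
#'   the last class is open-ended.
#' @param values activity fractions in \[0, 1\], one per class.
#' @return object of class `"activity_profile"`.
#' @examples
#' activity_profile(c(1, 10, 100), c(0.1, 0.6, 1.0))
#' @export
activity_profile <- function(breakpoints, values) {
  if (any(values < 0 | values > 1)) {
    stop("activity profile `values` must lie in [0, 1]", call. = FALSE)
  }
  new_step_function(breakpoints, values, "activity_profile")
}

#' Activity intensity: rRNA:rDNA copy ratio per abundance class
#'
#' The activity intensity m(k) gives, for each rDNA abundance class, the
#' ratio of rRNA copies to rDNA copies for active taxa in that class.
#'
#' @inheritParams activity_profile
#' @param values strictly positive intensities, one per class.
#' @return object of class `"intensity_function"`.
#' @examples
#' intensity_function(c(1, 10, 100), c(1, 10, 2000))
#' @export
intensity_function <- function(breakpoints, values) {
  if (any(values <= 0)) {
    stop("intensity `values` must be strictly > 0", call. = FALSE)
  }
  new_step_function(breakpoints, values, "intensity_function")
}

#' @export
print.abundance_step_function <- function(x, ...) {
  b <- x$breakpoints
  labs <- c(sprintf("[%d,%d)", b[-length(b)], b[-1]),
            sprintf("[%d,Inf)", b[length(b)]))
  cat(class(x)[1], "over", length(b), "abundance classes:\n")
  cat(paste0("  ", labs, ": ", format(x$values), collapse = "\n"), "\n")
  invisible(x)
}

#' Map an abundance to its abundance-class index
#'
#' Classes are half-open: abundance k belongs to class i (0-based) when
#' `breakpoints[i+1] <= k < breakpoints[i+2]`; values at or above the last
#' breakpoint map to the final class.
#'
#' @param k positive integer abundance(s).
#' @param breakpoints ascending positive integers, first equal to or below
#'   the smallest `k`.
#' @return 0-based integer class index, vectorized over `k`.
#' @examples
#' classify_abundance(c(1, 10, 5000), c(1, 10, 100))  # 0 1 2
#' @export
classify_abundance <- function(k, breakpoints) {
  if (length(breakpoints) == 0) {
    stop("`breakpoints` must be nonempty", call. = FALSE)
  }
  if (any(k < 1) || any(k != floor(k))) {
    stop("`k` must contain positive integers", call. = FALSE)
  }
  if (any(k < breakpoints[1])) {
    stop("abundance below the first breakpoint has no class", call. = FALSE)
  }
  findInterval(k, breakpoints) - 1L
}

# step-function evaluation at abundance k (vectorized)
step_value <- function(f, k) {
  f$values[classify_abundance(k, f$breakpoints) + 1L]
}

#' Assign activity states to taxa
#'
#' Marks each taxon active or inactive according to the activity profile.
#' `mode = "bernoulli"` draws each taxon independently with probability
#' alpha(k); `mode = "expected"` activates exactly
#' `round(alpha * class size)` taxa per abundance class (rounding half away
#' from zero), chosen by a seeded shuffle, which is useful for deterministic
#' tests.
#'
#' @param abundances positive integer rDNA abundances, one per taxon.
#' @param profile an [activity_profile()].
#' @param mode `"bernoulli"` or `"expected"`.
#' @param seed optional integer seed.
#' @return logical vector, `TRUE` for active taxa.
#' @export
assign_activity <- function(abundances, profile,
                            mode = c("bernoulli", "expected"), seed = NULL) {
  stopifnot(inherits(profile, "activity_profile"))
  mode <- match.arg(mode)
  if (length(abundances) == 0) {
    stop("`abundances` must be nonempty", call. = FALSE)
  }
  cls <- classify_abundance(abundances, profile$breakpoints)
  alpha <- profile$values[cls + 1L]
  with_seed_or_current(seed, {
    if (mode == "bernoulli") {
      stats::runif(length(abundances)) < alpha
    } else {
      active <- logical(length(abundances))
      for (ci in sort(unique(cls))) {
        idx <- which(cls == ci)
        n_active <- round_half_away(profile$values[ci + 1L] * length(idx))
        # same seed + larger alpha => superset of active taxa (monotone)
        shuffled <- idx[sample.int(length(idx))]
        if (n_active > 0) active[shuffled[seq_len(n_active)]] <- TRUE
      }
      active
    }
  })
}

#' rRNA copy count of a taxon
#'
#' An inactive taxon carries zero rRNA copies. An active taxon with rDNA
#' abundance k and intensity m carries `max(1, round(m * k))` copies
#' (rounding half away from zero): activity implies at least one rRNA copy,
#' so every active taxon is detectable in the rRNA pool at full sampling.
#'
#' @param k positive integer rDNA abundance(s).
#' @param m_value positive intensity value(s).
#' @param active logical activity state(s).
#' @return nonnegative integer rRNA copy count, vectorized.
#' @examples
#' compute_rrna(10, 10, TRUE)    # 100
#' compute_rrna(1, 0.2, TRUE)    # 1
#' compute_rrna(10, 10, FALSE)   # 0
#' @export
compute_rrna <- function(k, m_value, active) {
  if (any(k < 1) || any(k != floor(k))) {
    stop("`k` must contain positive integers", call. = FALSE)
  }
  if (any(m_value <= 0)) {
    stop("`m_value` must be > 0", call. = FALSE)
  }
  as.integer(ifelse(active, pmax(1, round_half_away(m_value * k)), 0))
}
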