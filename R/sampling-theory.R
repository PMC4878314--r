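# Analytic sampling theory: detection probabilities, expected richness,
# expected phantom counts, and rarefaction curves.

#' Specify a sampling design for the two pools
#'
#' The rDNA and rRNA pools are sampled independently (the two libraries are
#' sequenced separately), each either without replacement (uniform subset of
#' a finite pool) or with replacement (multinomial over copy proportions).
#'
#' @param n_rdna nonnegative integer, individuals drawn from the rDNA pool.
#' @param n_rrna nonnegative integer, copies drawn from the rRNA pool.
#' @param scheme `"without_replacement"` (default) or `"with_replacement"`.
#' @return object of class `"sampling_design"`.
#' @export
sampling_design <- function(n_rdna, n_rrna,
                            scheme = c("without_replacement", "with_replacement")) {
  structure(list(n_rdna = assert_count(n_rdna, "n_rdna"),
                 n_rrna = assert_count(n_rrna, "n_rrna"),
                 scheme = match.arg(scheme)),
            class = "sampling_design")
}

check_design <- function(community, design) {
  stopifnot(inherits(community, "community"), inherits(design, "sampling_design"))
  if (design$scheme == "without_replacement") {
    if (design$n_rdna > community$N) {
      stop(sprintf("n_rdna = %d exceeds rDNA pool size N = %d under without-replacement sampling",
                   design$n_rdna, community$N), call. = FALSE)
    }
    if (design$n_rrna > community$R) {
      stop(sprintf("n_rrna = %d exceeds rRNA pool size R = %d under without-replacement sampling",
                   design$n_rrna, community$R), call. = FALSE)
    }
  }
  invisible(design)
}

#' Probability that a taxon is detected in a random sample
#'
#' Occupancy probability of a taxon holding `copies` of the `pool_total`
#' copies in a pool when `n` copies are drawn. Without replacement this is
#' the hypergeometric `1 - C(pool_total - copies, n) / C(pool_total, n)`
#' (computed in log-gamma space, with `C(a, b) = 0` for `b > a`); with
#' replacement it is `1 - (1 - copies/pool_total)^n`.
#'
#' @param copies nonnegative integer copy count(s) of the taxon; vectorized.
#' @param pool_total positive integer pool size.
#' @param n nonnegative integer sample size; must not exceed `pool_total`
#'   under without-replacement sampling.
#' @param scheme `"without_replacement"` or `"with_replacement"`.
#' @return detection probability in \[0, 1\], vectorized over `copies`.
#' @examples
#' detection_prob(1, 3, 2, "without_replacement")  # 2/3
#' detection_prob(1, 10, 1, "with_replacement")    # 0.1
#' @export
detection_prob <- function(copies, pool_total, n,
                           scheme = c("without_replacement", "with_replacement")) {
  scheme <- match.arg(scheme)
  pool_total <- assert_count(pool_total, "pool_total", min = 1L)
  n <- assert_count(n, "n")
  if (any(copies < 0) || any(copies > pool_total)) {
    stop("`copies` must lie in [0, pool_total]", call. = FALSE)
  }
  if (scheme == "without_replacement" && n > pool_total) {
    stop("sample size `n` exceeds `pool_total` under without-replacement sampling",
         call. = FALSE)
  }
  if (scheme == "with_replacement") {
    1 - (1 - copies / pool_total)^n
  } else {
    # lchoose(a, b) = -Inf when b > a, giving a miss probability of 0
    p_miss <- exp(lchoose(pool_total - copies, n) - lchoose(pool_total, n))
    pmin(pmax(1 - p_miss, 0), 1)
  }
}

#' Expected observed richness of a pool at a given sampling effort
#'
#' Sum over taxa of the detection probability of that taxon's copies in the
#' chosen pool. Inactive taxa hold zero rRNA copies and so contribute
#' nothing to rRNA richness. At full without-replacement sampling the rDNA
#' expectation equals S exactly and the rRNA expectation equals S_active.
#'
#' @param community a [community()].
#' @param pool `"rdna"` or `"rrna"`.
#' @param n nonnegative integer sample size.
#' @param scheme sampling scheme, see [detection_prob()].
#' @return expected number of detected taxa (nonnegative real).
#' @export
expected_richness <- function(community, pool = c("rdna", "rrna"), n,
                              scheme = c("without_replacement", "with_replacement")) {
  pool <- match.arg(pool)
  scheme <- match.arg(scheme)
  stopifnot(inherits(community, "community"))
  n <- assert_count(n, "n")
  copies <- if (pool == "rdna") community$taxa$rdna_count else community$taxa$rrna_count
  total <- if (pool == "rdna") community$N else community$R
  if (n == 0) return(0)
  if (total == 0) {
    if (scheme == "without_replacement") {
      stop("rRNA pool is empty (R = 0); cannot draw n > 0 without replacement",
           call. = FALSE)
    }
    return(0)
  }
  sum(detection_prob(copies, total, n, scheme))
}

#' Expected number of phantom taxa under a sampling design
#'
#' A phantom taxon is one whose rRNA appears in the rRNA sample while its
#' rDNA avoids collection in the (independently drawn) rDNA sample. The
#' expectation is the sum over active taxa of
#' `P(detected in rRNA) * (1 - P(detected in rDNA))`. It is exactly 0 at
#' full without-replacement sampling of both pools.
#'
#' @param community a [community()].
#' @param design a [sampling_design()].
#' @return expected phantom count (nonnegative real).
#' @export
expected_phantom_count <- function(community, design) {
  check_design(community, design)
  act <- community$taxa[community$taxa$active, , drop = FALSE]
  if (nrow(act) == 0 || design$n_rrna == 0) return(0)
  if (community$R == 0) return(0)
  p_rrna <- detection_prob(act$rrna_count, community$R, design$n_rrna, design$scheme)
  p_rdna <- if (design$n_rdna == 0) {
    rep(0, nrow(act))
  } else {
    detection_prob(act$rdna_count, community$N, design$n_rdna, design$scheme)
  }
  sum(p_rrna * (1 - p_rdna))
}

#' Rarefaction curves for rDNA richness, rRNA richness and phantom taxa
#'
#' Evaluates the three analytic expectations over a grid of sampling
#' efforts. One effort fraction f is applied to both pools proportionally
#' (`n_rdna = round(f * N)`, `n_rrna = round(f * R)`, rounding half away
#' from zero); richness expectations are normalized by S so the rDNA curve
#' converges to 1 and the rRNA curve to `S_active / S` at full
#' without-replacement sampling, while the phantom curve is reported as an
#' expected count (or divided by `S_active` when `normalize_phantom`).
#'
#' @param community a [community()].
#' @param efforts ascending sampling fractions in \[0, 1\].
#' @param scheme sampling scheme applied to both pools.
#' @param normalize_phantom if `TRUE`, report phantom expectation divided by
#'   `S_active` instead of a count.
#' @return data.frame of class `"rarefaction_curves"` with columns
#'   `effort`, `n_rdna`, `n_rrna`, `rdna_fraction`, `rrna_fraction`,
#'   `phantom_count`; the scheme is stored as an attribute.
#' @export
rarefaction_curves <- function(community, efforts = seq(0, 1, by = 0.02),
                               scheme = c("without_replacement", "with_replacement"),
                               normalize_phantom = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(community, "community"))
  if (any(efforts < 0 | efforts > 1)) {
    stop("`efforts` must be fractions in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(efforts)) {
    stop("`efforts` must be ascending", call. = FALSE)
  }
  n_rd <- as.integer(round_half_away(efforts * community$N))
  n_rr <- as.integer(round_half_away(efforts * community$R))
  rdna <- vapply(n_rd, function(n) expected_richness(community, "rdna", n, scheme),
                 numeric(1)) / community$S
  rrna <- vapply(n_rr, function(n) {
    if (n == 0) 0 else expected_richness(community, "rrna", n, scheme)
  }, numeric(1)) / community$S
  phant <- mapply(function(a, b) {
    expected_phantom_count(community, sampling_design(a, b, scheme))
  }, n_rd, n_rr)
  if (normalize_phantom) {
    phant <- if (community$S_active > 0) phant / community$S_active else phant
  }
  structure(data.frame(effort = efforts, n_rdna = n_rd, n_rrna = n_rr,
                       rdna_fraction = rdna, rrna_fraction = rrna,
                       phantom_count = phant),
            scheme = scheme, normalized_phantom = normalize_phantom,
            class = c("rarefaction_curves", "data.frame"))
}

#' Plot rarefaction curves
#'
#' Draws the rDNA and rRNA expected-richness fractions (left axis) and the
#' expected phantom count (right axis) against sampling effort.
#'
#' @param x a [rarefaction_curves()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rarefaction_curves <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::matplot(x$effort, cbind(x$rdna_fraction, x$rrna_fraction),
                    type = "l", lty = 1, lwd = 2, col = c("darkorange", "forestgreen"),
                    xlab = "sampling effort (fraction of pool)",
                    ylab = "expected fraction of taxa detected", ylim = c(0, 1), ...)
  graphics::par(new = TRUE)
  graphics::plot(x$effort, x$phantom_count, type = "l", lwd = 2, col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("expected phantom taxa", side = 4, line = 2.5)
  graphics::legend("right", legend = c("rDNA", "rRNA", "phantoms"),
                   col = c("darkorange", "forestgreen", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}
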