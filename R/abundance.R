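# Species abundance distributions (SADs) for the rDNA community.
#
# All distributions are zero-truncated: support is the positive integers,
# because a taxon present in the community has at least one rDNA copy.

#' Specify a species abundance distribution
#'
#' Describes the taxa-abundance distribution of the total (rDNA) community.
#' All kinds are zero-truncated so that sampled abundances are always >= 1.
#'
#' @param kind one of `"negative_binomial"`, `"geometric"`, `"log_series"`,
#'   `"uniform"`, `"explicit"`.
#' @param ... named parameters of the chosen kind:
#'   * `negative_binomial`: `shape` (> 0) and `mean` (> 0) of the
#'     untruncated distribution; zero-truncation is applied by rejection.
#'   * `geometric`: `p` in (0, 1]; the zero-truncated geometric on
#'     \{1, 2, ...\} with mean `1/p`.
#'   * `log_series`: `p` in (0, 1), Fisher's log-series
#'     P(k) proportional to `p^k / k`.
#'   * `uniform`: either a single `value`, or integers `min` and `max`
#'     (discrete uniform on `min:max`).
#'   * `explicit`: integer `values` (all >= 1) and probability `weights`
#'     (nonnegative, summing to 1 within 1e-9).
#' @return an object of class `"abundance_distribution"`.
#' @examples
#' abundance_distribution("negative_binomial", shape = 1, mean = 10)
#' abundance_distribution("geometric", p = 0.5)
#' @seealso [draw_abundances()]
#' @export
abundance_distribution <- function(kind = c("negative_binomial", "geometric",
                                            "log_series", "uniform", "explicit"),
                                   ...) {
  kind <- match.arg(kind)
  params <- list(...)
  switch(kind,
    negative_binomial = {
      shape <- params$shape
      mean <- params$mean
      if (is.null(shape) || !is.numeric(shape) || shape <= 0) {
        stop("negative_binomial parameter `shape` must be > 0", call. = FALSE)
      }
      if (is.null(mean) || !is.numeric(mean) || mean <= 0) {
        stop("negative_binomial parameter `mean` must be > 0", call. = FALSE)
      }
    },
    geometric = {
      p <- params$p
      if (is.null(p) || !is.numeric(p) || p <= 0 || p > 1) {
        stop("geometric parameter `p` must be in (0, 1]", call. = FALSE)
      }
    },
    log_series = {
      p <- params$p
      if (is.null(p) || !is.numeric(p) || p <= 0 || p >= 1) {
        stop("log_series parameter `p` must be in (0, 1)", call. = FALSE)
      }
    },
    uniform = {
      if (!is.null(params$value)) {
        params$min <- params$max <- params$value
      }
      if (is.null(params$min) || is.null(params$max) ||
          params$min != floor(params$min) || params$max != floor(params$max) ||
          params$min < 1 || params$max < params$min) {
        stop("uniform parameters `min`/`max` (or `value`) must be integers with 1 <= min <= max",
             call. = FALSE)
      }
    },
    explicit = {
      values <- params$values
      weights <- params$weights
      if (is.null(values) || any(values != floor(values)) || any(values < 1)) {
        stop("explicit parameter `values` must be integers >= 1", call. = FALSE)
      }
      if (is.null(weights) || length(weights) != length(values) ||
          any(weights < 0)) {
        stop("explicit parameter `weights` must be nonnegative and match `values`",
             call. = FALSE)
      }
      if (abs(sum(weights) - 1) > 1e-9) {
        stop("explicit parameter `weights` must sum to 1 within 1e-9", call. = FALSE)
      }
    }
  )
  structure(list(kind = kind, params = params, truncation = "zero_truncated"),
            class = "abundance_distribution")
}

#' @export
print.abundance_distribution <- function(x, ...) {
  pars <- vapply(x$params, function(p) paste(format(p), collapse = ","), "")
  cat("Zero-truncated", x$kind, "abundance distribution\n")
  if (length(pars)) cat(" ", paste(names(pars), pars, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# log-series pmf table truncated where the tail mass drops below ~1e-12
log_series_table <- function(p, tol = 1e-12) {
  kmax <- max(10L, ceiling(log(tol * (1 - p)) / log(p)))
  kmax <- min(kmax, 1e6)
  k <- seq_len(kmax)
  w <- p^k / k
  list(k = k, w = w / sum(w))
}

#' Draw taxon abundances from a species abundance distribution
#'
#' Samples `n_taxa` per-taxon rDNA abundances (positive integers) from a
#' zero-truncated distribution.
#'
#' @param dist an [abundance_distribution()].
#' @param n_taxa number of taxa to draw (>= 1).
#' @param seed optional integer seed; fixed seed gives a reproducible draw
#'   without disturbing the caller's RNG stream.
#' @return integer vector of length `n_taxa`, all values >= 1.
#' @examples
#' draw_abundances(abundance_distribution("uniform", value = 5), 3)
#' draw_abundances(abundance_distribution("negative_binomial", shape = 1, mean = 10),
#'                 10, seed = 1)
#' @export
draw_abundances <- function(dist, n_taxa, seed = NULL) {
  stopifnot(inherits(dist, "abundance_distribution"))
  n_taxa <- assert_count(n_taxa, "n_taxa", min = 1L)
  p <- dist$params
  with_seed_or_current(seed, {
    k <- switch(dist$kind,
      uniform = {
        lo <- as.integer(p$min %||% p$value)
        hi <- as.integer(p$max %||% p$value)
        if (lo == hi) rep.int(lo, n_taxa) else sample(lo:hi, n_taxa, replace = TRUE)
      },
      geometric = stats::rgeom(n_taxa, p$p) + 1L,
      negative_binomial = {
        # zero-truncation by rejection: redraw zeros
        out <- stats::rnbinom(n_taxa, size = p$shape, mu = p$mean)
        while (any(out == 0L)) {
          idx <- which(out == 0L)
          out[idx] <- stats::rnbinom(length(idx), size = p$shape, mu = p$mean)
        }
        out
      },
      log_series = {
        tab <- log_series_table(p$p)
        sample(tab$k, n_taxa, replace = TRUE, prob = tab$w)
      },
      explicit = sample(as.integer(p$values), n_taxa, replace = TRUE,
                        prob = p$weights)
    )
    as.integer(k)
  })
}
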