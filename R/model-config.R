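# Model configurations: a SAD plus class-wise activity profile and
# intensity, storable as flat YAML, realizable into a community.

#' Bundle a community model configuration
#'
#' @param dist an [abundance_distribution()].
#' @param n_taxa number of taxa to realize.
#' @param breakpoints abundance-class breakpoints, or `NULL` to use the
#'   empirical tertiles of the realized abundances (computed at
#'   realization time).
#' @param alpha_values per-class activity fractions in \[0, 1\].
#' @param m_values per-class positive activity intensities.
#' @param mode activity assignment mode, see [assign_activity()].
#' @param seed optional integer seed used at realization.
#' @return object of class `"model_config"`.
#' @seealso [preset_figure4()], [realize_model()]
#' @export
model_config <- function(dist, n_taxa, breakpoints = NULL, alpha_values,
                         m_values, mode = "bernoulli", seed = NULL) {
  stopifnot(inherits(dist, "abundance_distribution"))
  if (length(alpha_values) != length(m_values)) {
    stop("`alpha_values` and `m_values` must have the same number of classes",
         call. = FALSE)
  }
  if (!is.null(breakpoints)) {
    breakpoints <- validate_breakpoints(breakpoints)
    if (length(breakpoints) != length(alpha_values)) {
      stop("`breakpoints` must define one class per alpha/m value", call. = FALSE)
    }
  }
  if (any(alpha_values < 0 | alpha_values > 1)) {
    stop("`alpha_values` must lie in [0, 1]", call. = FALSE)
  }
  if (any(m_values <= 0)) stop("`m_values` must be > 0", call. = FALSE)
  structure(list(dist = dist, n_taxa = assert_count(n_taxa, "n_taxa", 1L),
                 breakpoints = breakpoints,
                 alpha_values = as.numeric(alpha_values),
                 m_values = as.numeric(m_values),
                 mode = match.arg(mode, c("bernoulli", "expected")),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Community model configuration\n")
  print(x$dist)
  cat("  n_taxa:", x$n_taxa, "\n")
  cat("  breakpoints:",
      if (is.null(x$breakpoints)) "<empirical tertiles>" else paste(x$breakpoints, collapse = ", "),
      "\n")
  cat("  alpha(k):", paste(x$alpha_values, collapse = ", "), "\n")
  cat("  m(k):    ", paste(x$m_values, collapse = ", "), "\n")
  invisible(x)
}

#' Preset model configurations for the two contrasting activity regimes
#'
#' Returns the two canonical three-class parameterizations over a
#' zero-truncated negative binomial SAD with shape 1. In regime `"a"` the
#' proportion of active taxa increases with abundance (10%, 60%, 100%) and
#' so does the activity intensity (1, 10, 2000): most active taxa are
#' abundant, so phantoms vanish quickly with sampling effort. In regime
#' `"b"` both are reversed (100%, 60%, 10% and 2000, 10, 1): the active
#' taxa are concentrated among rare taxa with very high rRNA output, so
#' phantom taxa persist to much higher sampling effort.
#'
#' @param row `"a"` or `"b"`.
#' @param n_taxa number of taxa (default 500).
#' @param nb_mean mean of the (untruncated) negative binomial SAD
#'   (default 10).
#' @param breakpoints three-class breakpoints, or `NULL` for empirical
#'   tertiles at realization time.
#' @param mode activity assignment mode.
#' @param seed optional integer seed stored in the configuration.
#' @return a [model_config()] with three abundance classes.
#' @examples
#' preset_figure4("a")$alpha_values  # 0.1 0.6 1.0
#' preset_figure4("b")$m_values      # 2000 10 1
#' @export
preset_figure4 <- function(row = c("a", "b"), n_taxa = 500, nb_mean = 10,
                           breakpoints = NULL, mode = "bernoulli", seed = NULL) {
  row <- match.arg(row)
  if (!is.null(breakpoints) && length(breakpoints) != 3) {
    stop("`breakpoints` must define exactly 3 abundance classes", call. = FALSE)
  }
  alpha <- c(0.10, 0.60, 1.00)
  m <- c(1, 10, 2000)
  if (row == "b") {
    alpha <- rev(alpha)
    m <- rev(m)
  }
  model_config(abundance_distribution("negative_binomial", shape = 1, mean = nb_mean),
               n_taxa = n_taxa, breakpoints = breakpoints,
               alpha_values = alpha, m_values = m, mode = mode, seed = seed)
}

# breakpoints at the empirical tertiles of realized abundances
empirical_tertiles <- function(k, n_classes) {
  probs <- seq(0, 1, length.out = n_classes + 1L)[seq_len(n_classes)]
  bp <- unique(as.integer(stats::quantile(k, probs, type = 1)))
  bp[1] <- 1L
  bp <- unique(bp)
  if (length(bp) != n_classes) {
    stop(sprintf("empirical tertiles of the realized abundances give %d distinct classes, not %d; supply `breakpoints` explicitly",
                 length(bp), n_classes), call. = FALSE)
  }
  bp
}

#' Realize a community from a model configuration
#'
#' Draws abundances, resolves breakpoints (empirical tertiles when not
#' supplied), assigns activity and computes rRNA copies. Reproducible for a
#' fixed configuration seed (a `seed` argument overrides the stored one).
#'
#' @param config a [model_config()].
#' @param seed optional integer seed overriding `config$seed`.
#' @return a [community()].
#' @export
realize_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  seed <- seed %||% config$seed
  with_seed_or_current(seed, {
    k <- draw_abundances(config$dist, config$n_taxa)
    bp <- config$breakpoints %||% empirical_tertiles(k, length(config$alpha_values))
    profile <- activity_profile(bp, config$alpha_values)
    intensity <- intensity_function(bp, config$m_values)
    active <- assign_activity(k, profile, mode = config$mode)
    rrna <- compute_rrna(k, step_value(intensity, k), active)
    community(sprintf("OTU_%0*d", nchar(config$n_taxa), seq_len(config$n_taxa)),
              k, active, rrna, profile = profile, intensity = intensity)
  })
}

#' Read a model configuration from a YAML file
#'
#' The file is flat key-value YAML: `kind`, distribution parameters under
#' `params`, `n_taxa`, optional `breakpoints`, `alpha_values`, `m_values`,
#' optional `mode` and `seed`.
#'
#' @param path file path.
#' @return a [model_config()].
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (field in c("kind", "n_taxa", "alpha_values", "m_values")) {
    if (is.null(y[[field]])) {
      stop(sprintf("model configuration is missing required field `%s`", field),
           call. = FALSE)
    }
  }
  dist <- do.call(abundance_distribution, c(list(kind = y$kind), y$params))
  model_config(dist, n_taxa = y$n_taxa, breakpoints = y$breakpoints,
               alpha_values = y$alpha_values, m_values = y$m_values,
               mode = y$mode %||% "bernoulli", seed = y$seed)
}

#' Write a model configuration to a YAML file
#'
#' @param config a [model_config()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  y <- list(kind = config$dist$kind, params = config$dist$params,
            n_taxa = config$n_taxa, breakpoints = config$breakpoints,
            alpha_values = config$alpha_values, m_values = config$m_values,
            mode = config$mode, seed = config$seed)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}
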