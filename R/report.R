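# End-to-end comparative analysis report.

#' Run the full comparative rRNA/rDNA analysis
#'
#' Executes the pipeline stages in order — read (or take an in-memory
#' table), optional rarefaction, OTU partition, rRNA:rDNA ratios,
#' ratio-abundance correlation, alpha diversity, Canberra distances and
#' per-class shared-OTU percentages — logging every stage with its
#' input/output dimensions. Any stage failure aborts with the stage name.
#'
#' @param table an [otu_table()], or `NULL` to read from `path`.
#' @param path,metadata_path table file paths, used when `table` is `NULL`.
#' @param rarefy_depth optional even rarefaction depth; `NULL` skips
#'   rarefaction.
#' @param on_short short-column handling for [rarefy()].
#' @param seed integer seed for the rarefaction draw.
#' @param corr_method,corr_transform passed to
#'   [ratio_abundance_correlation()].
#' @param canberra_variant passed to [canberra_matrix()].
#' @param quiet suppress stage log messages.
#' @return object of class `"phantom_report"`: list with elements
#'   `partition`, `ratios` (data.frame), `ratio_summary` (range, mean,
#'   fraction below 1), `correlation`, `diversity`, `canberra`,
#'   `shared_pct` (per class) and `params`.
#' @export
run_report <- function(table = NULL, path = NULL,
                       metadata_path = if (!is.null(path)) paste0(path, ".meta.tsv"),
                       rarefy_depth = NULL, on_short = "error", seed = NULL,
                       corr_method = "pearson", corr_transform = "log10",
                       canberra_variant = "classic", quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message("[phantomtaxa] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(table)) {
    if (is.null(path)) stop("supply either `table` or `path`", call. = FALSE)
    table <- stage("read", read_otu_table(path, metadata_path))
  }
  stopifnot(inherits(table, "otu_table"))
  log_stage("input: %d OTUs x %d samples", nrow(table$counts), ncol(table$counts))
  if (!is.null(rarefy_depth)) {
    table <- stage("rarefy", rarefy(table, rarefy_depth, seed = seed,
                                    on_short = on_short))
    log_stage("rarefied to depth %d: %d OTUs x %d samples", rarefy_depth,
              nrow(table$counts), ncol(table$counts))
  }
  partition <- stage("partition", partition_otus(table, pooling = "pooled"))
  log_stage("partition: %d shared, %d rDNA-only, %d phantoms",
            partition$n_shared, partition$n_rdna_only, partition$n_rrna_only)
  ratios <- stage("ratios", rrna_rdna_ratios(table))
  log_stage("ratios: %d shared OTUs", nrow(ratios))
  ratio_summary <- if (nrow(ratios) > 0) {
    list(min = min(ratios$ratio), max = max(ratios$ratio),
         mean = mean(ratios$ratio),
         frac_below_1 = mean(ratios$ratio < 1))
  }
  correlation <- if (nrow(ratios) >= 3) {
    stage("correlation",
          ratio_abundance_correlation(ratios, method = corr_method,
                                      transform = corr_transform))
  }
  if (!is.null(correlation)) {
    log_stage("correlation (%s, %s): %.4f (p = %.3g)", corr_method,
              corr_transform, correlation$estimate, correlation$p_value)
  }
  diversity <- stage("diversity", alpha_diversity(table))
  canberra <- stage("canberra", canberra_matrix(table, variant = canberra_variant))
  shared_pct <- lapply(c(rDNA = "rDNA", rRNA = "rRNA"), function(acid) {
    if (sum(table$sample_meta$nucleic_acid == acid) >= 2) {
      stage("shared_pct", shared_otu_percentage(table, acid))
    }
  })
  structure(list(partition = partition, ratios = ratios,
                 ratio_summary = ratio_summary, correlation = correlation,
                 diversity = diversity, canberra = canberra,
                 shared_pct = shared_pct,
                 params = list(rarefy_depth = rarefy_depth, seed = seed,
                               corr_method = corr_method,
                               corr_transform = corr_transform,
                               canberra_variant = canberra_variant)),
            class = "phantom_report")
}

#' @export
print.phantom_report <- function(x, ...) {
  cat("Comparative rRNA/rDNA analysis report\n\n")
  print(x$partition)
  if (!is.null(x$ratio_summary)) {
    cat(sprintf("\nrRNA:rDNA ratios (n = %d shared OTUs): range %.3g-%.3g, mean %.3g; %.1f%% below 1\n",
                nrow(x$ratios), x$ratio_summary$min, x$ratio_summary$max,
                x$ratio_summary$mean, 100 * x$ratio_summary$frac_below_1))
  }
  if (!is.null(x$correlation)) {
    cat(sprintf("ratio-abundance correlation (%s, %s): %.4f (p = %.3g, n = %d)\n",
                x$correlation$method, x$correlation$transform,
                x$correlation$estimate, x$correlation$p_value, x$correlation$n))
  }
  cat("\nAlpha diversity:\n")
  print(x$diversity, row.names = FALSE)
  invisible(x)
}

#' Write a report to disk
#'
#' Emits `<prefix>_summary.json` (partition, ratio summary, correlation,
#' shared-OTU percentages, parameters), `<prefix>_ratios.tsv`,
#' `<prefix>_diversity.tsv` and `<prefix>_canberra.tsv`, all with stable
#' column order; identical reports write byte-identical files.
#'
#' @param report a [run_report()] result.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "phantom_report"))
  summary_path <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(partition = unclass(report$partition),
                            ratio_summary = report$ratio_summary,
                            correlation = report$correlation,
                            shared_pct = report$shared_pct,
                            params = report$params),
                       summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- summary_path
  write_tsv <- function(df, suffix) {
    p <- paste0(prefix, suffix)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, write_tsv(report$ratios, "_ratios.tsv"),
             write_tsv(report$diversity, "_diversity.tsv"))
  cb <- data.frame(sample_id = rownames(report$canberra), report$canberra,
                   check.names = FALSE)
  paths <- c(paths, write_tsv(cb, "_canberra.tsv"))
  invisible(paths)
}
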