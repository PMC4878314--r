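# The OTU count table: the unit of exchange between the synthetic-data
# generator and the analysis pipeline. Plain tab-separated text on disk,
# with a sidecar metadata file labelling each sample rDNA or rRNA.

#' Construct an OTU count table
#'
#' @param counts nonnegative integer matrix, OTUs (rows) x samples
#'   (columns), with unique rownames (OTU ids) and colnames (sample ids).
#' @param sample_meta data.frame with columns `sample_id`, `nucleic_acid`
#'   (`"rDNA"` or `"rRNA"`) and optionally `day`; must label every sample.
#' @return object of class `"otu_table"`: list with elements `counts` and
#'   `sample_meta`.
#' @export
otu_table <- function(counts, sample_meta) {
  if (!is.matrix(counts)) {
    stop("`counts` must be a matrix with OTU rownames and sample colnames",
         call. = FALSE)
  }
  if (ncol(counts) == 0) stop("OTU table must have at least one sample", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must be a matrix with OTU rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate OTU ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("`counts` must be nonnegative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.data.frame(sample_meta) ||
      !all(c("sample_id", "nucleic_acid") %in% names(sample_meta))) {
    stop("`sample_meta` must be a data.frame with columns sample_id and nucleic_acid",
         call. = FALSE)
  }
  missing <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(missing)) {
    stop("sample(s) missing a nucleic-acid label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  bad <- !sample_meta$nucleic_acid %in% c("rDNA", "rRNA")
  if (any(bad)) {
    stop("invalid nucleic_acid label for sample(s): ",
         paste(sample_meta$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!"day" %in% names(sample_meta)) sample_meta$day <- NA_character_
  structure(list(counts = counts, sample_meta = sample_meta), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  na <- table(factor(x$sample_meta$nucleic_acid, c("rDNA", "rRNA")))
  cat(sprintf("OTU table: %d OTUs x %d samples (%d rDNA, %d rRNA)\n",
              nrow(x$counts), ncol(x$counts), na[["rDNA"]], na[["rRNA"]]))
  cat(sprintf("  column sums: %s\n",
              paste(colSums(x$counts), collapse = ", ")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

# columns of one nucleic-acid class, as a matrix (possibly one column)
class_columns <- function(table, nucleic_acid) {
  sel <- table$sample_meta$nucleic_acid == nucleic_acid
  table$counts[, sel, drop = FALSE]
}

#' Write an OTU table and its metadata sidecar
#'
#' Writes tab-separated UTF-8 text with header `#OTU ID` followed by the
#' sample ids, one row per OTU, final line newline-terminated; the sidecar
#' (default `<path>.meta.tsv`) holds columns `sample_id`, `nucleic_acid`,
#' `day`. Identical tables produce byte-identical files.
#'
#' @param table an [otu_table()].
#' @param path output path for the count table.
#' @param metadata_path output path for the sidecar (default
#'   `paste0(path, ".meta.tsv")`).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, metadata_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(table, "otu_table"))
  header <- paste(c("#OTU ID", colnames(table$counts)), collapse = "\t")
  rows <- paste(rownames(table$counts),
                apply(table$counts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path, useBytes = TRUE)
  meta <- table$sample_meta[, c("sample_id", "nucleic_acid", "day")]
  meta_lines <- c("sample_id\tnucleic_acid\tday",
                  paste(meta$sample_id, meta$nucleic_acid,
                        ifelse(is.na(meta$day), "", meta$day), sep = "\t"))
  writeLines(meta_lines, metadata_path, useBytes = TRUE)
  invisible(path)
}

#' Read an OTU table and its metadata sidecar
#'
#' Expects the format written by [write_otu_table()]: a tab-separated count
#' table whose header starts with `#OTU ID` (a missing leading `#` is
#' tolerated) and a metadata file labelling every sample `rDNA` or `rRNA`.
#' Duplicate OTU ids, duplicate sample ids, negative and non-integer counts
#' are rejected.
#'
#' @param path count table path.
#' @param metadata_path sidecar path (default `paste0(path, ".meta.tsv")`).
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, metadata_path = paste0(path, ".meta.tsv")) {
  if (!file.exists(path)) stop("OTU table not found: ", path, call. = FALSE)
  if (!file.exists(metadata_path)) {
    stop("metadata sidecar not found: ", metadata_path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("OTU table has no data rows", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!header[1] %in% c("#OTU ID", "OTU ID")) {
    stop("OTU table header must start with '#OTU ID'", call. = FALSE)
  }
  sample_ids <- header[-1]
  if (length(sample_ids) == 0) stop("OTU table has no sample columns", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id in header", call. = FALSE)
  }
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(cells) != length(header))) {
    stop("ragged OTU table: row width does not match header", call. = FALSE)
  }
  otu_ids <- vapply(cells, `[[`, "", 1L)
  if (anyDuplicated(otu_ids)) stop("duplicated OTU id", call. = FALSE)
  raw <- suppressWarnings(
    vapply(cells, function(x) as.numeric(x[-1]), numeric(length(sample_ids)))
  )
  raw <- matrix(raw, nrow = length(sample_ids))  # samples x otus at this point
  if (any(is.na(raw))) stop("non-numeric count in OTU table", call. = FALSE)
  if (any(raw < 0)) stop("negative count in OTU table", call. = FALSE)
  if (any(raw != floor(raw))) stop("non-integer count in OTU table", call. = FALSE)
  counts <- t(raw)
  dimnames(counts) <- list(otu_ids, sample_ids)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  meta$day[!is.na(meta$day) & meta$day == ""] <- NA_character_
  otu_table(counts, meta)
}
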