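# Comparative analysis pipeline: reading, rarefaction, partitions, ratios,
# correlations, diversity and distances.

test_that("malformed OTU tables are rejected with informative errors", {
  dir <- withr::local_tempdir()
  tab_path <- file.path(dir, "t.tsv")
  meta_path <- paste0(tab_path, ".meta.tsv")
  writeLines(c("sample_id\tnucleic_acid\tday", "S1\trDNA\t", "S2\trRNA\t"),
             meta_path)

  writeLines(c("#OTU ID\tS1\tS2", "o1\t1\t-2", "o2\t0\t1"), tab_path)
  expect_error(read_otu_table(tab_path), "negative")

  writeLines(c("#OTU ID\tS1\tS1", "o1\t1\t2"), tab_path)
  expect_error(read_otu_table(tab_path), "duplicated sample")

  writeLines(c("#OTU ID\tS1\tS2", "o1\t1\t2", "o1\t0\t1"), tab_path)
  expect_error(read_otu_table(tab_path), "duplicated OTU")

  writeLines(c("#OTU ID\tS1\tS2", "o1\t1\t2.5"), tab_path)
  expect_error(read_otu_table(tab_path), "non-integer")

  # header without the leading '#' is tolerated
  writeLines(c("OTU ID\tS1\tS2", "o1\t1\t2"), tab_path)
  expect_s3_class(read_otu_table(tab_path), "otu_table")

  # a sample without a nucleic-acid label is named in the error
  writeLines(c("#OTU ID\tS1\tS2", "o1\t1\t2"), tab_path)
  writeLines(c("sample_id\tnucleic_acid\tday", "S1\trDNA\t"), meta_path)
  expect_error(read_otu_table(tab_path), "S2")
})

test_that("rarefaction subsamples every retained column to the exact depth", {
  counts <- matrix(rpois(40, 20) + 1L, nrow = 10,
                   dimnames = list(sprintf("o%d", 1:10), sprintf("s%d", 1:4)))
  tab <- make_table(counts, c("rDNA", "rRNA", "rDNA", "rRNA"))
  r <- rarefy(tab, 50, seed = 1)
  expect_true(all(colSums(r$counts) == 50))
  expect_true(all(rowSums(r$counts) > 0))
  # reproducible
  expect_identical(rarefy(tab, 50, seed = 1)$counts, r$counts)
  # a column already at depth keeps its total
  tot <- colSums(counts)[1]
  r2 <- rarefy(tab, tot, seed = 2, on_short = "drop")
  expect_true(all(colSums(r2$counts) == tot))
  # short columns: error by default, dropped on request
  expect_error(rarefy(tab, 1000), "below rarefaction depth")
  half <- make_table(cbind(counts[, 1, drop = FALSE],
                           s_short = c(2L, rep(0L, 9))),
                     c("rDNA", "rRNA"))
  dropped <- rarefy(half, 20, seed = 1, on_short = "drop")
  expect_equal(ncol(dropped$counts), 1)
  expect_error(rarefy(half, 10000, on_short = "drop"), "every sample")
})

test_that("rarefying [5,5] to depth 2 matches the hypergeometric mean", {
  tab <- make_table(matrix(c(5L, 5L), 2, dimnames = list(c("a", "b"), "s1")),
                    "rDNA")
  draws <- vapply(seq_len(2000), function(s) {
    r <- rarefy(tab, 2, seed = s)
    if ("a" %in% rownames(r$counts)) r$counts["a", 1] else 0L
  }, integer(1))
  # count of row a ~ Hypergeometric(5, 5, 2): mean 1
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1), 3 * se)
})

test_that("partition summaries reproduce the library-wide arithmetic", {
  p <- partition_summary(343, 424, 309)
  expect_equal(p$n_total, 1076)
  expect_equal(p$pct_shared, 31.9)
  expect_equal(p$pct_rdna_only, 39.4)
  expect_equal(p$pct_rrna_only, 28.7)
  expect_lt(abs(p$pct_shared + p$pct_rdna_only + p$pct_rrna_only - 100), 0.1 + 1e-9)
})

test_that("OTU partitions are computed from pooled detection sets", {
  # detection sets with sizes 343 shared / 424 rDNA-only / 309 rRNA-only
  n <- 1076
  counts <- matrix(0L, n, 2, dimnames = list(sprintf("o%04d", 1:n), c("d", "r")))
  counts[1:(343 + 424), 1] <- 1L
  counts[c(1:343, (343 + 424 + 1):n), 2] <- 1L
  tab <- make_table(counts, c("rDNA", "rRNA"))
  p <- partition_otus(tab)
  expect_equal(p$n_shared, 343)
  expect_equal(p$n_rdna_only, 424)
  expect_equal(p$n_rrna_only, 309)
  expect_equal(c(p$pct_shared, p$pct_rdna_only, p$pct_rrna_only),
               c(31.9, 39.4, 28.7))

  # identical detection sets: everything shared
  same <- make_table(matrix(c(1L, 2L, 3L, 6L), 2), c("rDNA", "rRNA"))
  ps <- partition_otus(same)
  expect_equal(ps$n_rdna_only, 0)
  expect_equal(ps$n_rrna_only, 0)
  expect_equal(ps$pct_shared, 100.0)

  # rRNA detections nested in rDNA detections: no phantoms
  nested <- make_table(matrix(c(1L, 1L, 1L, 0L), 2), c("rDNA", "rRNA"))
  expect_equal(partition_otus(nested)$n_rrna_only, 0)

  # partition needs both classes present and detected
  expect_error(partition_otus(make_table(matrix(1L, 1, 1), "rDNA")), "rRNA")
  allzero <- make_table(matrix(c(1L, 1L, 0L, 0L), 2), c("rDNA", "rRNA"))
  expect_error(partition_otus(allzero), "no OTUs detected in rRNA")
})

test_that("partition sets are disjoint and complete on random tables", {
  set.seed(99)
  for (i in 1:10) {
    counts <- matrix(rbinom(200, 2, 0.4), 25, 8)
    rownames(counts) <- sprintf("o%d", 1:25)
    tab <- make_table(counts, rep(c("rDNA", "rRNA"), 4))
    det <- rowSums(counts) > 0
    p <- tryCatch(partition_otus(tab), error = function(e) NULL)
    if (is.null(p)) next  # one class undetected in this draw
    expect_equal(p$n_shared + p$n_rdna_only + p$n_rrna_only, sum(det))
    expect_lt(abs(p$pct_shared + p$pct_rdna_only + p$pct_rrna_only - 100),
              0.1 + 1e-9)
  }
})

test_that("rRNA:rDNA ratios are class-mean relative-abundance quotients", {
  counts <- matrix(c(10L, 90L, 2L, 98L), 2,
                   dimnames = list(c("a", "b"), c("d", "r")))
  tab <- make_table(counts, c("rDNA", "rRNA"))
  rr <- rrna_rdna_ratios(tab)
  expect_equal(rr$ratio[rr$otu_id == "a"], 0.02 / 0.10)
  expect_equal(rr$ratio[rr$otu_id == "b"], 0.98 / 0.90)
  # identical relative abundances give ratio 1
  even <- make_table(matrix(c(1L, 3L, 2L, 6L), 2), c("rDNA", "rRNA"))
  expect_equal(rrna_rdna_ratios(even)$ratio, c(1, 1))
  # only shared OTUs get a record
  part <- make_table(matrix(c(1L, 0L, 0L, 2L), 2), c("rDNA", "rRNA"))
  expect_equal(nrow(rrna_rdna_ratios(part)), 0)
  # zero-sum columns are rejected
  zs <- make_table(matrix(c(1L, 1L, 0L, 0L), 2), c("rDNA", "rRNA"))
  expect_error(rrna_rdna_ratios(zs), "zero-sum")
})

test_that("swapping nucleic-acid labels inverts ratios and mirrors the partition", {
  set.seed(5)
  counts <- matrix(rpois(120, 3), 20, 6)
  counts[1:5, 1:3] <- 0L   # some one-sided OTUs
  counts[6:9, 4:6] <- 0L
  rownames(counts) <- sprintf("o%d", 1:20)
  tab <- make_table(counts, c(rep("rDNA", 3), rep("rRNA", 3)))
  swapped <- make_table(counts, c(rep("rRNA", 3), rep("rDNA", 3)))
  r1 <- rrna_rdna_ratios(tab)
  r2 <- rrna_rdna_ratios(swapped)
  expect_equal(r2$ratio[match(r1$otu_id, r2$otu_id)], 1 / r1$ratio)
  p1 <- partition_otus(tab)
  p2 <- partition_otus(swapped)
  expect_equal(p1$n_rdna_only, p2$n_rrna_only)
  expect_equal(p1$n_rrna_only, p2$n_rdna_only)
  expect_equal(p1$n_shared, p2$n_shared)
})

test_that("correlation handles perfect order, exact linearity and degeneracy", {
  rec <- data.frame(otu_id = letters[1:5],
                    mean_relabund_rdna = c(0.01, 0.02, 0.04, 0.08, 0.16),
                    mean_relabund_rrna = 1,
                    ratio = c(50, 40, 30, 20, 10))
  kt <- ratio_abundance_correlation(rec, method = "kendall_tau_b")
  expect_equal(kt$estimate, -1)
  lin <- rec
  lin$ratio <- 3 * lin$mean_relabund_rdna
  pe <- ratio_abundance_correlation(lin, method = "pearson", transform = "log10")
  expect_equal(pe$estimate, 1)
  flat <- rec
  flat$ratio <- 2
  expect_error(ratio_abundance_correlation(flat), "zero variance")
  expect_error(ratio_abundance_correlation(rec[1:2, ]), "at least 3")
})

test_that("alpha diversity follows the Shannon/Pielou formulas", {
  tab <- make_table(matrix(c(5L, 5L, 5L, 5L,
                             9L, 0L, 0L, 0L,
                             90L, 10L, 0L, 0L), 4),
                    c("rDNA", "rDNA", "rRNA"))
  d <- alpha_diversity(tab)
  expect_equal(d$richness, c(4L, 1L, 2L))
  expect_equal(d$shannon[1], log(4))
  expect_equal(d$pielou[1], 1)
  expect_equal(d$shannon[2], 0)
  expect_true(is.na(d$pielou[2]))
  h_90_10 <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(d$shannon[3], h_90_10)
  expect_equal(d$pielou[3], h_90_10 / log(2))
})

test_that("Canberra distances match their definitions and the vegan cross-check", {
  tab <- make_table(matrix(c(1L, 0L, 0L, 1L), 2), c("rDNA", "rRNA"))
  expect_equal(canberra_matrix(tab, "classic")[1, 2], 2)
  expect_equal(canberra_matrix(tab, "nonzero_normalized")[1, 2], 1)

  set.seed(31)
  counts <- matrix(rpois(60, 2), 15, 4,
                   dimnames = list(sprintf("o%d", 1:15), sprintf("s%d", 1:4)))
  counts[1, ] <- c(3L, 1L, 2L, 5L)  # keep every column nonzero
  tab2 <- make_table(counts, rep(c("rDNA", "rRNA"), 2))
  d <- canberra_matrix(tab2, "classic")
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  # identical columns are at distance zero
  dup <- make_table(cbind(counts[, 1, drop = FALSE], same = counts[, 1]),
                    c("rDNA", "rRNA"))
  expect_equal(canberra_matrix(dup, "classic")[1, 2], 0)
  # normalized variant agrees with vegan's Canberra
  dn <- canberra_matrix(tab2, "nonzero_normalized")
  dv <- as.matrix(vegan::vegdist(t(counts), method = "canberra"))
  expect_equal(unname(dn), unname(dv), tolerance = 1e-12)
})

test_that("shared-OTU percentages summarize the per-class core", {
  # identical detection sets: 100% shared, no spread
  same <- make_table(matrix(1L, 5, 3), rep("rDNA", 3))
  s <- shared_otu_percentage(same, "rDNA")
  expect_equal(s$mean_pct, 100)
  expect_equal(s$sd_pct, 0)
  # disjoint detection sets: nothing shared
  disj <- make_table(matrix(c(1L, 0L, 0L, 1L), 2), rep("rRNA", 2))
  expect_equal(shared_otu_percentage(disj, "rRNA")$mean_pct, 0)
  # 4 samples, each richness 100, common core of 25
  counts <- matrix(0L, 325, 4)
  counts[1:25, ] <- 1L
  for (j in 1:4) counts[25 + (j - 1) * 75 + 1:75, j] <- 1L
  core4 <- make_table(counts, rep("rDNA", 4))
  s4 <- shared_otu_percentage(core4, "rDNA")
  expect_equal(s4$mean_pct, 25)
  expect_equal(s4$sd_pct, 0)
  expect_equal(s4$core_size, 25)
  expect_error(shared_otu_percentage(same, "rRNA"), "no rRNA samples")
})

test_that("the end-to-end report is reproducible and aborts with stage names", {
  com <- random_model_community(80, seed = 41)
  tab <- generate_paired_tables(com, 4, 150, 150, seed = 7)
  rep1 <- run_report(tab, rarefy_depth = 120, seed = 3, quiet = TRUE)
  expect_s3_class(rep1$partition, "partition_summary")
  expect_true(all(c("min", "max", "mean", "frac_below_1") %in%
                  names(rep1$ratio_summary)))
  expect_equal(nrow(rep1$diversity), ncol(tab$counts))

  dir <- withr::local_tempdir()
  write_report(rep1, file.path(dir, "run1"))
  rep2 <- run_report(tab, rarefy_depth = 120, seed = 3, quiet = TRUE)
  write_report(rep2, file.path(dir, "run2"))
  for (suffix in c("_summary.json", "_ratios.tsv", "_diversity.tsv",
                   "_canberra.tsv")) {
    expect_identical(readLines(file.path(dir, paste0("run1", suffix))),
                     readLines(file.path(dir, paste0("run2", suffix))))
  }

  # an all-zero rRNA side aborts at the partition stage
  bad_counts <- tab$counts
  bad_counts[, tab$sample_meta$nucleic_acid == "rRNA"] <- 0L
  bad <- otu_table(bad_counts, tab$sample_meta)
  expect_error(run_report(bad, quiet = TRUE), "partition")
})
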