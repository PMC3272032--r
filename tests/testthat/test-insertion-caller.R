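make_ann <- function(...) {
  a <- data.frame(...)
  names(a) <- c("chrom", "start", "end", "family", "strand")[seq_along(a)]
  if (is.null(a$family)) a$family <- "AluY"
  if (is.null(a$strand)) a$strand <- "+"
  a
}

mk_mapped <- function(read_id, chrom, start, end, space = "CT",
                      library_id = "L1") {
  data.frame(read_id = read_id, status = "unique", chrom = chrom,
             start = start, end = end, space = space, identity = 1,
             aligned_length = end - start, cycle = 1L,
             score = end - start, n_accepted = 1L,
             library_id = library_id, stringsAsFactors = FALSE)
}

test_that("classify_junction applies the 10 bp adjacency window", {
  ann <- make_ann("chr1", 5000, 5300)
  ## junction 3 bp upstream of the annotated start -> known_adjacent
  jc <- classify_junction(mk_mapped("a", "chr1", 4800, 4997), ann)
  expect_equal(jc$verdict, "known_adjacent")
  expect_equal(jc$distance_to_nearest_alu, 3)
  ## junction 500 bp away -> putative_novel
  jc2 <- classify_junction(mk_mapped("b", "chr1", 4300, 4500), ann)
  expect_equal(jc2$verdict, "putative_novel")
  ## boundary: exactly 10 in, 11 out
  expect_equal(classify_junction(
    mk_mapped("c", "chr1", 4800, 4990), ann)$verdict, "known_adjacent")
  expect_equal(classify_junction(
    mk_mapped("d", "chr1", 4800, 4989), ann)$verdict, "putative_novel")
  ## reverse-space junction sits at the alignment start
  jr <- classify_junction(mk_mapped("e", "chr1", 5305, 5500, "GA"), ann)
  expect_equal(jr$junction_pos, 5305)
  expect_equal(jr$verdict, "known_adjacent")
  ## empty annotation: loud warning, everything novel
  expect_warning(
    j0 <- classify_junction(mk_mapped("f", "chr1", 1, 100), ann[0, ]),
    "putative_novel")
  expect_equal(j0$verdict, "putative_novel")
})

test_that("junction verdicts are invariant under coordinate shifts", {
  ann <- make_ann("chr1", 5000, 5300)
  shift <- 12345
  ann2 <- transform(ann, start = start + shift, end = end + shift)
  for (j in c(4990, 4800, 5100, 5316)) {
    v1 <- classify_junction(mk_mapped("x", "chr1", j - 150, j), ann)$verdict
    v2 <- classify_junction(mk_mapped("x", "chr1", j - 150 + shift,
                                      j + shift), ann2)$verdict
    expect_identical(v1, v2)
  }
})

test_that("cluster_candidates single-links within the merge window", {
  calls <- data.frame(read_id = c("r1", "r2", "r3"), chrom = "chr1",
                      junction_pos = c(1000, 1004, 1009),
                      verdict = "putative_novel", library_id = "L1",
                      stringsAsFactors = FALSE)
  cl <- cluster_candidates(calls)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_reads, 3)
  expect_equal(cl$breakpoint_lo, 1000)
  expect_equal(cl$breakpoint_hi, 1009)

  calls2 <- data.frame(read_id = c("r1", "r2"), chrom = "chr1",
                       junction_pos = c(1000, 1050),
                       verdict = "putative_novel", library_id = "L1")
  expect_equal(nrow(cluster_candidates(calls2)), 2)

  ## clusters partition the reads
  set.seed(5)
  many <- data.frame(read_id = sprintf("r%03d", 1:60), chrom = "chr1",
                     junction_pos = sort(sample(1e6, 60)),
                     verdict = "putative_novel",
                     library_id = sample(c("L1", "L2"), 60, TRUE))
  cl3 <- cluster_candidates(many)
  expect_equal(sum(cl3$n_reads), 60)
  expect_equal(sum(attr(cl3, "by_library")$n_reads), 60)
})

test_that("planted 1,762 junctions collapse to exactly 327 clusters", {
  ## echoes the study's read->cluster reduction: 327 sites, 1,762 reads
  set.seed(327)
  sites <- sort(sample(seq(5000, 5e7, by = 1), 327))
  sites <- sites + seq(0, by = 1000, length.out = 327)  # enforce spacing
  reads_per <- c(rmultinom(1, 1762 - 327, rep(1, 327))) + 1L
  jp <- unlist(lapply(seq_along(sites), function(i)
    sites[i] + cumsum(c(0, sample(0:5, reads_per[i] - 1, TRUE)))))
  calls <- data.frame(read_id = sprintf("r%04d", seq_along(jp)),
                      chrom = "chr1", junction_pos = jp,
                      verdict = "putative_novel",
                      library_id = sample(c("NC1", "NC2", "PA1"),
                                          length(jp), TRUE))
  cl <- cluster_candidates(calls, merge_window = 10)
  expect_equal(nrow(cl), 327)
  expect_equal(sum(cl$n_reads), 1762)

  ## 11 of the 327 planted sites written to the known table -> 316 novel
  known_idx <- sample(327, 11)
  kb <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tknown", sites[known_idx] - 1,
                     sites[known_idx] + 1), kb)
  cl <- annotate_novelty(cl, kb)
  expect_equal(sum(cl$novel), 316)
})

test_that("annotate_novelty handles empty and exact-hit tables", {
  calls <- data.frame(read_id = "r", chrom = "chr1", junction_pos = 1000,
                      verdict = "putative_novel", library_id = "L1")
  cl <- cluster_candidates(calls)
  kb0 <- tempfile(); writeLines(character(0), kb0)
  expect_true(annotate_novelty(cl, kb0)$novel)
  kb1 <- tempfile(); writeLines("chr1\t999\t1001\tknown", kb1)
  expect_false(annotate_novelty(cl, kb1)$novel)
  kbbad <- tempfile(); writeLines("chr1\toops", kbbad)
  expect_error(annotate_novelty(cl, kbbad), "line 1")
})

test_that("genic context follows the exon > UTR > intron precedence", {
  gm <- data.frame(
    chrom = "chr1",
    start = c(1000, 1000, 1500, 9800, 10000),
    end = c(10000, 1200, 1800, 10000, 10000),
    type = c("transcript", "utr5", "exon", "utr3", "transcript"),
    gene_id = "G1", stringsAsFactors = FALSE)[1:4, ]
  mk_cl <- function(pos) {
    calls <- data.frame(read_id = "r", chrom = "chr1",
                        junction_pos = pos, verdict = "putative_novel",
                        library_id = "L1")
    cluster_candidates(calls)
  }
  expect_equal(annotate_genic_context(mk_cl(1600), gm)$genic_context,
               "exonic")
  expect_equal(annotate_genic_context(mk_cl(1100), gm)$genic_context,
               "utr5")
  expect_equal(annotate_genic_context(mk_cl(9900), gm)$genic_context,
               "utr3")
  expect_equal(annotate_genic_context(mk_cl(5000), gm)$genic_context,
               "intronic")
  expect_equal(annotate_genic_context(mk_cl(20000), gm)$genic_context,
               "intergenic")
  expect_equal(annotate_genic_context(mk_cl(5000), gm)$gene_id, "G1")
  expect_error(annotate_genic_context(mk_cl(1), gm[, 1:2]), "invalid")
})

test_that("random placement recovers the gene model's geometry", {
  gm <- simulate_gene_models("chr1", 200000, n_genes = 5, seed = 3)
  set.seed(9)
  pos <- sample(0:199999, 4000, replace = TRUE)
  calls <- data.frame(read_id = sprintf("r%04d", seq_along(pos)),
                      chrom = "chr1", junction_pos = sort(pos),
                      verdict = "putative_novel", library_id = "L1")
  cl <- cluster_candidates(calls, merge_window = 0)
  cl <- annotate_genic_context(cl, gm)
  ## geometric oracle on midpoints (clusters with window 0 ~ positions)
  tx <- gm[gm$type == "transcript", ]
  tx_bp <- sum(tx$end - tx$start)
  frac_genic <- sum(cl$genic_context != "intergenic") / nrow(cl)
  p <- tx_bp / 200000
  expect_lt(abs(frac_genic - p), 4 * sqrt(p * (1 - p) / nrow(cl)) + 0.01)
})

test_that("library statistics reproduce the printed ratio arithmetic", {
  counts <- data.frame(library_id = c("NC2", "X"),
                       regions_mapped = c(47071, 1000),
                       insertion_reads = c(692, 10),
                       insertion_regions = c(159, 5))
  st <- library_stats_from_counts(counts)
  expect_equal(st$ratio[1], 0.34)
  expect_equal(st$ratio[2], 0.5)
  expect_error(library_stats_from_counts(counts[, 1:2]), "columns")

  ## single library, single cluster, one read
  calls <- data.frame(read_id = "r", chrom = "chr1", junction_pos = 100,
                      verdict = "putative_novel", library_id = "L1")
  cl <- cluster_candidates(calls)
  s <- summarize_libraries(cl, data.frame(library_id = "L1",
                                          reads_mapped = 50,
                                          regions_mapped = 40))
  expect_equal(s$per_library$ratio, round(100 / 40, 2))
  expect_equal(s$aggregate$pct_multiread, 0)
  expect_equal(s$aggregate$total_insertion_reads, 1)
  expect_equal(s$aggregate$total_region_incidences, 1)
  ## unknown library errors
  expect_error(
    summarize_libraries(cl, data.frame(library_id = "ZZ",
                                       reads_mapped = 1,
                                       regions_mapped = 1)),
    "absent")
})

test_that("region incidences exceed clusters only through sharing", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:6), chrom = "chr1",
    junction_pos = c(100, 101, 5000, 5001, 9000, 9001),
    verdict = "putative_novel",
    library_id = c("A", "B", "A", "A", "B", "B"))
  cl <- cluster_candidates(calls)
  s <- summarize_libraries(cl, data.frame(library_id = c("A", "B"),
                                          reads_mapped = c(10, 10),
                                          regions_mapped = c(10, 10)),
                           metadata = data.frame(
                             library_id = c("A", "B"),
                             tissue_class = c("normal", "tumor")))
  expect_equal(s$aggregate$n_clusters, 3)
  expect_equal(s$aggregate$total_region_incidences, 4)  # one shared
  expect_equal(s$aggregate$pct_multilibrary, pct <- round(100 / 3, 1))
  expect_equal(s$aggregate$pct_shared_normal_tumor, 100)
})
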