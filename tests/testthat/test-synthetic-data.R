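test_that("sim_config validates ranges and fractions", {
  expect_error(tiny_config(gc_fraction = 1.2), "fraction")
  expect_error(tiny_config(tsd_length_range = c(10, 4)), "range")
  expect_error(tiny_config(conversion_rate = -0.1), "fraction")
  expect_s3_class(tiny_config(), "alu_sim_config")
})

test_that("make_reference places and annotates background Alus", {
  cfg <- tiny_config(n_background_alus = 0)
  ref <- make_reference(cfg)
  expect_equal(nrow(ref$annotation), 0)
  expect_equal(nchar(ref$genome[[1]]), cfg$genome_length)

  ## determinism: same seed, byte-identical genome and table
  cfg7 <- tiny_config(seed = 7)
  r1 <- make_reference(cfg7)
  r2 <- make_reference(cfg7)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$annotation, r2$annotation)

  expect_error(make_reference(tiny_config(genome_length = 9000)), ">= 10 kb")
  expect_error(
    make_reference(tiny_config(genome_length = 12000,
                               n_background_alus = 40)),
    "place")
})

test_that("annotated intervals realign to their source consensus", {
  ## realignment oracle: each placed copy must match its consensus at
  ## >= the identity implied by the configured divergence
  cfg <- tiny_config(seed = 5, genome_length = 100000,
                     n_background_alus = 20, divergence = 0.05)
  ref <- make_reference(cfg)
  expect_equal(nrow(ref$annotation), 20)
  expect_true(all(ref$annotation$start < ref$annotation$end))
  expect_true(all(ref$annotation$end <= cfg$genome_length))
  ## non-overlapping
  a <- ref$annotation[order(ref$annotation$start), ]
  expect_true(all(utils::head(a$end, -1) <= utils::tail(a$start, -1)))
  for (i in seq_len(nrow(a))) {
    obs <- substr(ref$genome[[1]], a$start[i] + 1, a$end[i])
    if (a$strand[i] == "-") obs <- rc_chr(obs)
    aln <- Biostrings::pairwiseAlignment(obs, ref$consensus[[a$family[i]]])
    expect_gte(Biostrings::pid(aln), 100 * (1 - 3 * cfg$divergence))
  }
})

test_that("TPRT insertions carry their hallmarks verbatim", {
  w <- tiny_world(seed = 2, n_novel_insertions = 6)
  tr <- w$sim$truth
  expect_equal(nrow(tr), 6)
  ## conservation: modified length = original + sum of inserted material
  added <- sum(tr$body_length + tr$polya_length + nchar(tr$tsd_seq))
  expect_equal(nchar(w$sim$genome_hap1[[1]]),
               nchar(w$ref$genome[[1]]) + added)
  hom <- tr$zygosity == "homozygous"
  added2 <- sum((tr$body_length + tr$polya_length +
                   nchar(tr$tsd_seq))[hom])
  expect_equal(nchar(w$sim$genome_hap2[[1]]),
               nchar(w$ref$genome[[1]]) + added2)
  ## TSD occurs verbatim 5' of the element and 3' of the tail
  g <- w$sim$genome_hap1[[1]]
  ann <- w$sim$annotation_hap1
  for (i in seq_len(nrow(tr))) {
    a <- ann[ann$locus_id == tr$locus_id[i], ]
    t <- nchar(tr$tsd_seq[i])
    expect_identical(substr(g, a$start - t + 1, a$start), tr$tsd_seq[i])
    tail_end <- a$end + tr$polya_length[i]
    expect_identical(substr(g, tail_end + 1, tail_end + t), tr$tsd_seq[i])
    ## the body derives from the named subfamily consensus
    body <- substr(g, a$start + 1, a$end)
    expect_identical(body, w$ref$consensus[[tr$subfamily[i]]])
  }
  ## nick-site model: 6-mer at TSD start - 2 within Hamming 1 of TTAAAA
  ref_g <- w$ref$genome[[1]]
  for (i in seq_len(nrow(tr))) {
    b0 <- tr$breakpoint[i] - nchar(tr$tsd_seq[i])
    hex <- substr(ref_g, b0 - 1, b0 + 4)
    d <- sum(strsplit(hex, "")[[1]] != strsplit("TTAAAA", "")[[1]])
    expect_lte(d, 1)
  }
})

test_that("fixed hallmark ranges are honoured; no truncation at prob 0", {
  w <- tiny_world(seed = 9, n_novel_insertions = 4,
                  tsd_length_range = c(12, 12),
                  polya_length_range = c(40, 40))
  expect_true(all(nchar(w$sim$truth$tsd_seq) == 12))
  expect_true(all(w$sim$truth$polya_length == 40))
  expect_true(all(w$sim$truth$truncated_5p == 0))
  expect_true(all(w$sim$truth$body_length ==
                    nchar(w$ref$consensus[w$sim$truth$subfamily])))
})

test_that("round-trip: hallmark recovery is exact for 50 events", {
  cfg <- tiny_config(seed = 21, genome_length = 400000,
                     n_background_alus = 0, n_novel_insertions = 50)
  ref <- make_reference(cfg)
  sim <- simulate_tprt_insertion(ref, cfg)
  tr <- sim$truth
  expect_equal(nrow(tr), 50)
  g <- sim$genome_hap1[[1]]
  ann <- sim$annotation_hap1
  for (i in seq_len(nrow(tr))) {
    a <- ann[ann$locus_id == tr$locus_id[i], ]
    ins_start <- a$start; ins_end <- a$end + tr$polya_length[i]
    lo <- max(0, ins_start - 100); hi <- min(nchar(g), ins_end + 100)
    ft <- annotate_features(substr(g, lo + 1, hi), ins_start - lo,
                            ins_end - lo, ref$consensus)
    expect_identical(ft$tsd_seq, tr$tsd_seq[i])
    expect_identical(ft$polya_len, tr$polya_length[i])
    expect_identical(ft$subfamily, tr$subfamily[i])
  }
})

test_that("assign_methylome covers every CpG with the right probability", {
  w <- tiny_world(seed = 3)
  g <- w$ref$genome
  ## uniform profile 1.0
  m1 <- assign_methylome(g, profile = list(default = 1.0))
  cpg <- gregexpr("CG", g[[1]], fixed = TRUE)[[1]] - 1L
  expect_equal(m1$pos, as.integer(cpg))
  expect_true(all(m1$prob == 1.0))
  ## island override to 0 over [a, b)
  m2 <- assign_methylome(g, profile = list(
    default = 1.0,
    overrides = list(list(chrom = "chr1", start = 1000, end = 3000,
                          level = 0))))
  inside <- m2$pos >= 1000 & m2$pos < 3000
  expect_true(all(m2$prob[inside] == 0))
  expect_true(all(m2$prob[!inside] == 1))
  ## element-level applies inside annotated repeats
  m3 <- assign_methylome(g, w$ref$annotation,
                         profile = list(default = 0.2,
                                        element_level = 0.9))
  a <- w$ref$annotation[1, ]
  in_elem <- m3$pos >= a$start & m3$pos < a$end
  expect_true(all(m3$prob[in_elem] == 0.9))
  ## out-of-bounds override errors
  expect_error(assign_methylome(g, profile = list(
    default = 1, overrides = list(list(chrom = "chr1", start = -5,
                                       end = 10, level = 0)))),
    "bounds")
})

test_that("simulated reads honour the bisulfite chemistry", {
  ## conversion_rate 1, all-unmethylated: no C anywhere in the reads
  w <- tiny_world(seed = 4, methylation_profile = list(
    default = 0, element_level = 0, overrides = NULL))
  rd <- simulate_reads(w$sim, w$cfg)
  expect_false(any(grepl("C", rd$reads$seq, fixed = TRUE)))

  ## error 0, conversion 1, all-methylated: CpG Cs retained, others T
  w2 <- tiny_world(seed = 4, methylation_profile = list(
    default = 1, element_level = 1, overrides = NULL))
  ## frozen truth states are drawn at element_level = 1 so every CpG of
  ## every molecule retains its C; verify against the source haplotype
  rd2 <- simulate_reads(w2$sim, w2$cfg)
  tr <- rd2$truth
  g <- list(hap1 = w2$sim$genome_hap1[[1]], hap2 = w2$sim$genome_hap2[[1]])
  for (i in sample(nrow(tr), 10)) {
    src <- substr(g[[tr$hap[i]]], tr$region_start[i] + 1, tr$region_end[i])
    if (tr$strand[i] == "-") src <- rc_chr(src)
    read <- rd2$reads$seq[rd2$reads$read_id == tr$read_id[i]]
    v_src <- strsplit(src, "")[[1]]; v_read <- strsplit(read, "")[[1]]
    is_c <- v_src == "C"
    nxt <- c(v_src[-1], "N"); is_cpg <- is_c & nxt == "G"
    expect_true(all(v_read[is_cpg] == "C"))
    expect_true(all(v_read[is_c & !is_cpg] == "T"))
    expect_true(all(v_read[!is_c] == v_src[!is_c]))
  }
})

test_that("read simulation is deterministic and conserves truth rows", {
  w <- tiny_world(seed = 6, n_background_alus = 10,
                  n_novel_insertions = 10, reads_per_locus = 10)
  r1 <- simulate_reads(w$sim, w$cfg)
  r2 <- simulate_reads(w$sim, w$cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  expect_gte(nrow(r1$reads), 190)
  expect_equal(nrow(r1$reads), nrow(r1$truth))
  ## FASTQ round trip preserves record count and sequences
  fq <- tempfile(fileext = ".fastq")
  write_fastq(r1$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, r1$reads$seq)
  expect_equal(back$read_id, r1$reads$read_id)
})

test_that("hemizygous loci draw reads from the carrier haplotype only", {
  w <- tiny_world(seed = 8, n_novel_insertions = 8, reads_per_locus = 6)
  rd <- simulate_reads(w$sim, w$cfg)
  hemi <- w$sim$truth$locus_id[w$sim$truth$zygosity == "hemizygous"]
  skip_if(length(hemi) == 0)
  expect_true(all(rd$truth$hap[rd$truth$locus_id %in% hemi] == "hap1"))
})
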