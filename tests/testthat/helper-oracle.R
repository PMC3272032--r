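## Brute-force mapping oracle: scores EVERY offset of every flank on both
## reduced spaces, then applies the cycle semantics. Shares no code with
## map_iterative (mismatch counts come from Biostrings::neditStartingAt,
## exact-run lengths from rle on a per-offset match vector).

brute_force_map <- function(flanks, genome, schedule = cycle_schedule(),
                            margin = 5) {
  stopifnot(length(genome) == 1)
  chrom <- names(genome)
  spaces <- list(CT = chartr("C", "T", genome[[1]]),
                 GA = chartr("G", "A", genome[[1]]))
  subj <- lapply(spaces, Biostrings::DNAString)
  subj_vec <- lapply(spaces, function(s) strsplit(s, "")[[1]])
  glen <- nchar(genome[[1]])
  n_cycles <- length(schedule$word_sizes)
  w_min <- min(schedule$word_sizes)

  ## identity needed by any non-last cycle
  min_cut <- min(utils::head(schedule$identity_cutoffs, -1))

  out <- lapply(seq_len(nrow(flanks)), function(i) {
    fl <- toupper(flanks$flank_seq[i])
    L <- nchar(fl)
    pats <- c(CT = chartr("C", "T", fl),
              GA = chartr("G", "A", rc_chr(fl)))
    ## per-offset mismatch counts, both spaces
    cand <- list()
    for (sp in c("CT", "GA")) {
      starts <- seq_len(glen - L + 1L)
      mm <- Biostrings::neditStartingAt(
        Biostrings::DNAString(pats[[sp]]), subj[[sp]],
        starting.at = starts, with.indels = FALSE)
      ## candidate offsets: either close to the whole-flank identity
      ## cutoff, or carrying a perfect run >= w_min. Any w_min-long run
      ## contains a complete aligned block of the floor(w_min/2)-tiling,
      ## so exact block matches give a conservative superset.
      keep <- which(mm <= floor(L * (1 - min_cut)))
      blk <- floor(w_min / 2)
      if (!grepl("N", pats[[sp]], fixed = TRUE)) {
        for (b0 in unique(c(seq(1L, L - blk + 1L, by = blk),
                            L - blk + 1L))) {
          hits <- Biostrings::start(Biostrings::matchPattern(
            substr(pats[[sp]], b0, b0 + blk - 1L), subj[[sp]]))
          keep <- union(keep, hits - (b0 - 1L))
        }
      }
      keep <- sort(keep[keep >= 1L & keep <= glen - L + 1L])
      pv <- strsplit(pats[[sp]], "")[[1]]
      for (k in keep) {
        sv <- subj_vec[[sp]][k:(k + L - 1L)]
        r <- rle(pv == sv)
        runs <- r$lengths[r$values]
        max_run <- if (length(runs)) max(runs) else 0L
        ## 0-based start of the first maximal run
        ends <- cumsum(r$lengths)
        starts_r <- ends - r$lengths + 1L
        tpos <- which(r$values & r$lengths == max_run)[1]
        cand[[length(cand) + 1L]] <- data.frame(
          space = sp, d = k - 1L, mm = mm[k], max_run = max_run,
          run_start = if (is.na(tpos)) NA_integer_ else starts_r[tpos],
          run_end = if (is.na(tpos)) NA_integer_ else ends[tpos],
          stringsAsFactors = FALSE)
      }
    }
    cand <- if (length(cand)) do.call(rbind, cand) else NULL
    res <- list(read_id = flanks$read_id[i], status = "unmapped",
                chrom = NA, start = NA, end = NA, space = NA,
                cycle = NA, score = NA)
    if (is.null(cand)) return(res)
    for (ci in seq_len(n_cycles)) {
      w <- schedule$word_sizes[ci]
      if (L < w) next
      last <- ci == n_cycles
      if (last) {
        acc <- cand[cand$max_run >= w, , drop = FALSE]
        if (nrow(acc) == 0) next
        acc$score <- acc$max_run
        acc$start <- acc$d + acc$run_start - 1L
        acc$end <- acc$d + acc$run_end
      } else {
        ok <- cand$max_run >= w & (L - cand$mm) / L >=
          schedule$identity_cutoffs[ci]
        acc <- cand[ok, , drop = FALSE]
        if (nrow(acc) == 0) next
        acc$score <- L - 2 * acc$mm
        acc$start <- acc$d
        acc$end <- acc$d + L
      }
      s <- sort(acc$score, decreasing = TRUE)
      res$status <- if (nrow(acc) == 1 ||
                        s[1] - s[2] >= margin) "unique" else "ambiguous"
      b <- acc[order(-acc$score, acc$start, acc$space), , drop = FALSE][1, ]
      res$chrom <- chrom; res$start <- b$start; res$end <- b$end
      res$space <- b$space; res$cycle <- ci; res$score <- b$score
      return(res)
    }
    res
  })
  do.call(rbind, lapply(out, as.data.frame))
}

## generate one oracle-test instance: genome plus a mix of mappable,
## mutated, reverse-strand, duplicated-segment and random flanks
make_oracle_instance <- function(seed, genome_len = NULL, n_flanks = 15) {
  set.seed(seed)
  if (is.null(genome_len)) genome_len <- sample(3000:20000, 1)
  g <- random_seq(genome_len)
  ## plant a duplicated segment so ambiguity actually occurs
  dup_len <- 400
  src <- sample(genome_len - 3 * dup_len, 1)
  dst <- src + dup_len + sample(500:1000, 1)
  seg <- substr(g, src, src + dup_len - 1)
  g <- paste0(substr(g, 1, dst - 1), seg,
              substr(g, dst + dup_len, genome_len))
  g <- substr(g, 1, genome_len)
  flanks <- lapply(seq_len(n_flanks), function(i) {
    L <- sample(45:200, 1)
    kind <- sample(c("exact", "mutated", "reverse", "dup", "random"), 1)
    if (kind == "random") {
      fl <- random_seq(L)
    } else {
      s <- if (kind == "dup") src + sample(0:(dup_len - L), 1) else
        sample(nchar(g) - L, 1)
      fl <- substr(g, s, s + L - 1)
      if (kind == "mutated") {
        v <- strsplit(fl, "")[[1]]
        for (p in sample(L, sample(0:3, 1)))
          v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
        fl <- paste(v, collapse = "")
      }
      if (kind == "reverse") fl <- rc_chr(fl)
    }
    data.frame(read_id = sprintf("f%02d", i), flank_seq = fl,
               stringsAsFactors = FALSE)
  })
  list(genome = c(chr1 = g), flanks = do.call(rbind, flanks))
}
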