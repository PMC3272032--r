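## -------------------------------------------------------------------------
## Bisulfite mapper: multi-cycle decreasing-word-size seed-and-extend
## against the converted reference, with the unambiguity requirement.
##
## Matching is done in fully reduced space: the read flank is C->T reduced
## and searched forward against the CT reference; its reverse complement is
## G->A reduced and searched against the GA reference. This makes every
## conversion-consistent difference (read T over a reference C) an exact
## match by construction.
## -------------------------------------------------------------------------

#' Mapping cycle schedule
#'
#' Word sizes start at 100 and decrease by 20 per cycle down to 40; the
#' identity cutoff is 0.95 for all cycles but the last, for which
#' acceptance instead requires a best perfect match of at least the last
#' word size (reported with identity 1.00).
#'
#' @param word_sizes strictly decreasing seed lengths.
#' @param identity_cutoffs per-cycle identity fractions in (0,1].
#' @return validated list of class `cycle_schedule`.
#' @export
cycle_schedule <- function(word_sizes = c(100L, 80L, 60L, 40L),
                           identity_cutoffs = c(0.95, 0.95, 0.95, 1.00)) {
  if (length(word_sizes) != length(identity_cutoffs))
    stop("word_sizes and identity_cutoffs must have equal length",
         call. = FALSE)
  if (any(diff(word_sizes) >= 0))
    stop("word sizes must be strictly decreasing", call. = FALSE)
  if (any(identity_cutoffs <= 0 | identity_cutoffs > 1))
    stop("identity cutoffs must lie in (0,1]", call. = FALSE)
  structure(list(word_sizes = as.integer(word_sizes),
                 identity_cutoffs = identity_cutoffs,
                 last_cycle_mode = "min_length_best_perfect_match"),
            class = "cycle_schedule")
}

#' Build an exact k-mer seed index over one reduced-space genome
#'
#' @param sequences named character vector (one space, e.g. the CT space).
#' @param word_size seed length (>= 8).
#' @return `data.table` keyed by `kmer` with columns `kmer, chrom, pos`
#'   (0-based); k-mers containing N are excluded.
#' @export
build_index <- function(sequences, word_size) {
  if (word_size < 8L) stop("word_size must be >= 8", call. = FALSE)
  parts <- list()
  for (chrom in names(sequences)) {
    L <- nchar(sequences[[chrom]])
    if (word_size > L) {
      warning(sprintf("word size %d exceeds length of %s; chromosome %s",
                      word_size, chrom, "not indexed"), call. = FALSE)
      next
    }
    starts <- seq_len(L - word_size + 1L)
    kmers <- substring(sequences[[chrom]], starts, starts + word_size - 1L)
    parts[[chrom]] <- data.table::data.table(
      kmer = kmers, chrom = chrom, pos = starts - 1L)
  }
  idx <- if (length(parts)) data.table::rbindlist(parts) else
    data.table::data.table(kmer = character(0), chrom = character(0),
                           pos = integer(0))
  idx <- idx[!grepl("N", kmer, fixed = TRUE)]
  data.table::setkey(idx, kmer)
  idx
}

## longest exact-match run and mismatch positions of an ungapped placement
diagonal_runs <- function(pat_vec, sub_vec) {
  mmpos <- which(pat_vec != sub_vec)
  L <- length(pat_vec)
  bounds <- c(0L, mmpos, L + 1L)
  runs <- diff(bounds) - 1L
  k <- which.max(runs)
  list(mmpos = mmpos, max_run = runs[k],
       run_start = bounds[k] + 1L, run_end = bounds[k + 1L] - 1L)
}

#' Decide mapping uniqueness from accepted alignment scores
#'
#' A read maps uniquely when it has a single accepted alignment or when
#' the best score exceeds the second best by at least `margin`; exact
#' score ties are ambiguous.
#'
#' @param scores numeric vector of accepted alignment scores.
#' @param margin score-unit margin (default 5).
#' @return `"unique"` or `"ambiguous"`.
#' @export
assess_ambiguity <- function(scores, margin = 5) {
  stopifnot(length(scores) >= 1)
  if (length(scores) == 1) return("unique")
  s <- sort(scores, decreasing = TRUE)
  if (s[1] - s[2] >= margin) "unique" else "ambiguous"
}

#' Iteratively map extracted flanks to the converted reference
#'
#' Cycle `i` considers only reads not yet resolved: a candidate locus
#' needs an exact seed of `word_sizes[i]`, is extended ungapped along its
#' diagonal, and is accepted when the whole-flank identity reaches the
#' cycle cutoff. The last cycle instead accepts a locus whose best
#' perfect match spans at least the last word size, reporting that
#' perfect segment. Resolved reads (unique or ambiguous) leave the pool;
#' the remainder are unmapped.
#'
#' @param flanks data.frame with `read_id`, `flank_seq` and optionally
#'   `library_id`.
#' @param conv_ref a [convert_reference()] result.
#' @param schedule a [cycle_schedule()].
#' @param margin ambiguity score margin (see [assess_ambiguity()]).
#' @return data.frame with one row per read: `read_id, status, chrom,
#'   start, end, space, identity, aligned_length, cycle, score,
#'   n_accepted, library_id`; coordinates 0-based half-open, `space` is
#'   `"CT"` (forward) or `"GA"` (reverse).
#' @export
map_iterative <- function(flanks, conv_ref, schedule = cycle_schedule(),
                          margin = 5) {
  stopifnot(inherits(conv_ref, "converted_reference"))
  if (nrow(flanks) == 0) stop("no flanks to map", call. = FALSE)
  n <- nrow(flanks)
  pats <- list(
    CT = ct_space(toupper(flanks$flank_seq)),
    GA = ga_space(revcomp(toupper(flanks$flank_seq))))
  spaces <- list(CT = conv_ref$ct, GA = conv_ref$ga)
  sub_vecs <- lapply(spaces, function(sp)
    lapply(sp, function(s) strsplit(s, "", fixed = TRUE)[[1]]))
  pat_vecs <- lapply(pats, function(p) strsplit(p, "", fixed = TRUE))

  res <- data.frame(read_id = flanks$read_id, status = "unmapped",
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, space = NA_character_,
                    identity = NA_real_, aligned_length = NA_integer_,
                    cycle = NA_integer_, score = NA_real_,
                    n_accepted = 0L,
                    library_id = if ("library_id" %in% names(flanks))
                      flanks$library_id else NA_character_,
                    stringsAsFactors = FALSE)
  unresolved <- rep(TRUE, n)
  n_cycles <- length(schedule$word_sizes)

  for (ci in seq_len(n_cycles)) {
    w <- schedule$word_sizes[ci]
    cutoff <- schedule$identity_cutoffs[ci]
    last <- ci == n_cycles
    active <- which(unresolved & nchar(flanks$flank_seq) >= w)
    if (length(active) == 0) next

    cands <- list()
    for (sp_name in c("CT", "GA")) {
      idx <- build_index(spaces[[sp_name]], w)
      if (nrow(idx) == 0) next
      ## gather all seed k-mers of active reads
      seed_tabs <- lapply(active, function(r) {
        L <- nchar(pats[[sp_name]][r])
        offs <- seq_len(L - w + 1L)
        data.table::data.table(
          r = r, off = offs,
          kmer = substring(pats[[sp_name]][r], offs, offs + w - 1L))
      })
      seeds <- data.table::rbindlist(seed_tabs)
      seeds <- seeds[!grepl("N", kmer, fixed = TRUE)]
      if (nrow(seeds) == 0) next
      hits <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hits) == 0) next
      hits[, diag_start := pos - (off - 1L)]
      cand <- unique(hits[, .(r, chrom, diag_start)])
      ## clip candidates whose full-flank placement leaves the chromosome
      cand <- cand[diag_start >= 0L]
      lens <- conv_ref$lengths[cand$chrom]
      Lr <- nchar(flanks$flank_seq)[cand$r]
      cand <- cand[diag_start + Lr <= lens]
      if (nrow(cand) == 0) next
      cand[, space := sp_name]
      cands[[sp_name]] <- cand
    }
    if (length(cands) == 0) next
    cand_all <- as.data.frame(data.table::rbindlist(cands,
                                                    use.names = TRUE))
    if (nrow(cand_all) == 0) next

    ## evaluate candidates read by read
    for (r in unique(cand_all$r)) {
      rc <- cand_all[cand_all$r == r, , drop = FALSE]
      L <- nchar(flanks$flank_seq[r])
      acc <- list()
      for (k in seq_len(nrow(rc))) {
        sp <- rc$space[k]; chrom <- rc$chrom[k]; d <- rc$diag_start[k]
        pv <- pat_vecs[[sp]][[r]]
        sv <- sub_vecs[[sp]][[chrom]][(d + 1L):(d + L)]
        mm <- sum(pv != sv)
        if (!last) {
          identity <- (L - mm) / L
          if (identity >= cutoff) {
            acc[[length(acc) + 1L]] <- data.frame(
              chrom = chrom, start = d, end = d + L, space = sp,
              identity = identity, aligned_length = L,
              score = L - 2 * mm, stringsAsFactors = FALSE)
          }
        } else {
          if (L - mm < w) next      # cannot contain a w-long perfect run
          dr <- diagonal_runs(pv, sv)
          if (dr$max_run >= w) {
            acc[[length(acc) + 1L]] <- data.frame(
              chrom = chrom, start = d + dr$run_start - 1L,
              end = d + dr$run_end, space = sp,
              identity = 1.0, aligned_length = dr$max_run,
              score = dr$max_run, stringsAsFactors = FALSE)
          }
        }
      }
      if (length(acc) == 0) next
      acc <- do.call(rbind, acc)
      acc <- acc[order(-acc$score, acc$chrom, acc$start, acc$space), ,
                 drop = FALSE]
      status <- assess_ambiguity(acc$score, margin)
      res[r, c("status", "chrom", "space")] <-
        list(status, acc$chrom[1], acc$space[1])
      res[r, c("start", "end", "aligned_length", "cycle")] <-
        list(acc$start[1], acc$end[1], acc$aligned_length[1], ci)
      res[r, c("identity", "score")] <- list(acc$identity[1], acc$score[1])
      res[r, "n_accepted"] <- nrow(acc)
      unresolved[r] <- FALSE
    }
  }
  res
}

#' Write a mapping table to TSV
#' @param mapping result of [map_iterative()].
#' @param path output path.
#' @export
write_mapping <- function(mapping, path) {
  write.table(mapping, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
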