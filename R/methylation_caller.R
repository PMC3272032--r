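## -------------------------------------------------------------------------
## Methylation caller: per-read per-CpG calls from bisulfite reads against
## the unconverted local reference, region summaries (A/B boxes, arms,
## flanks) and hemizygous allele comparison.
##
## Calling convention: at a reference CpG cytosine a retained C in the
## read means methylated, a T means unmethylated (bisulfite deaminates
## only unmethylated cytosines); anything else, or an indel over the CpG,
## is uncallable and excluded from denominators.
## -------------------------------------------------------------------------

#' Call per-CpG methylation states for one read
#'
#' The read is aligned to the local reference in CT space (so conversion
#' never penalizes the alignment), then original bases are compared at
#' every covered reference CpG cytosine. The fraction of non-CpG
#' reference cytosines read as T is returned as a conversion QC measure;
#' reads below `qc_threshold` are flagged (not dropped).
#'
#' @param read character; one read (bisulfite space, plus strand).
#' @param local_ref unconverted local reference sequence.
#' @param read_id identifier carried into the output.
#' @param qc_threshold minimum conversion fraction before flagging.
#' @return data.frame `read_id, position, state, context` (positions
#'   0-based in `local_ref`; state `methylated`, `unmethylated` or
#'   `uncallable`), with attributes `conversion_qc` and `flagged`.
#' @export
call_cpg_states <- function(read, local_ref, read_id = "read",
                            qc_threshold = 0.98) {
  cpg <- find_cpg_sites(local_ref)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ct_space(read)),
    subject = Biostrings::DNAString(ct_space(local_ref)),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  rvec <- strsplit(read, "", fixed = TRUE)[[1]]
  ref_i <- Biostrings::start(Biostrings::subject(aln))   # 1-based
  read_i <- 1L
  pos <- integer(0); state <- character(0)
  n_conv <- 0L; n_unconv <- 0L
  for (k in seq_along(pat)) {
    p <- pat[k]; s <- sub[k]
    if (s != "-") {
      ref0 <- ref_i - 1L                                  # 0-based
      ref_base <- substr(local_ref, ref_i, ref_i)
      if (ref_base == "C") {
        is_cpg <- ref0 %in% cpg
        rb <- if (p == "-") "-" else rvec[read_i]
        if (is_cpg) {
          st <- if (identical(rb, "C")) "methylated" else
            if (identical(rb, "T")) "unmethylated" else "uncallable"
          pos <- c(pos, ref0); state <- c(state, st)
        } else {
          if (identical(rb, "T")) n_conv <- n_conv + 1L
          else if (identical(rb, "C")) n_unconv <- n_unconv + 1L
        }
      }
      ref_i <- ref_i + 1L
    }
    if (p != "-") read_i <- read_i + 1L
  }
  qc <- if (n_conv + n_unconv > 0) n_conv / (n_conv + n_unconv) else
    NA_real_
  out <- data.frame(read_id = read_id, position = pos, state = state,
                    context = "CpG", stringsAsFactors = FALSE)
  attr(out, "conversion_qc") <- qc
  attr(out, "flagged") <- !is.na(qc) && qc < qc_threshold
  out
}

#' Call CpG states for a set of reads
#'
#' @param reads data.frame with `read_id` and `seq`.
#' @inheritParams call_cpg_states
#' @return list `calls` (row-bound per-read calls) and `qc`
#'   (data.frame `read_id, conversion_qc, flagged`).
#' @export
call_cpg_states_batch <- function(reads, local_ref, qc_threshold = 0.98) {
  calls <- list(); qc <- list()
  for (i in seq_len(nrow(reads))) {
    cc <- call_cpg_states(reads$seq[i], local_ref, reads$read_id[i],
                          qc_threshold)
    calls[[i]] <- cc
    qc[[i]] <- data.frame(read_id = reads$read_id[i],
                          conversion_qc = attr(cc, "conversion_qc"),
                          flagged = attr(cc, "flagged"),
                          stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       qc = do.call(rbind, c(qc, list(make.row.names = FALSE))))
}

#' Canonical Alu region definitions
#'
#' A and B boxes sit 5-16 bp and 75-84 bp from the element 5' terminus
#' (1-based); arms are split at the internal A-rich linker.
#'
#' @param element_start 0-based element start in the local reference.
#' @param element_length element body length (bp).
#' @param linker 0-based half-open linker span in element coordinates.
#' @return data.frame `name, start, end` (0-based half-open, local
#'   reference coordinates).
#' @export
alu_regions <- function(element_start, element_length,
                        linker = c(130L, 135L)) {
  data.frame(
    name = c("whole_element", "A_box", "B_box", "left_arm", "right_arm"),
    start = element_start + c(0L, 4L, 74L, 0L, linker[2]),
    end = element_start + c(element_length, 16L, 84L, linker[1],
                            element_length),
    stringsAsFactors = FALSE)
}

#' Summarize methylation calls by region
#'
#' @param calls data.frame of CpG calls (see [call_cpg_states()]).
#' @param regions data.frame `name, start, end` (0-based half-open).
#' @return data.frame `region, n_calls, n_methylated, n_unmethylated,
#'   level` (percent; `NA` when a region covers no callable CpG), with
#'   attribute `"lollipop"`: a reads x CpG-positions character matrix
#'   (`"M"`, `"U"`, `"."`).
#' @export
summarize_methylation <- function(calls, regions) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    m <- calls[calls$position >= regions$start[i] &
                 calls$position < regions$end[i], , drop = FALSE]
    nm <- sum(m$state == "methylated")
    nu <- sum(m$state == "unmethylated")
    data.frame(region = regions$name[i], n_calls = nrow(m),
               n_methylated = nm, n_unmethylated = nu,
               level = if (nm + nu > 0) 100 * nm / (nm + nu) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  upos <- sort(unique(calls$position))
  urd <- unique(calls$read_id)
  lolli <- matrix(".", nrow = length(urd), ncol = length(upos),
                  dimnames = list(urd, as.character(upos)))
  code <- c(methylated = "M", unmethylated = "U", uncallable = ".")
  if (nrow(calls))
    lolli[cbind(match(calls$read_id, urd),
                match(calls$position, upos))] <- code[calls$state]
  attr(out, "lollipop") <- lolli
  out
}

#' Compare methylation between hemizygous alleles
#'
#' For every CpG position covered on both alleles (reads are assigned to
#' the with-insertion or without-insertion allele by junction presence),
#' reports per-allele levels and the level difference with a two-sample
#' binomial confidence interval; a pooled `all` row aggregates the
#' shared positions.
#'
#' @param calls data.frame of CpG calls (from the shared flank
#'   coordinates of both alleles).
#' @param assignments data.frame `read_id, allele` with allele labels
#'   `"with"` and `"without"`.
#' @param conf_level confidence level for the interval.
#' @return data.frame `position, n_with, n_without, level_with,
#'   level_without, diff, ci_lo, ci_hi`; allele sides without reads are
#'   `NA`.
#' @export
compare_alleles <- function(calls, assignments, conf_level = 0.95) {
  al <- setNames(assignments$allele, assignments$read_id)
  calls$allele <- al[calls$read_id]
  callable <- calls[calls$state %in% c("methylated", "unmethylated"), ,
                    drop = FALSE]
  one <- function(sub, position) {
    w <- sub[sub$allele == "with", , drop = FALSE]
    o <- sub[sub$allele == "without", , drop = FALSE]
    nw <- nrow(w); no <- nrow(o)
    mw <- sum(w$state == "methylated"); mo <- sum(o$state == "methylated")
    lw <- if (nw > 0) 100 * mw / nw else NA_real_
    lo <- if (no > 0) 100 * mo / no else NA_real_
    ci <- c(NA_real_, NA_real_)
    if (nw > 0 && no > 0) {
      pt <- suppressWarnings(
        prop.test(c(mw, mo), c(nw, no), conf.level = conf_level))
      ci <- 100 * pt$conf.int
    }
    data.frame(position = position, n_with = nw, n_without = no,
               level_with = lw, level_without = lo,
               diff = lw - lo, ci_lo = ci[1], ci_hi = ci[2],
               stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(callable$position)), function(p)
    one(callable[callable$position == p, , drop = FALSE], p))
  rows[[length(rows) + 1L]] <- one(callable, NA_integer_)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$region <- c(rep("cpg", nrow(out) - 1L), "all")
  out
}

#' Locate the CpG dinucleotides flanking an insertion
#'
#' The nearest CpG 5' of the first TSD copy and the nearest CpG 3' of
#' the second TSD copy in the local (insertion-carrying) reference.
#'
#' @param local_ref insertion-carrying local reference sequence.
#' @param tsd1_start,tsd2_end 0-based coordinates of the first TSD
#'   copy's start and the second TSD copy's end in `local_ref`.
#' @return list `flank_5p` and `flank_3p` (0-based CpG C positions, `NA`
#'   when absent).
#' @export
flanking_cpgs <- function(local_ref, tsd1_start, tsd2_end) {
  cpg <- find_cpg_sites(local_ref)
  up <- cpg[cpg + 1L < tsd1_start]
  dn <- cpg[cpg > tsd2_end]
  list(flank_5p = if (length(up)) max(up) else NA_integer_,
       flank_3p = if (length(dn)) min(dn) else NA_integer_)
}
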