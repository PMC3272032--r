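## -------------------------------------------------------------------------
## Feature annotator: TPRT hallmarks of an insertion allele — target site
## duplication, endonuclease cleavage motif, poly-A tail, and AluY
## subfamily classification.
## -------------------------------------------------------------------------

#' Detect the target site duplication at an insertion
#'
#' Returns the longest exact string that is simultaneously a suffix of
#' the upstream flank (searched within `max_scan` nt of the junction) and
#' a prefix of the sequence immediately downstream of the poly-A tail.
#' TSD matching is exact: observed TSDs are perfect direct repeats.
#'
#' @param upstream_flank sequence ending at the element 5' junction
#'   (its suffix is the first TSD copy).
#' @param downstream_after_tail sequence starting immediately after the
#'   poly-A tail (its prefix is the second TSD copy).
#' @param min_len minimum credible TSD length (nt).
#' @param max_scan maximum TSD length scanned (nt).
#' @return the TSD string, or `""` when no shared repeat of at least
#'   `min_len` nt exists.
#' @export
detect_tsd <- function(upstream_flank, downstream_after_tail,
                       min_len = 4L, max_scan = 25L) {
  lu <- nchar(upstream_flank); ld <- nchar(downstream_after_tail)
  kmax <- min(max_scan, lu, ld)
  if (kmax < min_len) return("")
  for (k in seq.int(kmax, min_len)) {
    if (substr(upstream_flank, lu - k + 1L, lu) ==
        substr(downstream_after_tail, 1L, k))
      return(substr(downstream_after_tail, 1L, k))
  }
  ""
}

#' Locate the ORF2P cleavage-site motif near the junction
#'
#' Scans the 6-mers whose start lies within `window` nt of the junction
#' (the end of `upstream_flank`, which includes the first TSD copy, so
#' the motif may overlap the TSD) for the best match to the degenerate
#' endonuclease consensus `TTAAAA`. Ties are broken by proximity to the
#' junction. An imperfect motif does not fail the locus; sites with more
#' than `max_mismatch` mismatches are merely flagged.
#'
#' @param upstream_flank sequence ending at the element 5' junction.
#' @param window number of trailing 6-mer start positions scanned.
#' @param max_mismatch mismatches tolerated before flagging.
#' @return list `site` (best 6-mer), `mismatches`, `offset` (0-based
#'   distance of the motif start from the junction, counted backwards)
#'   and `credible` (`mismatches <= max_mismatch`).
#' @export
find_cleavage_site <- function(upstream_flank, window = 20L,
                               max_mismatch = 1L) {
  L <- nchar(upstream_flank)
  if (L < 6L) stop("flank shorter than the 6-mer motif", call. = FALSE)
  starts <- seq.int(max(1L, L - 5L - window + 1L), L - 5L)
  best <- NULL
  for (s in starts) {     # later (junction-proximal) sites win ties
    hex <- substr(upstream_flank, s, s + 5L)
    mm <- hamming(hex, "TTAAAA")
    if (is.null(best) || mm <= best$mismatches)
      best <- list(site = hex, mismatches = mm, offset = L - 5L - s)
  }
  best$credible <- best$mismatches <= max_mismatch
  best
}

#' Measure the poly-A tail of an insertion
#'
#' The tail region is the sequence between the element 3' terminus and
#' the downstream TSD copy. After stripping the leading non-A prefix
#' (an element-terminal remnant such as `CTC...`), the poly-A length is
#' the uninterrupted A-run found there; the full tail-region length is
#' reported separately since A-rich tails may carry interruptions.
#'
#' @param tail_region the tail sequence.
#' @return list `polya_len` and `tail_len`.
#' @export
measure_polya <- function(tail_region) {
  if (is.na(tail_region) || nchar(tail_region) == 0)
    return(list(polya_len = 0L, tail_len = 0L))
  first_a <- regexpr("A", tail_region, fixed = TRUE)
  if (first_a == -1L)
    return(list(polya_len = 0L, tail_len = nchar(tail_region)))
  run <- attr(regexpr("^A+", substr(tail_region, first_a,
                                    nchar(tail_region))), "match.length")
  list(polya_len = as.integer(run), tail_len = nchar(tail_region))
}

#' Classify an Alu sequence into its subfamily
#'
#' Aligns the query globally against every consensus (local in the
#' consensus, so 5'-truncated elements still anchor) and returns the
#' best-scoring subfamily with its identity. Score ties are broken in
#' favour of the more derived (younger) subfamily, in the fixed order
#' AluYb9 > AluYb8 > AluYa5 > AluYg6 > AluY.
#'
#' @param alu_seq the element body sequence (unconverted space).
#' @param consensus_set named character vector of consensus sequences.
#' @return list `subfamily`, `identity` (fraction in `[0,1]`), `score`
#'   and `low_confidence` (`TRUE` when the query is shorter than 50 nt).
#' @export
classify_subfamily <- function(alu_seq, consensus_set) {
  if (length(consensus_set) == 0)
    stop("empty consensus set", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  scores <- numeric(length(consensus_set))
  pids <- numeric(length(consensus_set))
  for (i in seq_along(consensus_set)) {
    a <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(alu_seq),
      subject = Biostrings::DNAString(consensus_set[[i]]),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    scores[i] <- Biostrings::score(a)
    pids[i] <- Biostrings::pid(a) / 100
  }
  ord <- match(names(consensus_set), SUBFAMILY_ORDER)
  ord[is.na(ord)] <- length(SUBFAMILY_ORDER) + 1L
  pick <- order(-scores, ord)[1]
  list(subfamily = names(consensus_set)[pick],
       identity = pids[pick], score = scores[pick],
       low_confidence = nchar(alu_seq) < 50L)
}

#' Annotate the TPRT hallmarks of one insertion allele
#'
#' Convenience wrapper running [detect_tsd()], [find_cleavage_site()],
#' [measure_polya()] and [classify_subfamily()] on an allele sequence
#' with known insert boundaries (from simulation truth or a verified
#' locus annotation).
#'
#' @param locus_seq the full allele sequence (flank + insert + flank).
#' @param insert_start,insert_end 0-based half-open span of the inserted
#'   material (element body + poly-A tail) within `locus_seq`.
#' @param consensus_set subfamily consensus set.
#' @param tail_search_len bp at the insert 3' end searched for the tail.
#' @return list with `tsd_seq, tsd_len, cleavage_site, polya_len,
#'   polya_region, subfamily, subfamily_identity`.
#' @export
annotate_features <- function(locus_seq, insert_start, insert_end,
                              consensus_set,
                              tail_search_len = 60L) {
  upstream <- substr0(locus_seq, 0L, insert_start)
  insert <- substr0(locus_seq, insert_start, insert_end)
  downstream <- substr0(locus_seq, insert_end, nchar(locus_seq))
  ## split insert into body and trailing poly-A tail
  tail_m <- regexpr("A+$", insert)
  if (tail_m == -1L) {
    body <- insert; tail_region <- ""
  } else {
    body <- substr(insert, 1L, tail_m - 1L)
    tail_region <- substr(insert, tail_m, nchar(insert))
  }
  tsd <- detect_tsd(upstream, downstream)
  cleav <- find_cleavage_site(upstream)
  pa <- measure_polya(tail_region)
  cls <- classify_subfamily(body, consensus_set)
  list(tsd_seq = tsd, tsd_len = nchar(tsd),
       cleavage_site = cleav$site,
       cleavage_mismatches = cleav$mismatches,
       polya_len = pa$polya_len, polya_region = tail_region,
       subfamily = cls$subfamily,
       subfamily_identity = cls$identity,
       low_confidence = cls$low_confidence)
}
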