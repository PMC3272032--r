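## -------------------------------------------------------------------------
## Reference preparation: in-silico bisulfite conversion, repeat/gene/known
## annotation loading, and Alu masking / 5' flank extraction from reads.
## -------------------------------------------------------------------------

#' In-silico bisulfite conversion of a reference genome
#'
#' Builds both reduced-alphabet spaces: the CT space (every C replaced by
#' T; where plus-strand-derived converted reads map) and the GA space
#' (every G replaced by A; where reverse-complemented reads map). N is
#' preserved. The original sequence is retained so every converted
#' position remains identifiable.
#'
#' @param genome named character vector of A/C/G/T/N chromosome sequences.
#' @return object of class `converted_reference` with elements `ct`,
#'   `ga`, `source` (named character vectors) and `lengths`.
#' @export
convert_reference <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome must be a named vector of chromosome sequences",
         call. = FALSE)
  for (chrom in names(genome))
    check_dna_alphabet(genome[[chrom]], chrom)
  structure(list(ct = vapply(genome, ct_space, character(1)),
                 ga = vapply(genome, ga_space, character(1)),
                 source = genome,
                 lengths = vapply(genome, nchar, integer(1))),
            class = "converted_reference")
}

#' Load a repeat annotation table
#'
#' Reads either BED (`chrom start end name [score strand]`, 0-based
#' half-open, name = repeat family) or a RepeatMasker-style TSV whose
#' columns include `genoName, genoStart, genoEnd, strand, repName`
#' (1-based inclusive start, as in RepeatMasker `.out`-derived tables).
#'
#' @param path annotation file.
#' @param format `"bed"` or `"repeatmasker"`.
#' @return data.frame `chrom,start,end,family,strand` (0-based half-open),
#'   sorted by coordinate, of class `alu_annotation`.
#' @export
load_annotations <- function(path, format = c("bed", "repeatmasker")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(structure(empty, class =
                                             c("alu_annotation",
                                               "data.frame")))
  parse_line <- function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (format == "bed") {
      if (length(f) < 4)
        stop(sprintf("malformed BED line %d: fewer than 4 fields", i),
             call. = FALSE)
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      strand <- if (length(f) >= 6) f[6] else "+"
      fam <- f[4]
    } else {
      if (length(f) < 5)
        stop(sprintf("malformed RepeatMasker line %d: fewer than 5 fields",
                     i), call. = FALSE)
      start <- suppressWarnings(as.integer(f[2])) - 1L  # 1-based inclusive
      end <- suppressWarnings(as.integer(f[3]))
      strand <- f[4]
      fam <- f[5]
    }
    if (is.na(start) || is.na(end))
      stop(sprintf("malformed line %d in %s: non-numeric coordinates",
                   i, path), call. = FALSE)
    if (end <= start)
      stop(sprintf("line %d in %s: end <= start", i, path), call. = FALSE)
    if (!nzchar(fam))
      stop(sprintf("line %d in %s: empty family label", i, path),
           call. = FALSE)
    data.frame(chrom = f[1], start = start, end = end, family = fam,
               strand = strand, stringsAsFactors = FALSE)
  }
  skip <- if (format == "repeatmasker" &&
              grepl("genoName|genoStart", lines[1])) 1L else 0L
  rows <- lapply(seq_along(lines)[seq_along(lines) > skip],
                 function(i) parse_line(lines[i], i))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("loaded %d repeat annotation records from %s",
                  nrow(out), path))
  structure(out, class = c("alu_annotation", "data.frame"))
}

#' Signed distance from a position to the nearest annotated interval
#'
#' Distance is 0 when the position lies inside an interval; positive when
#' the nearest interval lies downstream (greater coordinates) of the
#' position, negative when upstream. `orientation = "-"` flips the sign so
#' that "downstream" is read in the query's orientation.
#'
#' @param annotation an annotation data.frame (see [load_annotations()]).
#' @param chrom,pos query position (0-based).
#' @param orientation `"+"` or `"-"`.
#' @return list `distance` (signed bp, `Inf` when no interval on the
#'   chromosome) and `index` (row of the nearest interval, or `NA`).
#' @export
nearest_alu_distance <- function(annotation, chrom, pos,
                                 orientation = "+") {
  a <- annotation[annotation$chrom == chrom, , drop = FALSE]
  if (nrow(a) == 0) return(list(distance = Inf, index = NA_integer_))
  gr <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)
  idx <- IRanges::nearest(q, gr)
  d <- 0L
  if (pos < a$start[idx]) d <- a$start[idx] - pos
  else if (pos >= a$end[idx]) d <- -(pos - (a$end[idx] - 1L))
  if (orientation == "-") d <- -d
  list(distance = as.integer(d),
       index = which(annotation$chrom == chrom)[idx])
}

## -- flank extraction ------------------------------------------------------

#' Extract the genomic 5' flank from an Alu-anchored read
#'
#' Locates the best local alignment of any bisulfite-converted consensus
#' 5' end inside the (already bisulfite-space) read, masks from the
#' alignment start to the read end, and retains the prefix as the genomic
#' flank. Matching is conversion-aware: both read and consensus are
#' reduced to CT space before alignment (match +1, mismatch -1; affine
#' gaps, opening -8 extension -2, so chance gapped extensions across the
#' junction cannot drag the inferred element start into the flank).
#'
#' @param read character; one read sequence (bisulfite space).
#' @param consensus_set named character vector of (unconverted) subfamily
#'   consensus sequences.
#' @param min_flank minimum retained flank length (bp).
#' @param score_threshold minimum local alignment score for an Alu hit.
#' @param consensus_5p_length bp of consensus used as the query; the
#'   default covers the whole consensus so that reads from 5'-truncated
#'   elements (which start inside the body) are still recognized.
#' @return on success a list of class `flank_extract` with `flank_seq`,
#'   `alu_seq`, `junction_offset` (0-based position in the read where the
#'   Alu begins), `alu_family` and `alu_score`; otherwise a list of class
#'   `flank_rejected` with a `reason` (`"no_alu"` or `"short_flank"`).
#' @export
extract_flank <- function(read, consensus_set, min_flank = 40L,
                          score_threshold = 25, consensus_5p_length = 400L) {
  if (length(consensus_set) == 0)
    stop("empty consensus set", call. = FALSE)
  heads <- vapply(consensus_set, function(s)
    ct_space(substr(s, 1L, min(consensus_5p_length, nchar(s)))),
    character(1))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(heads),
    subject = Biostrings::DNAString(ct_space(read)),
    type = "local", substitutionMatrix = mat,
    gapOpening = 8, gapExtension = 2)
  scores <- Biostrings::score(aln)
  best <- which.max(scores)
  if (scores[best] < score_threshold)
    return(structure(list(reason = "no_alu"), class = "flank_rejected"))
  junction <- Biostrings::start(Biostrings::subject(aln[best])) - 1L
  ## anchor the junction at the first solid (10-column) match run: a
  ## chance positive-scoring prefix of consensus interior over the
  ## genomic flank must not drag the element start leftwards
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln[best])),
                  "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln[best])),
                  "")[[1]]
  eq <- pat == sub & pat != "-"
  r <- rle(eq)
  first <- which(r$values & r$lengths >= 10L)[1]
  if (!is.na(first) && first > 1) {
    lead <- sum(r$lengths[seq_len(first - 1L)])
    junction <- junction + sum(sub[seq_len(lead)] != "-")
  }
  if (junction < min_flank)
    return(structure(list(reason = "short_flank",
                          junction_offset = junction),
                     class = "flank_rejected"))
  structure(list(flank_seq = substr(read, 1L, junction),
                 alu_seq = substr(read, junction + 1L, nchar(read)),
                 junction_offset = junction,
                 alu_family = names(consensus_set)[best],
                 alu_score = scores[best]),
            class = "flank_extract")
}

#' Extract flanks from a read set
#'
#' Vectorized driver over [extract_flank()].
#'
#' @param reads data.frame with `read_id` and `seq`; an optional
#'   `library_id` column is carried through.
#' @inheritParams extract_flank
#' @return list with `flanks` (data.frame `read_id, flank_seq, alu_seq,
#'   junction_offset, library_id`) and `rejected` (data.frame
#'   `read_id, reason`).
#' @export
extract_flanks <- function(reads, consensus_set, min_flank = 40L,
                           score_threshold = 25,
                           consensus_5p_length = 400L) {
  libs <- if ("library_id" %in% names(reads)) reads$library_id else
    rep(NA_character_, nrow(reads))
  ok <- list(); rej <- list()
  for (i in seq_len(nrow(reads))) {
    fx <- extract_flank(reads$seq[i], consensus_set, min_flank,
                        score_threshold, consensus_5p_length)
    if (inherits(fx, "flank_rejected")) {
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = reads$read_id[i], reason = fx$reason,
        stringsAsFactors = FALSE)
    } else {
      ok[[length(ok) + 1L]] <- data.frame(
        read_id = reads$read_id[i], flank_seq = fx$flank_seq,
        alu_seq = fx$alu_seq, junction_offset = fx$junction_offset,
        alu_family = fx$alu_family, library_id = libs[i],
        stringsAsFactors = FALSE)
    }
  }
  list(flanks = if (length(ok)) do.call(rbind, ok) else
         data.frame(read_id = character(0), flank_seq = character(0),
                    alu_seq = character(0), junction_offset = integer(0),
                    alu_family = character(0), library_id = character(0)),
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(read_id = character(0), reason = character(0)))
}
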