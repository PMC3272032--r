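## Internal string/sequence helpers shared across modules.
## All genomic coordinates inside the package are 0-based half-open;
## user-facing reports print 1-based inclusive "chrN:start-end".

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a plain character string
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## C->T reduction (bisulfite "CT space"); G->A reduction ("GA space")
ct_space <- function(x) chartr("C", "T", x)
ga_space <- function(x) chartr("G", "A", x)

## 0-based positions of the C of every CG dinucleotide on the plus strand
find_cpg_sites <- function(seq) {
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

## 0-based positions of every C
find_c_sites <- function(seq) {
  hits <- gregexpr("C", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

## random DNA string with a given GC fraction
random_dna <- function(n, gc = 0.41) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## substring by 0-based half-open coordinates
substr0 <- function(seq, start0, end0) substr(seq, start0 + 1L, end0)

## format a locus as 1-based inclusive for reports
format_locus <- function(chrom, start0, end0) {
  sprintf("%s:%d-%d", chrom, start0 + 1L, end0)
}

## Hamming distance between equal-length strings
hamming <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

## validate that a sequence contains only A/C/G/T/N, error with position
check_dna_alphabet <- function(seq, name = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1L) {
    stop(sprintf("%s contains non-IUPAC character '%s' at position %d",
                 name, substr(seq, bad, bad), as.integer(bad)), call. = FALSE)
  }
  invisible(TRUE)
}

## draw an integer uniformly from an inclusive [lo, hi] range
draw_range <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

pct1 <- function(numer, denom) {
  if (denom == 0) return(NA_real_)
  round(100 * numer / denom, 1)
}
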