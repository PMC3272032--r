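## -------------------------------------------------------------------------
## Synthetic data: toy references seeded with Alu copies, TPRT insertion
## events with their retrotransposition hallmarks, per-CpG methylomes, and
## bisulfite amplicon reads with full truth bookkeeping.
## -------------------------------------------------------------------------

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. The defaults are
#' the package's "stated world": hallmark ranges follow what is observed for
#' verified recent AluY insertions (TSDs of 4-17 nt, poly-A tails of
#' 11-45 nt), elements are heavily methylated (per-CpG probability 0.907),
#' and amplicon flanks span 40-250 bp.
#'
#' @param seed integer; fixes every downstream draw.
#' @param genome_length reference length in bp (single toy chromosome).
#' @param gc_fraction GC content of the random background sequence.
#' @param n_background_alus number of annotated full-length Alu copies
#'   seeded into the reference.
#' @param n_novel_insertions number of de-novo TPRT insertion events.
#' @param tsd_length_range inclusive range (nt) for target site duplications.
#' @param polya_length_range inclusive range (nt) for poly-A tails.
#' @param truncation_prob probability that an inserted element is 5'
#'   truncated (up to half its length).
#' @param methylation_profile list with elements `default` (genome-wide
#'   CpG methylation probability), `element_level` (probability inside
#'   annotated elements) and optional `overrides` (list of
#'   `list(chrom, start, end, level)`, 0-based half-open).
#' @param conversion_rate probability that an unmethylated cytosine is
#'   bisulfite-converted (read as T).
#' @param error_rate per-base sequencing substitution error rate.
#' @param reads_per_locus amplicon reads emitted per targeted element.
#' @param flank_length_range inclusive range (bp) of the genomic 5' flank
#'   captured in each amplicon read.
#' @param divergence per-base substitution rate applied to background Alu
#'   copies (novel insertions are inserted without divergence).
#' @param hemizygous_prob probability that a novel insertion is hemizygous
#'   (default 36/47, the fraction observed among verified events).
#' @param alu_read_length bp of element 5' end captured in each read.
#' @param libraries named character vector mapping library ids to tissue
#'   class (`"normal"` or `"tumor"`); reads are assigned uniformly.
#' @param consensus_path FASTA of subfamily consensus sequences; defaults
#'   to the bundled synthetic AluY-family stand-ins.
#' @return an object of class `alu_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       gc_fraction = 0.41,
                       n_background_alus = 20L,
                       n_novel_insertions = 30L,
                       tsd_length_range = c(4L, 17L),
                       polya_length_range = c(11L, 45L),
                       truncation_prob = 0.1,
                       methylation_profile = list(default = 0.75,
                                                  element_level = 0.907,
                                                  overrides = NULL),
                       conversion_rate = 0.99,
                       error_rate = 0.005,
                       reads_per_locus = 5L,
                       flank_length_range = c(40L, 250L),
                       divergence = 0.05,
                       hemizygous_prob = 36 / 47,
                       alu_read_length = 120L,
                       libraries = c(NC1 = "normal", PA1 = "tumor"),
                       consensus_path = NULL) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction,
              n_background_alus = as.integer(n_background_alus),
              n_novel_insertions = as.integer(n_novel_insertions),
              tsd_length_range = as.integer(tsd_length_range),
              polya_length_range = as.integer(polya_length_range),
              truncation_prob = truncation_prob,
              methylation_profile = methylation_profile,
              conversion_rate = conversion_rate,
              error_rate = error_rate,
              reads_per_locus = as.integer(reads_per_locus),
              flank_length_range = as.integer(flank_length_range),
              divergence = divergence,
              hemizygous_prob = hemizygous_prob,
              alu_read_length = as.integer(alu_read_length),
              libraries = libraries,
              consensus_path = consensus_path)
  validate_sim_config(cfg)
  class(cfg) <- "alu_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("gc_fraction", "truncation_prob", "conversion_rate",
              "error_rate", "divergence", "hemizygous_prob")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a fraction in [0,1]", f),
           call. = FALSE)
  }
  for (f in c("tsd_length_range", "polya_length_range",
              "flank_length_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1)
      stop(sprintf("config field '%s' must be a nonempty [min,max] range", f),
           call. = FALSE)
  }
  mp <- cfg$methylation_profile
  if (!is.list(mp) || is.null(mp$default))
    stop("methylation_profile must be a list with at least 'default'",
         call. = FALSE)
  if (is.null(names(cfg$libraries)) || any(!nzchar(names(cfg$libraries))))
    stop("libraries must be a named vector (library_id -> tissue class)",
         call. = FALSE)
  invisible(TRUE)
}

#' Load a subfamily consensus set
#'
#' @param path FASTA path; `NULL` loads the bundled synthetic AluY-family
#'   stand-ins (`AluY`, `AluYa5`, `AluYb8`, `AluYb9`, `AluYg6`).
#' @return named character vector, names are subfamily labels.
#' @export
load_consensus_set <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "alu_consensus_synthetic.fa",
                        package = "alutrace")
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty consensus set: ", path, call. = FALSE)
  out <- as.character(set)
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  out
}

## subfamily age order used for tie-breaks: most derived first
SUBFAMILY_ORDER <- c("AluYb9", "AluYb8", "AluYa5", "AluYg6", "AluY")

## -- make_reference --------------------------------------------------------

#' Generate a toy reference genome seeded with background Alu copies
#'
#' Draws a random genome and places `n_background_alus` full-length,
#' per-copy-diverged Alu copies (random subfamily, random strand) at
#' non-overlapping positions, each recorded in the annotation table.
#'
#' @param config an [sim_config()] object.
#' @return list of class `alu_reference` with elements `genome` (named
#'   character vector of chromosome sequences), `annotation` (data.frame
#'   with 0-based half-open `chrom,start,end,family,strand`) and
#'   `consensus` (the consensus set used).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "alu_sim_config"))
  if (config$genome_length < 10000L)
    stop("genome_length must be >= 10 kb", call. = FALSE)
  set.seed(config$seed)
  consensus <- load_consensus_set(config$consensus_path)
  genome <- random_dna(config$genome_length, config$gc_fraction)

  ann <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), family = character(0),
                    strand = character(0), stringsAsFactors = FALSE)
  n <- config$n_background_alus
  if (n > 0) {
    elem_len <- max(nchar(consensus))
    margin <- 300L
    gap <- 400L
    if (config$genome_length < 2L * margin + n * (elem_len + gap))
      stop(sprintf(paste0("cannot place %d background Alus in a %d bp ",
                          "genome: need at least %d bp"),
                   n, config$genome_length,
                   2L * margin + n * (elem_len + gap)), call. = FALSE)
    starts <- integer(0)
    fams <- sample(names(consensus), n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        s <- sample.int(config$genome_length - 2L * margin - elem_len,
                        1L) + margin
        if (all(abs(s - starts) >= elem_len + gap)) {
          starts <- c(starts, s); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("failed to place background Alu copies without overlap; ",
             "increase genome_length or lower n_background_alus",
             call. = FALSE)
    }
    gvec <- strsplit(genome, "", fixed = TRUE)[[1]]
    for (i in seq_len(n)) {
      body <- mutate_sequence(consensus[[fams[i]]], config$divergence)
      if (strands[i] == "-") body <- revcomp(body)
      bl <- nchar(body)
      gvec[(starts[i] + 1L):(starts[i] + bl)] <-
        strsplit(body, "", fixed = TRUE)[[1]]
      ann <- rbind(ann, data.frame(chrom = "chr1", start = starts[i],
                                   end = starts[i] + bl, family = fams[i],
                                   strand = strands[i],
                                   stringsAsFactors = FALSE))
    }
    genome <- paste(gvec, collapse = "")
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
  }
  structure(list(genome = c(chr1 = genome), annotation = ann,
                 consensus = consensus),
            class = "alu_reference")
}

## substitute each base with probability `rate` (to a different base)
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
  paste(v, collapse = "")
}

## -- simulate_tprt_insertion -----------------------------------------------

## 0-based starts of 6-mers within Hamming distance <= 1 of TTAAAA
find_nick_sites <- function(seq, max_mismatch = 1L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  motif <- c("T", "T", "A", "A", "A", "A")
  n <- length(v) - 5L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (k in 1:6) mm <- mm + (v[k:(n + k - 1L)] != motif[k])
  which(mm <= max_mismatch) - 1L
}

#' Simulate TPRT insertion events into a reference
#'
#' Each event picks a degenerate endonuclease nick site (6-mer within
#' Hamming distance 1 of `TTAAAA`, the cleavage occurring between the
#' TT and the AAAA), duplicates a target-site segment of drawn length,
#' and inserts a subfamily consensus body (optionally 5'-truncated)
#' followed by a poly-A tail between the two TSD copies. Hemizygous
#' events are applied to haplotype 1 only; homozygous events to both.
#'
#' @param reference an [make_reference()] result.
#' @param config an [sim_config()] object.
#' @param n number of insertion events.
#' @return list of class `alu_simulation`: `genome_hap1`, `genome_hap2`
#'   (named character vectors), `truth` (one row per event; `breakpoint`
#'   is the 0-based reference coordinate of the element insertion point,
#'   immediately after the first TSD copy), `annotation_hap1`,
#'   `annotation_hap2` (all elements in haplotype coordinates, with
#'   `locus_id` and `novel` columns), and the input `reference`.
#' @export
simulate_tprt_insertion <- function(reference, config, n = NULL) {
  stopifnot(inherits(reference, "alu_reference"))
  if (is.null(n)) n <- config$n_novel_insertions
  set.seed(config$seed + 1L)
  genome <- reference$genome[[1]]
  chrom <- names(reference$genome)[1]
  L <- nchar(genome)
  consensus <- reference$consensus
  ann <- reference$annotation

  sites <- find_nick_sites(genome)
  margin <- 300L
  max_t <- config$tsd_length_range[2]
  sites <- sites[sites >= margin & sites + 2L + max_t + 1L <= L - margin]
  ## keep sites clear of annotated elements (plus 50 bp guard)
  if (nrow(ann) > 0) {
    keep <- rep(TRUE, length(sites))
    for (i in seq_len(nrow(ann)))
      keep <- keep & (sites < ann$start[i] - 50L | sites > ann$end[i] + 50L)
    sites <- sites[keep]
  }
  if (length(sites) == 0)
    stop("no eligible TT/AAAA-like nick site in the reference", call. = FALSE)

  ## greedily pick n sites at least 400 bp apart
  chosen <- integer(0)
  for (q in sample(sites)) {
    if (all(abs(q - chosen) >= 400L)) chosen <- c(chosen, q)
    if (length(chosen) == n) break
  }
  if (length(chosen) < n)
    stop(sprintf("requested %d insertions but only %d eligible nick sites",
                 n, length(chosen)), call. = FALSE)
  chosen <- sort(chosen)

  events <- vector("list", n)
  for (i in seq_len(n)) {
    q <- chosen[i]
    b0 <- q + 2L              # 0-based start of the TSD (bottom-strand nick)
    tsd_seq <- NA_character_
    for (try in seq_len(20L)) {
      t <- draw_range(config$tsd_length_range)
      cand <- substr0(genome, b0, b0 + t)
      ## homopolymer TSDs make the hallmark boundaries unidentifiable
      if (length(unique(strsplit(cand, "", fixed = TRUE)[[1]])) > 1L) {
        tsd_seq <- cand; break
      }
    }
    if (is.na(tsd_seq)) next
    fam <- sample(names(consensus), 1L)
    body <- consensus[[fam]]
    trunc <- 0L
    if (runif(1) < config$truncation_prob)
      trunc <- sample.int(floor(nchar(body) / 2), 1L)
    body <- substr(body, trunc + 1L, nchar(body))
    polya <- draw_range(config$polya_length_range)
    zyg <- if (runif(1) < config$hemizygous_prob) "hemizygous" else
      "homozygous"
    cpg_rel <- find_cpg_sites(body)
    states <- as.integer(runif(length(cpg_rel)) <
                           config$methylation_profile$element_level)
    events[[i]] <- list(locus_id = sprintf("NI-%02d", i), chrom = chrom,
                        site = q, tsd_start = b0, tsd_seq = tsd_seq,
                        tsd_len = nchar(tsd_seq),
                        breakpoint = b0 + nchar(tsd_seq),
                        subfamily = fam, body = body,
                        body_len = nchar(body), truncated_5p = trunc,
                        polya_length = polya, zygosity = zyg,
                        cpg_rel = cpg_rel, states = states)
  }
  events <- Filter(Negate(is.null), events)
  if (length(events) < n)
    stop("could not draw non-degenerate TSDs at enough nick sites",
         call. = FALSE)

  truth <- data.frame(
    locus_id = vapply(events, `[[`, character(1), "locus_id"),
    chrom = chrom,
    breakpoint = vapply(events, `[[`, integer(1), "breakpoint"),
    tsd_seq = vapply(events, `[[`, character(1), "tsd_seq"),
    polya_length = vapply(events, `[[`, integer(1), "polya_length"),
    subfamily = vapply(events, `[[`, character(1), "subfamily"),
    truncated_5p = vapply(events, `[[`, integer(1), "truncated_5p"),
    zygosity = vapply(events, `[[`, character(1), "zygosity"),
    methylation_states = vapply(events, function(e)
      paste(e$states, collapse = ""), character(1)),
    body_length = vapply(events, `[[`, integer(1), "body_len"),
    stringsAsFactors = FALSE)

  ## insertion duplicates the TSD: modified = prefix(..breakpoint) +
  ## body + polyA + suffix(tsd_start..); applied ascending, earlier
  ## insertions shift later coordinates
  build_hap <- function(which_events) {
    g <- genome
    shift <- 0L
    starts <- rep(NA_integer_, length(events))
    for (i in seq_along(events)) {
      if (!which_events[i]) next
      e <- events[[i]]
      ins <- paste0(e$body, strrep("A", e$polya_length))
      at <- e$breakpoint + shift
      pre <- substr(g, 1L, at)
      suf <- substr(g, at - e$tsd_len + 1L, nchar(g))
      g <- paste0(pre, ins, suf)
      starts[i] <- at
      shift <- shift + nchar(ins) + e$tsd_len
    }
    list(genome = g, starts = starts)
  }
  hap1 <- build_hap(rep(TRUE, length(events)))
  hap2 <- build_hap(truth$zygosity == "homozygous")

  shift_ann <- function(which_events) {
    if (nrow(ann) == 0) return(ann)
    out <- ann
    ## total shift per annotation, computed in reference coordinates
    bps <- vapply(events, `[[`, integer(1), "breakpoint")
    added <- vapply(events, function(e)
      e$body_len + e$polya_length + e$tsd_len, integer(1))
    added[!which_events] <- 0L
    shift <- vapply(out$start, function(s)
      sum(added[bps <= s]), integer(1))
    out$start <- out$start + shift
    out$end <- out$end + shift
    out
  }
  novel_ann <- function(hap, which_events) {
    idx <- which(which_events)
    if (length(idx) == 0)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), family = character(0),
                        strand = character(0), locus_id = character(0),
                        stringsAsFactors = FALSE))
    data.frame(chrom = chrom,
               start = hap$starts[idx],
               end = hap$starts[idx] +
                 vapply(events[idx], `[[`, integer(1), "body_len"),
               family = truth$subfamily[idx],
               strand = "+",
               locus_id = truth$locus_id[idx],
               stringsAsFactors = FALSE)
  }
  mk_ann <- function(hap, which_events) {
    bg <- shift_ann(which_events)
    if (nrow(bg) > 0) {
      bg$locus_id <- sprintf("BG-%02d", seq_len(nrow(bg)))
      bg$novel <- FALSE
    } else {
      bg$locus_id <- character(0); bg$novel <- logical(0)
    }
    nv <- novel_ann(hap, which_events)
    nv$novel <- rep(TRUE, nrow(nv))
    out <- rbind(bg, nv)
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  all_ev <- rep(TRUE, length(events))
  hom_ev <- truth$zygosity == "homozygous"

  structure(list(genome_hap1 = setNames(hap1$genome, chrom),
                 genome_hap2 = setNames(hap2$genome, chrom),
                 truth = truth,
                 annotation_hap1 = mk_ann(hap1, all_ev),
                 annotation_hap2 = mk_ann(hap2, hom_ev),
                 reference = reference),
            class = "alu_simulation")
}

## -- assign_methylome ------------------------------------------------------

#' Assign a per-CpG methylation probability map
#'
#' Every CpG cytosine (plus-strand `CG`) receives a methylation
#' probability: `profile$default` genome-wide, `profile$element_level`
#' inside annotated element intervals, then explicit region overrides.
#' Non-CpG cytosines implicitly carry probability 0. When `truth` is
#' supplied, CpGs of novel inserted elements are frozen to the drawn
#' allele states (probability exactly 0 or 1).
#'
#' @param genome named character vector of chromosome sequences.
#' @param annotation element annotation matching `genome` coordinates.
#' @param profile list with `default`, `element_level`, `overrides`.
#' @param truth optional truth table from [simulate_tprt_insertion()].
#' @return data.frame `chrom, pos, prob` (0-based position of the CpG C).
#' @export
assign_methylome <- function(genome, annotation = NULL,
                             profile = list(default = 0.75,
                                            element_level = 0.907,
                                            overrides = NULL),
                             truth = NULL) {
  out <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    pos <- find_cpg_sites(seq)
    prob <- rep(profile$default, length(pos))
    if (!is.null(annotation) && nrow(annotation) > 0 &&
        !is.null(profile$element_level)) {
      a <- annotation[annotation$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(a))) {
        inside <- pos >= a$start[i] & pos < a$end[i]
        prob[inside] <- profile$element_level
      }
    }
    if (!is.null(truth) && !is.null(annotation) && nrow(annotation) > 0 &&
        "locus_id" %in% names(annotation)) {
      a <- annotation[annotation$chrom == chrom & annotation$novel, ,
                      drop = FALSE]
      for (i in seq_len(nrow(a))) {
        tr <- truth[truth$locus_id == a$locus_id[i], , drop = FALSE]
        if (nrow(tr) != 1) next
        states <- as.integer(strsplit(tr$methylation_states, "")[[1]])
        inside <- which(pos >= a$start[i] & pos < a$end[i])
        if (length(inside) == length(states))
          prob[inside] <- states
      }
    }
    if (!is.null(profile$overrides)) {
      for (ov in profile$overrides) {
        if (!identical(ov$chrom, chrom)) next
        if (ov$start < 0 || ov$end > nchar(seq))
          stop(sprintf("methylation override [%d,%d) outside %s bounds",
                       ov$start, ov$end, chrom), call. = FALSE)
        inside <- pos >= ov$start & pos < ov$end
        prob[inside] <- ov$level
      }
    }
    out[[chrom]] <- data.frame(chrom = chrom, pos = pos, prob = prob,
                               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## -- bisulfite chemistry ---------------------------------------------------

## Apply single-molecule bisulfite chemistry to a molecule string.
## posmap maps each molecule base to its plus-strand genome position
## (descending for minus-strand molecules). cpg_prob is a named numeric
## vector: names are genome positions of plus-strand CpG Cs.
## Returns list(seq, cpg_pos, cpg_states) where states are drawn per call.
bisulfite_molecule <- function(molecule, posmap, strand, cpg_prob,
                               conversion_rate) {
  v <- strsplit(molecule, "", fixed = TRUE)[[1]]
  cs <- which(v == "C")
  cpg_pos <- integer(0); cpg_state <- integer(0)
  for (i in cs) {
    gpos <- posmap[i]
    key <- if (strand == "+") as.character(gpos) else as.character(gpos - 1L)
    p <- cpg_prob[key]
    if (!is.na(p)) {                       # CpG-context cytosine
      st <- as.integer(runif(1) < p)
      cpg_pos <- c(cpg_pos, gpos); cpg_state <- c(cpg_state, st)
      if (st == 0L && runif(1) < conversion_rate) v[i] <- "T"
    } else {                               # non-CpG cytosine
      if (runif(1) < conversion_rate) v[i] <- "T"
    }
  }
  list(seq = paste(v, collapse = ""), cpg_pos = cpg_pos,
       cpg_states = cpg_state)
}

apply_sequencing_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < error_rate)
  for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
  paste(v, collapse = "")
}

## -- simulate_reads --------------------------------------------------------

#' Simulate Alu-anchored bisulfite amplicon reads
#'
#' For each annotated element (background and novel) on the simulated
#' haplotypes, emits `reads_per_locus` reads spanning a drawn genomic 5'
#' flank plus the element 5' end, with single-molecule bisulfite
#' conversion (unmethylated C read as T with probability
#' `conversion_rate`; methylated CpG C retained) and substitution
#' sequencing errors. Hemizygous novel loci yield reads from the carrier
#' haplotype only; all other loci draw haplotypes 1:1.
#'
#' @param sim an [simulate_tprt_insertion()] result.
#' @param config an [sim_config()] object.
#' @param methylome optional list with `hap1` and `hap2` methylomes
#'   (from [assign_methylome()]); computed from
#'   `config$methylation_profile` and the simulation truth when `NULL`.
#' @return list with `reads` (data.frame `read_id,seq,qual`), `truth`
#'   (per-read source bookkeeping incl. drawn per-CpG states) and
#'   `skipped` (reads dropped for lack of upstream sequence, with reason).
#' @export
simulate_reads <- function(sim, config, methylome = NULL) {
  stopifnot(inherits(sim, "alu_simulation"))
  set.seed(config$seed + 3L)
  if (is.null(methylome)) {
    methylome <- list(
      hap1 = assign_methylome(sim$genome_hap1, sim$annotation_hap1,
                              config$methylation_profile, sim$truth),
      hap2 = assign_methylome(sim$genome_hap2, sim$annotation_hap2,
                              config$methylation_profile, sim$truth))
  }
  cprob <- list(
    hap1 = setNames(methylome$hap1$prob, as.character(methylome$hap1$pos)),
    hap2 = setNames(methylome$hap2$prob, as.character(methylome$hap2$pos)))
  genomes <- list(hap1 = sim$genome_hap1[[1]], hap2 = sim$genome_hap2[[1]])
  anns <- list(hap1 = sim$annotation_hap1, hap2 = sim$annotation_hap2)
  hemi <- sim$truth$locus_id[sim$truth$zygosity == "hemizygous"]
  libs <- names(config$libraries)

  reads <- list(); truth <- list(); skipped <- list(); k <- 0L
  for (r in seq_len(nrow(anns$hap1))) {
    locus <- anns$hap1$locus_id[r]
    for (j in seq_len(config$reads_per_locus)) {
      hap <- if (locus %in% hemi) "hap1" else
        sample(c("hap1", "hap2"), 1L)
      a <- anns[[hap]][anns[[hap]]$locus_id == locus, , drop = FALSE]
      if (nrow(a) != 1) { hap <- "hap1"; a <- anns$hap1[r, , drop = FALSE] }
      g <- genomes[[hap]]
      f <- draw_range(config$flank_length_range)
      alu_part <- min(config$alu_read_length, a$end - a$start)
      if (a$strand == "+") {
        lo <- a$start - f; hi <- a$start + alu_part
        if (lo < 0) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(locus_id = locus, reason = "insufficient_upstream",
                       stringsAsFactors = FALSE)
          warning(sprintf("read skipped at %s: flank %d exceeds upstream",
                          locus, f), call. = FALSE)
          next
        }
        molecule <- substr0(g, lo, hi)
        posmap <- seq.int(lo, hi - 1L)
        strand <- "+"
      } else {
        lo <- a$end - alu_part; hi <- a$end + f
        if (hi > nchar(g)) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(locus_id = locus, reason = "insufficient_upstream",
                       stringsAsFactors = FALSE)
          warning(sprintf("read skipped at %s: flank %d exceeds upstream",
                          locus, f), call. = FALSE)
          next
        }
        molecule <- revcomp(substr0(g, lo, hi))
        posmap <- seq.int(hi - 1L, lo)
        strand <- "-"
      }
      bs <- bisulfite_molecule(molecule, posmap, strand, cprob[[hap]],
                               config$conversion_rate)
      seq <- apply_sequencing_errors(bs$seq, config$error_rate)
      k <- k + 1L
      rid <- sprintf("read_%04d_%s", k, locus)
      reads[[k]] <- data.frame(read_id = rid, seq = seq,
                               qual = strrep("I", nchar(seq)),
                               stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        read_id = rid, locus_id = locus, library_id = sample(libs, 1L),
        hap = hap, strand = strand, flank_len = f,
        region_start = lo, region_end = hi,
        novel = a$novel,
        cpg_states = paste(bs$cpg_states, collapse = ""),
        cpg_pos = paste(bs$cpg_pos, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  list(reads = do.call(rbind, c(reads, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(locus_id = character(0), reason = character(0)))
}

#' Simulate bisulfite clone reads from one local reference
#'
#' Emits `n` full-length clones of `local_ref` with per-molecule CpG
#' methylation states drawn at probability `meth_prob` (scalar or one
#' value per CpG), bisulfite conversion and substitution errors. Used to
#' exercise the methylation caller against a known per-CpG probability.
#'
#' @param local_ref character; the unconverted local reference sequence.
#' @param meth_prob scalar or per-CpG vector of methylation probabilities.
#' @param n number of clones.
#' @param conversion_rate,error_rate chemistry and sequencing noise.
#' @return data.frame `read_id, seq` plus attribute `"states"` (matrix of
#'   drawn states, clones in rows, CpGs in columns).
#' @export
simulate_bisulfite_clones <- function(local_ref, meth_prob, n,
                                      conversion_rate = 1, error_rate = 0) {
  cpg <- find_cpg_sites(local_ref)
  if (length(meth_prob) == 1L) meth_prob <- rep(meth_prob, length(cpg))
  stopifnot(length(meth_prob) == length(cpg))
  prob <- setNames(meth_prob, as.character(cpg))
  posmap <- seq.int(0L, nchar(local_ref) - 1L)
  states <- matrix(NA_integer_, nrow = n, ncol = length(cpg))
  seqs <- character(n)
  for (i in seq_len(n)) {
    bs <- bisulfite_molecule(local_ref, posmap, "+", prob, conversion_rate)
    seqs[i] <- apply_sequencing_errors(bs$seq, error_rate)
    if (length(cpg)) states[i, match(bs$cpg_pos, cpg)] <- bs$cpg_states
  }
  out <- data.frame(read_id = sprintf("clone_%05d", seq_len(n)), seq = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "states") <- states
  out
}

## -- toy gene models -------------------------------------------------------

#' Simulate a toy gene model table
#'
#' Places non-overlapping transcripts with alternating exon/intron blocks
#' and terminal UTRs on a chromosome; used to exercise genic-context
#' annotation. Exon features denote coding exons (disjoint from UTRs).
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length (bp).
#' @param n_genes number of transcripts.
#' @param seed RNG seed.
#' @return data.frame `chrom,start,end,type,gene_id` (0-based half-open)
#'   with types `transcript`, `exon`, `utr5`, `utr3`.
#' @export
simulate_gene_models <- function(chrom = "chr1", chrom_length, n_genes = 5L,
                                 seed = 1L) {
  set.seed(seed)
  slot <- floor(chrom_length / n_genes)
  rows <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("GENE%02d", i)
    lo <- (i - 1L) * slot + sample.int(max(1L, floor(slot * 0.1)), 1L)
    len <- min(floor(slot * 0.6), 20000L)
    hi <- lo + len
    u5 <- c(lo, lo + 200L)
    u3 <- c(hi - 200L, hi)
    n_ex <- 3L
    ex_w <- 300L
    gaps <- floor((len - 400L - n_ex * ex_w) / n_ex)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = lo, end = hi, type = "transcript",
      gene_id = gid, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = u5[1], end = u5[2], type = "utr5",
      gene_id = gid, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = u3[1], end = u3[2], type = "utr3",
      gene_id = gid, stringsAsFactors = FALSE)
    for (k in seq_len(n_ex)) {
      es <- u5[2] + (k - 1L) * (ex_w + gaps) + gaps
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = es, end = es + ex_w, type = "exon",
        gene_id = gid, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## -- writers ---------------------------------------------------------------

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33, constant quality)
#' @param reads data.frame with `read_id`, `seq` and optional `qual`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#' @param path FASTQ path.
#' @return data.frame `read_id, seq, qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  stopifnot(length(lines) %% 4 == 0)
  i <- seq(1L, length(lines), by = 4L)
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", lines[i])),
             seq = lines[i + 1L], qual = lines[i + 3L],
             stringsAsFactors = FALSE)
}

#' Write an annotation table to BED
#' @param ann data.frame `chrom,start,end,family,strand` (0-based).
#' @param path output path.
#' @export
write_annotation_bed <- function(ann, path) {
  bed <- data.frame(ann$chrom, ann$start, ann$end, ann$family, 0L,
                    ann$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
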