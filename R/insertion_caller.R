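## -------------------------------------------------------------------------
## Insertion caller: junction classification against the known-Alu
## annotation, coordinate clustering, novelty and genic-context
## annotation, and Table-1-style library statistics.
## -------------------------------------------------------------------------

#' Classify the junction of a uniquely mapped flank
#'
#' The junction is the reference coordinate abutting the read's Alu-mask
#' boundary: the alignment end for forward (CT-space) hits, the alignment
#' start for reverse (GA-space) hits. A junction within
#' `adjacency_window` bp of an annotated Alu is called `known_adjacent`;
#' otherwise `putative_novel`.
#'
#' @param mapped data.frame of mapped reads (see [map_iterative()]);
#'   only rows with `status == "unique"` are classified.
#' @param alu_table repeat annotation (see [load_annotations()]).
#' @param adjacency_window bp window for the known-adjacent call.
#' @return data.frame `read_id, chrom, junction_pos,
#'   distance_to_nearest_alu, verdict, library_id`.
#' @export
classify_junction <- function(mapped, alu_table, adjacency_window = 10L) {
  u <- mapped[mapped$status == "unique", , drop = FALSE]
  if (nrow(alu_table) == 0)
    warning("empty Alu annotation table: every junction will be called ",
            "putative_novel", call. = FALSE)
  out <- vector("list", nrow(u))
  for (i in seq_len(nrow(u))) {
    jpos <- if (u$space[i] == "CT") u$end[i] else u$start[i]
    orient <- if (u$space[i] == "CT") "+" else "-"
    nd <- nearest_alu_distance(alu_table, u$chrom[i], jpos, orient)
    verdict <- if (is.finite(nd$distance) &&
                   abs(nd$distance) <= adjacency_window)
      "known_adjacent" else "putative_novel"
    out[[i]] <- data.frame(
      read_id = u$read_id[i], chrom = u$chrom[i], junction_pos = jpos,
      distance_to_nearest_alu = nd$distance, verdict = verdict,
      library_id = u$library_id[i], stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE))) else
    data.frame(read_id = character(0), chrom = character(0),
               junction_pos = integer(0),
               distance_to_nearest_alu = numeric(0),
               verdict = character(0), library_id = character(0))
}

#' Cluster putative-novel junction calls by genomic coordinate
#'
#' Single-linkage merge of junctions on the same chromosome whose
#' consecutive positions differ by at most `merge_window` bp.
#'
#' @param calls junction calls (rows with `verdict == "putative_novel"`
#'   are used; pass a pre-filtered frame to cluster everything).
#' @param merge_window maximum within-cluster gap (bp).
#' @return data.frame `cluster_id, chrom, breakpoint_lo, breakpoint_hi,
#'   n_reads, n_libraries, libraries, read_ids`, sorted by coordinate,
#'   with attribute `"by_library"` (long data.frame
#'   `cluster_id, library_id, n_reads`).
#' @export
cluster_candidates <- function(calls, merge_window = 10L) {
  if ("verdict" %in% names(calls))
    calls <- calls[calls$verdict == "putative_novel", , drop = FALSE]
  empty <- data.frame(cluster_id = character(0), chrom = character(0),
                      breakpoint_lo = integer(0), breakpoint_hi = integer(0),
                      n_reads = integer(0), n_libraries = integer(0),
                      libraries = character(0), read_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) {
    attr(empty, "by_library") <- data.frame(cluster_id = character(0),
                                            library_id = character(0),
                                            n_reads = integer(0))
    return(empty)
  }
  calls <- calls[order(calls$chrom, calls$junction_pos), , drop = FALSE]
  newc <- c(TRUE, calls$chrom[-1] != calls$chrom[-nrow(calls)] |
              diff(calls$junction_pos) > merge_window)
  gid <- cumsum(newc)
  rows <- list(); bylib <- list()
  for (g in unique(gid)) {
    m <- calls[gid == g, , drop = FALSE]
    cid <- sprintf("CL-%04d", g)
    libs <- sort(unique(m$library_id[!is.na(m$library_id)]))
    rows[[g]] <- data.frame(
      cluster_id = cid, chrom = m$chrom[1],
      breakpoint_lo = min(m$junction_pos),
      breakpoint_hi = max(m$junction_pos),
      n_reads = nrow(m), n_libraries = length(libs),
      libraries = paste(libs, collapse = ","),
      read_ids = paste(m$read_id, collapse = ","),
      stringsAsFactors = FALSE)
    tab <- table(m$library_id, useNA = "ifany")
    bylib[[g]] <- data.frame(cluster_id = rep(cid, length(tab)),
                             library_id = names(tab),
                             n_reads = as.integer(tab),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "by_library") <-
    do.call(rbind, c(bylib, list(make.row.names = FALSE)))
  out
}

#' Flag clusters that match known polymorphic insertions
#'
#' A cluster is novel when no known polymorphic insertion lies within
#' `overlap_window` bp of its breakpoint span.
#'
#' @param clusters result of [cluster_candidates()].
#' @param known a BED path or a data.frame `chrom,start,end`.
#' @param overlap_window bp window (default 50).
#' @return `clusters` with a logical `novel` column added.
#' @export
annotate_novelty <- function(clusters, known, overlap_window = 50L) {
  if (is.character(known)) known <- load_known_table(known)
  novel <- rep(TRUE, nrow(clusters))
  if (!is.null(known) && nrow(known) > 0) {
    for (i in seq_len(nrow(clusters))) {
      k <- known[known$chrom == clusters$chrom[i], , drop = FALSE]
      if (nrow(k) == 0) next
      hit <- k$start <= clusters$breakpoint_hi[i] + overlap_window &
        k$end >= clusters$breakpoint_lo[i] - overlap_window
      if (any(hit)) novel[i] <- FALSE
    }
  }
  bl <- attr(clusters, "by_library")
  clusters$novel <- novel
  attr(clusters, "by_library") <- bl
  clusters
}

## minimal 3+-column BED reader for known-polymorphism tables
load_known_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed BED line %d in %s", i, path), call. = FALSE)
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || e <= s)
      stop(sprintf("malformed BED line %d in %s", i, path), call. = FALSE)
    data.frame(chrom = f[1], start = s, end = e, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Attach genic context to clusters
#'
#' The midpoint of each cluster's breakpoint span is classified with
#' precedence exon > UTR > intron > intergenic ("exon" features denote
#' coding exons, disjoint from the UTR features). A `gene_id` is attached
#' when the midpoint falls within a transcript.
#'
#' @param clusters result of [cluster_candidates()].
#' @param gene_models data.frame `chrom,start,end,type,gene_id` with
#'   types `transcript`, `exon`, `utr5`, `utr3` (see
#'   [simulate_gene_models()] / [load_gene_models()]).
#' @return `clusters` with `genic_context` and `gene_id` columns.
#' @export
annotate_genic_context <- function(clusters, gene_models) {
  req <- c("chrom", "start", "end", "type")
  if (!all(req %in% names(gene_models)))
    stop("invalid gene model table: need columns ",
         paste(req, collapse = ", "), call. = FALSE)
  ctx <- character(nrow(clusters)); gid <- rep(NA_character_,
                                               nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    mid <- floor((clusters$breakpoint_lo[i] + clusters$breakpoint_hi[i]) / 2)
    gm <- gene_models[gene_models$chrom == clusters$chrom[i] &
                        gene_models$start <= mid & gene_models$end > mid, ,
                      drop = FALSE]
    if (any(gm$type == "exon")) {
      ctx[i] <- "exonic"
    } else if (any(gm$type == "utr5")) {
      ctx[i] <- "utr5"
    } else if (any(gm$type == "utr3")) {
      ctx[i] <- "utr3"
    } else if (any(gm$type == "transcript")) {
      ctx[i] <- "intronic"
    } else {
      ctx[i] <- "intergenic"
    }
    if (ctx[i] != "intergenic" && "gene_id" %in% names(gm))
      gid[i] <- gm$gene_id[which(gm$type == "transcript")[1]]
  }
  bl <- attr(clusters, "by_library")
  clusters$genic_context <- ctx
  clusters$gene_id <- gid
  attr(clusters, "by_library") <- bl
  clusters
}

#' Load gene models from GFF3/GTF or a plain TSV
#'
#' GFF3/GTF files are read with `rtracklayer` (feature types `mRNA` /
#' `transcript`, `exon`, `five_prime_UTR`, `three_prime_UTR` are mapped
#' onto the internal vocabulary). A `.tsv` file must already carry the
#' internal columns `chrom,start,end,type,gene_id` (0-based half-open).
#'
#' @param path gene model file.
#' @return data.frame `chrom,start,end,type,gene_id`.
#' @export
load_gene_models <- function(path) {
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF/GTF gene models requires the rtracklayer package",
           call. = FALSE)
    gr <- rtracklayer::import(path)
    type <- as.character(gr$type)
    map <- c(mRNA = "transcript", transcript = "transcript",
             exon = "exon", five_prime_UTR = "utr5",
             three_prime_UTR = "utr3", CDS = "exon")
    keep <- type %in% names(map)
    gr <- gr[keep]; type <- map[type[keep]]
    gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else
      if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               type = unname(type), gene_id = gid,
               stringsAsFactors = FALSE)
  } else {
    gm <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    req <- c("chrom", "start", "end", "type")
    if (!all(req %in% names(gm)))
      stop("invalid gene model table ", path, call. = FALSE)
    gm
  }
}

## -- Table-1-style statistics ----------------------------------------------

#' Per-library insertion statistics from printed or derived counts
#'
#' The ratio column normalizes insertion regions per 100 mapped regions:
#' `round(100 * insertion_regions / regions_mapped, 2)`.
#'
#' @param counts data.frame with columns `library_id, regions_mapped,
#'   insertion_reads, insertion_regions` (and optionally `reads_mapped`).
#' @return the input with a `ratio` column, plus totals as attributes
#'   `total_insertion_reads` and `total_insertion_regions`.
#' @export
library_stats_from_counts <- function(counts) {
  req <- c("library_id", "regions_mapped", "insertion_reads",
           "insertion_regions")
  if (!all(req %in% names(counts)))
    stop("counts must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(counts$insertion_reads < 0 | counts$insertion_regions < 0 |
            counts$regions_mapped < 0))
    stop("counts must be nonnegative", call. = FALSE)
  counts$ratio <- round(100 * counts$insertion_regions /
                          counts$regions_mapped, 2)
  attr(counts, "total_insertion_reads") <- sum(counts$insertion_reads)
  attr(counts, "total_insertion_regions") <- sum(counts$insertion_regions)
  counts
}

#' Aggregate cluster-sharing percentages
#'
#' Reporting arithmetic for the aggregate summary: percentages are
#' printed with one decimal.
#'
#' @param n_clusters distinct cluster count.
#' @param n_multiread clusters supported by more than one read.
#' @param n_multilibrary clusters present in more than one library.
#' @param n_shared_normal_tumor multi-library clusters found in both
#'   normal- and tumor-tagged libraries.
#' @param n_intronic clusters with intronic integration sites.
#' @param n_verified,n_attempted validation outcome counts (optional).
#' @return named list of percentages.
#' @export
aggregate_percentages <- function(n_clusters, n_multiread,
                                  n_multilibrary,
                                  n_shared_normal_tumor = NA,
                                  n_intronic = NA,
                                  n_verified = NA, n_attempted = NA) {
  list(pct_multiread = pct1(n_multiread, n_clusters),
       pct_multilibrary = pct1(n_multilibrary, n_clusters),
       pct_shared_normal_tumor = if (is.na(n_shared_normal_tumor))
         NA_real_ else pct1(n_shared_normal_tumor, n_multilibrary),
       pct_intronic = if (is.na(n_intronic)) NA_real_ else
         pct1(n_intronic, n_clusters),
       verification_rate = if (is.na(n_verified)) NA_real_ else
         pct1(n_verified, n_attempted))
}

#' Summarize insertion clusters per library and in aggregate
#'
#' @param clusters annotated clusters (with `by_library` attribute).
#' @param mapping_totals data.frame `library_id, reads_mapped,
#'   regions_mapped`.
#' @param metadata optional data.frame `library_id, tissue_class`
#'   (`"normal"` / `"tumor"`), required for the normal/tumor sharing
#'   percentage.
#' @return list with `per_library` (LibraryStats table) and `aggregate`
#'   (totals and percentages; region incidences count a cluster once per
#'   library it appears in).
#' @export
summarize_libraries <- function(clusters, mapping_totals, metadata = NULL) {
  bylib <- attr(clusters, "by_library")
  if (is.null(bylib))
    stop("clusters must carry a by_library attribute ",
         "(see cluster_candidates)", call. = FALSE)
  libs_in_clusters <- unique(bylib$library_id)
  missing <- setdiff(libs_in_clusters, mapping_totals$library_id)
  if (length(missing))
    stop("libraries present in clusters but absent from mapping_totals: ",
         paste(missing, collapse = ", "), call. = FALSE)

  per_lib <- mapping_totals
  per_lib$insertion_reads <- vapply(per_lib$library_id, function(l)
    sum(bylib$n_reads[bylib$library_id == l]), integer(1))
  per_lib$insertion_regions <- vapply(per_lib$library_id, function(l)
    length(unique(bylib$cluster_id[bylib$library_id == l])), integer(1))
  per_lib <- library_stats_from_counts(per_lib)

  n_clusters <- nrow(clusters)
  n_multiread <- sum(clusters$n_reads > 1)
  n_multilib <- sum(clusters$n_libraries > 1)
  shared_nt <- NA_integer_
  if (!is.null(metadata)) {
    cls <- setNames(metadata$tissue_class, metadata$library_id)
    multilib <- clusters[clusters$n_libraries > 1, , drop = FALSE]
    shared_nt <- sum(vapply(strsplit(multilib$libraries, ","), function(l) {
      tc <- unique(cls[l]); all(c("normal", "tumor") %in% tc)
    }, logical(1)))
  }
  n_intronic <- if ("genic_context" %in% names(clusters))
    sum(clusters$genic_context == "intronic") else NA_integer_
  agg <- c(list(total_insertion_reads = sum(clusters$n_reads),
                total_region_incidences = nrow(bylib),
                n_clusters = n_clusters,
                n_novel = if ("novel" %in% names(clusters))
                  sum(clusters$novel) else NA_integer_),
           aggregate_percentages(n_clusters, n_multiread, n_multilib,
                                 shared_nt, n_intronic))
  list(per_library = per_lib, aggregate = agg)
}
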