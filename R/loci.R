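#' Merge hits into IS loci
#'
#' Hits of the same IS type and strand on one replicon whose genomic gap is
#' at most `max_gap` are merged into a single locus. Nucleotide- and
#' translated-level hits may co-support one locus. Locus coverage is the
#' union of consensus intervals covered by the supporting hits, divided by
#' the consensus length; locus boundaries are the outermost supporting hit
#' ends.
#'
#' @param hits Hit tibble (any mix of [search_nt()] and
#'   [search_translated()] output).
#' @param catalog IS catalog tibble.
#' @param max_gap Maximum genomic gap (bp) between merged hits.
#' @return Locus tibble: `locus_id`, `is_name`, `replicon_id`, `start`,
#'   `end`, `strand`, `coverage`, `n_hits`, `levels`.
#' @export
merge_hits <- function(hits, catalog, max_gap = 100) {
  empty <- tibble::tibble(locus_id = character(), is_name = character(),
                          replicon_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          coverage = double(), n_hits = integer(),
                          levels = character())
  if (nrow(hits) == 0) return(empty)
  clen <- setNames(nchar(catalog$consensus), catalog$name)
  grp <- dplyr::group_by(dplyr::arrange(hits, .data$start, .data$end),
                         .data$replicon_id, .data$is_name, .data$strand)
  loci <- dplyr::group_modify(grp, function(df, key) {
    gap_break <- c(0, pmax(df$start[-1] - cummax(df$end)[-nrow(df)] - 1L, 0))
    cl <- cumsum(gap_break > max_gap)
    purrr::map_dfr(split(df, cl), function(d) {
      tibble::tibble(
        start = min(d$start), end = max(d$end),
        coverage = consensus_union(d$qstart, d$qend) /
          clen[[key$is_name[[1]]]],
        n_hits = nrow(d),
        levels = paste(sort(unique(d$level)), collapse = ","))
    })
  })
  loci <- dplyr::arrange(dplyr::ungroup(loci), .data$replicon_id,
                         .data$start, .data$end)
  loci$locus_id <- sprintf("%s:%s:%d-%d", loci$replicon_id, loci$is_name,
                           loci$start, loci$end)
  dplyr::select(loci, dplyr::all_of(names(empty)))
}

# total length of the union of 1-based inclusive intervals (NA pairs dropped)
consensus_union <- function(qstart, qend) {
  ok <- !is.na(qstart) & !is.na(qend)
  if (!any(ok)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(qstart[ok], qend[ok]))
  sum(IRanges::width(ir))
}

#' Classify locus completeness
#'
#' A locus is `complete` when its consensus coverage is at least
#' `complete_cov_min` (inclusive) and its genomic length lies within
#' `[0.9 * min_len, 1.1 * max_len]` of the catalog length range; otherwise
#' it is `partial` (an IS scar).
#'
#' @param loci Locus tibble from [merge_hits()].
#' @param catalog IS catalog tibble.
#' @param complete_cov_min Minimum consensus coverage for a complete call.
#' @return `loci` with a `status` column.
#' @export
classify_completeness <- function(loci, catalog, complete_cov_min = 0.95) {
  if (nrow(loci) == 0) return(dplyr::mutate(loci, status = character()))
  k <- match(loci$is_name, catalog$name)
  len <- loci$end - loci$start + 1L
  ok_len <- len >= 0.9 * catalog$min_len[k] & len <= 1.1 * catalog$max_len[k]
  ok_len[is.na(ok_len)] <- TRUE
  loci$status <- ifelse(loci$coverage >= complete_cov_min & ok_len,
                        "complete", "partial")
  loci
}

#' Detect target-site duplications
#'
#' For each locus, compares the `dr_len`-bp windows immediately flanking the
#' locus; the flank string is reported as the TSD only when the two windows
#' are identical. Loci of types with `dr_len = 0`, loci whose windows
#' differ, and loci too close to a replicon edge (flagged in `tsd_at_edge`)
#' get `NA`.
#'
#' @param loci Locus tibble.
#' @param replicons Replicon tibble.
#' @param catalog IS catalog tibble.
#' @return `loci` with `tsd_seq` and `tsd_at_edge` columns.
#' @export
detect_tsd <- function(loci, replicons, catalog) {
  if (nrow(loci) == 0)
    return(dplyr::mutate(loci, tsd_seq = character(), tsd_at_edge = logical()))
  seqs <- setNames(replicons$seq, replicons$id)
  k <- match(loci$is_name, catalog$name)
  dr <- catalog$dr_len[k]
  tsd <- rep(NA_character_, nrow(loci))
  edge <- rep(FALSE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    t <- dr[i]
    if (is.na(t) || t == 0) next
    s <- seqs[[loci$replicon_id[i]]]
    if (loci$start[i] - t < 1 || loci$end[i] + t > nchar(s)) {
      edge[i] <- TRUE
      next
    }
    left <- substr(s, loci$start[i] - t, loci$start[i] - 1L)
    right <- substr(s, loci$end[i] + 1L, loci$end[i] + t)
    if (left == right && !grepl("N", left, fixed = TRUE)) tsd[i] <- left
  }
  loci$tsd_seq <- tsd
  loci$tsd_at_edge <- edge
  loci
}

#' Detect terminal inverted repeats
#'
#' Compares each locus's termini (read in consensus orientation, i.e. the
#' locus sequence is reverse-complemented first for minus-strand loci)
#' against the catalog IRs, or against the consensus termini (`ir_probe` bp)
#' when the catalog does not list IRs. Evidence is reported per side when at
#' most `max_mismatch` mismatches are seen.
#'
#' @param loci Locus tibble.
#' @param replicons Replicon tibble.
#' @param catalog IS catalog tibble.
#' @param max_mismatch Maximum mismatches per terminus.
#' @param ir_probe Terminus length used when the catalog lacks IR sequences.
#' @return `loci` with an `ir_evidence` column (`both`, `left`, `right`,
#'   `none`).
#' @export
detect_ir <- function(loci, replicons, catalog, max_mismatch = 3,
                      ir_probe = 25) {
  if (nrow(loci) == 0) return(dplyr::mutate(loci, ir_evidence = character()))
  seqs <- setNames(replicons$seq, replicons$id)
  k <- match(loci$is_name, catalog$name)
  ev <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    rec <- catalog[k[i], ]
    lseq <- substr(seqs[[loci$replicon_id[i]]], loci$start[i], loci$end[i])
    if (loci$strand[i] == "-") lseq <- revcomp(lseq)
    probe_l <- if (!is.na(rec$ir_left)) rec$ir_left
               else substr(rec$consensus, 1, ir_probe)
    probe_r <- if (!is.na(rec$ir_right)) rec$ir_right
               else substr(rec$consensus, nchar(rec$consensus) - ir_probe + 1L,
                           nchar(rec$consensus))
    left_ok <- hamming(substr(lseq, 1, nchar(probe_l)), probe_l) <=
      max_mismatch
    right_ok <- hamming(substr(lseq, nchar(lseq) - nchar(probe_r) + 1L,
                               nchar(lseq)), probe_r) <= max_mismatch
    ev[i] <- if (left_ok && right_ok) "both"
             else if (left_ok) "left"
             else if (right_ok) "right"
             else "none"
  }
  loci$ir_evidence <- ev
  loci
}

# mismatch count between equal-length strings; length mismatch counts fully
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(max(nchar(a), nchar(b)))
  if (nchar(a) == 0) return(0L)
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(va != vb | va == "N" | vb == "N")
}

#' Build annotated loci from raw hits
#'
#' Convenience wrapper chaining [merge_hits()], [classify_completeness()],
#' [detect_tsd()] and [detect_ir()].
#'
#' @inheritParams merge_hits
#' @inheritParams classify_completeness
#' @inheritParams detect_ir
#' @param replicons Replicon tibble.
#' @return Fully annotated locus tibble.
#' @export
build_loci <- function(hits, replicons, catalog, max_gap = 100,
                       complete_cov_min = 0.95, max_mismatch = 3,
                       ir_probe = 25) {
  merge_hits(hits, catalog, max_gap = max_gap) |>
    classify_completeness(catalog, complete_cov_min = complete_cov_min) |>
    detect_tsd(replicons, catalog) |>
    detect_ir(replicons, catalog, max_mismatch = max_mismatch,
              ir_probe = ir_probe)
}

#' Write loci as GFF3
#'
#' Loci are written as `mobile_genetic_element` features with `status`,
#' `coverage`, `tsd` and `ir_evidence` attributes.
#'
#' @param loci Annotated locus tibble.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$replicon_id,
    ranges = IRanges::IRanges(loci$start, loci$end),
    strand = loci$strand)
  S4Vectors::mcols(gr)$type <- "mobile_genetic_element"
  S4Vectors::mcols(gr)$source <- "issweep"
  S4Vectors::mcols(gr)$is_name <- loci$is_name
  S4Vectors::mcols(gr)$status <- loci$status
  S4Vectors::mcols(gr)$coverage <- round(loci$coverage, 4)
  if ("tsd_seq" %in% names(loci)) S4Vectors::mcols(gr)$tsd <- loci$tsd_seq
  if ("ir_evidence" %in% names(loci))
    S4Vectors::mcols(gr)$ir_evidence <- loci$ir_evidence
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
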