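#' Extract a sub-sequence of an IS consensus
#'
#' Used to pull the short repeat unit that seeded a CRISPR array out of its
#' source IS (e.g. a 32 bp slice of an IS110-family element).
#'
#' @param catalog IS catalog tibble.
#' @param name IS name within the catalog.
#' @param start,end 1-based inclusive coordinates on the consensus.
#' @return The sub-sequence (character scalar of length `end - start + 1`).
#' @export
extract_repeat <- function(catalog, name, start, end) {
  k <- match(name, catalog$name)
  if (is.na(k)) stop("unknown IS name: ", name, call. = FALSE)
  L <- nchar(catalog$consensus[k])
  if (start < 1 || end > L || start > end)
    stop(sprintf("coordinates %d-%d out of range for %s (length %d)",
                 start, end, name, L), call. = FALSE)
  substr(catalog$consensus[k], start, end)
}

#' Find copies of a short repeat across replicons
#'
#' Reports all ungapped occurrences of `repeat_seq` with at most
#' `max_mismatch` mismatches, on both strands, in deterministic
#' (replicon, start) order. N never matches.
#'
#' @param replicons Replicon tibble.
#' @param repeat_seq Repeat sequence (>= 16 bp).
#' @param max_mismatch Maximum mismatches per copy (default 0, exact).
#' @return Tibble: `replicon_id`, `start`, `end`, `strand`.
#' @export
find_repeat_copies <- function(replicons, repeat_seq, max_mismatch = 0) {
  stopifnot(nchar(repeat_seq) >= 16)
  pat <- Biostrings::DNAString(repeat_seq)
  res <- purrr::map_dfr(seq_len(nrow(replicons)), function(r) {
    subj <- Biostrings::DNAString(replicons$seq[r])
    per_strand <- function(p, std) {
      m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0) return(NULL)
      tibble::tibble(replicon_id = replicons$id[r],
                     start = Biostrings::start(m), end = Biostrings::end(m),
                     strand = std)
    }
    dplyr::bind_rows(per_strand(pat, "+"),
                     per_strand(Biostrings::reverseComplement(pat), "-"))
  })
  if (nrow(res) == 0)
    return(tibble::tibble(replicon_id = character(), start = integer(),
                          end = integer(), strand = character()))
  dplyr::arrange(res, .data$replicon_id, .data$start, .data$strand)
}

#' Cluster repeat copies into arrays
#'
#' Consecutive same-strand copies on one replicon chain into an array when
#' the inter-copy gap (`start[i+1] - start[i] - repeat_len`) lies within
#' `[spacer_min, spacer_max]` - the spacer-length signature of a CRISPR
#' array. Arrays with at least `min_array_copies` copies are classified
#' `crispr_array`; smaller chains are `isolated_fragment`.
#'
#' @param copies Tibble from [find_repeat_copies()].
#' @param repeat_len Repeat unit length (bp).
#' @param spacer_min,spacer_max Allowed spacer lengths (bp), defaults 30-40.
#' @param min_array_copies Minimum copies for a `crispr_array` call.
#' @return Array tibble: `array_id`, `replicon_id`, `strand`, `start`,
#'   `end`, `n_copies`, `classification`, `copy_starts` and `spacer_lengths`
#'   (list columns).
#' @export
cluster_arrays <- function(copies, repeat_len, spacer_min = 30,
                           spacer_max = 40, min_array_copies = 3) {
  empty <- tibble::tibble(array_id = character(), replicon_id = character(),
                          strand = character(), start = integer(),
                          end = integer(), n_copies = integer(),
                          classification = character(),
                          copy_starts = list(), spacer_lengths = list())
  if (nrow(copies) == 0) return(empty)
  grp <- dplyr::group_by(dplyr::arrange(copies, .data$start),
                         .data$replicon_id, .data$strand)
  out <- dplyr::group_modify(grp, function(df, key) {
    gaps <- diff(df$start) - repeat_len
    brk <- c(FALSE, gaps < spacer_min | gaps > spacer_max)
    cl <- cumsum(brk)
    purrr::map_dfr(split(seq_len(nrow(df)), cl), function(idx) {
      d <- df[idx, ]
      tibble::tibble(
        start = min(d$start), end = max(d$end), n_copies = nrow(d),
        classification = if (nrow(d) >= min_array_copies) "crispr_array"
                         else "isolated_fragment",
        copy_starts = list(d$start),
        spacer_lengths = list(if (nrow(d) > 1) diff(d$start) - repeat_len
                              else integer()))
    })
  })
  out <- dplyr::arrange(dplyr::ungroup(out), .data$replicon_id, .data$start)
  out$array_id <- sprintf("%s:%d-%d", out$replicon_id, out$start, out$end)
  dplyr::select(out, dplyr::all_of(names(empty)))
}

#' Reconcile IS loci with CRISPR arrays
#'
#' Partial loci whose span lies within a `crispr_array` (extended by
#' `margin` bp on each side) are IS-derived CRISPR repeats, not
#' transposition scars: they are removed from the locus set and logged.
#' The margin absorbs alignments seeded on an array repeat that extend a
#' few bases into flanking background; its default is one spacer length.
#' Complete loci are never removed; repeat copies outside arrays remain
#' partial IS fragments.
#'
#' @param loci Locus tibble (with `status`).
#' @param arrays Array tibble from [cluster_arrays()].
#' @param margin Slack (bp) added to each array end when testing
#'   containment.
#' @return List with `loci` (retained) and `excluded` (removed partials,
#'   with the covering `array_id`).
#' @export
reconcile_crispr <- function(loci, arrays, margin = 40) {
  arrays <- arrays[arrays$classification == "crispr_array", , drop = FALSE]
  if (nrow(loci) == 0 || nrow(arrays) == 0)
    return(list(loci = loci,
                excluded = dplyr::mutate(loci[0, ], array_id = character())))
  covered <- rep(NA_character_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (loci$status[i] != "partial") next
    hit <- which(arrays$replicon_id == loci$replicon_id[i] &
                   arrays$start - margin <= loci$start[i] &
                   arrays$end + margin >= loci$end[i])
    if (length(hit)) covered[i] <- arrays$array_id[hit[1]]
  }
  drop <- !is.na(covered)
  excluded <- dplyr::mutate(loci[drop, ], array_id = covered[drop])
  list(loci = loci[!drop, , drop = FALSE], excluded = excluded)
}

#' Write repeat arrays as GFF3
#'
#' Arrays are written as `direct_repeat` features with `n_copies` and
#' `classification` attributes.
#'
#' @param arrays Array tibble.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_arrays_gff3 <- function(arrays, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = arrays$replicon_id,
    ranges = IRanges::IRanges(arrays$start, arrays$end),
    strand = arrays$strand)
  S4Vectors::mcols(gr)$type <- "direct_repeat"
  S4Vectors::mcols(gr)$source <- "issweep"
  S4Vectors::mcols(gr)$n_copies <- arrays$n_copies
  S4Vectors::mcols(gr)$classification <- arrays$classification
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
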