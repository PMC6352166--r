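#' Read coordinate-sorted alignments from SAM/BAM
#'
#' SAM text is converted to BAM with Rsamtools (htslib) and scanned; the
#' fields the soft-clip caller needs are returned as a tibble.
#'
#' @param path Path to a SAM (or BAM) file with sequence fields present.
#' @return Tibble: `qname`, `flag`, `replicon_id`, `pos`, `mapq`, `cigar`,
#'   `seq`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble::tibble(
    qname = x$qname, flag = x$flag,
    replicon_id = as.character(x$rname), pos = x$pos, mapq = x$mapq,
    cigar = x$cigar, seq = as.character(x$seq))
}

#' Extract soft-clipped read segments
#'
#' One segment is emitted per soft-clipped read end that passes the length
#' and mapping-quality filters. `clip_pos` is the reference coordinate of
#' the last aligned base before a right clip, or the first aligned base
#' after a left clip. Reads with identical (position, CIGAR, sequence) are
#' counted once to avoid PCR-duplicate support inflation.
#'
#' @param alignments Alignment tibble from [read_alignments()] or a path to
#'   a SAM/BAM file.
#' @param min_clip_len Minimum clip length (bp) to retain.
#' @param min_mapq Minimum mapping quality.
#' @return Tibble: `read_id`, `replicon_id`, `clip_pos`, `side`
#'   (`left`/`right`), `clip_seq`.
#' @export
extract_softclips <- function(alignments, min_clip_len = 10, min_mapq = 20) {
  if (is.character(alignments) && length(alignments) == 1)
    alignments <- read_alignments(alignments)
  aln <- alignments
  aln <- aln[!bitwAnd(aln$flag, 4L) & !is.na(aln$pos), , drop = FALSE]
  aln <- aln[aln$mapq >= min_mapq, , drop = FALSE]
  aln <- aln[!duplicated(paste(aln$replicon_id, aln$pos, aln$cigar, aln$seq)),
             , drop = FALSE]
  aln <- aln[grepl("S", aln$cigar, fixed = TRUE), , drop = FALSE]
  empty <- tibble::tibble(read_id = character(), replicon_id = character(),
                          clip_pos = integer(), side = character(),
                          clip_seq = character())
  if (nrow(aln) == 0) return(empty)
  if (any(is.na(aln$seq) | aln$seq == "" | aln$seq == "*"))
    stop("alignment records lack sequence fields", call. = FALSE)
  ops <- stringr::str_match_all(aln$cigar, "(\\d+)([MIDNSHP=X])")
  out <- purrr::map_dfr(seq_len(nrow(aln)), function(i) {
    op <- ops[[i]]
    len <- as.integer(op[, 2]); typ <- op[, 3]
    ref_len <- sum(len[typ %in% c("M", "D", "N", "=", "X")])
    read_len <- nchar(aln$seq[i])
    segs <- NULL
    if (typ[1] == "S" && len[1] >= min_clip_len) {
      segs <- tibble::tibble(
        read_id = aln$qname[i], replicon_id = aln$replicon_id[i],
        clip_pos = aln$pos[i], side = "left",
        clip_seq = substr(aln$seq[i], 1, len[1]))
    }
    n <- length(typ)
    if (typ[n] == "S" && len[n] >= min_clip_len) {
      segs <- dplyr::bind_rows(segs, tibble::tibble(
        read_id = aln$qname[i], replicon_id = aln$replicon_id[i],
        clip_pos = aln$pos[i] + ref_len - 1L, side = "right",
        clip_seq = substr(aln$seq[i], read_len - len[n] + 1L, read_len)))
    }
    segs
  })
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$replicon_id, .data$clip_pos, .data$side)
}

#' Match a clip consensus against IS termini
#'
#' Compares a soft-clip cluster consensus against the first and last
#' `probe_len` bp of each catalog consensus and their reverse complements
#' (local alignment), returning the best-matching IS terminus when its
#' identity reaches `min_identity`.
#'
#' @param clip_consensus Consensus DNA string of a soft-clip cluster
#'   (>= 12 bp).
#' @param catalog IS catalog tibble.
#' @param min_identity Minimum alignment identity.
#' @param probe_len Terminus probe length (bp).
#' @return One-row tibble `is_name`, `terminus` (`5prime`/`3prime`),
#'   `identity`, or a zero-row tibble when nothing matches.
#' @export
match_termini <- function(clip_consensus, catalog, min_identity = 0.90,
                          probe_len = 60) {
  empty <- tibble::tibble(is_name = character(), terminus = character(),
                          identity = double())
  if (nchar(clip_consensus) < 12) return(empty)
  best <- NULL
  for (k in seq_len(nrow(catalog))) {
    cons <- catalog$consensus[k]
    L <- nchar(cons)
    probes <- list(
      `5prime` = substr(cons, 1, min(probe_len, L)),
      `3prime` = substr(cons, max(1L, L - probe_len + 1L), L))
    for (term in names(probes)) {
      for (p in c(probes[[term]], revcomp(probes[[term]]))) {
        a <- sw_oracle(clip_consensus, p, min_score = 10, max_hits = 1)
        if (nrow(a) == 0) next
        # identity over the clip-probe overlap, short alignments penalised
        span <- min(nchar(clip_consensus), nchar(p))
        id <- a$n_match[1] / max(a$n_cols[1], span)
        if (id >= min_identity &&
            (is.null(best) || id > best$identity)) {
          best <- tibble::tibble(is_name = catalog$name[k], terminus = term,
                                 identity = id)
        }
      }
    }
  }
  if (is.null(best)) empty else best
}

# majority-vote consensus of clip sequences anchored at the junction side
clip_consensus <- function(seqs, side) {
  if (length(seqs) == 1) return(seqs)
  if (side == "left") {
    seqs <- vapply(seqs, function(s)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "")
  }
  L <- max(nchar(seqs))
  mat <- vapply(seqs, function(s) {
    c(strsplit(s, "", fixed = TRUE)[[1]], rep(NA, L - nchar(s)))
  }, character(L))
  cons <- apply(matrix(mat, nrow = L), 1, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(NA_character_)
    names(sort(table(col), decreasing = TRUE))[1]
  })
  cons <- cons[!is.na(cons)]
  s <- paste(cons, collapse = "")
  if (side == "left")
    s <- paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  s
}

# chain clip positions into clusters (single linkage, gap <= window)
cluster_positions <- function(pos, window) {
  o <- order(pos)
  brk <- c(FALSE, diff(pos[o]) > window)
  cl <- integer(length(pos))
  cl[o] <- cumsum(brk)
  cl
}

#' Call novel IS insertion sites from soft-clipped segments
#'
#' Segments from one sample are clustered by replicon, side and position
#' (within `cluster_window`); clusters whose clip consensus matches an IS
#' terminus become candidate flanks. A right-side flank (reads running off
#' the left junction into the element) pairs with a left-side flank of the
#' same IS within `tsd_search_window` to form one insertion call; a
#' positive overlap between the flank positions is the inferred target-site
#' duplication length. Calls require both flanks supported by at least
#' `min_support` reads, or a single flank with `2 * min_support` (flagged
#' in `single_flank`).
#'
#' @param segments Segment tibble from [extract_softclips()].
#' @param catalog IS catalog tibble.
#' @param cluster_window Position window (bp) for clustering clips.
#' @param min_support Minimum reads per flank.
#' @param tsd_search_window Maximum distance (bp) between paired flanks.
#' @param min_identity,probe_len Passed to [match_termini()].
#' @return Call tibble: `replicon_id`, `start`, `end`, `is_name`,
#'   `left_support`, `right_support`, `tsd_len`, `single_flank`.
#' @export
call_insertions <- function(segments, catalog, cluster_window = 10,
                            min_support = 4, tsd_search_window = 20,
                            min_identity = 0.90, probe_len = 60) {
  empty <- tibble::tibble(replicon_id = character(), start = integer(),
                          end = integer(), is_name = character(),
                          left_support = integer(), right_support = integer(),
                          tsd_len = integer(), single_flank = logical())
  if (nrow(segments) == 0) return(empty)
  grp <- dplyr::group_by(segments, .data$replicon_id, .data$side)
  clusters <- dplyr::group_modify(grp, function(df, key) {
    cl <- cluster_positions(df$clip_pos, cluster_window)
    purrr::map_dfr(split(df, cl), function(d) {
      pos_tab <- sort(table(d$clip_pos), decreasing = TRUE)
      tibble::tibble(
        position = as.integer(names(pos_tab))[1],
        support = nrow(d),
        consensus = clip_consensus(d$clip_seq, key$side[[1]]))
    })
  })
  clusters <- dplyr::ungroup(clusters)
  matched <- purrr::map_dfr(seq_len(nrow(clusters)), function(i) {
    m <- match_termini(clusters$consensus[i], catalog,
                       min_identity = min_identity, probe_len = probe_len)
    if (nrow(m) == 0) return(NULL)
    dplyr::bind_cols(clusters[i, ], m)
  })
  if (nrow(matched) == 0) return(empty)
  calls <- list()
  used <- rep(FALSE, nrow(matched))
  for (rep_id in unique(matched$replicon_id)) {
    rights <- which(matched$replicon_id == rep_id & matched$side == "right")
    lefts <- which(matched$replicon_id == rep_id & matched$side == "left")
    for (ri in rights) {
      cand <- lefts[!used[lefts] &
                      matched$is_name[lefts] == matched$is_name[ri] &
                      abs(matched$position[lefts] - matched$position[ri]) <=
                        tsd_search_window]
      if (length(cand) == 0) next
      li <- cand[which.min(abs(matched$position[cand] -
                                 matched$position[ri]))]
      if (matched$support[ri] < min_support ||
          matched$support[li] < min_support) next
      p_r <- matched$position[ri]; p_l <- matched$position[li]
      tsd <- p_r - p_l + 1L
      calls[[length(calls) + 1]] <- tibble::tibble(
        replicon_id = rep_id, start = min(p_l, p_r), end = max(p_l, p_r),
        is_name = matched$is_name[ri],
        left_support = matched$support[li],
        right_support = matched$support[ri],
        tsd_len = if (tsd > 0) tsd else NA_integer_,
        single_flank = FALSE)
      used[ri] <- TRUE; used[li] <- TRUE
    }
  }
  # strong single-flank clusters
  singles <- which(!used & matched$support >= 2 * min_support)
  for (si in singles) {
    calls[[length(calls) + 1]] <- tibble::tibble(
      replicon_id = matched$replicon_id[si],
      start = matched$position[si], end = matched$position[si],
      is_name = matched$is_name[si],
      left_support = if (matched$side[si] == "left")
        matched$support[si] else 0L,
      right_support = if (matched$side[si] == "right")
        matched$support[si] else 0L,
      tsd_len = NA_integer_, single_flank = TRUE)
  }
  if (length(calls) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(calls), .data$replicon_id, .data$start)
}

#' Cross-sample presence/absence of insertion sites
#'
#' Builds one row per distinct site from the union of reference loci and
#' per-sample insertion calls, merging sites whose start coordinates fall
#' within `cluster_window`. Columns record presence in the reference and in
#' each sample; a site is novel in a sample when absent from the reference
#' and present in that sample.
#'
#' @param reference_loci Tibble of reference IS loci (columns
#'   `replicon_id`, `start`, `end`, optionally `is_name`).
#' @param calls_by_sample Named list of call tibbles (one per sample).
#' @param cluster_window Site-merging window (bp).
#' @return A presence tibble of class `is_presence`: `replicon_id`,
#'   `start`, `end`, `is_name`, `in_reference`, and one `in_<sample>`
#'   logical column per sample.
#' @export
compare_samples <- function(reference_loci, calls_by_sample,
                            cluster_window = 10) {
  stopifnot(!is.null(names(calls_by_sample)),
            all(names(calls_by_sample) != ""))
  take <- function(df, src) {
    tibble::tibble(
      replicon_id = as.character(df$replicon_id),
      start = as.integer(df$start), end = as.integer(df$end),
      is_name = if ("is_name" %in% names(df)) df$is_name
                else NA_character_,
      source = src)
  }
  sites <- dplyr::bind_rows(
    take(reference_loci, ".reference"),
    purrr::imap_dfr(calls_by_sample, take))
  if (nrow(sites) == 0) {
    out <- tibble::tibble(replicon_id = character(), start = integer(),
                          end = integer(), is_name = character(),
                          in_reference = logical())
    for (s in names(calls_by_sample)) out[[paste0("in_", s)]] <- logical()
    class(out) <- c("is_presence", class(out))
    return(out)
  }
  grp <- dplyr::group_by(sites, .data$replicon_id)
  merged <- dplyr::group_modify(grp, function(df, key) {
    cl <- cluster_positions(df$start, cluster_window)
    purrr::map_dfr(split(df, cl), function(d) {
      row <- tibble::tibble(
        start = min(d$start), end = max(d$end),
        is_name = if (all(is.na(d$is_name))) NA_character_
                  else sort(unique(d$is_name[!is.na(d$is_name)]))[1],
        in_reference = ".reference" %in% d$source)
      for (s in names(calls_by_sample))
        row[[paste0("in_", s)]] <- s %in% d$source
      row
    })
  })
  out <- dplyr::arrange(dplyr::ungroup(merged), .data$replicon_id,
                        .data$start)
  class(out) <- c("is_presence", class(out))
  out
}

#' Count novel insertion sites per sample
#'
#' A site is novel in a sample when it is present in that sample but absent
#' from the reference.
#'
#' @param presence An `is_presence` tibble from [compare_samples()].
#' @param by `"replicon"` (default) for per-replicon counts, `"sample"` for
#'   genome-wide totals.
#' @return Tibble with `sample`, (`replicon_id`,) `n_novel`.
#' @export
count_novel <- function(presence, by = c("replicon", "sample")) {
  by <- match.arg(by)
  samples <- sub("^in_", "", grep("^in_(?!reference$)", names(presence),
                                  perl = TRUE, value = TRUE))
  out <- purrr::map_dfr(samples, function(s) {
    novel <- !presence$in_reference & presence[[paste0("in_", s)]]
    if (by == "replicon") {
      dplyr::count(
        tibble::tibble(sample = s,
                       replicon_id = presence$replicon_id[novel]),
        .data$sample, .data$replicon_id, name = "n_novel", .drop = FALSE)
    } else {
      tibble::tibble(sample = s, n_novel = sum(novel))
    }
  })
  out
}

#' Count novel sites shared between sample pairs
#'
#' @param presence An `is_presence` tibble from [compare_samples()].
#' @return Tibble: `sample_a`, `sample_b`, `replicon_id`, `n_shared` (novel
#'   in both samples).
#' @export
shared_novel <- function(presence) {
  samples <- sub("^in_", "", grep("^in_(?!reference$)", names(presence),
                                  perl = TRUE, value = TRUE))
  if (length(samples) < 2)
    return(tibble::tibble(sample_a = character(), sample_b = character(),
                          replicon_id = character(), n_shared = integer()))
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    shared <- !presence$in_reference &
      presence[[paste0("in_", p[1])]] & presence[[paste0("in_", p[2])]]
    reps <- unique(presence$replicon_id)
    tibble::tibble(
      sample_a = p[1], sample_b = p[2], replicon_id = reps,
      n_shared = vapply(unname(reps), function(r)
        sum(shared & presence$replicon_id == r), integer(1),
        USE.NAMES = FALSE))
  })
}

#' Write insertion calls as BED
#'
#' @param calls Call tibble from [call_insertions()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$replicon_id, start = calls$start - 1L,
                    end = calls$end, name = calls$is_name,
                    score = calls$left_support + calls$right_support,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
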