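#' Per-IS locus counts
#'
#' Counts complete, partial and active loci per (replicon, IS type).
#'
#' @param loci Locus tibble with `status`.
#' @param activity Optional activity tibble from [assess_activity()].
#' @return Tibble: `replicon_id`, `is_name`, `complete`, `partial`,
#'   `active`.
#' @export
count_loci <- function(loci, activity = NULL) {
  if (nrow(loci) == 0)
    return(tibble::tibble(replicon_id = character(), is_name = character(),
                          complete = integer(), partial = integer(),
                          active = integer()))
  counts <- loci |>
    dplyr::count(.data$replicon_id, .data$is_name, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("complete", "partial"))
    if (!col %in% names(counts)) counts[[col]] <- 0L
  act <- if (!is.null(activity) && nrow(activity) > 0) {
    activity |>
      dplyr::filter(.data$verdict == "active") |>
      dplyr::count(.data$replicon_id, .data$is_name, name = "active")
  } else {
    tibble::tibble(replicon_id = character(), is_name = character(),
                   active = integer())
  }
  counts |>
    dplyr::left_join(act, by = c("replicon_id", "is_name")) |>
    dplyr::mutate(active = dplyr::coalesce(.data$active, 0L)) |>
    dplyr::select("replicon_id", "is_name", "complete", "partial",
                  "active") |>
    dplyr::arrange(.data$replicon_id, .data$is_name)
}

#' IS density in copies per Mbp
#'
#' @param count Copy count (complete and partial copies count equally).
#' @param length_bp Replicon length in bp (> 0).
#' @return Copies per Mbp.
#' @export
#' @examples
#' is_density(18, 2e6) # 9
is_density <- function(count, length_bp) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0", call. = FALSE)
  count / (length_bp / 1e6)
}

#' Occupancy and GC of IS loci on a replicon
#'
#' Occupancy is the fraction of replicon bp inside the union of locus
#' intervals (overlaps never double-count). GC is computed over \{G,C\} /
#' \{A,C,G,T\} with N excluded.
#'
#' @param loci Locus tibble for one replicon.
#' @param replicon_seq The replicon sequence (character scalar).
#' @return Tibble: `occupancy`, `gc_is`, `gc_host`.
#' @export
occupancy_and_gc <- function(loci, replicon_seq) {
  L <- nchar(replicon_seq)
  if (nrow(loci) == 0)
    return(tibble::tibble(occupancy = 0, gc_is = NA_real_,
                          gc_host = gc_content(replicon_seq)))
  ir <- IRanges::reduce(IRanges::IRanges(loci$start, pmin(loci$end, L)))
  occ <- sum(IRanges::width(ir)) / L
  is_seq <- paste(substring(replicon_seq, IRanges::start(ir),
                            IRanges::end(ir)), collapse = "")
  tibble::tibble(occupancy = occ, gc_is = gc_content(is_seq),
                 gc_host = gc_content(replicon_seq))
}

#' Per-replicon IS summary
#'
#' Aggregates loci into the per-replicon census: complete/partial/active
#' counts, density in copies per Mbp (complete and partial copies both
#' count), occupancy fraction and GC of IS loci vs host. Density, occupancy
#' and GC require replicon lengths/sequences and are `NA` when `replicons`
#' is not supplied.
#'
#' @param loci Locus tibble (reconciled against CRISPR arrays).
#' @param activity Optional activity tibble.
#' @param replicons Optional replicon tibble (columns `id`, `kind`, `seq`,
#'   `length_bp`).
#' @return Tibble: `replicon_id`, `kind`, `complete`, `partial`, `active`,
#'   `density`, `occupancy`, `gc_is`, `gc_host`.
#' @export
summarize_replicons <- function(loci, activity = NULL, replicons = NULL) {
  counts <- count_loci(loci, activity)
  per_rep <- counts |>
    dplyr::group_by(.data$replicon_id) |>
    dplyr::summarise(complete = sum(.data$complete),
                     partial = sum(.data$partial),
                     active = sum(.data$active), .groups = "drop")
  if (is.null(replicons)) {
    ids <- unique(loci$replicon_id)
    base <- tibble::tibble(replicon_id = ids, kind = NA_character_,
                           length_bp = NA_integer_, seq = NA_character_)
  } else {
    base <- tibble::tibble(replicon_id = replicons$id,
                           kind = replicons$kind,
                           length_bp = replicons$length_bp,
                           seq = replicons$seq)
  }
  out <- base |>
    dplyr::left_join(per_rep, by = "replicon_id") |>
    dplyr::mutate(dplyr::across(c("complete", "partial", "active"),
                                ~ dplyr::coalesce(.x, 0L)))
  extra <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
    n <- out$complete[i] + out$partial[i]
    if (is.na(out$length_bp[i]))
      return(tibble::tibble(density = NA_real_, occupancy = NA_real_,
                            gc_is = NA_real_, gc_host = NA_real_))
    og <- occupancy_and_gc(
      loci[loci$replicon_id == out$replicon_id[i], , drop = FALSE],
      out$seq[i])
    tibble::tibble(density = is_density(n, out$length_bp[i]),
                   occupancy = og$occupancy, gc_is = og$gc_is,
                   gc_host = og$gc_host)
  })
  dplyr::bind_cols(
    dplyr::select(out, "replicon_id", "kind", "complete", "partial",
                  "active"),
    extra)
}
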