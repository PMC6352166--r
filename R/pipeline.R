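#' Scan a genome for IS content
#'
#' End-to-end annotation: nucleotide and translated homology search of the
#' catalog against every replicon, locus building (merge, completeness,
#' TSD, IR), optional CRISPR-repeat filtering, transposase activity
#' assessment of complete loci, and per-replicon summary statistics.
#'
#' When `crispr` is supplied, copies of the designated repeat are located
#' genome-wide; tandem arrays with CRISPR-like spacing are removed from the
#' partial-IS set (logged in `$excluded`), while isolated copies are added
#' to the loci as partial fragments of the source IS.
#'
#' @param replicons Replicon tibble (see [read_replicons()]).
#' @param catalog IS catalog tibble.
#' @param cfg A [search_config()].
#' @param crispr Optional list describing the IS-derived repeat:
#'   `source` (IS name), `slice_start`, `slice_end` (consensus
#'   coordinates), and optionally `spacer_min` (30), `spacer_max` (40),
#'   `min_array_copies` (3), `max_mismatch` (0).
#' @param translated Also run the six-frame translated search (default
#'   TRUE; requires transposase references in the catalog).
#' @param max_gap,complete_cov_min Locus-building parameters (see
#'   [build_loci()]).
#' @return An `is_scan` object: list with `hits`, `loci`, `arrays`,
#'   `excluded`, `activity`, `summary`, `replicons`, `catalog`.
#' @export
scan_genome <- function(replicons, catalog, cfg = search_config(),
                        crispr = NULL, translated = TRUE, max_gap = 100,
                        complete_cov_min = 0.95) {
  hits <- search_nt(replicons, catalog, cfg)
  if (translated) {
    hits <- dplyr::bind_rows(hits, search_translated(replicons, catalog,
                                                     cfg))
  }
  loci <- build_loci(hits, replicons, catalog, max_gap = max_gap,
                     complete_cov_min = complete_cov_min)
  arrays <- NULL
  excluded <- loci[0, ]
  if (!is.null(crispr)) {
    rep_seq <- extract_repeat(catalog, crispr$source, crispr$slice_start,
                              crispr$slice_end)
    copies <- find_repeat_copies(replicons, rep_seq,
                                 max_mismatch = crispr$max_mismatch %||% 0)
    arrays <- cluster_arrays(
      copies, repeat_len = nchar(rep_seq),
      spacer_min = crispr$spacer_min %||% 30,
      spacer_max = crispr$spacer_max %||% 40,
      min_array_copies = crispr$min_array_copies %||% 3)
    rec <- reconcile_crispr(loci, arrays)
    loci <- rec$loci
    excluded <- rec$excluded
    # isolated repeat copies outside arrays and outside existing loci are
    # genuine partial fragments of the source IS
    iso <- arrays[arrays$classification == "isolated_fragment", ,
                  drop = FALSE]
    if (nrow(iso) > 0) {
      keep <- vapply(seq_len(nrow(iso)), function(i) {
        !any(loci$replicon_id == iso$replicon_id[i] &
               loci$start <= iso$end[i] & loci$end >= iso$start[i])
      }, logical(1))
      iso <- iso[keep, , drop = FALSE]
      if (nrow(iso) > 0) {
        clen <- nchar(catalog$consensus[match(crispr$source,
                                              catalog$name)])
        frag <- tibble::tibble(
          locus_id = sprintf("%s:%s:%d-%d", iso$replicon_id,
                             crispr$source, iso$start, iso$end),
          is_name = crispr$source, replicon_id = iso$replicon_id,
          start = iso$start, end = iso$end, strand = iso$strand,
          coverage = nchar(rep_seq) * iso$n_copies / clen,
          n_hits = iso$n_copies, levels = "nucleotide",
          status = "partial", tsd_seq = NA_character_,
          tsd_at_edge = FALSE, ir_evidence = "none")
        loci <- dplyr::arrange(dplyr::bind_rows(loci, frag),
                               .data$replicon_id, .data$start)
      }
    }
  }
  activity <- assess_activity(loci, replicons, catalog,
                              aa_identity_min = cfg$aa_identity_min)
  summary <- summarize_replicons(loci, activity, replicons)
  structure(list(hits = hits, loci = loci,
                 arrays = arrays %||%
                   cluster_arrays(tibble::tibble(replicon_id = character(),
                                                 start = integer(),
                                                 end = integer(),
                                                 strand = character()), 32),
                 excluded = excluded, activity = activity,
                 summary = summary, replicons = replicons,
                 catalog = catalog),
            class = "is_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.is_scan <- function(x, ...) {
  cat("<is_scan>", nrow(x$replicons), "replicon(s),",
      nrow(x$loci), "IS loci (",
      sum(x$loci$status == "complete"), "complete /",
      sum(x$loci$status == "partial"), "partial ),",
      sum(x$activity$verdict == "active"), "active,",
      sum(x$arrays$classification == "crispr_array"),
      "CRISPR array(s) excluded\n")
  invisible(x)
}

#' Tidy an IS scan
#'
#' @param x An `is_scan` object.
#' @param ... Unused.
#' @return The annotated locus tibble joined with activity verdicts.
#' @export
tidy.is_scan <- function(x, ...) {
  dplyr::left_join(
    x$loci,
    dplyr::select(x$activity, "locus_id", "verdict", "reason"),
    by = "locus_id")
}

#' One-row summary of an IS scan
#'
#' @param x An `is_scan` object.
#' @param ... Unused.
#' @return One-row tibble: replicon, locus, completeness, activity and
#'   CRISPR-array totals.
#' @export
glance.is_scan <- function(x, ...) {
  tibble::tibble(
    n_replicons = nrow(x$replicons),
    n_loci = nrow(x$loci),
    n_complete = sum(x$loci$status == "complete"),
    n_partial = sum(x$loci$status == "partial"),
    n_active = sum(x$activity$verdict == "active"),
    n_crispr_arrays = sum(x$arrays$classification == "crispr_array"),
    n_crispr_excluded = nrow(x$excluded))
}

#' Plot IS copy counts per replicon
#'
#' @param object An `is_scan` object.
#' @param ... Unused.
#' @return A ggplot: complete/partial/active counts per replicon.
#' @export
autoplot.is_scan <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("complete", "partial", "active"),
                        names_to = "class", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicon_id, y = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "IS copies", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an insertion-site presence/absence matrix
#'
#' @param object An `is_presence` tibble from [compare_samples()].
#' @param ... Unused.
#' @return A ggplot tile map of sites by sample.
#' @export
autoplot.is_presence <- function(object, ...) {
  cols <- grep("^in_", names(object), value = TRUE)
  df <- object |>
    dplyr::mutate(site = sprintf("%s:%d", .data$replicon_id,
                                 .data$start)) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "sample",
                        values_to = "present") |>
    dplyr::mutate(sample = sub("^in_", "", .data$sample))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$site,
                                   fill = .data$present)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2b8cbe",
                                          `FALSE` = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal()
}
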