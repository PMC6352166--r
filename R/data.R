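# Bundled reference tables: the published IS census of three
# T. thermophilus strains and the ISTth7 soft-clip site coordinates in the
# HB27 reference genome with presence in two laboratory-adapted
# derivatives. Both ship as plain TSV under extdata and are parsed on
# access.

#' IS copy census of *T. thermophilus* HB27, HB8 and NAR1
#'
#' Complete and partial IS copy counts per replicon for the three model
#' strains (chromosome plus megaplasmids pTT27, pVV8, M1, M2). The partial
#' counts for IS1000A/B include the IS-derived 32 bp CRISPR repeats that
#' the pipeline's CRISPR filter is designed to exclude.
#'
#' @return Tibble: `strain`, `replicon`, `kind`, `is_name`, `complete`,
#'   `partial`.
#' @export
thermus_is_census <- function() {
  readr::read_tsv(
    system.file("extdata", "thermus_is_census.tsv", package = "issweep"),
    col_types = "ccccii", progress = FALSE)
}

#' ISTth7 soft-clip sites in the *T. thermophilus* HB27 reference
#'
#' Coordinate ranges where soft-clipped reads matching ISTth7 termini were
#' located on the HB27 chromosome and megaplasmid, with presence in the
#' reference genome and in the two laboratory-adapted derivatives HB27A
#' and HB27E.
#'
#' @return Tibble: `replicon`, `start`, `end`, `in_reference`, `in_HB27A`,
#'   `in_HB27E` (`"YES"`/`"NO"`).
#' @export
istth7_softclip_sites <- function() {
  readr::read_tsv(
    system.file("extdata", "istth7_softclip_sites.tsv",
                package = "issweep"),
    col_types = "ciiccc", progress = FALSE)
}

#' Structural profiles of *Thermus* IS types
#'
#' Family, subgroup, genomic length range, target-site duplication (DR)
#' length, ORF count and catalytic motif class for the IS types recurrent
#' in *Thermus* genomes (ISTth1-8, IS1000A/B, IS421), plus the
#' genus-frequency grade. Where a type's DR length is reported as a range
#' the lower bound is used. ISTth7 is marked split-ORF tolerant: copies
#' encoding the transposase as separate N- and C-terminal ORFs can still be
#' active. Used as the default shape specification for
#' [simulate_catalog()].
#'
#' @return Tibble: `name`, `family`, `subgroup`, `min_len`, `max_len`,
#'   `dr_len`, `orf_count`, `motif`, `split_orf_ok`, `freq_grade`.
#' @export
is_type_profiles <- function() {
  tibble::tribble(
    ~name, ~family, ~subgroup, ~min_len, ~max_len, ~dr_len, ~orf_count,
    ~motif, ~split_orf_ok, ~freq_grade,
    "ISTth1", "IS3", "IS150", 1200L, 1600L, 3L, 2L, "DDE", FALSE, "+",
    "ISTth2", "IS4", "IS10", 1200L, 1350L, 9L, 1L, "DDE", FALSE, "+",
    "ISTth3", "IS1634", "IS4", 1500L, 2000L, 5L, 1L, "DDE", FALSE, "+++",
    "ISTth4", "IS256", NA, 1200L, 1500L, 8L, 1L, "DDE", FALSE, "+++",
    "ISTth5", "IS256", NA, 1200L, 1500L, 0L, 1L, "DDE", FALSE, "+",
    "ISTth6", "IS630", NA, 1000L, 1400L, 2L, 1L, "DDE", FALSE, "++",
    "ISTth7", "IS5", "ISH1", 900L, 1150L, 8L, 1L, "DDE", TRUE, "+++",
    "ISTth8", "IS701", NA, 1400L, 1550L, 4L, 1L, "DDE", FALSE, "++",
    "IS1000A", "IS110", NA, 1136L, 1558L, 2L, 1L, "DEDD", FALSE, "+++",
    "IS1000B", "IS110", NA, 954L, 1558L, 0L, 1L, "DEDD", FALSE, "++",
    "IS421", "IS4", "IS231", 1450L, 5400L, 10L, 1L, "DDE", FALSE, "+")
}

#' Expand a census table into a synthetic locus table
#'
#' Turns per-replicon complete/partial counts into one locus row per copy
#' with placeholder, non-overlapping coordinates, so census tables can be
#' fed through [count_loci()] / [summarize_replicons()].
#'
#' @param census Tibble with columns `replicon` (or `replicon_id`),
#'   `is_name`, `complete`, `partial`, and optionally `strain` (carried
#'   through).
#' @param spacing Placeholder spacing between synthetic loci (bp).
#' @return Locus tibble with `status` per copy.
#' @export
census_to_loci <- function(census, spacing = 2000L) {
  if ("replicon" %in% names(census) && !"replicon_id" %in% names(census))
    census <- dplyr::rename(census, replicon_id = "replicon")
  rows <- purrr::map_dfr(seq_len(nrow(census)), function(i) {
    n_c <- census$complete[i]
    n_p <- census$partial[i]
    status <- c(rep("complete", n_c), rep("partial", n_p))
    if (length(status) == 0) return(NULL)
    out <- tibble::tibble(
      replicon_id = census$replicon_id[i], is_name = census$is_name[i],
      status = status, strand = "+",
      coverage = ifelse(status == "complete", 1, 0.4))
    if ("strain" %in% names(census)) out$strain <- census$strain[i]
    out
  })
  if (is.null(rows) || nrow(rows) == 0)
    return(tibble::tibble(replicon_id = character(), is_name = character(),
                          status = character(), strand = character(),
                          coverage = double(), start = integer(),
                          end = integer(), locus_id = character()))
  rows <- rows |>
    dplyr::group_by(.data$replicon_id,
                    dplyr::across(dplyr::any_of("strain"))) |>
    dplyr::mutate(start = spacing * (dplyr::row_number() - 1L) + 1L,
                  end = .data$start + 999L) |>
    dplyr::ungroup()
  rows$locus_id <- sprintf("%s:%s:%d-%d", rows$replicon_id, rows$is_name,
                           rows$start, rows$end)
  rows
}
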