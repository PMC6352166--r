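#' Search configuration
#'
#' Parameters for the seed-and-extend homology search. The two identity
#' thresholds are the screening criteria used throughout the pipeline: 80%
#' nucleotide identity for BLASTn-style scans and 30% amino-acid identity for
#' BLASTX-style (six-frame translated) scans.
#'
#' @param nt_identity_min Minimum nucleotide identity (matches / aligned
#'   columns, gap columns count as mismatches). Default 0.80.
#' @param aa_identity_min Minimum amino-acid identity for translated hits.
#'   Default 0.30.
#' @param seed_len Exact k-mer seed length for nucleotide search (>= 8).
#' @param aa_seed_len Exact k-mer seed length for protein-level search.
#' @param x_drop Score drop-off terminating ungapped seed extension.
#' @param match,mismatch,gap_open,gap_extend Nucleotide scoring; a gap of
#'   length g scores `gap_open + (g - 1) * gap_extend`.
#' @param aa_gap_open,aa_gap_extend Protein gap scores (BLOSUM62 is used for
#'   substitutions).
#' @param min_hit_len Minimum aligned columns for a nucleotide hit (bp).
#' @param min_aa_hit_len Minimum aligned columns for a translated hit (aa).
#' @param band Half-width of the extension window around a seed diagonal.
#' @param ungapped_trigger Minimum ungapped seed-extension score required to
#'   run the gapped extension (nucleotide level).
#' @param aa_ungapped_trigger As `ungapped_trigger`, for the protein level.
#' @param aa_min_score Minimum BLOSUM62 raw score for a translated hit;
#'   suppresses the short spurious local alignments that random protein
#'   pairs produce at the 30% identity level (BLASTX uses E-values for the
#'   same purpose).
#' @return A `search_config` list.
#' @export
search_config <- function(nt_identity_min = 0.80, aa_identity_min = 0.30,
                          seed_len = 12, aa_seed_len = 3, x_drop = 20,
                          match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2, aa_gap_open = -11,
                          aa_gap_extend = -1, min_hit_len = 50,
                          min_aa_hit_len = 50, band = 32,
                          ungapped_trigger = 35, aa_ungapped_trigger = 45,
                          aa_min_score = 80) {
  stopifnot(nt_identity_min > 0, nt_identity_min <= 1,
            aa_identity_min > 0, aa_identity_min <= 1,
            seed_len >= 8, aa_seed_len >= 2, min_hit_len >= 1)
  structure(list(
    nt_identity_min = nt_identity_min, aa_identity_min = aa_identity_min,
    seed_len = as.integer(seed_len), aa_seed_len = as.integer(aa_seed_len),
    x_drop = as.integer(x_drop), match = as.integer(match),
    mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
    gap_extend = as.integer(gap_extend), aa_gap_open = as.integer(aa_gap_open),
    aa_gap_extend = as.integer(aa_gap_extend),
    min_hit_len = as.integer(min_hit_len),
    min_aa_hit_len = as.integer(min_aa_hit_len), band = as.integer(band),
    ungapped_trigger = as.integer(ungapped_trigger),
    aa_ungapped_trigger = as.integer(aa_ungapped_trigger),
    aa_min_score = as.integer(aa_min_score)
  ), class = "search_config")
}

hit_cols <- function() {
  tibble::tibble(is_name = character(), replicon_id = character(),
                 start = integer(), end = integer(), strand = character(),
                 identity = double(), is_cov = double(), level = character(),
                 score = integer(), qstart = integer(), qend = integer())
}

# min DP score worth reporting, derived from the identity/length thresholds
nt_min_score <- function(cfg) {
  est <- cfg$min_hit_len *
    (cfg$nt_identity_min * cfg$match + (1 - cfg$nt_identity_min) * cfg$mismatch)
  max(2L * cfg$seed_len, as.integer(floor(est * 0.8)))
}

#' Exhaustive local-alignment oracle
#'
#' Exact Smith-Waterman local alignment with affine gaps. Suboptimal,
#' subject-disjoint alignments are enumerated by masking the subject span of
#' each reported alignment and re-running the full dynamic program
#' (Waterman-Eggert style). Deterministic tie-breaks: highest score, then
#' lowest subject end, then lowest query end. Intended as the testing oracle
#' for the seeded search; instances are capped at
#' `nchar(query) * nchar(subject) <= 4e6`.
#'
#' @param query,subject Strings over the same alphabet (DNA or protein).
#' @param match,mismatch,gap_open,gap_extend Scoring (ignored for
#'   substitutions when `submat` is given).
#' @param submat Optional integer substitution matrix with single-letter
#'   dimnames (e.g. BLOSUM62) for protein alignment.
#' @param min_score Minimum alignment score to report.
#' @param max_hits Maximum number of alignments to enumerate.
#' @return Tibble with 1-based inclusive coordinates `qstart`, `qend`,
#'   `sstart`, `send`, plus `score`, `n_match`, `n_cols`, `identity`.
#' @export
sw_oracle <- function(query, subject, match = 2, mismatch = -3,
                      gap_open = -5, gap_extend = -2, submat = NULL,
                      min_score = 1, max_hits = 25) {
  if (as.double(nchar(query)) * nchar(subject) > 4e6)
    stop("instance too large: |query| * |subject| must be <= 4e6",
         call. = FALSE)
  df <- cpp_sw_all(query, subject, match, mismatch, gap_open, gap_extend,
                   submat, as.integer(min_score), as.integer(max_hits))
  tibble::tibble(
    score = df$score,
    qstart = df$qs + 1L, qend = df$qe,
    sstart = df$ss + 1L, send = df$se,
    n_match = df$nmatch, n_cols = df$ncols,
    identity = ifelse(df$ncols > 0, df$nmatch / df$ncols, 0)
  )
}

# best protein-protein local alignment (BLOSUM62); NULL when nothing aligns
protein_align <- function(query, ref, gap_open = -11, gap_extend = -1) {
  if (nchar(query) == 0 || nchar(ref) == 0) return(NULL)
  df <- cpp_sw_all(query, ref, 2L, -2L, as.integer(gap_open),
                   as.integer(gap_extend), blosum62(), 10L, 1L)
  if (nrow(df) == 0) return(NULL)
  list(score = df$score[1], qstart = df$qs[1] + 1L, qend = df$qe[1],
       rstart = df$ss[1] + 1L, rend = df$se[1], nmatch = df$nmatch[1],
       ncols = df$ncols[1],
       identity = if (df$ncols[1] > 0) df$nmatch[1] / df$ncols[1] else 0)
}

search_one_strand <- function(consensus, subject, cfg) {
  cpp_seed_extend(consensus, subject, cfg$seed_len, cfg$match, cfg$mismatch,
                  cfg$gap_open, cfg$gap_extend, NULL, cfg$x_drop, cfg$band,
                  cfg$ungapped_trigger, nt_min_score(cfg), 10000L)
}

#' Nucleotide-level IS search
#'
#' Seed-and-extend local search of each catalog consensus against each
#' replicon, on both strands: exact `seed_len`-mer seeds, ungapped x-drop
#' triage, then gapped extension in a banded window around the seed
#' diagonal. Hits are reported when identity >= `nt_identity_min` over
#' >= `min_hit_len` aligned columns. N bases never match.
#'
#' @param replicons Replicon tibble (columns `id`, `seq`) or a single row.
#' @param catalog IS catalog tibble.
#' @param cfg A [search_config()].
#' @return Hit tibble: `is_name`, `replicon_id`, `start`, `end` (1-based
#'   inclusive), `strand`, `identity`, `is_cov` (fraction of the consensus
#'   covered), `level = "nucleotide"`, `score`, and consensus coordinates
#'   `qstart`/`qend`, sorted by (`replicon_id`, `start`).
#' @export
search_nt <- function(replicons, catalog, cfg = search_config()) {
  res <- purrr::map_dfr(seq_len(nrow(replicons)), function(r) {
    rep_id <- replicons$id[r]
    fwd <- replicons$seq[r]
    rev <- revcomp(fwd)
    L <- nchar(fwd)
    purrr::map_dfr(seq_len(nrow(catalog)), function(k) {
      cons <- catalog$consensus[k]
      clen <- nchar(cons)
      per_strand <- function(subject, strand) {
        df <- search_one_strand(cons, subject, cfg)
        if (nrow(df) == 0) return(NULL)
        start <- df$ss + 1L; end <- df$se
        if (strand == "-") {
          tmp <- L - end + 1L
          end <- L - start + 1L
          start <- tmp
        }
        tibble::tibble(
          is_name = catalog$name[k], replicon_id = rep_id,
          start = start, end = end, strand = strand,
          identity = ifelse(df$ncols > 0, df$nmatch / df$ncols, 0),
          is_cov = (df$qe - df$qs) / clen, level = "nucleotide",
          score = df$score, qstart = df$qs + 1L, qend = df$qe
        )
      }
      dplyr::bind_rows(per_strand(fwd, "+"), per_strand(rev, "-"))
    })
  })
  if (nrow(res) == 0) return(hit_cols())
  res <- dplyr::filter(res, .data$identity >= cfg$nt_identity_min,
                       (.data$end - .data$start + 1L) >= cfg$min_hit_len)
  dplyr::arrange(res, .data$replicon_id, .data$start, .data$end)
}

# map a frame/strand protein interval (1-based aa) back to replicon nt coords
frame_to_nt <- function(astart, aend, frame, strand, L) {
  nt_start <- frame + 3L * (astart - 1L)
  nt_end <- frame + 3L * aend - 1L
  if (strand == "+") c(nt_start, nt_end)
  else c(L - nt_end + 1L, L - nt_start + 1L)
}

#' Translated (six-frame) IS search
#'
#' Emulates a BLASTX-style scan: the replicon is translated in all six
#' frames (translation table 11) and searched against each reference
#' transposase protein with BLOSUM62-scored seed-and-extend alignment. Hits
#' with amino-acid identity >= `aa_identity_min` over >= `min_aa_hit_len`
#' aligned columns are reported in nucleotide coordinates of the replicon,
#' with frame-consistent strand. Consensus coverage (`is_cov`, `qstart`,
#' `qend`) is mapped through the transposase CDS coordinates
#' (`tnp_start`/`tnp_end`) of the catalog record.
#'
#' @inheritParams search_nt
#' @return Hit tibble as in [search_nt()], with `level = "translated"`.
#' @export
search_translated <- function(replicons, catalog, cfg = search_config()) {
  no_ref <- vapply(catalog$tnp_ref, length, 1L) == 0
  if (any(no_ref))
    stop("missing transposase reference for: ",
         paste(catalog$name[no_ref], collapse = ", "), call. = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(replicons)), function(r) {
    rep_id <- replicons$id[r]
    L <- nchar(replicons$seq[r])
    strands <- list(`+` = replicons$seq[r], `-` = revcomp(replicons$seq[r]))
    purrr::map_dfr(c("+", "-"), function(std) {
      s <- strands[[std]]
      purrr::map_dfr(1:3, function(f) {
        prot <- translate_dna(substr(s, f, L))
        if (nchar(prot) < cfg$aa_seed_len) return(NULL)
        purrr::map_dfr(seq_len(nrow(catalog)), function(k) {
          clen <- nchar(catalog$consensus[k])
          purrr::map_dfr(seq_along(catalog$tnp_ref[[k]]), function(ri) {
            ref <- catalog$tnp_ref[[k]][[ri]]
            df <- cpp_seed_extend(ref, prot, cfg$aa_seed_len, 2L, -2L,
                                  cfg$aa_gap_open, cfg$aa_gap_extend,
                                  blosum62(), cfg$x_drop, cfg$band,
                                  cfg$aa_ungapped_trigger,
                                  cfg$aa_min_score, 1000L)
            if (nrow(df) == 0) return(NULL)
            coords <- t(vapply(seq_len(nrow(df)), function(i) {
              frame_to_nt(df$ss[i] + 1L, df$se[i], f, std, L)
            }, integer(2)))
            # consensus interval via the transposase CDS position
            ts <- catalog$tnp_start[k]
            qs <- qe <- rep(NA_integer_, nrow(df))
            if (!is.na(ts)) {
              qs <- ts + 3L * df$qs
              qe <- pmin.int(ts + 3L * df$qe - 1L, clen)
            }
            tibble::tibble(
              is_name = catalog$name[k], replicon_id = rep_id,
              start = coords[, 1], end = coords[, 2], strand = std,
              identity = ifelse(df$ncols > 0, df$nmatch / df$ncols, 0),
              is_cov = (df$qe - df$qs) * 3 / clen, level = "translated",
              score = df$score, qstart = qs, qend = qe,
              aa_len = df$ncols
            )
          })
        })
      })
    })
  })
  if (nrow(res) == 0) return(hit_cols())
  res <- dplyr::filter(res, .data$identity >= cfg$aa_identity_min,
                       .data$aa_len >= cfg$min_aa_hit_len)
  res$aa_len <- NULL
  dplyr::arrange(res, .data$replicon_id, .data$start, .data$end)
}

#' Write hits as GFF3
#'
#' Hits are written as `dispersed_repeat` features with `is_name`,
#' `identity`, `is_cov` and `level` attributes.
#'
#' @param hits Hit tibble from [search_nt()] / [search_translated()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$replicon_id,
    ranges = IRanges::IRanges(hits$start, hits$end),
    strand = hits$strand)
  S4Vectors::mcols(gr)$type <- "dispersed_repeat"
  S4Vectors::mcols(gr)$source <- "issweep"
  S4Vectors::mcols(gr)$is_name <- hits$is_name
  S4Vectors::mcols(gr)$identity <- round(hits$identity, 4)
  S4Vectors::mcols(gr)$is_cov <- round(hits$is_cov, 4)
  S4Vectors::mcols(gr)$level <- hits$level
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
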