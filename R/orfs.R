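#' Find open reading frames
#'
#' Scans all six frames for maximal ORFs under the bacterial genetic code
#' (translation table 11): an ORF runs from the first start codon (ATG, GTG
#' or TTG) after the previous in-frame stop to the next in-frame stop codon
#' (which must lie within the sequence and is included in the coordinates).
#' Nested ORFs from internal start codons are not reported.
#'
#' @param seq A single DNA string.
#' @param min_aa Minimum protein length in amino acids (excluding the stop).
#' @return Tibble with columns `start`, `end` (1-based inclusive nt
#'   coordinates on the input sequence, stop codon included), `frame` (1-3,
#'   on the strand read), `strand`, `aa_len`, `premature_stop` (always
#'   `FALSE` for called ORFs; kept for downstream annotation), `protein`.
#' @export
find_orfs <- function(seq, min_aa = 80) {
  stopifnot(length(seq) == 1)
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  for (std in c("+", "-")) {
    S <- if (std == "+") seq else revcomp(seq)
    if (L < 6) next
    ch <- strsplit(S, "", fixed = TRUE)[[1]]
    cod <- paste0(ch[1:(L - 2)], ch[2:(L - 1)], ch[3:L])
    is_start <- cod %in% c("ATG", "GTG", "TTG")
    is_stop <- cod %in% c("TAA", "TAG", "TGA")
    for (f in 1:3) {
      idx <- seq.int(f, L - 2, by = 3L)
      stops <- idx[is_stop[idx]]
      if (length(stops) == 0) next
      prev_stop <- c(f - 3L, head(stops, -1))
      for (si in seq_along(stops)) {
        cand <- idx[idx > prev_stop[si] & idx < stops[si]]
        cand <- cand[is_start[cand]]
        if (length(cand) == 0) next
        a <- cand[1]
        b <- stops[si] + 2L
        aa_len <- (stops[si] - a) %/% 3L
        if (aa_len < min_aa) next
        if (std == "+") {
          g1 <- a; g2 <- b
        } else {
          g1 <- L - b + 1L; g2 <- L - a + 1L
        }
        out[[length(out) + 1]] <- tibble::tibble(
          start = g1, end = g2, frame = f, strand = std,
          aa_len = aa_len, premature_stop = FALSE,
          protein = translate_dna(substr(S, a, stops[si] - 1L))
        )
      }
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(start = integer(), end = integer(),
                          frame = integer(), strand = character(),
                          aa_len = integer(), premature_stop = logical(),
                          protein = character()))
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$strand)
}
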