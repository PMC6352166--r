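# Small sequence helpers shared across modules. DNA is carried as plain
# uppercase character scalars/vectors over {A,C,G,T,N}; Biostrings does the
# heavy lifting.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of DNA strings
#'
#' N bases are excluded from both numerator and denominator.
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector of GC fractions (NaN for all-N/empty input).
#' @export
gc_content <- function(x) {
  if (length(x) == 0) return(numeric())
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(x),
                                        baseOnly = TRUE)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  rowSums(acgt[, c("C", "G"), drop = FALSE]) / rowSums(acgt)
}

#' Translate DNA with the bacterial genetic code
#'
#' Translates complete codons (trailing partial codons are dropped) using
#' translation table 11. Codons containing N translate to X.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of protein strings.
#' @export
translate_dna <- function(x) {
  if (length(x) == 0) return(character())
  x <- substr(x, 1, nchar(x) - nchar(x) %% 3)
  x[nchar(x) == 0] <- ""
  out <- character(length(x))
  nz <- nchar(x) > 0
  if (any(nz)) {
    aa <- Biostrings::translate(
      Biostrings::DNAStringSet(x[nz]),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "X"
    )
    out[nz] <- as.character(aa)
  }
  out
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-DNA characters (allowed: A,C,G,T,N) at entry %d",
                 what, which(bad)[1]), call. = FALSE)
  }
  invisible(x)
}

# i.i.d. random DNA at a target GC fraction (uses the current RNG stream)
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# BLOSUM62 scoring matrix from Biostrings, loaded once per session
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})
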