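# Independent naive oracles used to cross-check the optimised
# implementations. Deliberately written with different algorithms from the
# package code paths they verify.

# score-only affine-gap local alignment, plain R matrix recurrence
naive_sw_score <- function(q, s, match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2, submat = NULL) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- length(qc); n <- length(sc)
  sub <- function(a, b) {
    if (!is.null(submat)) return(submat[a, b])
    if (a == b && a %in% c("A", "C", "G", "T")) match else mismatch
  }
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] + gap_open, E[i - 1, j] + gap_extend)
      F[i, j] <- max(H[i, j - 1] + gap_open, F[i, j - 1] + gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub(qc[i - 1], sc[j - 1]),
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# enumerate-every-start ORF scan: all starts walk to their next in-frame
# stop; per (strand, stop) only the outermost start is kept
naive_orf_scan <- function(seq, min_aa = 80) {
  res <- list()
  for (std in c("+", "-")) {
    S <- if (std == "+") seq else issweep::revcomp(seq)
    L <- nchar(S)
    if (L < 6) next
    ch <- strsplit(S, "", fixed = TRUE)[[1]]
    cod <- paste0(ch[1:(L - 2)], ch[2:(L - 1)], ch[3:L])
    starts <- which(cod %in% c("ATG", "GTG", "TTG"))
    stops <- which(cod %in% c("TAA", "TAG", "TGA"))
    for (p in starts) {
      fstops <- stops[stops > p & (stops - p) %% 3 == 0]
      if (length(fstops) == 0) next
      q <- fstops[1]
      aa <- (q - p) / 3
      if (aa < min_aa) next
      res[[length(res) + 1]] <- data.frame(strand = std, p = p, q = q,
                                           aa = aa)
    }
  }
  if (length(res) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), aa_len = integer()))
  df <- do.call(rbind, res)
  # outermost start per stop
  df <- df[order(df$p), ]
  df <- df[!duplicated(df[, c("strand", "q")]), ]
  out <- data.frame(strand = df$strand, aa_len = df$aa)
  L <- nchar(seq)
  out$start <- ifelse(df$strand == "+", df$p, L - (df$q + 2) + 1)
  out$end <- ifelse(df$strand == "+", df$q + 2, L - df$p + 1)
  out <- out[order(out$start, out$strand), c("start", "end", "strand",
                                             "aa_len")]
  rownames(out) <- NULL
  out
}

# sliding-window Hamming scan on both strands
naive_repeat_scan <- function(seq, pat, max_mm = 0) {
  hits <- list()
  L <- nchar(seq)
  sv <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (std in c("+", "-")) {
    p <- if (std == "+") pat else issweep::revcomp(pat)
    k <- nchar(p)
    if (L < k) next
    pv <- strsplit(p, "", fixed = TRUE)[[1]]
    mm <- integer(L - k + 1)
    for (t in seq_len(k))
      mm <- mm + (sv[t:(L - k + t)] != pv[t] | sv[t:(L - k + t)] == "N")
    pos <- which(mm <= max_mm)
    if (length(pos))
      hits[[length(hits) + 1]] <- data.frame(start = pos, end = pos + k - 1,
                                             strand = std)
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  df <- do.call(rbind, hits)
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# brute-force interval-union length via position bitmap
bitmap_union <- function(starts, ends, L = max(ends)) {
  hit <- logical(L)
  for (i in seq_along(starts)) hit[starts[i]:ends[i]] <- TRUE
  sum(hit)
}

# random DNA string (uniform base composition)
rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# mutate a sequence to a target identity by random substitutions, with
# optional random 1-bp indels
mutate_copy <- function(s, identity, n_indel = 0) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  nm <- round((1 - identity) * length(v))
  if (nm > 0) {
    idx <- sample(length(v), nm)
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  if (n_indel > 0) {
    for (q in seq_len(n_indel)) {
      p <- sample(length(v), 1)
      v <- if (stats::runif(1) < 0.5) v[-p]
           else append(v, sample(c("A", "C", "G", "T"), 1), after = p)
    }
  }
  paste(v, collapse = "")
}

# mutate a protein to an approximate target identity
mutate_protein <- function(p, identity) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  v <- strsplit(p, "", fixed = TRUE)[[1]]
  nm <- round((1 - identity) * length(v))
  if (nm > 0) {
    idx <- sample(2:length(v), nm)
    v[idx] <- vapply(v[idx], function(b) sample(setdiff(aa20, b), 1), "")
  }
  paste(v, collapse = "")
}
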