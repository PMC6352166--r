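#' Assess transposase activity of complete loci
#'
#' A complete locus is called putatively `active` when its ORFs restore a
#' full-length transposase:
#'
#' * `full_orf` - a single ORF aligns to a reference transposase covering at
#'   least `ref_cov_min` (default 90%) of the reference length at amino-acid
#'   identity >= `aa_identity_min`; for two-ORF IS types every reference
#'   protein must be covered this way.
#' * `split_orf_pair` - for split-ORF-tolerant types (`split_orf_ok`), two
#'   same-strand ORFs in translation order jointly cover >= `ref_cov_min` of
#'   the reference, the first matching its N-terminal and the second its
#'   C-terminal region, overlapping by at most `max_pair_overlap` aa.
#'
#' Otherwise the locus is `inactive` with a reason: `truncated` (no ORF, or
#' best coverage short of the threshold), `frameshift` (two ORFs in
#' different frames jointly cover the reference but fail the split-ORF
#' rules), or `interrupted` (joint coverage reached only by ORFs on opposite
#' strands or separated on the reference). DDE/DEDD motif content is
#' reported as an annotation and never changes the verdict.
#'
#' @param loci Annotated locus tibble; only `status == "complete"` rows are
#'   assessed.
#' @param replicons Replicon tibble.
#' @param catalog IS catalog tibble.
#' @param min_aa Minimum ORF length passed to [find_orfs()].
#' @param ref_cov_min Reference coverage required for an active call.
#' @param max_pair_overlap Maximum reference overlap (aa) between a split
#'   ORF pair.
#' @param aa_identity_min Minimum amino-acid identity for an ORF-reference
#'   alignment to count.
#' @param motif_gap_min,motif_gap_max Spacing window (aa) between successive
#'   catalytic residues for the motif annotation.
#' @return Tibble: `locus_id`, `is_name`, `replicon_id`, `verdict`,
#'   `reason`, `motif_class`, `motif_found`.
#' @export
assess_activity <- function(loci, replicons, catalog, min_aa = 80,
                            ref_cov_min = 0.90, max_pair_overlap = 30,
                            aa_identity_min = 0.30, motif_gap_min = 40,
                            motif_gap_max = 160) {
  empty <- tibble::tibble(locus_id = character(), is_name = character(),
                          replicon_id = character(), verdict = character(),
                          reason = character(), motif_class = character(),
                          motif_found = logical())
  loci <- loci[loci$status == "complete", , drop = FALSE]
  if (nrow(loci) == 0) return(empty)
  seqs <- setNames(replicons$seq, replicons$id)
  purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    rec <- catalog[match(loci$is_name[i], catalog$name), ]
    lseq <- substr(seqs[[loci$replicon_id[i]]], loci$start[i], loci$end[i])
    if (loci$strand[i] == "-") lseq <- revcomp(lseq)
    orfs <- find_orfs(lseq, min_aa = min_aa)
    call <- activity_call(orfs, rec, ref_cov_min, max_pair_overlap,
                          aa_identity_min)
    motif_found <- FALSE
    if (rec$motif %in% c("DDE", "DEDD") && nrow(orfs) > 0) {
      motif_found <- any(vapply(orfs$protein, function(p) {
        motif_check(p, rec$motif, gap_min = motif_gap_min,
                    gap_max = motif_gap_max)$found
      }, logical(1)))
    }
    tibble::tibble(locus_id = loci$locus_id[i], is_name = loci$is_name[i],
                   replicon_id = loci$replicon_id[i],
                   verdict = call$verdict, reason = call$reason,
                   motif_class = rec$motif, motif_found = motif_found)
  })
}

# core verdict logic on locus-local ORFs (consensus orientation)
activity_call <- function(orfs, rec, ref_cov_min, max_pair_overlap,
                          aa_identity_min) {
  refs <- rec$tnp_ref[[1]]
  if (length(refs) == 0)
    return(list(verdict = "inactive", reason = "motif_absent_note"))
  if (nrow(orfs) == 0)
    return(list(verdict = "inactive", reason = "truncated"))
  # alignments of every ORF against every reference
  aln <- purrr::map_dfr(seq_len(nrow(orfs)), function(oi) {
    purrr::map_dfr(seq_along(refs), function(ri) {
      a <- protein_align(orfs$protein[oi], refs[[ri]])
      if (is.null(a) || a$identity < aa_identity_min) return(NULL)
      tibble::tibble(orf = oi, ref = ri, rstart = a$rstart, rend = a$rend,
                     cov = (a$rend - a$rstart + 1) / nchar(refs[[ri]]),
                     identity = a$identity)
    })
  })
  if (nrow(aln) == 0)
    return(list(verdict = "inactive", reason = "truncated"))
  full <- vapply(seq_along(refs), function(ri) {
    any(aln$cov[aln$ref == ri] >= ref_cov_min)
  }, logical(1))
  if (all(full))
    return(list(verdict = "active", reason = "full_orf"))
  if (isTRUE(rec$split_orf_ok) && length(refs) == 1) {
    reflen <- nchar(refs[[1]])
    cand <- aln[aln$ref == 1, ]
    if (nrow(cand) >= 2) {
      for (a1 in seq_len(nrow(cand))) {
        for (a2 in seq_len(nrow(cand))) {
          if (a1 == a2) next
          o1 <- cand$orf[a1]; o2 <- cand$orf[a2]
          if (orfs$strand[o1] != orfs$strand[o2]) next
          # translation order: ascending start on +, descending on -
          in_order <- if (orfs$strand[o1] == "+")
            orfs$start[o1] < orfs$start[o2]
          else orfs$start[o1] > orfs$start[o2]
          if (!in_order) next
          if (cand$rstart[a1] > cand$rstart[a2]) next # N before C
          overlap <- cand$rend[a1] - cand$rstart[a2] + 1
          if (overlap > max_pair_overlap) next
          joint <- consensus_union(c(cand$rstart[a1], cand$rstart[a2]),
                                   c(cand$rend[a1], cand$rend[a2]))
          if (joint / reflen >= ref_cov_min)
            return(list(verdict = "active", reason = "split_orf_pair"))
        }
      }
    }
  }
  # diagnose the failure mode from joint coverage across ORFs
  joint_all <- consensus_union(
    aln$rstart + (aln$ref - 1) * 1e6, aln$rend + (aln$ref - 1) * 1e6)
  total_ref <- sum(nchar(refs))
  if (joint_all / total_ref >= ref_cov_min) {
    same_strand <- length(unique(orfs$strand[unique(aln$orf)])) == 1
    frames <- unique(paste(orfs$strand[unique(aln$orf)],
                           orfs$frame[unique(aln$orf)]))
    if (same_strand && length(frames) > 1)
      return(list(verdict = "inactive", reason = "frameshift"))
    return(list(verdict = "inactive", reason = "interrupted"))
  }
  list(verdict = "inactive", reason = "truncated")
}

#' Check a transposase catalytic motif
#'
#' Looks for the ordered acidic-residue pattern of the motif class - D..D..E
#' for DDE, D..E..D..D for DEDD - with each successive catalytic residue
#' separated by `gap_min` to `gap_max` amino acids. Advisory annotation
#' only; activity verdicts never depend on it.
#'
#' @param protein A single protein string.
#' @param motif_class `"DDE"` or `"DEDD"`.
#' @param gap_min,gap_max Allowed spacing (aa) between successive residues.
#' @return List with `found` (logical) and `positions` (integer vector of
#'   the first, leftmost-greedy solution; empty when not found).
#' @export
motif_check <- function(protein, motif_class = c("DDE", "DEDD"),
                        gap_min = 40, gap_max = 160) {
  motif_class <- match.arg(motif_class)
  residues <- strsplit(motif_class, "", fixed = TRUE)[[1]]
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  pos_of <- lapply(c(D = "D", E = "E"), function(a) which(ch == a))
  found <- function(prefix, level) {
    if (level > length(residues)) return(prefix)
    cand <- pos_of[[residues[level]]]
    if (level > 1) {
      last <- prefix[length(prefix)]
      cand <- cand[cand - last >= gap_min & cand - last <= gap_max]
    }
    for (p in cand) {
      r <- found(c(prefix, p), level + 1)
      if (!is.null(r)) return(r)
    }
    NULL
  }
  res <- found(integer(), 1)
  list(found = !is.null(res),
       positions = if (is.null(res)) integer() else res)
}
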