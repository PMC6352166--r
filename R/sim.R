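# Ground-truthed simulator: synthetic IS catalogs, multi-replicon genomes
# with planted complete/partial copies and CRISPR-like repeat arrays,
# derived strains with novel insertions, and junction-aware read alignments
# synthesised directly from the known junctions (no external mapper).

# deterministic GC-leaning codon per amino acid (identical under code 11)
aa_codon <- c(A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC",
              Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
              L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCG",
              S = "TCC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

reverse_translate <- function(protein) {
  paste(aa_codon[strsplit(protein, "", fixed = TRUE)[[1]]], collapse = "")
}

# residue frequencies lean on Ala/Gly/Arg/Pro (GC-rich codons), typical of
# thermophile proteomes, so coding segments sit near host GC
aa_weights <- c(A = 2, R = 1.8, N = 1, D = 1, C = 1, Q = 1, E = 1, G = 1.8,
                H = 1, I = 1, L = 1, K = 1, M = 1, F = 1, P = 1.2, S = 1,
                T = 1, W = 1, Y = 1, V = 1)

random_protein <- function(n_aa, motif = c("DDE", "DEDD", "unknown")) {
  motif <- match.arg(motif)
  aa <- sample(names(aa_codon), n_aa, replace = TRUE,
               prob = aa_weights[names(aa_codon)])
  aa[1] <- "M"
  plant <- function(positions, residues) {
    aa[positions] <<- residues
    # keep the motif unambiguous: no stray catalytic residues between sites
    guard <- setdiff(seq(min(positions), max(positions)), positions)
    aa[guard] <<- sample(setdiff(names(aa_codon), c("D", "E")),
                         length(guard), replace = TRUE)
  }
  if (motif == "DDE" && n_aa >= 260) {
    p1 <- max(20, round(n_aa * 0.3))
    plant(c(p1, p1 + 90, p1 + 150), c("D", "D", "E"))
  } else if (motif == "DEDD" && n_aa >= 280) {
    p1 <- max(20, round(n_aa * 0.2))
    plant(p1 + c(0, 55, 110, 165), c("D", "E", "D", "D"))
  }
  paste(aa, collapse = "")
}

#' Simulate an IS catalog
#'
#' Generates a fully synthetic IS catalog whose records have the structural
#' anatomy the pipeline expects: 25 bp terminal inverted repeats (the right
#' IR the reverse complement of the left), one or two transposase CDSs with
#' the declared DDE/DEDD catalytic motif planted at field-typical spacings,
#' and family-typical lengths and target-site-duplication lengths. The
#' consensus sequences are random (host-like GC) and carry no real IS
#' sequence.
#'
#' @param types Tibble describing the types to generate, with columns
#'   `name`, `family`, `subgroup`, `min_len`, `max_len`, `dr_len`,
#'   `orf_count`, `motif`, `split_orf_ok`, `consensus_len`. Defaults to
#'   three contrasting profiles from [is_type_profiles()]: an ISTth7-like
#'   IS5-family element (8 bp TSD, split-ORF tolerant), an ISTth4-like
#'   IS256-family element, and an IS1000B-like IS110-family element (no
#'   TSD, DEDD motif).
#' @param gc Background GC of non-coding consensus segments.
#' @param seed Integer seed; the catalog is reproducible from it.
#' @return A validated IS catalog tibble (see [is_catalog]).
#' @export
simulate_catalog <- function(types = NULL, gc = 0.681, seed = 1) {
  if (is.null(types)) {
    prof <- is_type_profiles()
    types <- prof[prof$name %in% c("ISTth7", "ISTth4", "IS1000B"), ]
  }
  if (!"consensus_len" %in% names(types))
    types$consensus_len <- pmax(
      types$min_len,
      pmin(types$max_len, round((types$min_len + types$max_len) / 2)))
  if (!"split_orf_ok" %in% names(types)) types$split_orf_ok <- FALSE
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(types)), function(i) {
      t <- types[i, ]
      L <- t$consensus_len
      ir_len <- 25L
      ir_left <- random_dna(ir_len, gc)
      ir_right <- revcomp(ir_left)
      n_orf <- t$orf_count
      budget <- L - 2L * ir_len - 30L * (n_orf + 1L)
      aa_each <- (budget %/% n_orf) %/% 3L - 2L
      prot <- vapply(seq_len(n_orf), function(j) {
        random_protein(aa_each, t$motif)
      }, "")
      cds <- vapply(prot, function(p)
        paste0(reverse_translate(p), "TGA"), "")
      pad_total <- L - 2L * ir_len - sum(nchar(cds))
      pads <- c(pad_total %/% 2L, rep(30L, n_orf - 1L))
      pads <- c(pads, pad_total - sum(pads))
      body <- ir_left
      tnp_start <- NA_integer_
      for (j in seq_len(n_orf)) {
        body <- paste0(body, random_dna(pads[j], gc))
        if (j == 1) tnp_start <- nchar(body) + 1L
        body <- paste0(body, cds[j])
      }
      body <- paste0(body, random_dna(pads[n_orf + 1L], gc), ir_right)
      stopifnot(nchar(body) == L)
      tibble::tibble(
        name = t$name, family = t$family, subgroup = t$subgroup,
        min_len = t$min_len, max_len = t$max_len, dr_len = t$dr_len,
        orf_count = t$orf_count, motif = t$motif,
        ir_left = ir_left, ir_right = ir_right,
        split_orf_ok = t$split_orf_ok,
        tnp_start = tnp_start, tnp_end = tnp_start + nchar(cds[1]) - 1L,
        consensus = body, length = L,
        tnp_ref = list(setNames(prot, paste0(t$name, "_", seq_len(n_orf)))))
    })
    validate_catalog(rows)
  })
}

#' Simulate a multi-replicon genome with planted IS copies
#'
#' Background bases are i.i.d. at the target GC (the host-like default is
#' 68.1%). Complete copies are planted with intact termini and, for types
#' with `dr_len > 0`, a target-site duplication copied from the
#' pre-insertion flank. Partial copies (scars) are contiguous consensus
#' fragments at the configured truncation fraction. CRISPR-like arrays are
#' tandem copies of a short slice of a designated IS separated by
#' random-length spacers. Planted elements are separated by at least
#' `min_separation` bp of background. Fully reproducible from `seed`.
#'
#' @param catalog IS catalog tibble.
#' @param replicon_plan Tibble `id`, `kind`, `length_bp` (background length
#'   before insertions).
#' @param is_plan Tibble `replicon_id`, `is_name`, `status`
#'   (`complete`/`partial`), `truncation` (fraction of the consensus kept
#'   for partials), `strand`.
#' @param crispr_plan Optional tibble `replicon_id`, `source` (IS name),
#'   `slice_start`, `slice_end` (repeat coordinates on the source
#'   consensus), `n_copies`, `spacer_min`, `spacer_max`.
#' @param gc Background GC fraction.
#' @param min_separation Minimum background gap between planted elements.
#' @param seed Integer seed.
#' @return List of class `is_sim`: `replicons` (tibble), `truth` (list with
#'   `loci` and `arrays` tibbles), `catalog`, `gc`.
#' @export
simulate_genome <- function(catalog, replicon_plan, is_plan = NULL,
                            crispr_plan = NULL, gc = 0.681,
                            min_separation = 500, seed = 1) {
  withr::with_seed(seed, {
    truth_loci <- list()
    truth_arrays <- list()
    reps <- purrr::map_dfr(seq_len(nrow(replicon_plan)), function(r) {
      rid <- replicon_plan$id[r]
      L0 <- replicon_plan$length_bp[r]
      bg <- random_dna(L0, gc)
      elems <- list()
      if (!is.null(is_plan)) {
        pl <- is_plan[is_plan$replicon_id == rid, , drop = FALSE]
        for (i in seq_len(nrow(pl))) {
          k <- match(pl$is_name[i], catalog$name)
          stopifnot(!is.na(k))
          cons <- catalog$consensus[k]
          strand <- if ("strand" %in% names(pl) && !is.na(pl$strand[i]))
            pl$strand[i] else sample(c("+", "-"), 1)
          if (pl$status[i] == "complete") {
            frag <- cons
            fs <- 1L; fe <- nchar(cons)
          } else {
            frac <- if ("truncation" %in% names(pl) &&
                        !is.na(pl$truncation[i])) pl$truncation[i] else 0.4
            keep <- max(60L, round(frac * nchar(cons)))
            if (sample(c(TRUE, FALSE), 1)) {
              fs <- 1L; fe <- keep
            } else {
              fs <- nchar(cons) - keep + 1L; fe <- nchar(cons)
            }
            frag <- substr(cons, fs, fe)
          }
          seq_out <- if (strand == "-") revcomp(frag) else frag
          elems[[length(elems) + 1]] <- list(
            type = "locus", is_name = pl$is_name[i],
            status = pl$status[i], strand = strand, seq = seq_out,
            dr_len = if (pl$status[i] == "complete") catalog$dr_len[k]
                     else 0L,
            frag_start = fs, frag_end = fe,
            coverage = (fe - fs + 1) / nchar(cons))
        }
      }
      if (!is.null(crispr_plan)) {
        cp <- crispr_plan[crispr_plan$replicon_id == rid, , drop = FALSE]
        for (i in seq_len(nrow(cp))) {
          rep_seq <- extract_repeat(catalog, cp$source[i],
                                    cp$slice_start[i], cp$slice_end[i])
          spacers <- sample(cp$spacer_min[i]:cp$spacer_max[i],
                            cp$n_copies[i] - 1L, replace = TRUE)
          block <- rep_seq
          for (sp in spacers)
            block <- paste0(block, random_dna(sp, gc), rep_seq)
          elems[[length(elems) + 1]] <- list(
            type = "array", is_name = cp$source[i], seq = block,
            n_copies = cp$n_copies[i], repeat_seq = rep_seq,
            spacers = spacers, dr_len = 0L)
        }
      }
      k <- length(elems)
      if (k == 0)
        return(tibble::tibble(id = rid, kind = replicon_plan$kind[r],
                              seq = bg, length_bp = nchar(bg)))
      elems <- elems[sample(k)]
      g <- min_separation + 50L
      slack <- L0 - 1200L - (k - 1L) * g
      if (slack <= k)
        stop("planted elements do not fit in replicon '", rid,
             "' with the separation constraint", call. = FALSE)
      u <- sort(sample.int(slack, k))
      p <- 600L + u + (seq_len(k) - 1L) * g
      pieces <- character(0)
      prev <- 0L
      delta <- 0L
      for (i in seq_len(k)) {
        e <- elems[[i]]
        pieces <- c(pieces, substr(bg, prev + 1L, p[i]))
        ins <- e$seq
        tsd <- NA_character_
        t <- e$dr_len
        if (!is.null(t) && t > 0) {
          tsd <- substr(bg, p[i] - t + 1L, p[i])
          ins <- paste0(ins, tsd)
        } else {
          t <- 0L
        }
        start <- p[i] + delta + 1L
        end <- start + nchar(e$seq) - 1L
        if (e$type == "locus") {
          truth_loci[[length(truth_loci) + 1]] <<- tibble::tibble(
            replicon_id = rid, is_name = e$is_name, start = start,
            end = end, strand = e$strand, status = e$status,
            coverage = e$coverage, tsd_seq = tsd,
            frag_start = e$frag_start, frag_end = e$frag_end)
        } else {
          truth_arrays[[length(truth_arrays) + 1]] <<- tibble::tibble(
            replicon_id = rid, start = start, end = end,
            source = e$is_name, n_copies = e$n_copies,
            repeat_seq = e$repeat_seq)
        }
        pieces <- c(pieces, ins)
        delta <- delta + nchar(ins)
        prev <- p[i]
      }
      pieces <- c(pieces, substr(bg, prev + 1L, L0))
      seq_final <- paste(pieces, collapse = "")
      tibble::tibble(id = rid, kind = replicon_plan$kind[r],
                     seq = seq_final, length_bp = nchar(seq_final))
    })
    structure(list(
      replicons = reps,
      truth = list(
        loci = if (length(truth_loci)) dplyr::bind_rows(truth_loci)
               else tibble::tibble(),
        arrays = if (length(truth_arrays)) dplyr::bind_rows(truth_arrays)
                 else tibble::tibble()),
      catalog = catalog, gc = gc), class = "is_sim")
  })
}

#' Derive a strain by planting novel IS insertions
#'
#' Inserts the full IS consensus (plus a target-site duplication of the
#' type's `dr_len`) after each requested parent coordinate. Insertion sites
#' must be at least 500 bp apart and must not fall inside intervals given
#' in `avoid`.
#'
#' @param replicons Parent replicon tibble.
#' @param insertions Tibble `replicon_id`, `site` (1-based parent
#'   coordinate; the element is inserted after it), `is_name`, optional
#'   `strand`.
#' @param catalog IS catalog tibble.
#' @param avoid Optional tibble of intervals (`replicon_id`, `start`,
#'   `end`) that sites must not fall inside (e.g. existing loci).
#' @return List: `replicons` (derived), `truth` - one row per insertion
#'   with `site`, `tsd_len`, the expected soft-clip flank coordinates
#'   `left_flank` (first reference base after the insertion, left-side
#'   clips) and `right_flank` (last reference base before it, right-side
#'   clips), and the derived-coordinate interval of the inserted element
#'   (`is_start_d`, `is_end_d`).
#' @export
derive_strain <- function(replicons, insertions, catalog, avoid = NULL) {
  if (nrow(insertions) == 0)
    return(list(replicons = replicons,
                truth = tibble::tibble(
                  replicon_id = character(), site = integer(),
                  is_name = character(), tsd_len = integer(),
                  left_flank = integer(), right_flank = integer(),
                  is_start_d = integer(), is_end_d = integer())))
  insertions <- dplyr::arrange(insertions, .data$replicon_id, .data$site)
  for (rid in unique(insertions$replicon_id)) {
    s <- insertions$site[insertions$replicon_id == rid]
    if (length(s) > 1 && any(diff(s) < 500))
      stop("insertion sites on '", rid, "' closer than 500 bp",
           call. = FALSE)
    if (!is.null(avoid)) {
      av <- avoid[avoid$replicon_id == rid, , drop = FALSE]
      for (x in s)
        if (any(av$start <= x & av$end >= x))
          stop("insertion site ", x, " on '", rid,
               "' falls inside an existing locus", call. = FALSE)
    }
  }
  truth <- list()
  reps <- replicons
  for (rid in unique(insertions$replicon_id)) {
    r <- match(rid, reps$id)
    stopifnot(!is.na(r))
    s <- reps$seq[r]
    ins <- insertions[insertions$replicon_id == rid, , drop = FALSE]
    delta <- 0L
    pieces <- character(0)
    prev <- 0L
    for (i in seq_len(nrow(ins))) {
      k <- match(ins$is_name[i], catalog$name)
      stopifnot(!is.na(k))
      elem <- catalog$consensus[k]
      strand <- if ("strand" %in% names(ins) && !is.na(ins$strand[i]))
        ins$strand[i] else "+"
      if (strand == "-") elem <- revcomp(elem)
      t <- catalog$dr_len[k]
      site <- ins$site[i]
      tsd <- if (t > 0) substr(s, site - t + 1L, site) else ""
      pieces <- c(pieces, substr(s, prev + 1L, site), elem, tsd)
      truth[[length(truth) + 1]] <- tibble::tibble(
        replicon_id = rid, site = site, is_name = ins$is_name[i],
        tsd_len = t,
        left_flank = if (t > 0) site - t + 1L else site + 1L,
        right_flank = site,
        is_start_d = site + delta + 1L,
        is_end_d = site + delta + nchar(elem))
      delta <- delta + nchar(elem) + t
      prev <- site
    }
    pieces <- c(pieces, substr(s, prev + 1L, nchar(s)))
    reps$seq[r] <- paste(pieces, collapse = "")
    reps$length_bp[r] <- nchar(reps$seq[r])
  }
  list(replicons = reps, truth = dplyr::bind_rows(truth))
}

#' Simulate junction-aware read alignments against a parent genome
#'
#' Read start positions are uniform over the derived genome at the
#' configured coverage. Reads fully inside conserved segments emit
#' full-match CIGARs at parent coordinates; reads straddling a novel
#' junction emit soft-clipped CIGARs with the clipped portion taken from
#' the inserted element; reads fully inside an inserted element are
#' unmapped. Substitution errors are i.i.d. at `error_rate`. Deterministic
#' per seed; records are coordinate-sorted.
#'
#' @param derived Derived replicon tibble (from [derive_strain()]).
#' @param parent Parent replicon tibble.
#' @param truth Insertion truth tibble from [derive_strain()].
#' @param read_len Read length (>= 50).
#' @param coverage Target mean coverage (> 0).
#' @param error_rate Per-base substitution probability.
#' @param min_anchor Minimum aligned bases for a clipped read to be
#'   reported as mapped (shorter anchors are emitted unmapped, as a real
#'   mapper would place them elsewhere or not at all).
#' @param seed Integer seed.
#' @return Alignment tibble (`qname`, `flag`, `replicon_id`, `pos`,
#'   `mapq`, `cigar`, `seq`), mapped records coordinate-sorted, unmapped
#'   records last.
#' @export
simulate_alignments <- function(derived, parent, truth, read_len = 150,
                                coverage = 30, error_rate = 0,
                                min_anchor = 20, seed = 1) {
  stopifnot(read_len >= 50)
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(derived)), function(r) {
      rid <- derived$id[r]
      dseq <- derived$seq[r]
      Ld <- nchar(dseq)
      ins <- truth[truth$replicon_id == rid, , drop = FALSE]
      ins <- dplyr::arrange(ins, .data$is_start_d)
      n_ins <- nrow(ins)
      ins_len <- (ins$is_end_d - ins$is_start_d + 1L) + ins$tsd_len
      block_end <- c(0L, ins$is_end_d + ins$tsd_len)
      block_shift <- c(0L, as.integer(cumsum(ins_len)))
      map_d2p <- function(x) {
        px <- x - block_shift[findInterval(x, block_end + 1L)]
        # inside a TSD copy the parent coordinate folds back onto the site
        for (j in seq_len(n_ins)) {
          if (ins$tsd_len[j] == 0) next
          idx <- x > ins$is_end_d[j] & x <= ins$is_end_d[j] + ins$tsd_len[j]
          px[idx] <- ins$site[j] - ins$tsd_len[j] + (x[idx] - ins$is_end_d[j])
        }
        px
      }
      n_reads <- max(1L, round(coverage * Ld / read_len))
      r1 <- sample.int(Ld - read_len + 1L, n_reads, replace = TRUE)
      r2 <- r1 + read_len - 1L
      seqs <- substring(dseq, r1, r2)
      if (error_rate > 0)
        seqs <- vapply(seqs, add_subs, "", rate = error_rate,
                       USE.NAMES = FALSE)
      flag <- sample(c(0L, 16L), n_reads, replace = TRUE)
      pos <- map_d2p(r1)
      cigar <- rep(paste0(read_len, "M"), n_reads)
      if (n_ins > 0) {
        j <- findInterval(r2, ins$is_start_d)
        j[j == 0] <- NA_integer_
        ovl <- !is.na(j) & ins$is_end_d[j] >= r1
        a <- ins$is_start_d[j]
        b <- ins$is_end_d[j]
        # read enters the element from the left: right soft clip
        left_side <- ovl & r1 < a
        m <- a - r1
        cl <- r2 - a + 1L
        cigar[left_side] <- paste0(m[left_side], "M", cl[left_side], "S")
        bad <- left_side & m < min_anchor
        # read exits the element to the right: left soft clip
        right_side <- ovl & r1 >= a & r2 > b
        cl2 <- b - r1 + 1L
        m2 <- r2 - b
        cigar[right_side] <- paste0(cl2[right_side], "S", m2[right_side], "M")
        pos[right_side] <- map_d2p(b[right_side] + 1L)
        bad <- bad | (right_side & m2 < min_anchor)
        inside <- ovl & r1 >= a & r2 <= b
        unmap <- inside | bad
        flag[unmap] <- 4L
        pos[unmap] <- NA_integer_
        cigar[unmap] <- "*"
      }
      tibble::tibble(
        qname = sprintf("%s_r%06d", rid, seq_len(n_reads)),
        flag = flag,
        replicon_id = ifelse(flag == 4L, NA_character_, rid),
        pos = pos, mapq = ifelse(flag == 4L, 0L, 60L),
        cigar = cigar, seq = seqs)
    })
    mapped <- out[!bitwAnd(out$flag, 4L), , drop = FALSE]
    unmapped <- out[bitwAnd(out$flag, 4L) > 0, , drop = FALSE]
    mapped <- dplyr::arrange(mapped, match(.data$replicon_id, parent$id),
                             .data$pos)
    dplyr::bind_rows(mapped, unmapped)
  })
}

add_subs <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  paste(ch, collapse = "")
}

#' Write alignments as SAM
#'
#' Emits a coordinate-sorted SAM file with `@SQ` headers taken from the
#' parent replicons.
#'
#' @param alignments Alignment tibble from [simulate_alignments()].
#' @param replicons Parent replicon tibble (for `@SQ` lengths).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, replicons, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", replicons$id, replicons$length_bp))
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  alignments$qname, alignments$flag,
                  ifelse(is.na(alignments$replicon_id), "*",
                         alignments$replicon_id),
                  ifelse(is.na(alignments$pos), 0L, alignments$pos),
                  alignments$mapq, alignments$cigar, alignments$seq)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
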