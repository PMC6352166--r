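#' IS reference catalog
#'
#' The catalog is a tibble with one row per IS type, modelled on ISFinder
#' records restricted to the fields the pipeline uses:
#'
#' * `name`, `family`, `subgroup` - identifiers (`subgroup` may be `NA`)
#' * `consensus` - consensus DNA sequence (A/C/G/T/N), 700-6000 bp
#' * `length` - `nchar(consensus)`
#' * `min_len`, `max_len` - expected genomic copy length range (bp)
#' * `dr_len` - target-site duplication length in bp (0 = none), at most 12
#' * `orf_count` - number of transposase ORFs (1 or 2)
#' * `motif` - transposase catalytic motif class: `"DDE"`, `"DEDD"` or
#'   `"unknown"`
#' * `ir_left`, `ir_right` - terminal inverted repeat sequences or `NA`
#'   (when absent, locus IR detection falls back to the consensus termini)
#' * `split_orf_ok` - logical; `TRUE` for types whose transposase may be
#'   encoded as two consecutive ORFs (N- and C-terminal domains) and still
#'   be active
#' * `tnp_ref` - list column of named character vectors, the reference
#'   transposase protein(s)
#' * `tnp_start`, `tnp_end` - 1-based nt coordinates of the (first)
#'   transposase CDS within the consensus, used to map translated hits onto
#'   consensus coverage; inferred from the ORF layout when not supplied
#'
#' @name is_catalog
NULL

catalog_metadata_cols <- c("name", "family", "subgroup", "min_len", "max_len",
                           "dr_len", "orf_count", "motif", "ir_left",
                           "ir_right", "split_orf_ok", "tnp_start", "tnp_end")

#' Read an IS catalog from FASTA + TSV metadata
#'
#' FASTA ids must match the metadata `name` column one-to-one. An optional
#' protein FASTA supplies reference transposases, with ids `name` (single
#' ORF) or `name_1`/`name_2`.
#'
#' @param fasta_path Path to the consensus-sequence FASTA.
#' @param metadata_path Path to tab-delimited metadata with header columns
#'   `name family subgroup min_len max_len dr_len orf_count motif ir_left
#'   ir_right split_orf_ok tnp_start tnp_end` (the last five optional).
#' @param protein_path Optional path to a protein FASTA of reference
#'   transposases.
#' @return A validated catalog tibble (see [is_catalog]).
#' @export
read_is_catalog <- function(fasta_path, metadata_path, protein_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    name = readr::col_character(), family = readr::col_character(),
    subgroup = readr::col_character(), .default = readr::col_guess()
  ), progress = FALSE)
  if (anyDuplicated(meta$name))
    stop("duplicate IS name in metadata: ",
         meta$name[duplicated(meta$name)][1], call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  missing_meta <- setdiff(ids, meta$name)
  if (length(missing_meta))
    stop("missing metadata row for FASTA record: ", missing_meta[1],
         call. = FALSE)
  missing_seq <- setdiff(meta$name, ids)
  if (length(missing_seq))
    stop("missing FASTA record for metadata row: ", missing_seq[1],
         call. = FALSE)
  cat <- meta
  cat$consensus <- unname(toupper(as.character(seqs)[match(cat$name, ids)]))
  cat$length <- nchar(cat$consensus)
  for (col in c("ir_left", "ir_right"))
    if (!col %in% names(cat)) cat[[col]] <- NA_character_
  if (!"split_orf_ok" %in% names(cat)) cat$split_orf_ok <- FALSE
  cat$split_orf_ok <- as.logical(cat$split_orf_ok)
  cat$split_orf_ok[is.na(cat$split_orf_ok)] <- FALSE
  for (col in c("tnp_start", "tnp_end"))
    if (!col %in% names(cat)) cat[[col]] <- NA_integer_
  prot <- list()
  if (!is.null(protein_path)) {
    ps <- Biostrings::readAAStringSet(protein_path)
    pid <- sub("\\s.*$", "", names(ps))
    base <- sub("_[0-9]+$", "", pid)
    prot <- split(setNames(as.character(ps), pid), base)
  }
  cat$tnp_ref <- lapply(cat$name, function(nm) {
    v <- prot[[nm]]
    if (is.null(v)) character() else v[order(names(v))]
  })
  cat <- tibble::as_tibble(cat)
  validate_catalog(cat)
}

#' Write an IS catalog to FASTA + TSV metadata
#'
#' Inverse of [read_is_catalog()]: `read_is_catalog()` on the written files
#' reproduces the catalog.
#'
#' @param catalog A catalog tibble.
#' @param fasta_path,metadata_path,protein_path Output paths; `protein_path`
#'   may be `NULL` to skip writing transposase references.
#' @return `catalog`, invisibly.
#' @export
write_is_catalog <- function(catalog, fasta_path, metadata_path,
                             protein_path = NULL) {
  seqs <- Biostrings::DNAStringSet(setNames(catalog$consensus, catalog$name))
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- catalog[, intersect(catalog_metadata_cols, names(catalog))]
  readr::write_tsv(meta, metadata_path, progress = FALSE)
  if (!is.null(protein_path)) {
    refs <- unlist(lapply(seq_len(nrow(catalog)), function(i) {
      v <- catalog$tnp_ref[[i]]
      if (length(v) == 0) return(NULL)
      if (length(v) == 1 && (is.null(names(v)) || names(v) == catalog$name[i]))
        names(v) <- catalog$name[i]
      if (is.null(names(v)) || any(names(v) == ""))
        names(v) <- paste0(catalog$name[i], "_", seq_along(v))
      v
    }))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(refs), protein_path)
  }
  invisible(catalog)
}

#' Validate an IS catalog
#'
#' Checks the record invariants: consensus length 700-6000 bp over
#' \{A,C,G,T,N\}, `min_len <= length <= max_len`, `dr_len` in 0-12,
#' `orf_count` in \{1, 2\}. Rows failing a check are reported with their row
#' number. Missing `tnp_start`/`tnp_end` are inferred by locating the ORF
#' whose translation best matches the first transposase reference.
#'
#' @param catalog A catalog tibble.
#' @return The validated (possibly completed) catalog.
#' @export
validate_catalog <- function(catalog) {
  fail <- function(i, msg)
    stop(sprintf("catalog row %d (%s): %s", i, catalog$name[i], msg),
         call. = FALSE)
  for (i in seq_len(nrow(catalog))) {
    cs <- catalog$consensus[i]
    if (grepl("[^ACGTN]", cs))
      fail(i, "consensus contains characters outside {A,C,G,T,N}")
    if (nchar(cs) < 700 || nchar(cs) > 6000)
      fail(i, sprintf("consensus length %d outside 700-6000 bp", nchar(cs)))
    if (!is.na(catalog$min_len[i]) && !is.na(catalog$max_len[i]) &&
        (nchar(cs) < catalog$min_len[i] || nchar(cs) > catalog$max_len[i]))
      fail(i, "consensus length outside declared length range")
    if (is.na(catalog$dr_len[i]) || catalog$dr_len[i] < 0 ||
        catalog$dr_len[i] > 12)
      fail(i, "dr_len outside 0-12 bp")
    if (!catalog$orf_count[i] %in% c(1L, 2L))
      fail(i, "orf_count must be 1 or 2")
    for (col in c("ir_left", "ir_right")) {
      v <- catalog[[col]][i]
      if (!is.na(v) && grepl("[^ACGTN]", v)) fail(i, paste(col, "not DNA"))
    }
  }
  need <- which(is.na(catalog$tnp_start) &
                  vapply(catalog$tnp_ref, length, 1L) > 0)
  for (i in need) {
    orfs <- find_orfs(catalog$consensus[i], min_aa = 50)
    if (nrow(orfs) == 0) next
    ref <- catalog$tnp_ref[[i]][[1]]
    sim <- vapply(orfs$protein, function(p) {
      a <- protein_align(p, ref)
      if (is.null(a)) 0 else a$nmatch
    }, 1)
    best <- which.max(sim)
    catalog$tnp_start[i] <- orfs$start[best]
    catalog$tnp_end[i] <- orfs$end[best]
  }
  catalog
}

#' Grade genus-wide IS frequency
#'
#' Grades how widespread an IS type is across isolates of a genus:
#' `"+++"` (high) for more than 6 isolates, `"++"` (moderate) for 3-6, and
#' `"+"` (low) for 2 or fewer.
#'
#' @param n_isolates Non-negative integer vector of isolate counts.
#' @return Character vector of grades (`"+"`, `"++"`, `"+++"`).
#' @export
#' @examples
#' grade_frequency(c(0, 2, 3, 6, 7))
grade_frequency <- function(n_isolates) {
  if (any(is.na(n_isolates)) || any(n_isolates < 0))
    stop("n_isolates must be non-negative", call. = FALSE)
  dplyr::case_when(
    n_isolates > 6 ~ "+++",
    n_isolates >= 3 ~ "++",
    TRUE ~ "+"
  )
}

#' Read genome replicons from FASTA
#'
#' @param fasta_path Path to a genome FASTA, one record per replicon.
#' @param kinds Optional named character vector mapping replicon id to one of
#'   `"chromosome"`, `"megaplasmid"`, `"plasmid"`. Unmapped replicons default
#'   to `"chromosome"` for the longest record and `"plasmid"` otherwise.
#' @return Tibble with columns `id`, `kind`, `seq`, `length_bp`.
#' @export
read_replicons <- function(fasta_path, kinds = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  seq <- toupper(as.character(seqs))
  assert_dna(seq, "replicon")
  kind <- rep("plasmid", length(ids))
  if (length(ids)) kind[which.max(nchar(seq))] <- "chromosome"
  if (!is.null(kinds)) {
    hit <- match(ids, names(kinds))
    kind[!is.na(hit)] <- unname(kinds[hit[!is.na(hit)]])
  }
  tibble::tibble(id = ids, kind = kind, seq = unname(seq),
                 length_bp = nchar(seq))
}

#' Write replicons to FASTA
#'
#' @param replicons Replicon tibble (columns `id`, `seq`).
#' @param fasta_path Output path.
#' @return `replicons`, invisibly.
#' @export
write_replicons <- function(replicons, fasta_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(replicons$seq, replicons$id)),
    fasta_path)
  invisible(replicons)
}
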