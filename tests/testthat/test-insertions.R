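test_that("CIGAR arithmetic places clip boundaries on the reference", {
  aln <- tibble::tibble(
    qname = c("a", "b", "c"),
    flag = 0L,
    replicon_id = "chr",
    pos = c(1000L, 500L, 2000L),
    mapq = 60L,
    cigar = c("100M50S", "150M", "40S110M"),
    seq = c(paste0(strrep("A", 100), strrep("C", 50)),
            strrep("G", 150),
            paste0(strrep("T", 40), strrep("G", 110))))
  segs <- extract_softclips(aln, min_clip_len = 10, min_mapq = 20)
  expect_equal(nrow(segs), 2)
  right <- segs[segs$side == "right", ]
  expect_equal(right$clip_pos, 1099L)
  expect_equal(right$clip_seq, strrep("C", 50))
  left <- segs[segs$side == "left", ]
  expect_equal(left$clip_pos, 2000L)
  expect_equal(left$clip_seq, strrep("T", 40))
})

test_that("filters drop short clips, low mapq, unmapped and duplicates", {
  base <- tibble::tibble(
    qname = "x", flag = 0L, replicon_id = "chr", pos = 100L, mapq = 60L,
    cigar = "50S100M", seq = strrep("A", 150))
  expect_equal(nrow(extract_softclips(base, min_clip_len = 60)), 0)
  low <- dplyr::mutate(base, mapq = 5L)
  expect_equal(nrow(extract_softclips(low)), 0)
  unm <- dplyr::mutate(base, flag = 4L)
  expect_equal(nrow(extract_softclips(unm)), 0)
  dup <- dplyr::bind_rows(base, base, dplyr::mutate(base, qname = "y"))
  expect_equal(nrow(extract_softclips(dup)), 1)
})

test_that("clip consensi match the correct IS terminus and orientation", {
  cat_ <- test_catalog()
  cons <- cat_$consensus[cat_$name == "ISTth7"]
  L <- nchar(cons)
  m5 <- match_termini(substr(cons, 1, 40), cat_)
  expect_equal(m5$is_name, "ISTth7")
  expect_equal(m5$terminus, "5prime")
  expect_equal(m5$identity, 1)
  m3 <- match_termini(revcomp(substr(cons, L - 39, L)), cat_)
  expect_equal(m3$is_name, "ISTth7")
  expect_equal(m3$terminus, "3prime")
  set.seed(71)
  expect_equal(nrow(match_termini(rand_dna(40), cat_)), 0)
  expect_equal(nrow(match_termini("ACGT", cat_)), 0)
})

test_that("SAM written by the simulator round-trips through htslib", {
  set.seed(72)
  cat_ <- test_catalog()
  parent <- simulate_genome(
    cat_, tibble::tibble(id = "chr", kind = "chromosome",
                         length_bp = 20000L), seed = 3)$replicons
  d <- derive_strain(parent,
                     tibble::tibble(replicon_id = "chr", site = 9000L,
                                    is_name = "ISTth7"), cat_)
  aln <- simulate_alignments(d$replicons, parent, d$truth, coverage = 10,
                             seed = 4)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, parent, sam)
  back <- read_alignments(sam)
  mapped <- aln[aln$flag != 4L, ]
  expect_equal(nrow(back[!bitwAnd(back$flag, 4L), ]), nrow(mapped))
  expect_equal(sort(back$pos[!bitwAnd(back$flag, 4L)]), sort(mapped$pos))
  # soft-clip extraction is identical from tibble and from file
  expect_equal(extract_softclips(sam), extract_softclips(aln))
})

test_that("planted insertions are called with exact flanks and TSD", {
  cat_ <- test_catalog()
  parent <- simulate_genome(
    cat_, tibble::tibble(id = "chr", kind = "chromosome",
                         length_bp = 40000L), seed = 8)$replicons
  sites <- c(8000L, 17000L, 31000L)
  d <- derive_strain(parent,
                     tibble::tibble(replicon_id = "chr", site = sites,
                                    is_name = "ISTth7",
                                    strand = c("+", "-", "+")), cat_)
  aln <- simulate_alignments(d$replicons, parent, d$truth, coverage = 30,
                             seed = 9)
  calls <- call_insertions(extract_softclips(aln), cat_)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$start, sites - 7L)
  expect_equal(calls$end, sites)
  expect_equal(calls$tsd_len, rep(8L, 3))
  expect_equal(calls$is_name, rep("ISTth7", 3))
  expect_false(any(calls$single_flank))
  # no soft-clipped reads: empty call set
  none <- simulate_alignments(parent, parent,
                              d$truth[0, ], coverage = 5, seed = 10)
  expect_equal(nrow(call_insertions(extract_softclips(none), cat_)), 0)
})

test_that("two samples sharing planted sites give identical coordinates", {
  cat_ <- test_catalog()
  parent <- simulate_genome(
    cat_, tibble::tibble(id = "chr", kind = "chromosome",
                         length_bp = 30000L), seed = 12)$replicons
  d <- derive_strain(parent,
                     tibble::tibble(replicon_id = "chr",
                                    site = c(7000L, 20000L),
                                    is_name = "ISTth4"), cat_)
  c1 <- call_insertions(extract_softclips(
    simulate_alignments(d$replicons, parent, d$truth, coverage = 25,
                        seed = 13)), cat_)
  c2 <- call_insertions(extract_softclips(
    simulate_alignments(d$replicons, parent, d$truth, coverage = 25,
                        seed = 14)), cat_)
  expect_equal(c1$start, c2$start)
  expect_equal(c1$end, c2$end)
})

test_that("presence matrix merges sites and counts novel occurrences", {
  inp <- sites_as_presence_inputs()
  pres <- compare_samples(inp$reference, inp$calls)
  expect_s3_class(pres, "is_presence")
  expect_equal(nrow(pres), 15)
  # no all-absent rows
  flags <- pres[, grep("^in_", names(pres))]
  expect_true(all(rowSums(as.matrix(flags)) > 0))
  nov <- count_novel(pres)
  expect_equal(nov$n_novel[nov$sample == "HB27E" &
                             nov$replicon_id == "chromosome"], 7L)
  expect_equal(nov$n_novel[nov$sample == "HB27E" &
                             nov$replicon_id == "megaplasmid"], 2L)
  expect_equal(nov$n_novel[nov$sample == "HB27A" &
                             nov$replicon_id == "chromosome"], 6L)
  sh <- shared_novel(pres)
  expect_equal(sh$n_shared[sh$replicon_id == "chromosome"], 6L)
  expect_equal(sh$n_shared[sh$replicon_id == "megaplasmid"], 1L)
  # all-reference matrix has zero novel everywhere
  ref_only <- compare_samples(inp$reference,
                              list(A = inp$reference[0, ]))
  novA <- count_novel(ref_only, by = "sample")
  expect_equal(novA$n_novel, 0L)
})

test_that("insertion-caller recall degrades monotonically with coverage", {
  cat_ <- test_catalog()
  parent <- simulate_genome(
    cat_, tibble::tibble(id = "chr", kind = "chromosome",
                         length_bp = 40000L), seed = 20)$replicons
  sites <- c(6000L, 14000L, 22000L, 30000L, 36000L)
  d <- derive_strain(parent,
                     tibble::tibble(replicon_id = "chr", site = sites,
                                    is_name = "ISTth7"), cat_)
  recall <- vapply(c(2, 6, 20), function(cov) {
    hit <- 0L
    for (sd in 1:4) {
      calls <- call_insertions(extract_softclips(
        simulate_alignments(d$replicons, parent, d$truth, coverage = cov,
                            seed = 900 + sd)), cat_)
      hit <- hit + sum(sites %in% calls$end)
    }
    hit / (4 * length(sites))
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
  expect_lt(recall[1], 1)
  expect_equal(recall[3], 1)
})
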