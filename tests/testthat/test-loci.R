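make_hit <- function(start, end, qstart, qend, is_name = "ISTth7",
                     strand = "+", level = "nucleotide",
                     replicon_id = "chr") {
  tibble::tibble(is_name = is_name, replicon_id = replicon_id,
                 start = start, end = end, strand = strand,
                 identity = 1, is_cov = (qend - qstart + 1) / 1000,
                 level = level, score = 2L * (qend - qstart + 1L),
                 qstart = qstart, qend = qend)
}

test_that("abutting hits partitioning the consensus merge to coverage 1", {
  cat_ <- query_catalog(rand_dna(1100))
  hits <- dplyr::bind_rows(
    make_hit(5001, 5600, 1, 600, is_name = "Q"),
    make_hit(5601, 6100, 601, 1100, is_name = "Q"))
  loci <- merge_hits(hits, cat_)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 5001)
  expect_equal(loci$end, 6100)
  expect_equal(loci$coverage, 1)
  expect_equal(loci$n_hits, 2L)
})

test_that("a lone 40% hit becomes one locus at coverage 0.4", {
  cat_ <- query_catalog(rand_dna(1000))
  loci <- merge_hits(make_hit(100, 499, 1, 400, is_name = "Q"), cat_)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$coverage, 0.4)
})

test_that("hits beyond the merge gap stay separate loci", {
  cat_ <- query_catalog(rand_dna(1000))
  hits <- dplyr::bind_rows(
    make_hit(100, 499, 1, 400, is_name = "Q"),
    make_hit(700, 1099, 500, 899, is_name = "Q"))
  expect_equal(nrow(merge_hits(hits, cat_, max_gap = 100)), 2)
  expect_equal(nrow(merge_hits(hits, cat_, max_gap = 300)), 1)
})

test_that("random fragmentations merge to the interval-union coverage", {
  set.seed(41)
  for (i in 1:20) {
    clen <- sample(900:1500, 1)
    cat_ <- query_catalog(rand_dna(clen))
    n_frag <- sample(1:5, 1)
    # random consensus fragments laid out colinearly with small gaps
    qs <- sort(sample(seq_len(clen - 80), n_frag))
    qe <- pmin(qs + sample(60:400, n_frag, replace = TRUE), clen)
    gpos <- cumsum(c(2000, utils::head(qe - qs + 1, -1) +
                       sample(0:50, n_frag - 1, replace = TRUE)))
    hits <- purrr::map_dfr(seq_len(n_frag), function(j)
      make_hit(gpos[j], gpos[j] + (qe[j] - qs[j]), qs[j], qe[j],
               is_name = "Q"))
    loci <- merge_hits(hits, cat_, max_gap = 100)
    expect_equal(nrow(loci), 1)
    expect_equal(loci$coverage, bitmap_union(qs, qe, clen) / clen,
                 info = paste("instance", i))
  }
})

test_that("completeness combines the coverage floor with the length window", {
  cat_ <- tibble::tibble(name = "ISTth7", consensus = rand_dna(1100),
                         min_len = 900L, max_len = 1150L)
  base <- tibble::tibble(locus_id = "x", is_name = "ISTth7",
                         replicon_id = "chr", start = 1000L, end = 2099L,
                         strand = "+", coverage = 1, n_hits = 1L,
                         levels = "nucleotide")
  expect_equal(classify_completeness(base, cat_)$status, "complete")
  # the coverage boundary is inclusive
  b2 <- base; b2$coverage <- 0.95
  expect_equal(classify_completeness(b2, cat_)$status, "complete")
  b3 <- base; b3$coverage <- 0.9499
  expect_equal(classify_completeness(b3, cat_)$status, "partial")
  b4 <- base; b4$coverage <- 0.40
  expect_equal(classify_completeness(b4, cat_)$status, "partial")
  # full coverage but genomic span outside [0.9 min, 1.1 max]
  b5 <- base; b5$end <- base$start + 1400L
  expect_equal(classify_completeness(b5, cat_)$status, "partial")
})

test_that("target-site duplications are detected only on identical flanks", {
  set.seed(42)
  cat_ <- test_catalog()
  rec <- cat_[cat_$name == "ISTth7", ]
  cons <- rec$consensus
  tsd <- "GCCTTAAC"
  bg <- rand_dna(4000)
  s <- paste0(substr(bg, 1, 2000), tsd, cons, tsd, substr(bg, 2001, 4000))
  locus <- tibble::tibble(locus_id = "x", is_name = "ISTth7",
                          replicon_id = "chr", start = 2009L,
                          end = 2008L + nchar(cons), strand = "+",
                          coverage = 1, n_hits = 1L, levels = "nt",
                          status = "complete")
  got <- detect_tsd(locus, as_replicon(s), cat_)
  expect_equal(got$tsd_seq, tsd)
  expect_false(got$tsd_at_edge)
  # one flank base changed: no TSD
  s2 <- paste0(substr(bg, 1, 2000), "ACCTTAAC", cons, tsd,
               substr(bg, 2001, 4000))
  expect_true(is.na(detect_tsd(locus, as_replicon(s2), cat_)$tsd_seq))
  # a type without target-site duplication never reports one
  rec0 <- cat_[cat_$name == "IS1000B", ]
  locus0 <- locus
  locus0$is_name <- "IS1000B"
  locus0$end <- locus0$start + rec0$length - 1L
  s0 <- paste0(substr(bg, 1, 2008), rec0$consensus, substr(bg, 2001, 4000))
  expect_true(is.na(detect_tsd(locus0, as_replicon(s0), cat_)$tsd_seq))
  # locus at the replicon edge is flagged
  edge <- locus
  edge$start <- 3L
  edge$end <- 2L + nchar(cons)
  got_edge <- detect_tsd(edge, as_replicon(paste0(substr(cons, 1, 2),
                                                  cons, bg)), cat_)
  expect_true(got_edge$tsd_at_edge)
  expect_true(is.na(got_edge$tsd_seq))
})

test_that("inverted-repeat evidence tracks which terminus survives", {
  set.seed(43)
  cat_ <- test_catalog()
  rec <- cat_[cat_$name == "ISTth4", ]
  cons <- rec$consensus
  bg <- rand_dna(6000)
  mk_locus <- function(start, end, strand = "+")
    tibble::tibble(locus_id = "x", is_name = "ISTth4", replicon_id = "chr",
                   start = start, end = end, strand = strand, coverage = 1,
                   n_hits = 1L, levels = "nt", status = "complete")
  s <- paste0(substr(bg, 1, 1000), cons, substr(bg, 1001, 6000))
  full <- detect_ir(mk_locus(1001L, 1000L + nchar(cons)), as_replicon(s),
                    cat_)
  expect_equal(full$ir_evidence, "both")
  # 5' truncation leaves only right-terminus evidence
  trunc <- substr(cons, 301, nchar(cons))
  s2 <- paste0(substr(bg, 1, 1000), trunc, substr(bg, 1001, 6000))
  part <- detect_ir(mk_locus(1001L, 1000L + nchar(trunc)), as_replicon(s2),
                    cat_)
  expect_equal(part$ir_evidence, "right")
  # randomized termini: none
  mid <- substr(cons, 26, nchar(cons) - 25)
  s3 <- paste0(substr(bg, 1, 1000), rand_dna(25), mid, rand_dna(25),
               substr(bg, 1001, 6000))
  none <- detect_ir(mk_locus(1001L, 1000L + nchar(cons)), as_replicon(s3),
                    cat_)
  expect_equal(none$ir_evidence, "none")
  # a minus-strand copy still shows both termini
  s4 <- paste0(substr(bg, 1, 1000), revcomp(cons), substr(bg, 1001, 6000))
  minus <- detect_ir(mk_locus(1001L, 1000L + nchar(cons), "-"),
                     as_replicon(s4), cat_)
  expect_equal(minus$ir_evidence, "both")
})

test_that("planting k verbatim copies yields k complete loci with TSDs", {
  cat_ <- test_catalog()
  for (sd in 1:3) {
    plan <- tibble::tibble(
      replicon_id = "chr",
      is_name = sample(cat_$name, 4, replace = TRUE),
      status = "complete", truncation = NA_real_,
      strand = sample(c("+", "-"), 4, replace = TRUE))
    sim <- simulate_genome(cat_, tibble::tibble(id = "chr",
                                                kind = "chromosome",
                                                length_bp = 60000L),
                           plan, seed = 100 + sd)
    hits <- search_nt(sim$replicons, cat_)
    loci <- build_loci(hits, sim$replicons, cat_)
    expect_equal(nrow(loci), 4)
    expect_true(all(loci$status == "complete"))
    truth <- dplyr::arrange(sim$truth$loci, start)
    expect_equal(loci$start, as.integer(truth$start))
    expect_equal(loci$end, as.integer(truth$end))
    expect_equal(loci$tsd_seq, truth$tsd_seq)
    # counts are conserved across replicons
    expect_equal(sum(count_loci(loci)$complete), 4)
  }
})

test_that("truncation below the coverage floor always yields a partial", {
  cat_ <- test_catalog()
  plan <- tibble::tibble(replicon_id = "chr",
                         is_name = c("ISTth7", "ISTth4"),
                         status = "partial", truncation = c(0.5, 0.8),
                         strand = c("+", "-"))
  sim <- simulate_genome(cat_, tibble::tibble(id = "chr",
                                              kind = "chromosome",
                                              length_bp = 40000L),
                         plan, seed = 7)
  loci <- build_loci(search_nt(sim$replicons, cat_), sim$replicons, cat_)
  expect_equal(nrow(loci), 2)
  expect_true(all(loci$status == "partial"))
})
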