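test_that("the simulator is byte-identical under a fixed seed", {
  cat_ <- test_catalog()
  plan_rep <- tibble::tibble(id = "chr", kind = "chromosome",
                             length_bp = 30000L)
  plan_is <- tibble::tibble(replicon_id = "chr", is_name = "ISTth7",
                            status = "complete", truncation = NA_real_,
                            strand = "+")
  s1 <- simulate_genome(cat_, plan_rep, plan_is, seed = 5)
  s2 <- simulate_genome(cat_, plan_rep, plan_is, seed = 5)
  expect_identical(s1$replicons, s2$replicons)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(
    s1$replicons$seq,
    simulate_genome(cat_, plan_rep, plan_is, seed = 6)$replicons$seq))
  # catalogs and alignment files reproduce too
  expect_identical(simulate_catalog(seed = 9), simulate_catalog(seed = 9))
  d <- derive_strain(s1$replicons,
                     tibble::tibble(replicon_id = "chr", site = 20000L,
                                    is_name = "ISTth4"), cat_)
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(simulate_alignments(d$replicons, s1$replicons, d$truth,
                                coverage = 8, seed = 2), s1$replicons, f1)
  write_sam(simulate_alignments(d$replicons, s1$replicons, d$truth,
                                coverage = 8, seed = 2), s1$replicons, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted elements re-extract verbatim from the genome", {
  cat_ <- test_catalog()
  plan_is <- tibble::tibble(
    replicon_id = "chr",
    is_name = c("ISTth7", "ISTth4", "IS1000B"),
    status = c("complete", "partial", "complete"),
    truncation = c(NA, 0.45, NA),
    strand = c("+", "-", "-"))
  sim <- simulate_genome(cat_,
                         tibble::tibble(id = "chr", kind = "chromosome",
                                        length_bp = 50000L),
                         plan_is, seed = 44)
  truth <- sim$truth$loci
  for (i in seq_len(nrow(truth))) {
    planted <- substr(sim$replicons$seq, truth$start[i], truth$end[i])
    if (truth$strand[i] == "-") planted <- revcomp(planted)
    cons <- cat_$consensus[cat_$name == truth$is_name[i]]
    expect_equal(planted,
                 substr(cons, truth$frag_start[i], truth$frag_end[i]),
                 info = truth$is_name[i])
  }
  # TSD flanks sit immediately around complete loci with dr_len > 0
  tsd <- truth[!is.na(truth$tsd_seq), ]
  for (i in seq_len(nrow(tsd))) {
    t <- nchar(tsd$tsd_seq[i])
    expect_equal(substr(sim$replicons$seq, tsd$start[i] - t,
                        tsd$start[i] - 1L), tsd$tsd_seq[i])
    expect_equal(substr(sim$replicons$seq, tsd$end[i] + 1L,
                        tsd$end[i] + t), tsd$tsd_seq[i])
  }
})

test_that("background GC lands within one point of the target", {
  cat_ <- test_catalog()
  for (sd in 1:3) {
    sim <- simulate_genome(cat_,
                           tibble::tibble(id = "chr", kind = "chromosome",
                                          length_bp = 120000L),
                           seed = 50 + sd)
    expect_lt(abs(gc_content(sim$replicons$seq) - 0.681), 0.01)
  }
})

test_that("realised coverage is within 10% of the plan", {
  cat_ <- test_catalog()
  parent <- simulate_genome(cat_,
                            tibble::tibble(id = "chr", kind = "chromosome",
                                           length_bp = 100000L),
                            seed = 55)$replicons
  aln <- simulate_alignments(parent, parent,
                             tibble::tibble(replicon_id = character(),
                                            site = integer(),
                                            is_name = character(),
                                            tsd_len = integer(),
                                            left_flank = integer(),
                                            right_flank = integer(),
                                            is_start_d = integer(),
                                            is_end_d = integer()),
                             read_len = 150, coverage = 25, seed = 56)
  realised <- sum(nchar(aln$seq)) / parent$length_bp
  expect_lt(abs(realised - 25) / 25, 0.10)
})

test_that("an empty plan yields a genome with no detectable loci", {
  cat_ <- test_catalog()
  for (sd in 1:6) {
    sim <- simulate_genome(cat_,
                           tibble::tibble(id = "chr", kind = "chromosome",
                                          length_bp = 50000L),
                           seed = 60 + sd)
    sc <- scan_genome(sim$replicons, cat_)
    expect_equal(nrow(sc$loci), 0, info = paste("seed", 60 + sd))
  }
})

test_that("infeasible plans and invalid derived sites are rejected", {
  cat_ <- test_catalog()
  plan_is <- tibble::tibble(replicon_id = "chr",
                            is_name = rep("ISTth7", 8),
                            status = "complete", truncation = NA_real_,
                            strand = "+")
  expect_error(
    simulate_genome(cat_, tibble::tibble(id = "chr", kind = "chromosome",
                                         length_bp = 5000L),
                    plan_is, seed = 1),
    "do not fit")
  parent <- simulate_genome(cat_,
                            tibble::tibble(id = "chr", kind = "chromosome",
                                           length_bp = 20000L),
                            seed = 2)$replicons
  expect_error(
    derive_strain(parent,
                  tibble::tibble(replicon_id = "chr",
                                 site = c(5000L, 5200L),
                                 is_name = "ISTth7"), cat_),
    "closer than 500")
  expect_error(
    derive_strain(parent,
                  tibble::tibble(replicon_id = "chr", site = 5000L,
                                 is_name = "ISTth7"), cat_,
                  avoid = tibble::tibble(replicon_id = "chr",
                                         start = 4900L, end = 5100L)),
    "inside an existing locus")
  # zero insertions: derived equals parent
  same <- derive_strain(parent, tibble::tibble(replicon_id = character(),
                                               site = integer(),
                                               is_name = character()),
                        cat_)
  expect_identical(same$replicons, parent)
})
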