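test_that("repeat extraction honours 1-based inclusive coordinates", {
  cat_ <- test_catalog()
  rep32 <- extract_repeat(cat_, "IS1000B", 1165, 1196)
  expect_equal(nchar(rep32), 32L)
  expect_equal(rep32,
               substr(cat_$consensus[cat_$name == "IS1000B"], 1165, 1196))
  expect_equal(nchar(extract_repeat(cat_, "IS1000B", 1, 1)), 1L)
  expect_error(extract_repeat(cat_, "IS1000B", 2000, 2031), "out of range")
  expect_error(extract_repeat(cat_, "nope", 1, 32), "unknown")
})

test_that("planted repeat copies are found on both strands", {
  set.seed(61)
  rep32 <- rand_dna(32)
  bg <- rand_dna(20000)
  pos <- c(2000L, 5000L, 9000L, 15000L)
  s <- bg
  for (p in pos)
    s <- paste0(substr(s, 1, p - 1), rep32, substr(s, p + 32, nchar(s)))
  copies <- find_repeat_copies(as_replicon(s), rep32)
  expect_equal(nrow(copies), 4)
  expect_equal(copies$start, pos)
  expect_true(all(copies$strand == "+"))
  # a reverse-strand copy is found with strand "-"
  s2 <- paste0(substr(bg, 1, 3000), revcomp(rep32),
               substr(bg, 3033, nchar(bg)))
  copies2 <- find_repeat_copies(as_replicon(s2), rep32)
  expect_equal(copies2$start, 3001L)
  expect_equal(copies2$strand, "-")
})

test_that("mismatch-tolerant repeat scan equals the sliding Hamming oracle", {
  set.seed(62)
  for (i in 1:15) {
    rep_unit <- rand_dna(sample(16:32, 1))
    s <- rand_dna(4000)
    # plant exact and 1-mismatch copies
    for (p in sample(seq(100, 3500, by = 600), 3)) {
      u <- mutate_copy(rep_unit, 1 - sample(0:1, 1) / nchar(rep_unit))
      s <- paste0(substr(s, 1, p - 1), u,
                  substr(s, p + nchar(u), nchar(s)))
    }
    got <- find_repeat_copies(as_replicon(s), rep_unit, max_mismatch = 1)
    want <- naive_repeat_scan(s, rep_unit, max_mm = 1)
    expect_equal(sprintf("%d:%s", got$start, got$strand),
                 sprintf("%d:%s", want$start, want$strand),
                 info = paste("instance", i))
  }
})

test_that("spacer-gap chaining forms CRISPR arrays and isolates fragments", {
  # 4 copies with 35/33/38 bp spacers: one array of 4
  starts <- cumsum(c(1000L, 32L + 35L, 32L + 33L, 32L + 38L))
  copies <- tibble::tibble(replicon_id = "chr", start = starts,
                           end = starts + 31L, strand = "+")
  arr <- cluster_arrays(copies, repeat_len = 32)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$n_copies, 4L)
  expect_equal(arr$classification, "crispr_array")
  expect_equal(arr$spacer_lengths[[1]], c(35L, 33L, 38L))
  # 2 copies 500 bp apart: two isolated fragments
  far <- tibble::tibble(replicon_id = "chr", start = c(1000L, 1532L),
                        end = c(1031L, 1563L), strand = "+")
  arr2 <- cluster_arrays(far, repeat_len = 32)
  expect_equal(nrow(arr2), 2)
  expect_true(all(arr2$classification == "isolated_fragment"))
  # a spacer just outside the band breaks the chain
  starts3 <- cumsum(c(1000L, 32L + 35L, 32L + 41L))
  near <- tibble::tibble(replicon_id = "chr", start = starts3,
                         end = starts3 + 31L, strand = "+")
  arr3 <- cluster_arrays(near, repeat_len = 32)
  expect_equal(sort(arr3$n_copies), c(1L, 2L))
})

test_that("chaining equals a brute-force partition on random position sets", {
  set.seed(63)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    gaps <- sample(c(30:40, 5:20, 60:500), n - 1, replace = TRUE)
    starts <- cumsum(c(500L, 32L + gaps))
    copies <- tibble::tibble(replicon_id = "chr", start = starts,
                             end = starts + 31L, strand = "+")
    arr <- cluster_arrays(copies, 32)
    # brute force: split whenever the spacer leaves [30, 40]
    brk <- which(gaps < 30 | gaps > 40)
    sizes <- diff(c(0, brk, n))
    expect_equal(sort(arr$n_copies), sort(as.integer(sizes)),
                 info = paste("instance", i))
    # every copy in exactly one array
    expect_equal(sum(arr$n_copies), n)
    expect_setequal(unlist(arr$copy_starts), starts)
  }
})

test_that("planted arrays of 3 to 12 copies are recovered as one array", {
  cat_ <- test_catalog()
  for (n in c(3L, 5L, 8L, 12L)) {
    cp <- tibble::tibble(replicon_id = "chr", source = "IS1000B",
                         slice_start = 1165L, slice_end = 1196L,
                         n_copies = n, spacer_min = 30L, spacer_max = 40L)
    sim <- simulate_genome(cat_, tibble::tibble(id = "chr",
                                                kind = "chromosome",
                                                length_bp = 30000L),
                           crispr_plan = cp, seed = 700 + n)
    rep32 <- extract_repeat(cat_, "IS1000B", 1165, 1196)
    copies <- find_repeat_copies(sim$replicons, rep32)
    arrays <- cluster_arrays(copies, 32)
    arrays <- arrays[arrays$classification == "crispr_array", ]
    expect_equal(nrow(arrays), 1, info = paste("n =", n))
    expect_equal(arrays$n_copies, n, info = paste("n =", n))
    expect_equal(arrays$start, as.integer(sim$truth$arrays$start))
  }
})

test_that("reconciliation removes only partials inside arrays", {
  loci <- tibble::tibble(
    locus_id = c("a", "b", "c"), is_name = "IS1000B",
    replicon_id = "chr",
    start = c(1010L, 5000L, 9000L), end = c(1041L, 6255L, 9031L),
    strand = "+", coverage = c(0.03, 1, 0.03), n_hits = 1L,
    levels = "nucleotide", status = c("partial", "complete", "partial"))
  arrays <- tibble::tibble(
    array_id = c("chr:1000-1300", "chr:8990-9100"),
    replicon_id = "chr", strand = "+",
    start = c(1000L, 8990L), end = c(1300L, 9100L),
    n_copies = c(5L, 2L),
    classification = c("crispr_array", "isolated_fragment"),
    copy_starts = list(integer(), integer()),
    spacer_lengths = list(integer(), integer()))
  rec <- reconcile_crispr(loci, arrays)
  # the partial inside the crispr array is excluded and logged
  expect_equal(rec$excluded$locus_id, "a")
  expect_equal(rec$excluded$array_id, "chr:1000-1300")
  # the complete locus and the isolated copy survive
  expect_setequal(rec$loci$locus_id, c("b", "c"))
  # complete loci are never removed even inside an array span
  loci2 <- loci
  loci2$status <- "complete"
  rec2 <- reconcile_crispr(loci2, arrays)
  expect_equal(nrow(rec2$excluded), 0)
  expect_equal(nrow(rec2$loci), 3)
})
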