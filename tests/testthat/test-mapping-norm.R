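test_that("aligner places exact, reverse-complement, and over-threshold inserts correctly", {
  set.seed(21)
  ref <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  cat <- data.frame(id = "TE1", class = "transposon", sequence = ref,
                    length = 120L, stringsAsFactors = FALSE)
  cat <- validate_catalog(cat)

  ins <- substr(ref, 13, 38)  # offset 12, 0-based
  al <- align_reads(data.frame(insert = ins, count = 5L), cat, 0, seed = 1)
  expect_equal(nrow(al$alignments), 1L)
  expect_equal(al$alignments$strand, "+")
  expect_equal(al$alignments$start, 12L)
  expect_equal(al$alignments$five_prime, 12L)
  expect_equal(al$alignments$copies, 5L)

  # reverse complement of the substring ending at offset 80 (half-open)
  rc <- bf_revcomp(substr(ref, 55, 80))
  am <- align_reads(data.frame(insert = rc, count = 1L), cat, 0, seed = 1)
  expect_equal(am$alignments$strand, "-")
  expect_equal(am$alignments$end, 80L)
  expect_equal(am$alignments$five_prime, 79L)

  # two substitutions cannot be rescued at max_mismatches = 1
  bad <- ins
  substr(bad, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(bad, 3, 3))[1]
  substr(bad, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(bad, 9, 9))[1]
  ab <- align_reads(data.frame(insert = bad, count = 2L), cat, 1, seed = 1)
  expect_equal(nrow(ab$alignments), 0L)
  expect_equal(ab$unmapped, 2L)

  # N-containing inserts are unmapped
  an <- align_reads(data.frame(insert = sub("A", "N", ins), count = 3L),
                    cat, 1, seed = 1)
  expect_equal(an$unmapped, 3L)
})

test_that("aligner matches the all-substring brute force at 0 and 1 mismatches", {
  cat <- make_reference_catalog(3, 1, 0, 1, length_range = c(500, 900), seed = 17)
  set.seed(99)
  inserts <- character(0)
  # exact copies, single-substitution copies, double-substitution copies, junk
  for (i in 1:25) {
    ref <- cat[sample(nrow(cat), 1), ]
    len <- sample(20:32, 1)
    st <- sample(ref$length - len, 1)
    s <- substr(ref$sequence, st, st + len - 1)
    if (runif(1) < 0.5) s <- bf_revcomp(s)
    nmut <- sample(0:2, 1)
    for (k in seq_len(nmut)) {
      p <- sample(len, 1)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    inserts <- c(inserts, s)
  }
  inserts <- c(inserts, replicate(10, paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                                            collapse = "")))
  lib <- data.frame(insert = unique(inserts),
                    count = seq_along(unique(inserts)))
  for (mm in 0:1) {
    al <- align_reads(lib, cat, mm, seed = 3)
    got <- al$alignments
    oracle_unmapped <- 0L
    for (i in seq_len(nrow(lib))) {
      best <- bf_align_one(lib$insert[i], cat, mm)
      row <- got[got$insert == lib$insert[i], , drop = FALSE]
      if (is.null(best)) {
        expect_equal(nrow(row), 0L)
        oracle_unmapped <- oracle_unmapped + lib$count[i]
      } else {
        expect_equal(nrow(row), 1L)
        expect_equal(row$n_best, nrow(best))
        expect_equal(row$mismatches, best$mismatches[1])
        hit <- best[best$ref_id == row$ref_id & best$strand == row$strand &
                      best$start == row$start, ]
        expect_equal(nrow(hit), 1L)
      }
    }
    expect_equal(al$unmapped, oracle_unmapped)
  }
})

test_that("multi-placement ties are seed-reproducible and uniform across seeds", {
  motif <- "ACGTTGCAACGGATCCTAGG"  # 20-mer, 4 spaced copies in the reference
  set.seed(5)
  spacer <- function() paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  ref <- paste0(spacer(), motif, spacer(), motif, spacer(), motif, spacer(),
                motif, spacer())
  cat <- validate_catalog(data.frame(id = "TE1", class = "transposon",
                                     sequence = ref, length = nchar(ref),
                                     stringsAsFactors = FALSE))
  lib <- data.frame(insert = motif, count = 1L)
  a1 <- align_reads(lib, cat, 0, seed = 11)
  a2 <- align_reads(lib, cat, 0, seed = 11)
  expect_identical(a1$alignments, a2$alignments)
  expect_equal(a1$alignments$n_best, 4L)

  starts <- vapply(1:400, function(s) align_reads(lib, cat, 0, seed = s)$alignments$start, 0L)
  tab <- table(factor(starts, levels = unique(starts)))
  expect_equal(length(tab), 4L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("mapping rate, normalization denominators and RPM follow their definitions", {
  set.seed(31)
  mkseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  cat <- validate_catalog(data.frame(
    id = c("TE1", "TE2", "RRNA1", "GENE1"),
    class = c("transposon", "transposon", "rRNA_repeat", "gene"),
    sequence = c(mkseq(300), mkseq(300), mkseq(300), mkseq(300)),
    stringsAsFactors = FALSE, length = 300L))
  lib <- data.frame(
    insert = c(substr(cat$sequence[1], 11, 36), substr(cat$sequence[2], 41, 66),
               substr(cat$sequence[3], 21, 46), mkseq(26)),
    count = c(30L, 50L, 20L, 60L))
  pl <- structure(list(library_id = "toy", metadata = list(),
                       counts = lib,
                       stats = list(input = 160L, no_adapter = 0L,
                                    length_rejected = 0L, kept = 160L)),
                  class = "processed_library")
  al <- align_reads(pl, cat, 0, seed = 1)
  expect_equal(mapping_rate(al, pl, "transposon"), 100 * 80 / 160)

  f <- normalization_factor(al, cat, "transposon")
  expect_equal(f$denominator, 80)
  rt <- rpm_table(al, f, cat)
  expect_equal(sum(rt$rpm[rt$ref_id == "TE1"]), 30 / 80 * 1e6)
  expect_equal(sum(rt$rpm[rt$class == "transposon"]), 1e6)
  expect_equal(sum(rt$rpm[rt$ref_id == "GENE1"]), 0)

  empty <- structure(list(counts = lib[0, ],
                          stats = list(kept = 0L)), class = "processed_library")
  expect_error(mapping_rate(al, empty), "empty library")
})

test_that("top-10 miRNA normalization sums the ten largest miRNA counts", {
  cat <- make_reference_catalog(1, 0, 12, 0, length_range = c(400, 500), seed = 8)
  mir <- cat[cat$class == "miRNA", ]
  set.seed(77)
  counts <- sample(5:500, 12)
  lib <- data.frame(insert = substr(mir$sequence, 1, 22), count = counts)
  al <- align_reads(lib, cat, 0, seed = 1)
  f <- normalization_factor(al, cat, "mirna_top10")
  expect_equal(f$denominator, sum(sort(counts, decreasing = TRUE)[1:10]))

  # no transposon-mapped reads at all -> transposon-mode error
  expect_error(normalization_factor(al, cat, "transposon"),
               "no mapped reads")
})

test_that("RPM closure holds on a simulated library", {
  cat <- tiny_catalog(seed = 23, n_te = 4, te_len = c(1200, 2000))
  sim <- simulate_small_rna_library(cat, smallrna_sim_params(depth = 8000, seed = 2))
  lib <- process_library(sim$reads)
  al <- align_reads(lib, cat, 1, seed = 9)
  f <- normalization_factor(al, cat, "transposon")
  rt <- rpm_table(al, f, cat)
  expect_lt(abs(sum(rt$rpm[rt$class == "transposon"]) - 1e6), 1e6 * 1e-6)
})

test_that("SAM export/import round-trips the chosen alignments", {
  cat <- tiny_catalog(seed = 14)
  sim <- simulate_small_rna_library(cat, smallrna_sim_params(depth = 600, seed = 5))
  lib <- process_library(sim$reads)
  al <- align_reads(lib, cat, 1, seed = 2)
  sam <- tempfile(fileext = ".sam")
  write_sam(al, cat, sam)
  back <- read_sam(sam, cat)
  key <- function(d) d[order(d$insert), c("insert", "copies", "ref_id", "strand",
                                          "start", "end", "five_prime", "mismatches")]
  expect_equal(key(back), key(al$alignments), ignore_attr = TRUE)
})
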