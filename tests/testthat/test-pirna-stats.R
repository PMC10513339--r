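fake_factor <- function(denom, mode = "transposon") {
  structure(list(library_id = "t", mode = mode, denominator = denom),
            class = "normalization_factor")
}

fake_library <- function(inserts, counts) {
  structure(list(library_id = "t", metadata = list(),
                 counts = data.frame(insert = inserts, count = counts,
                                     stringsAsFactors = FALSE),
                 stats = list(input = sum(counts), no_adapter = 0L,
                              length_rejected = 0L, kept = sum(counts))),
            class = "processed_library")
}

test_that("length distribution scales copy-weighted counts to RPM", {
  lib <- fake_library(c(strrep("A", 26), strrep("C", 26), strrep("G", 28)),
                      c(1L, 1L, 2L))
  h <- length_distribution(lib, fake_factor(4))
  expect_equal(h$rpm[h$length == 26], 5e5)
  expect_equal(h$rpm[h$length == 28], 5e5)
  empty <- fake_library(character(0), integer(0))
  expect_equal(nrow(length_distribution(empty, fake_factor(4))), 0L)
})

test_that("first-base composition reports U percentages in the window", {
  lib <- fake_library(c(paste0("T", strrep("G", 25)), paste0("T", strrep("C", 26)),
                        paste0("A", strrep("G", 25))),
                      c(2L, 1L, 1L))
  bc <- first_base_composition(lib)
  expect_equal(bc$percent[bc$base == "U"], 75)
  expect_equal(bc$percent[bc$base == "A"], 25)
  expect_equal(sum(bc$percent), 100)

  out <- first_base_composition(lib, length_window = c(35, 40))
  expect_true(attr(out, "empty"))
  expect_true(all(is.na(out$percent)))
})

test_that("overlap signature reproduces hand-computed pair weights", {
  # one sense 5'@0 (26-mer) + one antisense 5'@9: exact ping-pong pair
  a <- manual_alignments(c(strrep("A", 26), strrep("C", 26)), "TE1",
                         c("+", "-"), c(0L, 9L))
  os <- overlap_signature(a)
  expect_equal(unname(os$z["10"]), 1)
  expect_equal(os$pingpong_fraction, 1)

  # antisense 5'@14 instead: overlap 15
  b <- manual_alignments(c(strrep("A", 26), strrep("C", 26)), "TE1",
                         c("+", "-"), c(0L, 14L))
  ob <- overlap_signature(b)
  expect_equal(unname(ob$z["15"]), 1)
  expect_equal(ob$pingpong_fraction, 0)

  # n+(0)=3, n-(9)=2, n-(14)=1 -> z(10)=6, z(15)=3, fraction 2/3
  c3 <- manual_alignments(rep(strrep("A", 26), 3), "TE1",
                          c("+", "-", "-"), c(0L, 9L, 14L),
                          copies = c(3L, 2L, 1L))
  oc <- overlap_signature(c3)
  expect_equal(unname(oc$z["10"]), 6)
  expect_equal(unname(oc$z["15"]), 3)
  expect_equal(oc$pingpong_fraction, 6 / 9)

  # species weighting counts each unique insert once
  osp <- overlap_signature(c3, weight = "species")
  expect_equal(unname(osp$z["10"]), 1)
  expect_equal(unname(osp$z["15"]), 1)

  # no opposite-strand co-occurrence: fraction 0, not an error
  solo <- manual_alignments(strrep("A", 26), "TE1", "+", 5L)
  expect_equal(overlap_signature(solo)$pingpong_fraction, 0)
})

test_that("overlap signature equals the all-pairs brute force on random sets", {
  set.seed(512)
  for (i in 1:30) {
    n <- sample(10:120, 1)
    ali <- manual_alignments(
      insert = replicate(n, paste(sample(c("A", "C", "G", "T"), 26, TRUE),
                                  collapse = "")),
      ref_id = sample(paste0("TE", 1:3), n, TRUE),
      strand = sample(c("+", "-"), n, TRUE),
      five_prime = sample(30:90, n, TRUE),
      copies = sample(1:5, n, TRUE))
    for (wmode in c("copies", "species")) {
      os <- overlap_signature(ali, weight = wmode)
      expect_equal(unname(os$z), unname(bf_overlap(ali, 25, wmode)))
    }
  }
})

test_that("strand-bias percentages follow read-level 1U/10A and survive read duplication", {
  mk <- function(first, tenth) {
    s <- strrep("G", 26)
    substr(s, 1, 1) <- first; substr(s, 10, 10) <- tenth
    s
  }
  ali <- manual_alignments(
    c(mk("T", "C"), mk("T", "C"), mk("T", "A"), mk("A", "A"),
      mk("C", "A"), mk("G", "C")),
    "TE1", c("+", "+", "+", "+", "-", "-"), c(10L, 20L, 30L, 40L, 60L, 70L))
  sb <- strand_bias_table(ali)
  expect_equal(sb$pct_1U_sense, 75)
  expect_equal(sb$pct_10A_sense, 50)
  expect_equal(sb$pct_10A_antisense, 50)
  expect_equal(sb$sort_key, sb$pct_1U_sense - sb$pct_1U_antisense)

  dup <- ali; dup$copies <- dup$copies * 7L
  sd <- strand_bias_table(dup)
  expect_equal(sd[, c("pct_1U_sense", "pct_1U_antisense",
                      "pct_10A_sense", "pct_10A_antisense")],
               sb[, c("pct_1U_sense", "pct_1U_antisense",
                      "pct_10A_sense", "pct_10A_antisense")])

  # a strand with no reads carries NA percentages
  solo <- manual_alignments(mk("T", "A"), "TE2", "+", 15L)
  ss <- strand_bias_table(solo)
  expect_true(is.na(ss$pct_1U_antisense))
})

test_that("5'-end profiles respect the coordinate convention and conserve mass", {
  ali <- manual_alignments(c(strrep("A", 26), strrep("C", 26)), "TE1",
                           c("+", "-"), c(5L, 35L), copies = c(2L, 3L))
  pr <- five_prime_profile(ali, "TE1")
  expect_equal(pr$count[pr$strand == "+" & pr$position == 5], 2)
  # the minus read spans [10, 36): its 5' end is end - 1 = 35
  expect_equal(ali$start[2], 10L)
  expect_equal(pr$count[pr$strand == "-" & pr$position == 35], 3)
  expect_equal(sum(pr$count), sum(ali$copies))
  expect_equal(nrow(five_prime_profile(ali, "TE9")), 0L)
})

test_that("producer classification is strict at the RPM threshold", {
  rpm <- data.frame(
    ref_id = rep(c("TE1", "TE2", "TE3", "GENE1"), each = 2),
    class = rep(c("transposon", "transposon", "transposon", "gene"), each = 2),
    strand = rep(c("+", "-"), 4),
    rpm = c(2, 2, 2, 2.1, 80, 3, 50, 50))
  got <- classify_producers(rpm, 4)
  expect_setequal(got, c("TE2", "TE3"))  # 4.0 excluded, 4.1 and 83 included

  set.seed(60)
  r2 <- data.frame(ref_id = rep(paste0("TE", 1:50), each = 2),
                   class = "transposon", strand = rep(c("+", "-"), 50),
                   rpm = runif(100, 0, 10))
  tot <- tapply(r2$rpm, r2$ref_id, sum)
  expect_setequal(classify_producers(r2, 4), names(tot)[tot > 4])
})

test_that("venn regions reproduce the published three-tissue producer counts", {
  # construct sets with the printed sizes: |OV|=1008, |WD|=412, |FB|=208,
  # |OV&WD|=412, |OV&FB|=205, |OV&WD&FB|=200 (so WD is inside OV)
  triple <- paste0("t", 1:200)
  ov_wd <- paste0("ow", 1:212)      # in OV and WD only
  ov_fb <- paste0("of", 1:5)        # in OV and FB only
  ov_only <- paste0("o", 1:591)
  fb_only <- paste0("f", 1:3)
  ov <- c(triple, ov_wd, ov_fb, ov_only)
  wd <- c(triple, ov_wd)
  fb <- c(triple, ov_fb, fb_only)
  expect_equal(length(ov), 1008L)
  expect_equal(length(wd), 412L)
  expect_equal(length(fb), 208L)
  expect_equal(length(intersect(ov, wd)), 412L)
  expect_equal(length(intersect(ov, fb)), 205L)

  v <- venn_regions(ov, wd, fb, labels = c("ovary", "wing_disc", "fat_body"))
  expect_equal(v$union, 1011L)
  expect_equal(v$a_only, 591L)
  expect_equal(v$c_only, 3L)
  expect_equal(v$b_only, 0L)
  expect_equal(v$abc, 200L)
})

test_that("venn regions match exhaustive membership enumeration on random sets", {
  v0 <- venn_regions("x", "y", "z")
  expect_equal(v0$union, 3L)
  expect_equal(c(v0$a_only, v0$b_only, v0$c_only), c(1L, 1L, 1L))

  set.seed(81)
  for (i in 1:20) {
    pool <- paste0("e", 1:100)
    a <- sample(pool, sample(0:60, 1))
    b <- sample(pool, sample(0:60, 1))
    c <- sample(pool, sample(0:60, 1))
    v <- venn_regions(a, b, c)
    o <- bf_venn(a, b, c)
    expect_equal(v[names(o)], o)
  }
})

test_that("named piRNA quantification anchors at the 5' end with length tolerance", {
  q <- "TAGGCATCGAAGTCCGATCCAATGCGA"  # 27 nt
  lib <- fake_library(
    c(q, substr(q, 1, 25), paste0(q, "TT"),        # exact, -2 nt, +2 nt
      substr(q, 1, 23),                            # -4 nt: outside tolerance
      paste0(substr(q, 1, 26), "G"),               # mismatch in overlap? no: length 27
      sub("^T", "C", q)),                          # 5' mismatch
    c(4L, 3L, 2L, 50L, 0L, 7L))
  # note: paste0(substr(q,1,26),"G") differs from q at position 27 only when
  # q's base 27 != G; it is A, so this is a mismatch within the compared span
  rpm <- quantify_named_pirna(lib, q, fake_factor(2e5))
  expect_equal(rpm, 1e6 * (4 + 3 + 2) / 2e5)
  expect_equal(quantify_named_pirna(fake_library(strrep("A", 26), 5L), q,
                                    fake_factor(2e5)), 0)
  expect_error(quantify_named_pirna(lib, substr(q, 1, 15), fake_factor(2e5)),
               ">= 20")
})

test_that("genic silencing candidates require both-strand RPM and fold change in one tissue", {
  g <- paste0("G", 1:4)
  m <- function(v) matrix(v, nrow = 4, dimnames = list(g, c("OV", "FB", "WD")))
  sense <- m(c(12, 8, 15, 12,   1, 1, 1, 1,  1, 1, 1, 1))
  anti <- m(c(15, 15, 15, 15,   1, 1, 1, 1,  1, 1, 1, 1))
  wt <- m(rep(5, 12))
  ko <- m(c(21, 21, 9.4, 21,    5, 5, 5, 5,  5, 5, 5, 5))
  got <- genic_silencing_candidates(sense, anti, wt, ko)
  # G1: all conditions in OV; G2 fails sense RPM; G3 fails the 2-fold rule
  # ((9.4+0.01)/(5+0.01) = 1.88); G4 passes
  expect_setequal(got, c("G1", "G4"))

  wt_bad <- wt; rownames(wt_bad) <- rev(g)
  expect_error(genic_silencing_candidates(sense, anti, wt_bad, ko), "tpm_wt")
})
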