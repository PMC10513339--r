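#' Default piRNA insert length distribution
#'
#' Discrete law over 20-35 nt centered near 27 nt, the typical silkworm piRNA
#' length mode.
#' @return named numeric vector of probabilities summing to 1.
#' @export
default_pirna_length_law <- function() {
  lens <- 20:35
  p <- stats::dnorm(lens, mean = 27, sd = 1.5)
  stats::setNames(p / sum(p), lens)
}

#' Default background (non-piRNA, non-miRNA) length distribution
#'
#' Short degradation-like fragments, 20-25 nt with geometric decay. Keeps the
#' 26-30 nt window piRNA-specific, mirroring knockout libraries where only the
#' ~22 nt small RNA peak remains.
#' @return named numeric vector of probabilities summing to 1.
#' @export
default_background_length_law <- function() {
  lens <- 20:25
  p <- 0.55^(0:5)
  stats::setNames(p / sum(p), lens)
}

#' Parameters for the small RNA library simulator
#'
#' @param pingpong_fraction target ping-pong fraction z(10)/sum z in `[0,1]`.
#' @param bias_1U probability that an antisense (guide-strand) piRNA read
#'   starts with T (reported as U).
#' @param bias_10A probability that a sense (responder-strand) piRNA read
#'   carries A at position 10.
#' @param length_law named probability vector over insert lengths (nt) for
#'   piRNA reads; must sum to 1.
#' @param depth total read count of the library before knockout depletion.
#' @param background_fraction fraction of reads that are background (miRNAs
#'   plus short degradation fragments), not subject to `ko_depletion`.
#' @param ko_depletion multiplier in `[0,1]` on piRNA read mass; 1 = wild type,
#'   0.01 emulates a piRNA-pathway knockout.
#' @param seed integer seed.
#' @param reads_per_locus mean piRNA reads per 5'-end hotspot locus; piRNAs are
#'   emitted from discrete shared 5' ends, as in real libraries.
#' @param o_max maximal 5'-5' overlap used when assigning non-10 offsets to
#'   non-ping-pong locus pairs.
#' @param adapter 3'-adapter core appended after the insert and 3' 4N block.
#' @param spikes optional data.frame with columns `name`, `sequence`, `count`:
#'   defined piRNA sequences (e.g. Fem/Masc-like piRNAs) spiked into the piRNA
#'   mass at a known copy number (scaled by `ko_depletion`).
#' @param bg_length_law named probability vector over background fragment
#'   lengths.
#' @return a validated list of class `smallrna_sim_params`.
#' @export
smallrna_sim_params <- function(pingpong_fraction = 0.7, bias_1U = 0.9,
                                bias_10A = 0.8,
                                length_law = default_pirna_length_law(),
                                depth = 1e5, background_fraction = 0.2,
                                ko_depletion = 1, seed = 1L,
                                reads_per_locus = 800,
                                o_max = 25L,
                                adapter = PIRNA_ADAPTER_CORE,
                                spikes = NULL,
                                bg_length_law = default_background_length_law()) {
  check_prob(pingpong_fraction, "pingpong_fraction")
  check_prob(bias_1U, "bias_1U")
  check_prob(bias_10A, "bias_10A")
  check_prob(background_fraction, "background_fraction")
  check_prob(ko_depletion, "ko_depletion")
  if (depth <= 0) stop_fmt("depth must be > 0")
  if (abs(sum(length_law) - 1) > 1e-8) stop_fmt("length_law must sum to 1")
  if (is.null(names(length_law))) stop_fmt("length_law must be named by length")
  if (abs(sum(bg_length_law) - 1) > 1e-8) stop_fmt("bg_length_law must sum to 1")
  if (o_max < 10) stop_fmt("o_max must be >= 10")
  if (!is.null(spikes) &&
      !all(c("name", "sequence", "count") %in% names(spikes)))
    stop_fmt("spikes must have columns name, sequence, count")
  structure(list(
    pingpong_fraction = pingpong_fraction, bias_1U = bias_1U,
    bias_10A = bias_10A, length_law = length_law, depth = depth,
    background_fraction = background_fraction, ko_depletion = ko_depletion,
    seed = as.integer(seed), reads_per_locus = reads_per_locus,
    o_max = as.integer(o_max), adapter = normalize_nt(adapter),
    spikes = spikes, bg_length_law = bg_length_law
  ), class = "smallrna_sim_params")
}

# draw one 0-based hotspot position on a transposon, restricted to [34, L-36],
# with the reference base at the position being A with probability `p_a`
# (templated 1U on the antisense strand / 10A on the sense strand)
.draw_locus_pos <- function(seq, len, p_a) {
  lo <- 35L; hi <- len - 35L              # 1-based window
  if (hi < lo) stop_fmt("transposon too short for read placement (need >= 71 nt)")
  chars <- strsplit(substr(seq, lo, hi), "", fixed = TRUE)[[1]]
  is_a <- chars == "A"
  want_a <- stats::runif(1) < p_a
  pool <- if (want_a) which(is_a) else which(!is_a)
  if (!length(pool)) pool <- seq_along(chars)
  (lo - 1L) + (pool[sample.int(length(pool), 1L)] - 1L)   # 0-based
}

#' Simulate a 4N-adapter small RNA library with known ping-pong structure
#'
#' Emits raw 50-nt single-end reads laid out as
#' `[4N][insert][4N][3'-adapter core]`, truncated at 50 nt, together with a
#' per-read ground-truth table. piRNA reads are generated from discrete 5'-end
#' hotspot loci on the transposon entries of `catalog`: each locus carries an
#' antisense (guide, 1U-biased) pile and a sense pile on the opposite strand
#' whose 5' end is offset so that the 5'-5' overlap is exactly 10 nt for a
#' `pingpong_fraction` share of loci (sense reads there are responders,
#' 10A-biased) and a non-10 offset otherwise. Background reads are miRNAs
#' (22 nt) and short degradation fragments from all catalog classes.
#' `ko_depletion` scales the piRNA (and spike) read mass only.
#'
#' @param catalog a `reference_catalog` with at least one transposon.
#' @param params a `smallrna_sim_params` object.
#' @return list with elements `reads` (data.frame `id`, `sequence`, `quality`),
#'   `truth` (list: `reads` per-read table with origin/strand/5' position/
#'   category/insert; `library` realized summary values), and `params`.
#' @export
simulate_small_rna_library <- function(catalog, params) {
  catalog <- validate_catalog(catalog)
  if (!inherits(params, "smallrna_sim_params"))
    stop_fmt("params must come from smallrna_sim_params()")
  tes <- catalog[catalog$class == "transposon", , drop = FALSE]
  if (nrow(tes) == 0) stop_fmt("catalog must contain at least one transposon")
  if (params$depth <= 0) stop_fmt("depth must be > 0")

  withr::with_seed(params$seed, {
    n_bg <- round(params$depth * params$background_fraction)
    n_pi <- round(params$depth * (1 - params$background_fraction) *
                    params$ko_depletion)

    pieces <- list()

    ## ---- piRNA hotspot loci ------------------------------------------------
    if (n_pi > 0) {
      # locus count is set by the pre-depletion budget: a knockout thins the
      # reads at each hotspot rather than removing hotspots, so the paired
      # overlap mass z(10) scales with the square of the depletion factor
      n_loci <- max(1L, round(params$depth * (1 - params$background_fraction) /
                                params$reads_per_locus))
      n10 <- round(params$pingpong_fraction * n_loci)
      offsets <- integer(n_loci)
      offsets[seq_len(n10)] <- 10L
      if (n10 < n_loci) {
        other <- setdiff(seq_len(params$o_max), 10L)
        offsets[(n10 + 1L):n_loci] <- sample(other, n_loci - n10, replace = TRUE)
      }
      offsets <- offsets[sample.int(n_loci)]   # shuffle locus order

      te_idx <- sample.int(nrow(tes), n_loci, replace = TRUE,
                           prob = tes$length)
      pos <- integer(n_loci)
      for (i in seq_len(n_loci)) {
        p_a <- if (offsets[i] == 10L) params$bias_10A else params$bias_1U
        pos[i] <- .draw_locus_pos(tes$sequence[te_idx[i]], tes$length[te_idx[i]],
                                  p_a)
      }

      alloc <- tabulate(sample.int(n_loci, n_pi, replace = TRUE), n_loci)
      locus_of <- rep.int(seq_len(n_loci), alloc)
      is_anti <- stats::runif(n_pi) < 0.5
      lens <- sample(as.integer(names(params$length_law)), n_pi,
                     replace = TRUE, prob = params$length_law)

      p0 <- pos[locus_of]                 # antisense 5' (0-based)
      o <- offsets[locus_of]
      q0 <- p0 - o + 1L                   # sense 5' (0-based)
      seqs_te <- tes$sequence[te_idx[locus_of]]

      ins <- character(n_pi)
      # antisense read with 5' end at p covers [p-len+1, p]; sequence is the
      # reverse complement of the reference segment
      ai <- which(is_anti)
      if (length(ai))
        ins[ai] <- revcomp(substr(seqs_te[ai], p0[ai] - lens[ai] + 2L,
                                  p0[ai] + 1L))
      si <- which(!is_anti)
      if (length(si))
        ins[si] <- substr(seqs_te[si], q0[si] + 1L, q0[si] + lens[si])

      # read-level first-base / tenth-base biases (at most one substitution
      # relative to the template; see vignette for why the two biases cannot
      # both be templated at an exact-overlap locus)
      if (length(ai)) {
        forceT <- stats::runif(length(ai)) < params$bias_1U
        b1 <- character(length(ai))
        b1[forceT] <- "T"
        b1[!forceT] <- sample(c("A", "C", "G"), sum(!forceT), replace = TRUE)
        substr(ins[ai], 1L, 1L) <- b1
      }
      if (length(si)) {
        forceA <- stats::runif(length(si)) < params$bias_10A
        b10 <- character(length(si))
        b10[forceA] <- "A"
        b10[!forceA] <- sample(c("C", "G", "T"), sum(!forceA), replace = TRUE)
        substr(ins[si], 10L, 10L) <- b10
      }

      cat_read <- ifelse(is_anti, "primary",
                         ifelse(o == 10L, "responder", "primary"))
      # a responder must have a guide to pair with: demote sense reads at
      # loci that drew no antisense read (vanishingly rare at normal depth)
      orphan <- setdiff(locus_of[cat_read == "responder"],
                        locus_of[is_anti])
      cat_read[cat_read == "responder" & locus_of %in% orphan] <- "primary"
      pieces$pirna <- data.table(
        origin_ref = tes$id[te_idx[locus_of]],
        strand = ifelse(is_anti, "-", "+"),
        five_prime = ifelse(is_anti, p0, q0),
        category = cat_read,
        insert = ins,
        locus = locus_of,
        overlap_offset = o
      )
    }

    ## ---- spiked named piRNAs ----------------------------------------------
    if (!is.null(params$spikes) && nrow(params$spikes) > 0) {
      n_sp <- round(params$spikes$count * params$ko_depletion)
      if (sum(n_sp) > 0) {
        pieces$spike <- data.table(
          origin_ref = rep(paste0("spike:", params$spikes$name), n_sp),
          strand = NA_character_,
          five_prime = NA_integer_,
          category = "primary",
          insert = rep(normalize_nt(params$spikes$sequence), n_sp),
          locus = NA_integer_,
          overlap_offset = NA_integer_
        )
      }
    }

    ## ---- background: miRNAs + degradation fragments ------------------------
    if (n_bg > 0) {
      cls_avail <- unique(catalog$class)
      cls <- sample(cls_avail, n_bg, replace = TRUE)
      bg <- vector("list", length(cls_avail))
      for (k in seq_along(cls_avail)) {
        cc <- cls_avail[k]
        nk <- sum(cls == cc)
        if (nk == 0) next
        sub <- catalog[catalog$class == cc, , drop = FALSE]
        if (cc == "miRNA") {
          j <- sample.int(nrow(sub), nk, replace = TRUE)
          bg[[k]] <- data.table(
            origin_ref = sub$id[j], strand = "+", five_prime = 0L,
            category = "background",
            insert = substr(sub$sequence[j], 1L, 22L),
            locus = NA_integer_, overlap_offset = NA_integer_
          )
        } else {
          j <- sample.int(nrow(sub), nk, replace = TRUE, prob = sub$length)
          lens <- sample(as.integer(names(params$bg_length_law)), nk,
                         replace = TRUE, prob = params$bg_length_law)
          anti <- stats::runif(nk) < 0.5
          L <- sub$length[j]
          start0 <- floor(stats::runif(nk) * (L - lens + 1L))  # 0-based start
          fp <- ifelse(anti, start0 + lens - 1L, start0)
          ins <- substr(sub$sequence[j], start0 + 1L, start0 + lens)
          ins[anti] <- revcomp(ins[anti])
          bg[[k]] <- data.table(
            origin_ref = sub$id[j], strand = ifelse(anti, "-", "+"),
            five_prime = as.integer(fp), category = "background",
            insert = ins, locus = NA_integer_, overlap_offset = NA_integer_
          )
        }
      }
      pieces$bg <- rbindlist(bg)
    }

    truth <- rbindlist(pieces, use.names = TRUE)
    if (nrow(truth) == 0) stop_fmt("simulation produced no reads")
    truth <- truth[sample.int(nrow(truth))]
    truth[, id := sprintf("read%07d", .I)]
    truth[, insert_length := nchar(insert)]

    ## ---- raw read assembly -------------------------------------------------
    n <- nrow(truth)
    n4a <- random_dna_vec(rep(4L, n))
    n4b <- random_dna_vec(rep(4L, n))
    raw <- substr(paste0(n4a, truth$insert, n4b, params$adapter), 1L, 50L)
    reads <- data.frame(
      id = truth$id, sequence = raw,
      quality = strrep("I", nchar(raw)),
      stringsAsFactors = FALSE
    )

    ## ---- realized library-level truth --------------------------------------
    pir <- truth[!is.na(locus)]
    lib_truth <- list(
      true_pingpong_fraction = NA_real_,
      true_1U_rate = NA_real_,
      true_10A_rate = NA_real_,
      n_pirna_reads = nrow(pir),
      n_background_reads = sum(truth$category == "background"),
      target_pingpong_fraction = params$pingpong_fraction
    )
    if (nrow(pir) > 0) {
      cnt <- pir[, .(a = sum(strand == "-"), s = sum(strand == "+")),
                 by = .(locus, overlap_offset)]
      prod <- cnt$a * cnt$s
      denom <- sum(prod)
      lib_truth$true_pingpong_fraction <-
        if (denom > 0) sum(prod[cnt$overlap_offset == 10L]) / denom else 0
      anti <- pir[strand == "-"]
      if (nrow(anti) > 0)
        lib_truth$true_1U_rate <- mean(substr(anti$insert, 1, 1) == "T")
      sen <- pir[strand == "+"]
      if (nrow(sen) > 0)
        lib_truth$true_10A_rate <- mean(substr(sen$insert, 10, 10) == "A")
    }

    list(reads = reads,
         truth = list(reads = as.data.frame(truth), library = lib_truth),
         params = params)
  })
}
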