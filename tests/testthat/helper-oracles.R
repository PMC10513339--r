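# independent brute-force oracles + shared fixtures for the suite

# reverse complement without Biostrings (kept independent of the package path)
bf_revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]])
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

bf_mismatches <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# leftmost adapter start (1-based) with <= mm substitutions over the full core
# or a core prefix >= 10 nt at the read end; NA when absent
bf_trim_start <- function(read, adapter, mm) {
  lr <- nchar(read); la <- nchar(adapter)
  for (s in seq_len(max(0, lr - 9))) {
    w <- min(la, lr - s + 1)
    if (w < 10) next
    if (bf_mismatches(substr(read, s, s + w - 1), substr(adapter, 1, w)) <= mm)
      return(s)
  }
  NA_integer_
}

# all best-stratum placements of an insert on the catalog (0-based starts)
bf_align_one <- function(insert, catalog, max_mm) {
  len <- nchar(insert)
  rc <- bf_revcomp(insert)
  hits <- list()
  for (i in seq_len(nrow(catalog))) {
    L <- catalog$length[i]
    if (len > L) next
    for (st in 0:(L - len)) {
      sub <- substr(catalog$sequence[i], st + 1, st + len)
      mmp <- bf_mismatches(insert, sub)
      if (mmp <= max_mm)
        hits[[length(hits) + 1]] <- data.frame(
          ref_id = catalog$id[i], strand = "+", start = st, mismatches = mmp)
      mmm <- bf_mismatches(rc, sub)
      if (mmm <= max_mm)
        hits[[length(hits) + 1]] <- data.frame(
          ref_id = catalog$id[i], strand = "-", start = st, mismatches = mmm)
    }
  }
  if (!length(hits)) return(NULL)
  all <- do.call(rbind, hits)
  all[all$mismatches == min(all$mismatches), , drop = FALSE]
}

# all-pairs 5'-5' overlap histogram over aligned reads (outer-product route,
# algorithmically unrelated to the package's keyed joins)
bf_overlap <- function(ali, o_max = 25, weight = "copies") {
  z <- setNames(numeric(o_max), seq_len(o_max))
  w <- if (weight == "copies") ali$copies else rep(1, nrow(ali))
  for (r in unique(ali$ref_id)) {
    p <- ali$ref_id == r & ali$strand == "+"
    m <- ali$ref_id == r & ali$strand == "-"
    if (!any(p) || !any(m)) next
    d <- outer(ali$five_prime[m], ali$five_prime[p], "-") + 1L
    ww <- outer(w[m], w[p])
    for (o in seq_len(o_max)) z[o] <- z[o] + sum(ww[d == o])
  }
  z
}

bf_venn <- function(a, b, c) {
  u <- unique(c(a, b, c))
  reg <- sapply(u, function(x) {
    paste0(as.integer(x %in% a), as.integer(x %in% b), as.integer(x %in% c))
  })
  list(a_only = sum(reg == "100"), b_only = sum(reg == "010"),
       c_only = sum(reg == "001"), ab_only = sum(reg == "110"),
       ac_only = sum(reg == "101"), bc_only = sum(reg == "011"),
       abc = sum(reg == "111"), union = length(u))
}

# random small catalog for unit tests
tiny_catalog <- function(seed = 3, n_te = 3, te_len = c(400, 800)) {
  make_reference_catalog(n_te, 1, 2, 1, length_range = te_len, seed = seed)
}

# build an alignment data.frame by hand (for stats-level tests)
manual_alignments <- function(insert, ref_id, strand, five_prime,
                              copies = 1L, class = "transposon") {
  len <- nchar(insert)
  start <- ifelse(strand == "+", five_prime, five_prime - len + 1L)
  data.frame(insert = insert, copies = copies, ref_id = ref_id, class = class,
             strand = strand, start = start, end = start + len,
             five_prime = five_prime, mismatches = 0L, n_best = 1L,
             stringsAsFactors = FALSE)
}

# ---- cached heavy fixtures (shared by acceptance blocks) --------------------
.acc_cache <- new.env(parent = emptyenv())

acc_catalog <- function() {
  if (is.null(.acc_cache$cat))
    .acc_cache$cat <- make_reference_catalog(35, 10, 12, 3,
                                             length_range = c(3000, 6000),
                                             seed = 11)
  .acc_cache$cat
}

acc_spikes <- function() {
  data.frame(
    name = c("fem_like", "masc_like"),
    sequence = c("TAGGCATCGAAGTCCGATCCAATGCGA", "TCGCATTGGATCGGACTTCGATGCCTA"),
    count = c(400, 300), stringsAsFactors = FALSE
  )
}

# full WT pipeline at study depth (1e5 reads, ping-pong 0.7, background 20%)
acc_wt <- function() {
  if (is.null(.acc_cache$wt)) {
    cat <- acc_catalog()
    sim <- simulate_small_rna_library(
      cat, smallrna_sim_params(pingpong_fraction = 0.7, depth = 1e5,
                               seed = 42, spikes = acc_spikes()))
    lib <- process_library(sim$reads, library_id = "WT")
    al <- align_reads(lib, cat, max_mismatches = 1, seed = 5)
    .acc_cache$wt <- list(sim = sim, lib = lib, al = al)
  }
  .acc_cache$wt
}

# matched knockout library (1% piRNA mass)
acc_ko <- function() {
  if (is.null(.acc_cache$ko)) {
    cat <- acc_catalog()
    sim <- simulate_small_rna_library(
      cat, smallrna_sim_params(pingpong_fraction = 0.7, depth = 1e5,
                               seed = 43, ko_depletion = 0.01,
                               spikes = acc_spikes()))
    lib <- process_library(sim$reads, library_id = "KO")
    al <- align_reads(lib, cat, max_mismatches = 1, seed = 5)
    .acc_cache$ko <- list(sim = sim, lib = lib, al = al)
  }
  .acc_cache$ko
}
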