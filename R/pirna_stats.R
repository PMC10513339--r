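#' Normalized length distribution of a processed library
#'
#' Copy-weighted insert counts per length, scaled to RPM with the supplied
#' normalization factor.
#'
#' @param library a `processed_library`.
#' @param factor a `normalization_factor`.
#' @return data.frame `length`, `rpm` (empty for an empty library).
#' @export
length_distribution <- function(library, factor) {
  if (!inherits(factor, "normalization_factor"))
    stop_fmt("factor must come from normalization_factor()")
  cnt <- library$counts
  if (nrow(cnt) == 0)
    return(data.frame(length = integer(0), rpm = numeric(0)))
  agg <- tapply(cnt$count, nchar(cnt$insert), sum)
  data.frame(length = as.integer(names(agg)),
             rpm = 1e6 * unname(agg) / factor$denominator)
}

#' First-base composition of reads in a length window
#'
#' Copy-weighted percentages of A/C/G/U at read position 1 among inserts whose
#' length falls in `length_window` (default 26-30 nt, the piRNA window).
#' T is reported as U.
#'
#' @param library a `processed_library`.
#' @param length_window inclusive length bounds.
#' @return data.frame `base` (A, C, G, U), `percent`; when no read falls in
#'   the window all percentages are `NA` and attribute `empty` is `TRUE`.
#' @export
first_base_composition <- function(library, length_window = c(26L, 30L)) {
  cnt <- library$counts
  lens <- nchar(cnt$insert)
  keep <- lens >= length_window[1] & lens <= length_window[2]
  out <- data.frame(base = c("A", "C", "G", "U"), percent = NA_real_,
                    stringsAsFactors = FALSE)
  if (!any(keep)) {
    attr(out, "empty") <- TRUE
    return(out)
  }
  fb <- substr(cnt$insert[keep], 1, 1)
  fb[fb == "T"] <- "U"
  w <- cnt$count[keep]
  tot <- sum(w)
  out$percent <- vapply(out$base, function(b) 100 * sum(w[fb == b]) / tot, 0)
  attr(out, "empty") <- FALSE
  out
}

# copy-weighted (or species-weighted) 5'-end count tables per strand
.five_prime_tables <- function(ali, weight) {
  dt <- as.data.table(ali)
  dt[, w := if (weight == "copies") copies else 1L]
  dt[, .(w = sum(w)), by = .(ref_id, strand, five_prime)]
}

#' Ping-pong overlap signature
#'
#' Computes the 5'-5' overlap histogram z(o) = sum over references and
#' positions p of n_plus(p) * n_minus(p + o - 1), where n_plus / n_minus are
#' (copy-weighted) counts of sense / antisense reads with the given 5' end.
#' The o = 10 bin is the ping-pong signal; `pingpong_fraction` is
#' z(10) / sum(z), defined as 0 when no opposite-strand co-occurrence exists.
#'
#' @param aligned result of [align_reads()] (or its `alignments` element),
#'   optionally pre-filtered; use `ref_ids` to restrict references.
#' @param o_max maximal overlap (default 25); must be >= 10.
#' @param weight `"copies"` (reads; default) or `"species"` (each unique
#'   insert once) — the two readings of "sense and antisense pairs".
#' @param ref_ids optional character vector restricting the references used.
#' @return object of class `overlap_histogram`: list `z` (named numeric,
#'   overlaps 1..o_max) and `pingpong_fraction`.
#' @export
overlap_signature <- function(aligned, o_max = 25L, weight = c("copies", "species"),
                              ref_ids = NULL) {
  weight <- match.arg(weight)
  if (o_max < 10) stop_fmt("o_max must be >= 10")
  ali <- if (is.data.frame(aligned)) aligned else aligned$alignments
  if (!is.null(ref_ids)) ali <- ali[ali$ref_id %in% ref_ids, , drop = FALSE]
  z <- stats::setNames(numeric(o_max), seq_len(o_max))
  if (nrow(ali)) {
    tab <- .five_prime_tables(ali, weight)
    plus <- tab[strand == "+", .(ref_id, p5 = five_prime, wp = w)]
    minus <- tab[strand == "-", .(ref_id, q5 = five_prime, wm = w)]
    if (nrow(plus) && nrow(minus)) {
      setkey(minus, ref_id, q5)
      for (o in seq_len(o_max)) {
        j <- minus[plus[, .(ref_id, q5 = p5 + o - 1L, wp)],
                   on = c("ref_id", "q5"), nomatch = NULL]
        if (nrow(j)) z[o] <- sum(as.numeric(j$wp) * as.numeric(j$wm))
      }
    }
  }
  tot <- sum(z)
  structure(list(z = z,
                 pingpong_fraction = if (tot > 0) unname(z["10"]) / tot else 0),
            class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat(sprintf("<overlap_histogram> z(10) = %.4g, ping-pong fraction = %.4f\n",
              x$z["10"], x$pingpong_fraction))
  invisible(x)
}

#' Per-transposon 1U/10A strand-bias table
#'
#' For each transposon and strand, the copy-weighted percentage of reads
#' (inserts in `length_window`) whose first base is T (1U) and whose tenth
#' base is A (10A), evaluated on the read as sequenced (antisense reads are
#' reverse complements of the reference). Records are sorted descending by
#' `sort_key` = 1U% sense minus 1U% antisense; pass `order_by` to impose the
#' ordering computed from a designated (e.g. wild-type ovary) library.
#'
#' @param aligned result of [align_reads()] (or its `alignments` element).
#' @param length_window inclusive insert length bounds (default 26-30).
#' @param min_reads strand records with fewer copy-weighted reads than this
#'   carry `NA` percentages (default 1 keeps everything with >= 1 read).
#' @param order_by optional character vector of transposon ids giving the sort
#'   order from another library's table.
#' @return data.frame `ref_id`, `pct_1U_sense`, `pct_1U_antisense`,
#'   `pct_10A_sense`, `pct_10A_antisense`, `n_sense`, `n_antisense`,
#'   `sort_key`.
#' @export
strand_bias_table <- function(aligned, length_window = c(26L, 30L),
                              min_reads = 1, order_by = NULL) {
  ali <- if (is.data.frame(aligned)) aligned else aligned$alignments
  ali <- ali[ali$class == "transposon", , drop = FALSE]
  lens <- nchar(ali$insert)
  ali <- ali[lens >= length_window[1] & lens <= length_window[2], , drop = FALSE]
  if (nrow(ali) == 0)
    return(data.frame(ref_id = character(0), pct_1U_sense = numeric(0),
                      pct_1U_antisense = numeric(0), pct_10A_sense = numeric(0),
                      pct_10A_antisense = numeric(0), n_sense = numeric(0),
                      n_antisense = numeric(0), sort_key = numeric(0)))
  dt <- as.data.table(ali)
  dt[, first_base := substr(insert, 1, 1)]
  dt[, tenth_base := substr(insert, 10, 10)]
  agg <- dt[, .(n = sum(copies),
                p1u = 100 * sum(copies * (first_base == "T")) / sum(copies),
                p10a = 100 * sum(copies * (tenth_base == "A")) / sum(copies)),
            by = .(ref_id, strand)]
  wide <- dcast(agg, ref_id ~ strand, value.var = c("n", "p1u", "p10a"))
  getcol <- function(nm) if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
  out <- data.frame(
    ref_id = wide$ref_id,
    pct_1U_sense = getcol("p1u_+"),
    pct_1U_antisense = getcol("p1u_-"),
    pct_10A_sense = getcol("p10a_+"),
    pct_10A_antisense = getcol("p10a_-"),
    n_sense = getcol("n_+"),
    n_antisense = getcol("n_-"),
    stringsAsFactors = FALSE
  )
  out$n_sense[is.na(out$n_sense)] <- 0
  out$n_antisense[is.na(out$n_antisense)] <- 0
  out$pct_1U_sense[out$n_sense < min_reads] <- NA_real_
  out$pct_10A_sense[out$n_sense < min_reads] <- NA_real_
  out$pct_1U_antisense[out$n_antisense < min_reads] <- NA_real_
  out$pct_10A_antisense[out$n_antisense < min_reads] <- NA_real_
  out$sort_key <- out$pct_1U_sense - out$pct_1U_antisense
  if (is.null(order_by)) {
    out <- out[order(-xtfrm(out$sort_key)), , drop = FALSE]
  } else {
    out <- out[match(intersect(order_by, out$ref_id), out$ref_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Strand-resolved 5'-end position profile of one reference
#'
#' @param aligned result of [align_reads()] (or its `alignments` element).
#' @param ref_id reference to profile.
#' @return data.frame `position` (0-based), `strand`, `count` (copy-weighted
#'   5'-end count). Exports put sense counts on the positive axis and
#'   antisense on the negative axis; here raw counts are returned.
#' @export
five_prime_profile <- function(aligned, ref_id) {
  ali <- if (is.data.frame(aligned)) aligned else aligned$alignments
  ali <- ali[ali$ref_id == ref_id, , drop = FALSE]
  if (nrow(ali) == 0)
    return(data.frame(position = integer(0), strand = character(0),
                      count = numeric(0)))
  dt <- as.data.table(ali)[, .(count = sum(copies)),
                           by = .(position = five_prime, strand)]
  setorder(dt, strand, position)
  as.data.frame(dt)
}

#' Classify piRNA-producing transposons by an RPM threshold
#'
#' A transposon is a producer when its sense + antisense RPM is strictly
#' greater than `threshold` (default 4).
#'
#' @param rpm a data.frame from [rpm_table()].
#' @param threshold RPM threshold (strict).
#' @return character vector of producing transposon ids.
#' @export
classify_producers <- function(rpm, threshold = 4) {
  if (threshold < 0) stop_fmt("threshold must be >= 0")
  te <- rpm[rpm$class == "transposon", , drop = FALSE]
  tot <- tapply(te$rpm, te$ref_id, sum)
  names(tot)[tot > threshold]
}

#' Three-set Venn decomposition with inclusion-exclusion check
#'
#' @param set_a,set_b,set_c finite sets (vectors of ids).
#' @param labels names for the three sets.
#' @return list with the seven exclusive region counts (`a_only`, `b_only`,
#'   `c_only`, `ab_only`, `ac_only`, `bc_only`, `abc`), the `union` size, and
#'   `labels`. The exclusive regions are verified internally to sum to the
#'   union and to satisfy inclusion-exclusion.
#' @export
venn_regions <- function(set_a, set_b, set_c, labels = c("A", "B", "C")) {
  a <- unique(set_a); b <- unique(set_b); c <- unique(set_c)
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  out <- list(
    a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab_only = sum(ina & inb & !inc),
    ac_only = sum(ina & !inb & inc),
    bc_only = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc),
    union = length(u),
    labels = labels
  )
  stopifnot(
    out$a_only + out$b_only + out$c_only + out$ab_only + out$ac_only +
      out$bc_only + out$abc == out$union,
    length(a) + length(b) + length(c) -
      sum(ina & inb) - sum(ina & inc) - sum(inb & inc) +
      out$abc == out$union
  )
  structure(out, class = "venn_regions")
}

#' Quantify a named piRNA (e.g. a Fem- or Masc-type piRNA) in a library
#'
#' Counts collapsed inserts identical to the query over
#' `min(insert length, query length)` bases anchored at the 5' end, with
#' insert length within `len_tol` nt of the query and zero mismatches, scaled
#' to RPM.
#'
#' @param library a `processed_library`.
#' @param query piRNA sequence (RNA or DNA alphabet), length >= 20.
#' @param factor a `normalization_factor`.
#' @param len_tol allowed 3'-length heterogeneity in nt (default 3).
#' @return normalized RPM (0 when the query is absent).
#' @export
quantify_named_pirna <- function(library, query, factor, len_tol = 3L) {
  query <- normalize_nt(query)
  if (nchar(query) < 20) stop_fmt("query length must be >= 20")
  if (!inherits(factor, "normalization_factor"))
    stop_fmt("factor must come from normalization_factor()")
  cnt <- library$counts
  if (nrow(cnt) == 0) return(0)
  lens <- nchar(cnt$insert)
  lq <- nchar(query)
  cand <- abs(lens - lq) <= len_tol
  if (!any(cand)) return(0)
  m <- pmin(lens[cand], lq)
  hit <- substring(cnt$insert[cand], 1, m) == substring(query, 1, m)
  1e6 * sum(cnt$count[cand][hit]) / factor$denominator
}

#' Genic piRNA-silencing candidate search
#'
#' Genes (transposons excluded by construction of the inputs) where, in at
#' least one tissue, both sense and antisense piRNA RPM exceed
#' `rpm_threshold` and expression is more than `fc_threshold`-fold
#' up-regulated in the knockout.
#'
#' @param sense_rpm,antisense_rpm gene x tissue matrices of piRNA RPM.
#' @param tpm_wt,tpm_ko gene x tissue matrices of expression TPM.
#' @param rpm_threshold strict RPM threshold per strand (default 10).
#' @param fc_threshold strict fold-change threshold (default 2).
#' @param pseudocount added to TPM on both sides of the ratio (default 0.01).
#' @return character vector of candidate gene ids.
#' @export
genic_silencing_candidates <- function(sense_rpm, antisense_rpm, tpm_wt, tpm_ko,
                                       rpm_threshold = 10, fc_threshold = 2,
                                       pseudocount = 0.01) {
  if (rpm_threshold <= 0 || fc_threshold <= 0)
    stop_fmt("thresholds must be > 0")
  mats <- list(sense_rpm = sense_rpm, antisense_rpm = antisense_rpm,
               tpm_wt = tpm_wt, tpm_ko = tpm_ko)
  genes <- rownames(sense_rpm)
  bad <- names(mats)[!vapply(mats, function(m)
    identical(rownames(m), genes), TRUE)]
  if (length(bad))
    stop_fmt("gene universes differ across inputs: %s",
             paste(bad, collapse = ", "))
  fc <- (tpm_ko + pseudocount) / (tpm_wt + pseudocount)
  ok <- sense_rpm > rpm_threshold & antisense_rpm > rpm_threshold &
    fc > fc_threshold
  genes[rowSums(ok, na.rm = TRUE) > 0]
}
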