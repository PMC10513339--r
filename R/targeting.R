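#' Do two piRNAs form a ping-pong pair?
#'
#' True iff the first 10 nt of one sequence are the reverse complement of the
#' first 10 nt of the other (strict Watson-Crick, no wobble). Symmetric in its
#' arguments.
#'
#' @param seq_a,seq_b piRNA sequences (RNA or DNA alphabet), each >= 10 nt.
#' @return logical scalar.
#' @examples
#' a <- "TGCGATATTGCAAGTCCGATGCACGGT"
#' b <- paste0(revcomp_seq(substr(a, 1, 10)), "GGGTTTAAACCCGGG")
#' pairs_by_pingpong(a, b)
#' @export
pairs_by_pingpong <- function(seq_a, seq_b) {
  a <- normalize_nt(seq_a); b <- normalize_nt(seq_b)
  if (nchar(a) < 10 || nchar(b) < 10)
    stop_fmt("both sequences must be at least 10 nt")
  substr(a, 1, 10) == revcomp(substr(b, 1, 10))
}

#' Reverse complement (exported convenience wrapper)
#'
#' @param x DNA character vector.
#' @return reverse-complemented character vector.
#' @export
revcomp_seq <- function(x) revcomp(normalize_nt(x))

#' Scan a target for piRNA-guided slicer cleavage sites
#'
#' Finds every placement where guide positions `required_span[1]` to
#' `required_span[2]` (default 2-18) pair perfectly, antiparallel
#' Watson-Crick, with the target. Guide position 1 (the 1U pocket base) and
#' positions beyond the span are unconstrained. Each site is reported with
#' the cleavage bond between the target bases opposite guide positions 10 and
#' 11.
#'
#' @param guide guide piRNA sequence (>= 18 nt for the default span).
#' @param target target sequence (mRNA/DNA alphabet).
#' @param required_span 1-based inclusive guide positions that must pair.
#' @param max_mismatches mismatches tolerated inside the span (default 0, the
#'   strict sufficiency rule).
#' @return data.frame with one row per site: `pair_start`, `pair_end`
#'   (0-based half-open pairing interval on the target), `bond_i`, `bond_j`
#'   (the cleavage bond, adjacent 0-based target indices), and
#'   `mismatches_span`. Zero rows when no site exists.
#' @export
find_cleavage_sites <- function(guide, target, required_span = c(2L, 18L),
                                max_mismatches = 0L) {
  guide <- normalize_nt(guide)
  target <- normalize_nt(target)
  s1 <- required_span[1]; s2 <- required_span[2]
  if (s1 < 2 || s2 <= s1) stop_fmt("invalid required_span")
  if (nchar(guide) < s2) stop_fmt("guide must be at least %d nt", s2)
  empty <- data.frame(pair_start = integer(0), pair_end = integer(0),
                      bond_i = integer(0), bond_j = integer(0),
                      mismatches_span = integer(0))
  span_len <- s2 - s1 + 1L
  if (nchar(target) < span_len) return(empty)
  # guide positions s1..s2 pair target indices t1-(s1-1) .. t1-(s2-1)
  # (t1 = target index opposite guide position 1); on the target's forward
  # strand the paired block reads revcomp(guide[s1..s2])
  pat <- revcomp(substr(guide, s1, s2))
  hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(target),
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE)
  if (length(hits) == 0) return(empty)
  start0 <- BiocGenerics::start(hits) - 1L          # 0-based block start
  mm <- vapply(seq_along(hits), function(i) {
    sum(strsplit(as.character(hits[[i]]), "")[[1]] !=
          strsplit(pat, "")[[1]])
  }, 1L)
  t1 <- start0 + (s2 - 1L)                          # index opposite guide pos 1
  bond_i <- t1 - 10L                                 # opposite guide pos 11
  bond_j <- t1 - 9L                                  # opposite guide pos 10
  ok <- bond_i >= 0 & bond_j <= nchar(target) - 1L
  data.frame(pair_start = (t1 - (s2 - 1L))[ok],
             pair_end = (t1 - (s1 - 1L) + 1L)[ok],
             bond_i = bond_i[ok], bond_j = bond_j[ok],
             mismatches_span = mm[ok])
}

#' 5' end of the responder piRNA implied by a cleavage site
#'
#' Slicer cuts the target between the bases opposite guide positions 10 and
#' 11; the 3' cleavage fragment becomes the responder piRNA precursor, so its
#' 5' end is the target base paired to guide position 10. The implied
#' responder overlaps the guide by exactly 10 nt at the 5' ends.
#'
#' @param site one row of [find_cleavage_sites()] output (or a list with
#'   `bond_j`).
#' @param guide the guide sequence (unused in the coordinate arithmetic; kept
#'   so callers can verify the implied pairing).
#' @return 0-based target index of the responder 5' end (= `bond_j`).
#' @export
responder_five_prime <- function(site, guide = NULL) {
  if (is.data.frame(site)) {
    if (nrow(site) != 1) stop_fmt("site must be a single cleavage site")
    site <- as.list(site)
  }
  if (is.null(site$bond_j)) stop_fmt("site must carry 'bond_j'")
  as.integer(site$bond_j)
}
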