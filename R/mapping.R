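# enumerate all substrings of the catalog at the given lengths.
# Returns a data.table (seq, ref_id, start0, strand "+") keyed by seq; a
# negative-strand placement of a read is found by joining its reverse
# complement against this table.
.substring_index <- function(catalog, lengths) {
  lengths <- sort(unique(as.integer(lengths)))
  out <- vector("list", nrow(catalog) * length(lengths))
  k <- 0L
  for (i in seq_len(nrow(catalog))) {
    L <- catalog$length[i]
    sq <- catalog$sequence[i]
    for (len in lengths) {
      if (len > L) next
      k <- k + 1L
      starts <- seq_len(L - len + 1L)
      out[[k]] <- data.table(
        seq = substring(sq, starts, starts + len - 1L),
        ref_id = catalog$id[i],
        start0 = starts - 1L
      )
    }
  }
  idx <- rbindlist(out[seq_len(k)])
  if (nrow(idx)) setkey(idx, seq)
  idx
}

# all single-substitution variants of the given sequences.
# Returns data.table(orig, variant); the original sequence itself is excluded.
.one_sub_variants <- function(seqs) {
  if (!length(seqs)) return(data.table(orig = character(0), variant = character(0)))
  lens <- nchar(seqs)
  # generate all 4 bases at every position, then drop the identity rows
  orig4 <- rep.int(seqs, lens * 4L)
  pos4 <- unlist(lapply(lens, function(l) rep(seq_len(l), each = 4L)),
                 use.names = FALSE)
  alt4 <- rep_len(.DNA_BASES, length(orig4))
  keep <- substr(orig4, pos4, pos4) != alt4
  orig4 <- orig4[keep]; pos4 <- pos4[keep]; alt4 <- alt4[keep]
  variant <- orig4
  substr(variant, pos4, pos4) <- alt4
  data.table(orig = orig4, variant = variant)
}

#' Align collapsed inserts to the reference catalog
#'
#' Enumerates every placement of each unique insert on both strands of every
#' reference with at most `max_mismatches` substitutions, keeps the placements
#' with the minimum mismatch count, and resolves multi-placement ties by one
#' uniform seeded draw. Multi-mapping reads are therefore counted once, never
#' fractionally.
#'
#' @param library a `processed_library` (or data.frame with `insert`, `count`).
#' @param catalog a `reference_catalog`.
#' @param max_mismatches 0 or 1 substitutions.
#' @param seed integer seed for the tie-break draw.
#' @return list with `alignments` (data.frame: `insert`, `copies`, `ref_id`,
#'   `class`, `strand`, `start` 0-based, `end` half-open, `five_prime`,
#'   `mismatches`, `n_best` = size of the best stratum) and `unmapped`
#'   (copy-weighted unmapped read count).
#' @export
align_reads <- function(library, catalog, max_mismatches = 1L, seed = 1L) {
  catalog <- validate_catalog(catalog)
  if (!max_mismatches %in% c(0L, 1L))
    stop_fmt("max_mismatches must be 0 or 1")
  counts <- if (inherits(library, "processed_library")) library$counts else library
  if (!all(c("insert", "count") %in% names(counts)))
    stop_fmt("library must provide columns 'insert' and 'count'")
  empty <- data.frame(
    insert = character(0), copies = integer(0), ref_id = character(0),
    class = character(0), strand = character(0), start = integer(0),
    end = integer(0), five_prime = integer(0), mismatches = integer(0),
    n_best = integer(0), stringsAsFactors = FALSE)
  if (nrow(counts) == 0) return(list(alignments = empty, unmapped = 0L))

  dt <- data.table(insert = counts$insert, copies = counts$count)
  has_n <- grepl("[^ACGT]", dt$insert)
  unmapped_copies <- sum(dt$copies[has_n])
  dt <- dt[!has_n]
  if (nrow(dt) == 0) return(list(alignments = empty, unmapped = unmapped_copies))

  idx <- .substring_index(catalog, nchar(dt$insert))
  dt[, rc := revcomp(insert)]

  join_hits <- function(queries, orient) {
    if (!length(queries)) return(NULL)
    h <- idx[J(unique(queries)), nomatch = NULL]
    if (!nrow(h)) return(NULL)
    h[, strand := orient]
    h
  }
  plus0 <- join_hits(dt$insert, "+")
  if (!is.null(plus0)) plus0[, orig := seq]
  minus0 <- join_hits(dt$rc, "-")
  if (!is.null(minus0)) {
    # map the matched rc sequence back to the original insert
    rc_map <- dt[, .(rcseq = rc, orig = insert)]
    setkey(rc_map, rcseq)
    minus0[, orig := rc_map[J(seq), orig, mult = "first"]]
  }
  hits0 <- rbindlist(list(plus0, minus0), use.names = TRUE, fill = TRUE)
  if (nrow(hits0)) hits0[, mismatches := 0L]

  hits1 <- NULL
  if (max_mismatches >= 1L) {
    found0 <- unique(hits0$orig)
    rest <- dt[!insert %in% found0]
    if (nrow(rest)) {
      # join variants against the index keeping every (orig, placement) pair;
      # a variant can be shared by two inserts at Hamming distance 2
      vplus <- .one_sub_variants(rest$insert)
      hp <- idx[vplus, on = c(seq = "variant"), nomatch = NULL,
                allow.cartesian = TRUE]
      if (nrow(hp)) hp[, strand := "+"] else hp <- NULL
      vminus <- .one_sub_variants(rest$rc)
      hm <- idx[vminus, on = c(seq = "variant"), nomatch = NULL,
                allow.cartesian = TRUE]
      if (nrow(hm)) {
        rc_map <- rest[, .(rcseq = rc, ins = insert)]
        setkey(rc_map, rcseq)
        hm[, orig := rc_map[J(orig), ins, mult = "first"]]
        hm[, strand := "-"]
      } else hm <- NULL
      hits1 <- rbindlist(list(hp, hm), use.names = TRUE, fill = TRUE)
      if (!is.null(hits1) && nrow(hits1)) hits1[, mismatches := 1L]
      else hits1 <- NULL
    }
  }

  if (!is.null(hits0) && nrow(hits0) == 0) hits0 <- NULL
  hits <- rbindlist(list(hits0, hits1), use.names = TRUE, fill = TRUE)
  if (is.null(hits) || nrow(hits) == 0)
    return(list(alignments = empty,
                unmapped = unmapped_copies + sum(dt$copies)))

  hits <- hits[, .(orig, ref_id, start0, strand, mismatches)]
  setorder(hits, orig, mismatches, ref_id, strand, start0)
  hits[, n_best := .N, by = orig]
  chosen <- withr::with_seed(as.integer(seed), {
    hits[, .SD[sample.int(.N, 1L)], by = orig]
  })

  chosen <- merge(chosen, dt[, .(insert, copies)], by.x = "orig",
                  by.y = "insert", sort = FALSE)
  cls <- stats::setNames(catalog$class, catalog$id)
  len <- nchar(chosen$orig)
  ali <- data.frame(
    insert = chosen$orig,
    copies = chosen$copies,
    ref_id = chosen$ref_id,
    class = unname(cls[chosen$ref_id]),
    strand = chosen$strand,
    start = chosen$start0,
    end = chosen$start0 + len,
    five_prime = ifelse(chosen$strand == "+", chosen$start0,
                        chosen$start0 + len - 1L),
    mismatches = chosen$mismatches,
    n_best = chosen$n_best,
    stringsAsFactors = FALSE
  )
  unmapped <- unmapped_copies + sum(dt$copies) - sum(ali$copies)
  list(alignments = ali, unmapped = unmapped)
}

#' Copy-weighted mapping rate to a reference class
#'
#' @param aligned result of [align_reads()] (or its `alignments` element).
#' @param library the `processed_library` the alignments came from.
#' @param target_class reference class, e.g. `"transposon"`.
#' @return percentage of copy-weighted kept reads whose chosen placement is on
#'   a reference of `target_class`.
#' @export
mapping_rate <- function(aligned, library, target_class = "transposon") {
  ali <- if (is.data.frame(aligned)) aligned else aligned$alignments
  kept <- if (inherits(library, "processed_library")) library$stats$kept
          else sum(library$count)
  if (is.null(kept) || kept == 0) stop_fmt("empty library")
  100 * sum(ali$copies[ali$class == target_class]) / kept
}

#' Library normalization factor (transposon-mapped or top-10 miRNA reads)
#'
#' In `transposon` mode the denominator is the copy-weighted read count on
#' transposon-class references (rRNA-derived repeats carry their own class and
#' are therefore excluded, as the normalization demands). In `mirna_top10`
#' mode it is the copy-weighted count on the 10 most abundant miRNA references
#' of this library (all of them when fewer than 10 are hit).
#'
#' @param aligned result of [align_reads()] (or its `alignments` element).
#' @param catalog the `reference_catalog` (kept for interface symmetry; class
#'   labels already travel with the alignments).
#' @param mode `"transposon"` or `"mirna_top10"`.
#' @param library_id label carried on the factor.
#' @return object of class `normalization_factor`: list `library_id`, `mode`,
#'   `denominator`.
#' @export
normalization_factor <- function(aligned, catalog = NULL,
                                 mode = c("transposon", "mirna_top10"),
                                 library_id = "library") {
  mode <- match.arg(mode)
  ali <- if (is.data.frame(aligned)) aligned else aligned$alignments
  denom <- if (mode == "transposon") {
    sum(ali$copies[ali$class == "transposon"])
  } else {
    per <- tapply(ali$copies[ali$class == "miRNA"],
                  ali$ref_id[ali$class == "miRNA"], sum)
    sum(head(sort(unname(per), decreasing = TRUE), 10L))
  }
  if (is.na(denom) || denom <= 0) stop_fmt("no mapped reads for normalization")
  structure(list(library_id = library_id, mode = mode, denominator = denom),
            class = "normalization_factor")
}

#' Per-reference, per-strand RPM table
#'
#' RPM(ref, strand) = 1e6 x copy-weighted reads on (ref, strand) /
#' denominator. All catalog references appear on both strands (zero when no
#' reads); in transposon mode the RPM summed over transposon-class references
#' closes to 1e6.
#'
#' @param aligned result of [align_reads()] (or its `alignments` element).
#' @param factor a `normalization_factor`.
#' @param catalog the `reference_catalog`.
#' @return data.frame `ref_id`, `class`, `strand`, `rpm`, with the factor
#'   attached as attribute `factor`.
#' @export
rpm_table <- function(aligned, factor, catalog) {
  if (!inherits(factor, "normalization_factor"))
    stop_fmt("factor must come from normalization_factor()")
  catalog <- validate_catalog(catalog)
  ali <- if (is.data.frame(aligned)) aligned else aligned$alignments
  grid <- data.table(ref_id = rep(catalog$id, each = 2L),
                     class = rep(catalog$class, each = 2L),
                     strand = rep(c("+", "-"), nrow(catalog)))
  if (nrow(ali)) {
    agg <- as.data.table(ali)[, .(n = sum(copies)), by = .(ref_id, strand)]
    grid <- merge(grid, agg, by = c("ref_id", "strand"), all.x = TRUE,
                  sort = FALSE)
  } else grid[, n := NA_real_]
  grid[is.na(n), n := 0]
  grid[, rpm := 1e6 * n / factor$denominator]
  out <- as.data.frame(grid[, .(ref_id, class, strand, rpm)])
  attr(out, "factor") <- factor
  out
}

#' Export chosen alignments as minimal SAM text
#'
#' Writes one record per unique insert with fields QNAME, FLAG (0x10 for the
#' minus strand), RNAME, 1-based POS, full-length-match CIGAR, the
#' reference-forward SEQ, and tags `NM:i` (mismatches) and `XC:i` (collapsed
#' copy number).
#'
#' @param aligned result of [align_reads()] (or its `alignments` element).
#' @param catalog the `reference_catalog` (for `@SQ` headers).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aligned, catalog, path) {
  catalog <- validate_catalog(catalog)
  ali <- if (is.data.frame(aligned)) aligned else aligned$alignments
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", catalog$id, catalog$length))
  seq_fwd <- ifelse(ali$strand == "-", revcomp(ali$insert), ali$insert)
  recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tXC:i:%d",
                  ali$insert, ifelse(ali$strand == "-", 16L, 0L), ali$ref_id,
                  ali$start + 1L, nchar(ali$insert), seq_fwd, ali$mismatches,
                  ali$copies)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Import minimal SAM alignments (alternative entry point to the aligner)
#'
#' Reads 11-column SAM records; strand from FLAG bit 0x10, copies from the
#' `XC:i` tag when present (1 otherwise), mismatches from `NM:i` (0 otherwise).
#' The stored reference-forward SEQ is reverse-complemented back to the read
#' as sequenced for minus-strand records.
#'
#' @param path SAM path.
#' @param catalog the `reference_catalog`, used to annotate reference classes.
#' @return data.frame in the same shape as `align_reads()$alignments`.
#' @export
read_sam <- function(path, catalog) {
  catalog <- validate_catalog(catalog)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(align_reads(data.frame(insert = character(0), count = integer(0)),
                       catalog)$alignments)
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  seq_fwd <- toupper(get(10))
  insert <- ifelse(strand == "-", revcomp(seq_fwd), seq_fwd)
  tagval <- function(tag) {
    vapply(f, function(x) {
      hit <- grep(paste0("^", tag, ":i:"), x, value = TRUE)
      if (length(hit)) as.integer(sub(".*:", "", hit[1])) else NA_integer_
    }, 1L)
  }
  nm <- tagval("NM"); nm[is.na(nm)] <- 0L
  xc <- tagval("XC"); xc[is.na(xc)] <- 1L
  start0 <- as.integer(get(4)) - 1L
  len <- nchar(insert)
  cls <- stats::setNames(catalog$class, catalog$id)
  data.frame(
    insert = insert, copies = xc, ref_id = get(3),
    class = unname(cls[get(3)]), strand = strand, start = start0,
    end = start0 + len,
    five_prime = ifelse(strand == "+", start0, start0 + len - 1L),
    mismatches = nm, n_best = NA_integer_, stringsAsFactors = FALSE
  )
}
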