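#' Read a FASTQ file into a data.frame
#'
#' Minimal strict FASTQ reader (4-line records, gzip transparently supported).
#' Malformed records raise an error naming the record index, which is part of
#' the preprocessing contract.
#'
#' @param path FASTQ (or .gz) path.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop_fmt("malformed FASTQ: truncated record %d", length(lines) %/% 4L + 1L)
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop_fmt("malformed FASTQ record %d: header must start with '@'", bad[1])
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop_fmt("malformed FASTQ record %d: missing '+' line", bad[1])
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) stop_fmt("malformed FASTQ record %d: sequence/quality length mismatch", bad[1])
  bad <- which(nchar(seqs) == 0L)
  if (length(bad)) stop_fmt("malformed FASTQ record %d: empty sequence", bad[1])
  data.frame(id = sub("^@", "", hdr), sequence = toupper(seqs), quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   (constant high quality is emitted when absent).
#' @param path output path (plain text, or gzip when ending in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  out <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

# vectorized leftmost adapter-core locator.
# Returns 1-based adapter start per read (NA when not found). A hit requires
# <= max_mismatches substitutions over the full core, or over a core prefix of
# at least `min_overlap` nt when the read ends before the core does.
.locate_adapter <- function(seqs, adapter, max_mismatches, min_overlap = 10L) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  lr <- nchar(seqs)
  lmax <- max(lr)
  ad <- strsplit(adapter, "", fixed = TRUE)[[1]]
  la <- length(ad)
  padded <- paste0(seqs, strrep("?", lmax - lr))
  m <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  found <- rep(NA_integer_, n)
  for (s in seq_len(max(0L, lmax - min_overlap + 1L))) {
    open <- is.na(found) & (lr - s + 1L >= min_overlap)
    if (!any(open)) next
    wmax <- min(la, lmax - s + 1L)
    ws <- pmin(la, lr - s + 1L)          # per-read usable core width
    mm <- integer(n)
    hit <- rep(FALSE, n)
    for (j in seq_len(wmax)) {
      mm <- mm + (m[, s + j - 1L] != ad[j])
      done <- open & (ws == j)
      if (any(done)) hit[done] <- mm[done] <= max_mismatches
    }
    found[hit] <- s
  }
  found
}

#' Remove the 3'-adapter core and flanking 4N bases from one read
#'
#' Locates the leftmost position where the adapter core matches the read with
#' at most `max_mismatches` substitutions (the full core, or a core prefix of
#' at least 10 nt when the read ends first), then strips the adapter and the
#' two 4-nt randomized blocks (the first 4 nt of the read and the last 4 nt
#' before the adapter).
#'
#' @param sequence read sequence (A/C/G/T/N; U tolerated and folded to T).
#' @param adapter_core adapter core sequence (default the 4N-library 3'
#'   adapter minus its randomized bases).
#' @param max_mismatches maximal substitutions in the adapter match; the
#'   default 1 implements the "fewer than 2 mismatches" rule.
#' @return the insert string, or `NULL` when no adapter is found or when the
#'   segment 5' of the adapter is shorter than the two 4N blocks (8 nt).
#' @examples
#' trim_adapter(paste0("AAGC", strrep("T", 26), "GCCA", PIRNA_ADAPTER_CORE))
#' @export
trim_adapter <- function(sequence, adapter_core = PIRNA_ADAPTER_CORE,
                         max_mismatches = 1L) {
  if (nchar(adapter_core) == 0) stop_fmt("adapter_core must be non-empty")
  if (max_mismatches < 0) stop_fmt("max_mismatches must be >= 0")
  s <- .locate_adapter(normalize_nt(sequence), normalize_nt(adapter_core),
                       max_mismatches)[1]
  if (is.na(s) || s - 1L < 8L) return(NULL)
  substr(normalize_nt(sequence), 5L, s - 5L)
}

#' Process a raw small RNA library into a collapsed unique-insert count table
#'
#' Applies adapter/4N trimming to every read, filters inserts outside
#' `[min_len, max_len]`, and collapses identical inserts with summed counts.
#' Read fates are tracked exactly: `input = no_adapter + length_rejected +
#' kept`.
#'
#' @param reads a data.frame with columns `id` and `sequence` (e.g. from
#'   [read_fastq()] or the simulator), or a FASTQ path.
#' @param adapter_core,max_mismatches see [trim_adapter()].
#' @param min_len,max_len inclusive insert length bounds (defaults 20 and 40).
#' @param library_id,tissue,genotype library metadata carried on the result.
#' @return an object of class `processed_library`: list with `library_id`,
#'   `metadata`, `counts` (data.frame `insert`, `count`, sorted by decreasing
#'   count) and `stats` (`input`, `no_adapter`, `length_rejected`, `kept`).
#' @export
process_library <- function(reads, adapter_core = PIRNA_ADAPTER_CORE,
                            max_mismatches = 1L, min_len = 20L, max_len = 40L,
                            library_id = "library", tissue = NA_character_,
                            genotype = NA_character_) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (!all(c("id", "sequence") %in% names(reads)))
    stop_fmt("reads must have columns 'id' and 'sequence'")
  if (min_len > max_len) stop_fmt("min_len must be <= max_len")

  seqs <- normalize_nt(reads$sequence)
  n <- length(seqs)
  stats <- list(input = n, no_adapter = 0L, length_rejected = 0L, kept = 0L)
  counts <- data.frame(insert = character(0), count = integer(0),
                       stringsAsFactors = FALSE)
  if (n > 0) {
    s <- .locate_adapter(seqs, normalize_nt(adapter_core), max_mismatches)
    no_ad <- is.na(s)
    ins_len <- ifelse(no_ad, NA_integer_, s - 9L)
    keep <- !no_ad & ins_len >= min_len & ins_len <= max_len
    stats$no_adapter <- sum(no_ad)
    stats$length_rejected <- sum(!no_ad & !keep)
    stats$kept <- sum(keep)
    if (any(keep)) {
      inserts <- substr(seqs[keep], 5L, s[keep] - 5L)
      dt <- data.table(insert = inserts)[, .(count = .N), by = insert]
      setorder(dt, -count, insert)
      counts <- as.data.frame(dt)
    }
  }
  structure(list(
    library_id = library_id,
    metadata = list(tissue = tissue, genotype = genotype),
    counts = counts,
    stats = stats
  ), class = "processed_library")
}

#' @export
print.processed_library <- function(x, ...) {
  cat(sprintf(
    "<processed_library> %s: %d reads in, %d kept (%d unique inserts), %d no adapter, %d length-rejected\n",
    x$library_id, x$stats$input, x$stats$kept, nrow(x$counts),
    x$stats$no_adapter, x$stats$length_rejected))
  invisible(x)
}

#' Write a collapsed count table (TSV) with a JSON-like stats sidecar
#'
#' @param library a `processed_library`.
#' @param prefix output prefix; writes `<prefix>.counts.tsv` and
#'   `<prefix>.stats.tsv`.
#' @return the counts path, invisibly.
#' @export
write_library <- function(library, prefix) {
  cp <- paste0(prefix, ".counts.tsv")
  utils::write.table(library$counts, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sp <- paste0(prefix, ".stats.tsv")
  st <- data.frame(stat = names(library$stats),
                   value = unlist(library$stats), row.names = NULL)
  utils::write.table(st, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cp)
}
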