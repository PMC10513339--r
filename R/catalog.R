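#' Generate a reference catalog of transposons, genes, miRNAs and rRNA repeats
#'
#' Builds a classed set of random reference sequences that the whole pipeline
#' maps against: transposon consensus sequences, gene models, miRNA precursors
#' and rRNA-derived repeats. Transposon, gene and rRNA-repeat lengths are drawn
#' uniformly from `length_range`; miRNA entries are precursor-sized
#' (`mirna_length_range`, default 65-90 nt) since mature miRNA reads are 22 nt
#' regardless of the catalog-wide length range.
#'
#' @param n_transposons,n_genes,n_mirnas,n_rrna number of entries per class.
#' @param length_range integer pair, inclusive length range (nt) for
#'   transposon/gene/rRNA-repeat entries.
#' @param seed integer seed; the same seed reproduces the catalog exactly.
#' @param mirna_length_range integer pair, length range for miRNA entries.
#' @return A `data.frame` of class `reference_catalog` with columns `id`,
#'   `class` (one of `transposon`, `gene`, `miRNA`, `rRNA_repeat`), `sequence`
#'   and `length`.
#' @examples
#' cat <- make_reference_catalog(2, 1, 1, 1, length_range = c(500, 1000), seed = 7)
#' table(cat$class)
#' @export
make_reference_catalog <- function(n_transposons, n_genes = 0L, n_mirnas = 0L,
                                   n_rrna = 0L, length_range = c(1000L, 5000L),
                                   seed = 1L,
                                   mirna_length_range = c(65L, 90L)) {
  counts <- c(n_transposons, n_genes, n_mirnas, n_rrna)
  if (any(counts < 0)) stop_fmt("entry counts must be >= 0")
  if (sum(counts) == 0) stop_fmt("empty catalog")
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 1)
    stop_fmt("invalid length_range")

  withr::with_seed(as.integer(seed), {
    classes <- rep(c("transposon", "gene", "miRNA", "rRNA_repeat"), counts)
    ids <- c(
      sprintf("TE%04d", seq_len(n_transposons)),
      sprintf("GENE%04d", seq_len(n_genes)),
      sprintf("MIR%03d", seq_len(n_mirnas)),
      sprintf("RRNA%03d", seq_len(n_rrna))
    )
    draw_len <- function(n, rng) {
      rng[1] - 1L + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE)
    }
    lens <- integer(length(classes))
    main <- classes != "miRNA"
    lens[main] <- draw_len(sum(main), as.integer(length_range))
    lens[!main] <- draw_len(sum(!main), as.integer(mirna_length_range))
    out <- data.frame(
      id = ids, class = classes,
      sequence = random_dna_vec(lens),
      length = lens,
      stringsAsFactors = FALSE
    )
    class(out) <- c("reference_catalog", "data.frame")
    validate_catalog(out)
  })
}

#' Validate a reference catalog
#'
#' Checks the catalog invariants: unique ids, non-empty sequences over
#' \{A,C,G,T\}, `length` equal to the sequence length, and classes drawn from
#' the four-way enum.
#'
#' @param catalog a `reference_catalog` (or plain data.frame with the same
#'   columns).
#' @return the catalog, invisibly usable, with class `reference_catalog`.
#' @export
validate_catalog <- function(catalog) {
  need <- c("id", "class", "sequence", "length")
  if (!all(need %in% names(catalog)))
    stop_fmt("catalog must have columns %s", paste(need, collapse = ", "))
  if (nrow(catalog) == 0) stop_fmt("empty catalog")
  if (anyDuplicated(catalog$id)) stop_fmt("catalog ids must be unique")
  if (any(nchar(catalog$sequence) == 0)) stop_fmt("catalog sequences must be non-empty")
  if (!all(catalog$length == nchar(catalog$sequence)))
    stop_fmt("catalog 'length' must equal sequence length")
  ok <- c("transposon", "gene", "miRNA", "rRNA_repeat")
  if (!all(catalog$class %in% ok))
    stop_fmt("catalog classes must be one of: %s", paste(ok, collapse = ", "))
  if (any(grepl("[^ACGT]", catalog$sequence)))
    stop_fmt("catalog sequences must be over {A,C,G,T}")
  if (!inherits(catalog, "reference_catalog"))
    class(catalog) <- c("reference_catalog", class(catalog))
  catalog
}

#' Write a reference catalog to FASTA (+ class annotation TSV)
#'
#' @param catalog a `reference_catalog`.
#' @param fasta_path output FASTA path.
#' @param classes_path optional TSV path for the `id`/`class` annotation table.
#' @return `fasta_path`, invisibly.
#' @export
write_catalog <- function(catalog, fasta_path, classes_path = NULL) {
  catalog <- validate_catalog(catalog)
  seqs <- Biostrings::DNAStringSet(catalog$sequence)
  names(seqs) <- catalog$id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  if (!is.null(classes_path)) {
    utils::write.table(catalog[, c("id", "class")], classes_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Read a reference catalog from FASTA and a class annotation TSV
#'
#' @param fasta_path FASTA of reference sequences.
#' @param classes_path TSV with columns `id` and `class`.
#' @return a `reference_catalog`.
#' @export
read_catalog <- function(fasta_path, classes_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- utils::read.table(classes_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "class") %in% names(ann)))
    stop_fmt("class annotation must have columns 'id' and 'class'")
  ids <- sub("\\s.*$", "", names(seqs))
  m <- match(ids, ann$id)
  if (anyNA(m)) stop_fmt("missing class annotation for: %s",
                         paste(head(ids[is.na(m)], 5), collapse = ", "))
  out <- data.frame(
    id = ids, class = ann$class[m],
    sequence = normalize_nt(as.character(seqs)),
    length = Biostrings::width(seqs),
    stringsAsFactors = FALSE
  )
  validate_catalog(out)
}
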