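# small internal helpers shared across modules

# vectorized reverse complement of DNA character vectors
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# fold RNA to DNA alphabet, uppercase
normalize_nt <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# one random DNA string of length n (uses current RNG stream)
random_dna <- function(n) {
  paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}

# n random DNA strings with lengths `lens`
random_dna_vec <- function(lens) {
  if (!length(lens)) return(character(0))
  total <- sum(lens)
  bases <- sample(.DNA_BASES, total, replace = TRUE)
  stops <- cumsum(lens)
  starts <- stops - lens + 1L
  all <- paste(bases, collapse = "")
  substring(all, starts, stops)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_fmt("'%s' must be a single value in [0, 1]", name)
  invisible(x)
}
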