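#' Synthetic codon decoding-rate table
#'
#' A reproducible stand-in for an empirically estimated decoding-rate
#' table: the 61 sense codons get lognormal rates spanning roughly
#' 0.5-35/s, rescaled so the mean is exactly 10/s (the transcriptome
#' average used throughout).  The packaged copy lives at
#' `system.file("extdata", "codon_rates_synthetic.tsv", package = "riboloop")`.
#'
#' @param seed integer seed for the lognormal draw.
#' @param mean_rate target mean decoding rate in 1/s.
#' @return Named numeric vector, codon -> rate in 1/s, mean exactly
#'   `mean_rate`.
#' @export
synthetic_rate_table <- function(seed = 20170609L, mean_rate = 10) {
  set.seed(seed)
  raw <- exp(stats::rnorm(length(SENSE_CODONS), mean = 0, sd = 0.8))
  rates <- raw * mean_rate / mean(raw)
  validate_rate_table(setNames(rates, SENSE_CODONS))
}

#' Generate a synthetic transcriptome
#'
#' Random CDS records with a valid start codon, no internal stops, and a
#' terminal stop codon, for exercising the codon-specific pipeline without
#' external data.  Codons are sampled uniformly from the 61 sense codons
#' (after the fixed ATG start).
#'
#' @param n number of transcripts.
#' @param length_range CDS length range in codons (stop included), each
#'   length drawn uniformly.
#' @param seed integer seed.
#' @return Named character vector of CDS sequences (ids `synth_0001`, ...).
#' @export
make_transcriptome <- function(n, length_range = c(100L, 600L), seed) {
  if (n < 1) stop("n must be >= 1")
  length_range <- as.integer(length_range)
  if (any(length_range < 3)) stop("CDS length must be at least 3 codons")
  set.seed(seed)
  lens <- if (length_range[1] == length_range[2]) rep(length_range[1], n) else
    sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    body <- sample(SENSE_CODONS, L - 2L, replace = TRUE)
    stop_codon <- sample(STOP_CODONS, 1L)
    paste0("ATG", paste(body, collapse = ""), stop_codon)
  }, character(1))
  setNames(seqs, sprintf("synth_%04d", seq_len(n)))
}

#' Write a transcriptome to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a rate table to TSV
#'
#' @param table named numeric vector, codon -> rate in 1/s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path) {
  df <- data.frame(codon = names(table), rate_per_s = unname(table))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
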