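SENSE_CODONS <- {
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

#' Read coding sequences from FASTA
#'
#' @param path path to a (plain-text) FASTA file of CDS records.
#' @return Named character vector of uppercase DNA sequences (`U`
#'   converted to `T`).  Duplicate ids and empty files are errors.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records")
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  setNames(seqs, ids)
}

#' Read a codon decoding-rate table
#'
#' Two-column delimited text (codon, rate in 1/s), tab- or
#' whitespace-delimited, header optional.  Codons may use RNA letters (`U`
#' is converted).  The table must contain exactly the 61 sense codons with
#' positive rates and no stop codons.
#'
#' @param path path to the table.
#' @return Named numeric vector, codon -> decoding rate (1/s).
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(raw) < 2) stop("rate table needs two columns: codon, rate")
  if (suppressWarnings(is.na(as.numeric(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  codons <- toupper(gsub("U", "T", as.character(raw[[1]]), fixed = TRUE))
  rates <- suppressWarnings(as.numeric(raw[[2]]))
  if (any(is.na(rates))) stop("non-numeric rate entries in table")
  validate_rate_table(setNames(rates, codons))
}

#' Validate a codon decoding-rate table
#'
#' @param table named numeric vector, codon -> rate in 1/s.
#' @return The table (sorted by codon), invisibly usable.
#' @export
validate_rate_table <- function(table) {
  codons <- names(table)
  if (is.null(codons)) stop("rate table must be named by codon")
  bad <- codons[!grepl("^[ACGT]{3}$", codons)]
  if (length(bad) > 0)
    stop(sprintf("invalid codon(s): %s", paste(unique(bad), collapse = ", ")))
  stops <- intersect(codons, STOP_CODONS)
  if (length(stops) > 0)
    stop(sprintf("stop codon(s) present in rate table: %s",
                 paste(stops, collapse = ", ")))
  if (anyDuplicated(codons)) stop("duplicate codon entries in rate table")
  missing <- setdiff(SENSE_CODONS, codons)
  if (length(missing) > 0)
    stop(sprintf("rate table missing %d sense codon(s): %s",
                 length(missing), paste(head(missing, 6), collapse = ", ")))
  if (any(table <= 0) || any(!is.finite(table)))
    stop("all decoding rates must be finite and > 0")
  table[order(names(table))]
}

#' Read per-transcript lifetimes
#'
#' Delimited text with a header, either `id` + `lifetime` (s), or `id` +
#' `abundance` + `transcription_rate` (1/s), in which case lifetime =
#' abundance / transcription rate.
#'
#' @param path path to the table.
#' @return Named numeric vector, id -> lifetime (s), all positive.
#' @export
read_lifetimes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- read.delim(path, stringsAsFactors = FALSE, sep = "")
  cols <- tolower(names(tab))
  names(tab) <- cols
  if (!("id" %in% cols)) stop("lifetime table needs an `id` column")
  lt <- if ("lifetime" %in% cols) {
    as.numeric(tab$lifetime)
  } else if (all(c("abundance", "transcription_rate") %in% cols)) {
    rate <- as.numeric(tab$transcription_rate)
    if (any(rate <= 0)) stop("transcription rates must be > 0")
    as.numeric(tab$abundance) / rate
  } else {
    stop("unknown schema: need `lifetime`, or `abundance` + `transcription_rate`")
  }
  if (any(!is.finite(lt)) || any(lt <= 0)) stop("lifetimes must be finite and > 0")
  if (anyDuplicated(tab$id)) stop("duplicate ids in lifetime table")
  setNames(lt, tab$id)
}

#' Write / read a summary table
#'
#' Tab-delimited with a fixed header; `write` then `read` round-trips.
#'
#' @param rows a data frame (e.g. `translatome_run(...)$table`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a JSON run manifest
#'
#' Records the full configuration of a run (parameters, seeds, package
#' version) so outputs are auditable; round-trips through [read_manifest()].
#'
#' @param config a named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  config$riboloop_version <- as.character(utils::packageVersion("riboloop"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
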