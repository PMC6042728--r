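# Reading, validating and windowing amino-acid sequences.

#' Create a sequence record
#'
#' A sequence record holds one identifier/sequence pair.  The sequence is
#' uppercased on ingest and validated against the 20-letter standard
#' amino-acid alphabet; records containing other characters (ambiguity codes
#' such as B, J, O, U, X, Z, or `*`) are flagged invalid rather than silently
#' altered or dropped.
#'
#' @param id free-text identifier.
#' @param sequence amino-acid sequence (case-insensitive on input).
#' @return an object of class `seq_record` with fields `id`, `sequence`
#'   (uppercased), `length`, `valid` and `invalid_chars`.
#' @export
#' @examples
#' seq_record("p1", "aappPYaa")
seq_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- unique(chars[!chars %in% AA_ALPHABET])
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         valid = length(bad) == 0L && nchar(sequence) >= 1L,
         invalid_chars = bad),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  shown <- if (x$length > 60L) paste0(substr(x$sequence, 1L, 57L), "...") else x$sequence
  cat(sprintf("<seq_record> %s (%d aa%s)\n  %s\n", x$id, x$length,
              if (x$valid) "" else paste0("; INVALID: ",
                                          paste(x$invalid_chars, collapse = ",")),
              shown))
  invisible(x)
}

#' Read a FASTA file of protein or peptide sequences
#'
#' Entries are returned in file order with sequences uppercased.  Sequences
#' containing characters outside the 20 standard amino-acid codes are kept
#' but flagged invalid (see [seq_record()]); a warning names the offending
#' records and characters.
#'
#' @param path path to a FASTA (`.fasta`/`.txt`) file.
#' @return a list of [seq_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) {
    warning("FASTA file '", path, "' contains no sequences")
    return(list())
  }
  records <- mapply(seq_record, names(set), as.character(set),
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  bad <- Filter(function(r) !r$valid, records)
  if (length(bad) > 0L) {
    warning("record(s) with non-standard residues flagged invalid: ",
            paste(vapply(bad, function(r)
              sprintf("%s [%s]", r$id, paste(r$invalid_chars, collapse = ",")),
              character(1)), collapse = "; "))
  }
  records
}

#' Write sequence records to a FASTA file
#'
#' @param records a list of [seq_record()] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Extract all sliding windows of a fixed length
#'
#' Returns every contiguous length-`L` substring of a record with 1-based
#' inclusive coordinates.  Exactly one window -- the last -- carries
#' `is_c_terminal = TRUE`, marking that it ends at the parent sequence's
#' C-terminus (the feature PDZ prediction uses).  A sequence shorter than
#' `L` yields zero windows.
#'
#' @param record a [seq_record()].
#' @param L window length (positive integer).
#' @return a data.frame with columns `parent_id`, `start`, `end`,
#'   `sequence`, `is_c_terminal`; zero rows if the record is shorter
#'   than `L`.
#' @export
#' @examples
#' windows(seq_record("p1", "AAPPPYAA"), 6)
windows <- function(record, L) {
  stopifnot(inherits(record, "seq_record"), L >= 1L)
  L <- as.integer(L)
  n <- record$length - L + 1L
  if (n < 1L) {
    return(data.frame(parent_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      is_c_terminal = logical(0)))
  }
  start <- seq_len(n)
  end <- start + L - 1L
  data.frame(parent_id = record$id, start = start, end = end,
             sequence = substring(record$sequence, start, end),
             is_c_terminal = end == record$length)
}

# Em dash used in the combined report for "no call from this method",
# mirroring the tabular server-style output.
NO_CALL <- "—"

#' Write a combined hit table to TSV
#'
#' One row per predicted peptide region, with the output of all four methods
#' side by side; a method that did not call the region shows an em dash.
#' Scores are printed with 4 decimal places unless `digits = NA` (full
#' precision).
#'
#' @param hits a data.frame as returned by [scan_sequences()] (columns
#'   `parent_id`, `start`, `end`, `sequence`, `svm_score`, `pssm_score`,
#'   `mim_instance`, `res_pattern`, `n_methods_agreeing`).
#' @param path output path.
#' @param digits decimal places for scores (default 4; `NA` for full
#'   precision).
#' @return invisibly, `path`.
#' @export
write_hits_table <- function(hits, path, digits = 4L) {
  fmt_score <- function(x) {
    out <- rep(NO_CALL, length(x))
    ok <- !is.na(x)
    out[ok] <- if (is.na(digits)) format(x[ok], digits = 17) else
      formatC(x[ok], format = "f", digits = digits)
    out
  }
  fmt_chr <- function(x) ifelse(is.na(x), NO_CALL, x)
  out <- data.frame(
    query_id = hits$parent_id, start = hits$start, end = hits$end,
    window = hits$sequence,
    svm_score = fmt_score(hits$svm_score),
    pssm_score = fmt_score(hits$pssm_score),
    mim_instance = fmt_chr(hits$mim_instance),
    res_pattern = fmt_chr(hits$res_pattern),
    n_methods_agreeing = hits$n_methods_agreeing,
    check.names = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
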