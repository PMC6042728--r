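# String-matching predictors: regular-expression scanning (RES) and exact
# motif-instance matching (MIM).

#' Create a regular-expression motif library
#'
#' Patterns use standard regular-expression syntax over amino-acid letters:
#' `.` for a wildcard position, character classes like `[RK]`, and a `$`
#' end anchor for C-terminal motifs (PDZ).  Every pattern is compiled at
#' construction; an invalid pattern raises an error naming it.
#'
#' @param patterns character vector of patterns (order preserved).
#' @param domain_class optional domain label.
#' @return an object of class `regex_library`.
#' @export
regex_library <- function(patterns, domain_class = NULL) {
  stopifnot(is.character(patterns), length(patterns) > 0L)
  for (p in patterns) {
    ok <- tryCatch({ suppressWarnings(regexpr(p, "A", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("invalid regular expression pattern: '", p, "'")
  }
  structure(list(domain_class = domain_class, patterns = patterns),
            class = "regex_library")
}

# Replaceable default motif patterns per domain, assembled from canonical
# literature motifs: SH3 binds proline-rich PxxP cores often flanked by
# basic residues; WW binds PPxY / PPLP; PDZ binds C-terminal [ST]x[VIL]-COOH
# (class I) or hydrophobic class II motifs.
DEFAULT_REGEX <- list(
  SH3 = c("P..P", "[RK]..P..P", "P..P.[RK]"),
  WW  = c("PP.Y", "PPLP"),
  PDZ = c("[ST].[VIL]$", "[FYV].[VIL]$")
)

#' Default regular-expression library for a domain
#'
#' Canonical literature motifs shipped as a replaceable default; supply
#' your own curated list via [read_regex_library()] for serious use.
#'
#' @param domain `"SH3"`, `"WW"` or `"PDZ"`.
#' @return a [regex_library()].
#' @export
#' @examples
#' default_regex_library("PDZ")
default_regex_library <- function(domain) {
  domain <- match.arg(domain, DOMAIN_CLASSES)
  regex_library(DEFAULT_REGEX[[domain]], domain)
}

#' @export
print.regex_library <- function(x, ...) {
  cat(sprintf("<regex_library>%s %d pattern(s): %s\n",
              if (is.null(x$domain_class)) "" else paste0(" ", x$domain_class),
              length(x$patterns), paste(x$patterns, collapse = "  ")))
  invisible(x)
}

#' Read a regular-expression library from a plain-text file
#'
#' One pattern per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @param domain_class optional domain label.
#' @return a [regex_library()].
#' @export
read_regex_library <- function(path, domain_class = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no patterns in '", path, "'")
  regex_library(lines, domain_class)
}

#' Create a known-instance library
#'
#' A set of experimentally validated binder peptides used for exact
#' substring matching.
#'
#' @param instances character vector of peptides (uppercased, deduplicated).
#' @param domain_class optional domain label.
#' @return an object of class `instance_library`.
#' @export
instance_library <- function(instances, domain_class = NULL) {
  stopifnot(is.character(instances), length(instances) > 0L)
  structure(list(domain_class = domain_class,
                 instances = unique(toupper(instances))),
            class = "instance_library")
}

#' @export
print.instance_library <- function(x, ...) {
  cat(sprintf("<instance_library>%s %d instance(s)\n",
              if (is.null(x$domain_class)) "" else paste0(" ", x$domain_class),
              length(x$instances)))
  invisible(x)
}

#' Read an instance library from a peptide list or FASTA file
#'
#' @param path plain-text file with one peptide per line (`#` comments
#'   allowed) or a FASTA file (detected by a leading `>`).
#' @param domain_class optional domain label.
#' @return an [instance_library()].
#' @export
read_instance_library <- function(path, domain_class = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0L && startsWith(first, ">")) {
    recs <- read_fasta(path)
    instance_library(vapply(recs, `[[`, character(1), "sequence"),
                     domain_class)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    instance_library(lines, domain_class)
  }
}

empty_hits <- function() {
  data.frame(method = character(0), parent_id = character(0),
             start = integer(0), end = integer(0),
             sequence = character(0), matched_pattern = character(0))
}

bind_hit_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty_hits())
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$start, out$end, out$matched_pattern), , drop = FALSE]
}

# All (possibly overlapping) matches of one regex in a sequence: anchor the
# pattern at every start position.  End-anchored ($) patterns then match
# only when they reach the sequence terminus.
regex_matches_all <- function(sequence, pattern) {
  n <- nchar(sequence)
  anchored <- paste0("^(?:", pattern, ")")
  hits <- lapply(seq_len(n), function(i) {
    m <- regexpr(anchored, substring(sequence, i), perl = TRUE)
    if (m == 1L) c(start = i, end = i + attr(m, "match.length") - 1L) else NULL
  })
  do.call(rbind, hits)
}

#' Scan a sequence with a regular-expression motif library
#'
#' Every match of every pattern is reported, including overlapping matches;
#' end-anchored patterns match only at the sequence terminus.  Coordinates
#' are 1-based inclusive and refer to the matched span itself.
#'
#' @param record a [seq_record()] (or a bare peptide string).
#' @param library a [regex_library()].
#' @return data.frame of hits: `method` (`"RES"`), `parent_id`, `start`,
#'   `end`, `sequence` (matched span), `matched_pattern`.
#' @export
#' @examples
#' res_scan(seq_record("q", "AAPPPYAA"), regex_library("PP.Y"))
res_scan <- function(record, library) {
  stopifnot(inherits(library, "regex_library"))
  if (is.character(record)) record <- seq_record("query", record)
  rows <- lapply(library$patterns, function(pat) {
    m <- regex_matches_all(record$sequence, pat)
    if (is.null(m)) return(NULL)
    data.frame(method = "RES", parent_id = record$id,
               start = m[, "start"], end = m[, "end"],
               sequence = substring(record$sequence, m[, "start"], m[, "end"]),
               matched_pattern = pat)
  })
  bind_hit_rows(rows)
}

# All exact (overlapping) substring occurrences of `inst` in `sequence`.
exact_matches_all <- function(sequence, inst) {
  n <- nchar(sequence)
  m <- nchar(inst)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  starts[substring(sequence, starts, starts + m - 1L) == inst]
}

#' Match known motif instances exactly within a sequence
#'
#' Reports every exact substring occurrence of every library instance,
#' including multiple and overlapping occurrences.
#'
#' @param record a [seq_record()] (or a bare peptide string).
#' @param library an [instance_library()].
#' @return data.frame of hits: `method` (`"MIM"`), `parent_id`, `start`,
#'   `end`, `sequence`, `matched_pattern` (the matching instance).
#' @export
#' @examples
#' mim_match(seq_record("q", "AAKPRPLPVA"), instance_library("KPRPLP"))
mim_match <- function(record, library) {
  stopifnot(inherits(library, "instance_library"))
  if (is.character(record)) record <- seq_record("query", record)
  rows <- lapply(library$instances, function(inst) {
    starts <- exact_matches_all(record$sequence, inst)
    if (length(starts) == 0L) return(NULL)
    data.frame(method = "MIM", parent_id = record$id, start = starts,
               end = starts + nchar(inst) - 1L, sequence = inst,
               matched_pattern = inst)
  })
  bind_hit_rows(rows)
}

#' Binary classification of a peptide by exact instance matching
#'
#' @param peptide peptide string.
#' @param library an [instance_library()].
#' @return `TRUE` iff any library instance occurs as an exact substring of
#'   the peptide.
#' @export
mim_classify <- function(peptide, library) {
  nrow(mim_match(seq_record("q", peptide), library)) > 0L
}

#' Binary classification of a peptide by regular-expression scanning
#'
#' @param peptide peptide string.
#' @param library a [regex_library()].
#' @return `TRUE` iff any pattern matches anywhere in the peptide.
#' @export
res_classify <- function(peptide, library) {
  nrow(res_scan(seq_record("q", peptide), library)) > 0L
}
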