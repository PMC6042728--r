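# Compositional feature encoding: amino-acid (AAC), dipeptide (DPC) and
# over-represented tripeptide (TPC) percentage compositions, plus the
# C-terminal location flag used for PDZ ligands.

# Lexicographic k-mer orderings over the fixed alphabet, computed once.
ALL_DIPEPTIDES <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))

split_kmers <- function(peptide, k) {
  n <- nchar(peptide)
  if (n < k) stop("peptide shorter than ", k, " residues: '", peptide, "'")
  substring(peptide, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

check_peptide <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nchar(peptide) >= 1L)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid residue(s) in peptide '", peptide, "': ",
         paste(bad, collapse = ","))
  chars
}

#' Amino-acid composition (AAC)
#'
#' Percentage of each of the 20 standard amino acids in the peptide:
#' `100 * count_i / length`.  Entries are in fixed alphabetical order
#' (A, C, D, ..., Y) and sum to 100.
#'
#' @param peptide amino-acid string (standard alphabet).
#' @return named numeric vector of length 20.
#' @export
#' @examples
#' aac("PPPGGG")
aac <- function(peptide) {
  chars <- check_peptide(peptide)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  setNames(100 * as.vector(counts) / length(chars), AA_ALPHABET)
}

#' Dipeptide composition (DPC)
#'
#' Percentage of each of the 400 possible dipeptides among the peptide's
#' `length - 1` overlapping dipeptides: `100 * count_j / (length - 1)`.
#' Entries follow lexicographic order (AA, AC, ..., YY) and sum to 100.
#'
#' @inheritParams aac
#' @return named numeric vector of length 400.
#' @export
dpc <- function(peptide) {
  check_peptide(peptide)
  dimers <- split_kmers(peptide, 2L)
  counts <- table(factor(dimers, levels = ALL_DIPEPTIDES))
  setNames(100 * as.vector(counts) / length(dimers), ALL_DIPEPTIDES)
}

#' Select over-represented tripeptides for a ligand class
#'
#' A tripeptide is over-represented when it occurs in more than one ligand
#' peptide of the class, i.e. in at least two distinct positive peptides
#' (multiple occurrences inside a single peptide do not count).  Using only
#' these tripeptides keeps the TPC feature block far below the 8000 possible
#' tripeptides.  The returned list is sorted lexicographically so that the
#' feature order is stable and serializable.
#'
#' @param positives character vector of positive peptides from one class.
#' @return character vector of selected tripeptides (possibly empty).
#' @export
select_overrepresented_tripeptides <- function(positives) {
  if (length(positives) < 2L) return(character(0))
  per_pep <- lapply(positives, function(p) unique(split_kmers(p, 3L)))
  counts <- table(unlist(per_pep))
  sort(names(counts)[counts >= 2L])
}

#' Tripeptide composition (TPC) over a selected tripeptide list
#'
#' Percentage of each selected tripeptide among the peptide's `length - 2`
#' overlapping tripeptides: `100 * count_k / (length - 2)`.  Because only
#' the selected tripeptides are counted, the block sums to at most 100.
#'
#' @inheritParams aac
#' @param selected ordered character vector of tripeptides (from
#'   [select_overrepresented_tripeptides()]).
#' @return named numeric vector of length `length(selected)`.
#' @export
tpc <- function(peptide, selected) {
  check_peptide(peptide)
  trimers <- split_kmers(peptide, 3L)
  counts <- table(factor(trimers, levels = selected))
  setNames(100 * as.vector(counts) / length(trimers), selected)
}

#' Define a feature scheme
#'
#' An ordered combination of feature blocks: `"AAC"` (20), `"DPC"` (400),
#' `"TPC"` (one per selected tripeptide) and `"CTERM"` (a single 0/1 flag
#' marking a C-terminal window, used for PDZ ligands).
#'
#' @param components ordered subset of `c("AAC", "DPC", "TPC", "CTERM")`.
#' @param selected_tripeptides tripeptide list (required iff `"TPC"` is in
#'   `components`).
#' @return an object of class `feature_scheme` with a `total_length` field.
#' @export
#' @examples
#' feature_scheme(c("AAC", "DPC"))
feature_scheme <- function(components, selected_tripeptides = character(0)) {
  components <- match.arg(components, c("AAC", "DPC", "TPC", "CTERM"),
                          several.ok = TRUE)
  if ("TPC" %in% components && length(selected_tripeptides) == 0L)
    warning("TPC component with an empty tripeptide list contributes no features")
  total <- sum(c(AAC = 20L, DPC = 400L,
                 TPC = length(selected_tripeptides),
                 CTERM = 1L)[components])
  structure(list(components = components,
                 selected_tripeptides = selected_tripeptides,
                 total_length = total),
            class = "feature_scheme")
}

#' @export
print.feature_scheme <- function(x, ...) {
  cat(sprintf("<feature_scheme> %s (%d features)\n",
              paste(x$components, collapse = "+"), x$total_length))
  invisible(x)
}

#' Encode a peptide as a feature vector
#'
#' Concatenates the scheme's blocks in order.  The CTERM block is 1 iff the
#' peptide window ends at its parent protein's C-terminus; for a standalone
#' peptide query (no parent protein) the peptide's own end is its terminus,
#' so `is_c_terminal` defaults to `TRUE`.
#'
#' @inheritParams aac
#' @param scheme a [feature_scheme()].
#' @param is_c_terminal logical C-terminal flag (only used when the scheme
#'   contains `"CTERM"`).
#' @return numeric vector of length `scheme$total_length`.
#' @export
encode <- function(peptide, scheme, is_c_terminal = TRUE) {
  stopifnot(inherits(scheme, "feature_scheme"))
  blocks <- lapply(scheme$components, function(comp)
    switch(comp,
           AAC = aac(peptide),
           DPC = dpc(peptide),
           TPC = tpc(peptide, scheme$selected_tripeptides),
           CTERM = c(CTERM = as.numeric(isTRUE(is_c_terminal)))))
  unlist(blocks)
}

# Encode many peptides into a feature matrix (rows = peptides).
encode_matrix <- function(peptides, scheme, is_c_terminal = TRUE) {
  is_c_terminal <- rep_len(is_c_terminal, length(peptides))
  mat <- t(vapply(seq_along(peptides),
                  function(i) encode(peptides[i], scheme, is_c_terminal[i]),
                  numeric(scheme$total_length)))
  rownames(mat) <- NULL
  mat
}
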