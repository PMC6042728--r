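# Training-set construction: redundancy collapse, cross-class union
# negatives, balanced subsampling, and stratified cross-validation folds.

# Run expr under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a table of labeled ligand peptides
#'
#' A ligand entry is one fixed-length peptide window with its provenance:
#' the source protein id, the 1-based start position within that protein,
#' the domain class it binds (or was sampled for), and whether the window
#' ends at the protein's C-terminus.  `ext_sequence` optionally carries a
#' longer (6-mer) sequence context ending in the peptide, used when a short
#' peptide must be re-cut to a longer window length (see
#' [assemble_negatives()]).
#'
#' @param sequence character vector of peptides (uppercase standard
#'   alphabet).
#' @param domain_class `"SH3"`, `"WW"` or `"PDZ"` (recycled).
#' @param protein_id source protein identifiers (recycled; default
#'   `"synthetic"`).
#' @param start 1-based start positions in the source protein (`NA` if
#'   unknown).
#' @param is_c_terminal logical, whether the peptide ends at the source
#'   protein's C-terminus.
#' @param ext_sequence optional longer sequence context ending in
#'   `sequence`.
#' @return a data.frame of class `ligand_entries`.
#' @export
ligand_entries <- function(sequence, domain_class, protein_id = "synthetic",
                           start = NA_integer_, is_c_terminal = FALSE,
                           ext_sequence = NA_character_) {
  stopifnot(all(domain_class %in% c(DOMAIN_CLASSES, "background")))
  df <- data.frame(sequence = toupper(sequence),
                   protein_id = protein_id,
                   start = as.integer(start),
                   domain_class = domain_class,
                   is_c_terminal = is_c_terminal,
                   ext_sequence = toupper(ext_sequence))
  class(df) <- c("ligand_entries", class(df))
  df
}

#' Collapse redundant ligand entries
#'
#' Entries that represent the same motif sequence at the same position of
#' the same protein are collapsed to a single entry.  Identical sequences
#' observed in a different protein (or isoform) or at a different position
#' are all retained, so the collapsed set is non-redundant without
#' discarding independent motif occurrences.
#'
#' @param entries a [ligand_entries()] data.frame from one domain class.
#' @return the collapsed data.frame (first occurrence kept, order
#'   preserved).
#' @export
collapse_redundant <- function(entries) {
  if (nrow(entries) == 0L) return(entries)
  key <- paste(entries$sequence, entries$protein_id, entries$start, sep = "\r")
  entries[!duplicated(key), , drop = FALSE]
}

# Re-cut peptides to window length L.  Longer peptides keep their last L
# residues (the C-terminal side, which carries the PDZ-relevant signal);
# shorter peptides fall back on the stored ext_sequence context.
fit_to_length <- function(entries, L) {
  if (nrow(entries) == 0L) return(entries)
  len <- nchar(entries$sequence)
  long <- len > L
  entries$sequence[long] <- substring(entries$sequence[long],
                                      len[long] - L + 1L, len[long])
  entries$start[long] <- entries$start[long] + (len[long] - L)
  short <- nchar(entries$sequence) < L
  if (any(short)) {
    ext <- entries$ext_sequence[short]
    if (anyNA(ext) || any(nchar(ext) < L))
      stop("cannot extend ", sum(short), " peptide(s) shorter than ", L,
           " residues: no sequence context (ext_sequence) of length >= ", L)
    entries$sequence[short] <- substring(ext, nchar(ext) - L + 1L, nchar(ext))
    entries$start[short] <- NA_integer_
  }
  entries
}

# The balanced-mode subsampling quotas (counts drawn from each of the other
# two ligand classes, in SH3/WW/PDZ order, then from the random background).
BALANCED_QUOTAS <- list(SH3 = c(WW = 30L, PDZ = 30L, background = 55L),
                        WW  = c(SH3 = 45L, PDZ = 45L, background = 50L),
                        PDZ = c(SH3 = 50L, WW = 50L, background = 65L))

#' Assemble the negative training set for a domain class
#'
#' Negatives for one domain are the union of the positive sets of the other
#' two domains plus a random-peptide background.  In `"unbalanced"` mode all
#' three pools are taken in full (e.g. 140 + 165 + 120 = 425 negatives for
#' SH3 when positives number 115/140/165 and the background 120).  In
#' `"balanced"` mode a per-pool quota is subsampled uniformly without
#' replacement so that negatives match positives 1:1; the default quotas are
#' 30+30+55 (SH3), 45+45+50 (WW) and 50+50+65 (PDZ).
#'
#' Cross-class peptides are re-cut to the target domain's window length:
#' 6-mers used as PDZ negatives are trimmed to their last 4 residues, and
#' 4-mers used as SH3/WW negatives are extended C-terminally-anchored from
#' their stored sequence context.
#'
#' @param domain target domain class.
#' @param class_sets named list mapping each domain class to its positive
#'   [ligand_entries()].
#' @param background [ligand_entries()] of random background peptides, cut
#'   to the target window length.
#' @param balance_mode `"unbalanced"` (full union) or `"balanced"` (quota
#'   subsample).
#' @param quotas optional named integer vector (other classes then
#'   `background`) overriding the balanced-mode defaults.
#' @param seed RNG seed for balanced subsampling.
#' @return a [ligand_entries()] data.frame of negatives.
#' @export
assemble_negatives <- function(domain, class_sets, background,
                               balance_mode = c("unbalanced", "balanced"),
                               quotas = NULL, seed = NULL) {
  domain <- match.arg(domain, DOMAIN_CLASSES)
  balance_mode <- match.arg(balance_mode)
  L <- domain_window(domain)
  others <- setdiff(DOMAIN_CLASSES, domain)
  pools <- c(lapply(class_sets[others], fit_to_length, L = L),
             list(background = fit_to_length(background, L)))
  if (balance_mode == "balanced") {
    if (is.null(quotas)) quotas <- BALANCED_QUOTAS[[domain]]
    stopifnot(length(quotas) == length(pools))
    names(quotas) <- names(quotas) %||% names(pools)
    pools <- with_seed(seed, lapply(names(pools), function(nm) {
      pool <- pools[[nm]]
      q <- quotas[[nm]]
      if (q > nrow(pool))
        stop("balanced quota ", q, " exceeds pool '", nm, "' (",
             nrow(pool), " peptides)")
      pool[sample.int(nrow(pool), q), , drop = FALSE]
    }))
  }
  out <- do.call(rbind, c(pools, list(make.row.names = FALSE)))
  class(out) <- c("ligand_entries", "data.frame")
  out
}

#' Bundle positives and negatives for one domain class
#'
#' @param domain_class the domain the positives bind.
#' @param positives,negatives [ligand_entries()] data.frames.
#' @param balance_mode `"unbalanced"` or `"balanced"`.
#' @return an object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(domain_class, positives, negatives,
                           balance_mode = "unbalanced") {
  domain_class <- match.arg(domain_class, DOMAIN_CLASSES)
  if (balance_mode == "balanced" && nrow(positives) != nrow(negatives))
    stop("balanced bundle requires |negatives| == |positives|")
  structure(list(domain_class = domain_class, positives = positives,
                 negatives = negatives, balance_mode = balance_mode),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %s (%s): %d positives, %d negatives (~1:%.1f)\n",
              x$domain_class, x$balance_mode, nrow(x$positives),
              nrow(x$negatives), nrow(x$negatives) / nrow(x$positives)))
  invisible(x)
}

#' Sample random background peptides from protein sequences
#'
#' Draws `n` length-`L` peptides from uniformly random (protein, start)
#' positions across the supplied records, emulating a background of random
#' peptides cut from real protein sequences.
#'
#' @param records list of [seq_record()] proteins (each of length >= `L`).
#' @param n number of peptides to draw (positions drawn with replacement).
#' @param L peptide length.
#' @param seed RNG seed.
#' @return a [ligand_entries()] data.frame with `domain_class`
#'   `"background"`.
#' @export
sample_background <- function(records, n, L, seed = NULL) {
  if (n <= 0L) stop("n must be a positive count")
  lens <- vapply(records, `[[`, numeric(1), "length")
  keep <- lens >= L
  if (!any(keep)) stop("all records are shorter than L = ", L)
  records <- records[keep]
  lens <- lens[keep]
  n_windows <- lens - L + 1
  cum <- cumsum(n_windows)
  idx <- with_seed(seed, sample.int(cum[length(cum)], n, replace = TRUE))
  rec_i <- findInterval(idx - 1L, c(0, cum), rightmost.closed = FALSE)
  start <- idx - c(0, cum)[rec_i]
  seqs <- vapply(seq_len(n), function(k)
    substr(records[[rec_i[k]]]$sequence, start[k], start[k] + L - 1L),
    character(1))
  ligand_entries(
    sequence = seqs,
    domain_class = "background",
    protein_id = vapply(records[rec_i], `[[`, character(1), "id"),
    start = start,
    is_c_terminal = start + L - 1L == lens[rec_i]
  )
}

#' Stratified cross-validation fold assignment
#'
#' Positives and negatives are partitioned into `n_folds` folds separately
#' (stratified), so every fold preserves the bundle's class ratio up to
#' rounding; fold sizes within each stratum differ by at most one.
#'
#' @param bundle a [dataset_bundle()].
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed; the same seed always yields the same assignment.
#' @return an object of class `fold_assignment`: list with `n_folds`,
#'   `pos_fold` and `neg_fold` (integer fold index 1..n_folds per example)
#'   and `seed`.
#' @export
make_folds <- function(bundle, n_folds = 5L, seed = NULL) {
  n_pos <- nrow(bundle$positives)
  n_neg <- nrow(bundle$negatives)
  if (n_pos < n_folds || n_neg < n_folds)
    stop("need at least ", n_folds, " examples per class to make ",
         n_folds, " folds")
  assign_stratum <- function(n) {
    fold <- rep(seq_len(n_folds), length.out = n)
    fold[sample.int(n)]
  }
  with_seed(seed, {
    structure(list(n_folds = as.integer(n_folds),
                   pos_fold = assign_stratum(n_pos),
                   neg_fold = assign_stratum(n_neg),
                   seed = seed),
              class = "fold_assignment")
  })
}

#' Write / read a labeled peptide dataset as TSV
#'
#' Flat interchange format: columns `sequence`, `domain_class`, `label`
#' (+1 positive / -1 negative), `protein_id`, `start`, `is_c_terminal`,
#' `ext_sequence`.
#'
#' @param bundle a [dataset_bundle()].
#' @param path output path.
#' @return invisibly, `path` (write) or a [dataset_bundle()] (read).
#' @export
write_dataset_tsv <- function(bundle, path) {
  lab <- function(df, l) cbind(df[, c("sequence", "domain_class")], label = l,
                               df[, c("protein_id", "start", "is_c_terminal",
                                      "ext_sequence")])
  out <- rbind(lab(bundle$positives, 1L), lab(bundle$negatives, -1L))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @param domain_class domain of the bundle being read (defaults to the
#'   majority class among the positives).
#' @param balance_mode recorded balance mode.
#' @export
read_dataset_tsv <- function(path, domain_class = NULL,
                             balance_mode = "unbalanced") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "domain_class", "label", "protein_id", "start",
            "is_c_terminal")
  if (!all(need %in% names(df)))
    stop("dataset TSV must have columns: ", paste(need, collapse = ", "))
  if (!"ext_sequence" %in% names(df)) df$ext_sequence <- NA_character_
  as_entries <- function(d) ligand_entries(d$sequence, d$domain_class,
                                           d$protein_id, d$start,
                                           d$is_c_terminal, d$ext_sequence)
  pos <- as_entries(df[df$label > 0, , drop = FALSE])
  neg <- as_entries(df[df$label < 0, , drop = FALSE])
  if (is.null(domain_class))
    domain_class <- names(sort(table(pos$domain_class), decreasing = TRUE))[1]
  dataset_bundle(domain_class, pos, neg, balance_mode)
}
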