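# Frequency position-specific scoring matrix (PSSM) prediction.

#' Build a position-specific scoring matrix from aligned positive peptides
#'
#' For amino acid i at position p the position score is the observed
#' frequency `PS(i,p) = n(i,p) / N`, where `n(i,p)` is the number of
#' training peptides carrying residue i at position p and `N` is the number
#' of training peptides.  A query of the same length is scored by
#' multiplying its per-position scores (see [pssm_score()]).
#'
#' Two scoring modes are supported.  `"raw"` multiplies the frequencies
#' directly, giving a score in \[0, 1\].  `"background_odds"` (the default)
#' divides each position score by the uniform background frequency 1/20
#' before multiplying, so a score of 1 means "as likely as a uniform random
#' peptide" and thresholds around 0.5-1 are meaningful operating points.
#'
#' @param positives character vector of aligned positive peptides, all of
#'   length `L`.
#' @param L window length (default: length of the first peptide).
#' @param mode `"background_odds"` or `"raw"`.
#' @param domain_class optional domain label carried on the object.
#' @return an object of class `pssm`: list with `scores` (20 x L frequency
#'   matrix, rows in fixed alphabetical amino-acid order), `N`, `L`,
#'   `mode`, `domain_class`.
#' @export
#' @examples
#' m <- build_pssm(c("PPPA", "PPPC"), mode = "raw")
#' pssm_score(m, "PPPA")  # 1 * 1 * 1 * 0.5
build_pssm <- function(positives, L = NULL,
                       mode = c("background_odds", "raw"),
                       domain_class = NULL) {
  mode <- match.arg(mode)
  if (length(positives) == 0L) stop("empty training set")
  positives <- toupper(positives)
  if (is.null(L)) L <- nchar(positives[1])
  if (any(nchar(positives) != L))
    stop("all training peptides must have length ", L)
  N <- length(positives)
  chars <- matrix(unlist(strsplit(positives, "", fixed = TRUE)),
                  nrow = N, byrow = TRUE)
  scores <- vapply(seq_len(L), function(p)
    as.vector(table(factor(chars[, p], levels = AA_ALPHABET))) / N,
    numeric(20L))
  dimnames(scores) <- list(AA_ALPHABET, seq_len(L))
  structure(list(scores = scores, N = N, L = as.integer(L), mode = mode,
                 domain_class = domain_class),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s%d positions, N = %d training peptides, mode = %s\n",
              if (is.null(x$domain_class)) "" else paste0(x$domain_class, ": "),
              x$L, x$N, x$mode))
  top <- apply(x$scores, 2, function(col) AA_ALPHABET[which.max(col)])
  cat("  consensus:", paste(top, collapse = ""), "\n")
  invisible(x)
}

#' Score a query peptide against a PSSM
#'
#' Multiplies the matrix entries for the query's residue at each position.
#' In `"raw"` mode the result is the plain product of frequencies (0 if any
#' residue was never seen at its position); in `"background_odds"` mode each
#' factor is divided by the uniform background 1/20, i.e. the product is
#' multiplied by `20^L`.
#'
#' @param matrix a [build_pssm()] object.
#' @param peptide query peptide of length `matrix$L`.
#' @param mode optional override of the matrix's scoring mode.
#' @return a single numeric score.
#' @export
pssm_score <- function(matrix, peptide, mode = NULL) {
  stopifnot(inherits(matrix, "pssm"))
  mode <- mode %||% matrix$mode
  peptide <- toupper(peptide)
  if (nchar(peptide) != matrix$L)
    stop("query length ", nchar(peptide), " != matrix length ", matrix$L)
  chars <- check_peptide(peptide)
  ps <- matrix$scores[cbind(chars, seq_len(matrix$L))]
  if (mode == "background_odds") ps <- ps * 20
  prod(ps)
}

#' Classify a peptide by PSSM score threshold
#'
#' @inheritParams pssm_score
#' @param threshold operating threshold; the call is positive iff
#'   `score >= threshold` (boundary inclusive).
#' @return logical.
#' @export
pssm_classify <- function(matrix, peptide, threshold) {
  pssm_score(matrix, peptide) >= threshold
}

#' Predict method for PSSM objects
#'
#' @param object a [build_pssm()] object.
#' @param peptides character vector of query peptides of length
#'   `object$L`.
#' @param threshold if non-`NULL`, return logical calls instead of scores.
#' @param ... unused.
#' @return numeric scores, or logical calls when `threshold` is given.
#' @export
predict.pssm <- function(object, peptides, threshold = NULL, ...) {
  scores <- vapply(peptides, pssm_score, numeric(1), matrix = object,
                   USE.NAMES = FALSE)
  if (is.null(threshold)) scores else scores >= threshold
}
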