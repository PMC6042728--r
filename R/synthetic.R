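# Synthetic planted-motif peptide and protein generator.  Emulates the
# statistical structure the predictors assume -- proline-rich 6-mer ligands
# for SH3/WW, C-terminally located 4-mer ligands for PDZ, and a uniform
# random-peptide background -- so training, evaluation and benchmarking run
# end to end without any external data.

# Per-position target residue sets for each domain's planted motif.
# NULL = unconstrained (wildcard) position.
#   SH3: [RK]xPxxP-style proline-rich core with a basic N-terminal flank.
#   WW:  PPxY-style.
#   PDZ: x[ST]x[VIL]-style class-I C-terminal motif.
MOTIF_TEMPLATES <- list(
  SH3 = list(c("R", "K"), NULL, "P", NULL, NULL, "P"),
  WW  = list("P", "P", NULL, "Y", NULL, NULL),
  PDZ = list(NULL, c("S", "T"), NULL, c("V", "I", "L"))
)

#' Specify a synthetic peptide generator
#'
#' Positive peptides are drawn position by position: with probability
#' `signal_strength` the residue comes uniformly from the position's target
#' set (e.g. \{R, K\} at position 1 of the SH3 template), otherwise
#' uniformly from all 20 amino acids; wildcard positions are always
#' uniform.  At `signal_strength = 1` every peptide matches the template
#' exactly.
#'
#' @param domain_class `"SH3"`, `"WW"` or `"PDZ"`.
#' @param n_pos number of positive peptides to draw.
#' @param signal_strength probability mass placed on the template residues
#'   at constrained positions, in (0.05, 1\]; default 0.9 (strongly
#'   conserved motif).
#' @param c_terminal_prob probability that a PDZ positive carries the
#'   C-terminal flag (default 0.9; PDZ ligands are predominantly
#'   C-terminal).  Ignored for SH3/WW.
#' @param template optional custom template: list of length
#'   `domain_window(domain_class)` whose elements are target residue sets
#'   (`NULL` for unconstrained positions).
#' @param seed RNG seed.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(domain_class, n_pos,
                           signal_strength = 0.9,
                           c_terminal_prob = 0.9,
                           template = NULL, seed = NULL) {
  domain_class <- match.arg(domain_class, DOMAIN_CLASSES)
  L <- domain_window(domain_class)
  template <- template %||% MOTIF_TEMPLATES[[domain_class]]
  stopifnot(length(template) == L,
            signal_strength > 0.05, signal_strength <= 1,
            c_terminal_prob >= 0, c_terminal_prob <= 1, n_pos >= 1)
  bad <- unlist(template)
  if (!all(bad %in% AA_ALPHABET)) stop("template residues must be standard amino acids")
  structure(list(domain_class = domain_class, n_pos = as.integer(n_pos),
                 signal_strength = signal_strength,
                 c_terminal_prob = c_terminal_prob,
                 template = template, L = L, seed = seed),
            class = "generator_spec")
}

# Per-position sampling probabilities over the 20-letter alphabet.
position_probs <- function(targets, signal_strength) {
  p <- rep(1 / 20, 20)
  names(p) <- AA_ALPHABET
  if (!is.null(targets)) {
    p <- (1 - signal_strength) * p
    p[targets] <- p[targets] + signal_strength / length(targets)
  }
  p
}

draw_peptides <- function(n, template, signal_strength) {
  cols <- lapply(template, function(targets) {
    p <- position_probs(targets, signal_strength)
    sample(AA_ALPHABET, n, replace = TRUE, prob = p)
  })
  do.call(paste0, cols)
}

uniform_peptides <- function(n, L) {
  draw_peptides(n, vector("list", L), 1)
}

#' Generate one class of synthetic positive peptides
#'
#' @param spec a [generator_spec()].
#' @return a [ligand_entries()] data.frame of `spec$n_pos` peptides of the
#'   domain's window length.  PDZ peptides carry `is_c_terminal = TRUE`
#'   with probability `spec$c_terminal_prob`; each also stores a 6-residue
#'   `ext_sequence` context (two random residues prepended) so 4-mers can
#'   serve as 6-mer cross-class negatives.
#' @export
generate_class <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    seqs <- draw_peptides(spec$n_pos, spec$template, spec$signal_strength)
    ct <- if (spec$domain_class == "PDZ")
      runif(spec$n_pos) < spec$c_terminal_prob else
      rep(FALSE, spec$n_pos)
    ext <- if (spec$L < 6L)
      paste0(uniform_peptides(spec$n_pos, 6L - spec$L), seqs) else seqs
    ligand_entries(sequence = seqs, domain_class = spec$domain_class,
                   protein_id = paste0("syn_", spec$domain_class,
                                       "_", seq_len(spec$n_pos)),
                   start = NA_integer_, is_c_terminal = ct,
                   ext_sequence = ext)
  })
}

#' Generate a full set of per-domain training bundles
#'
#' Draws positives for all three domain classes and a uniform random
#' background, then assembles each domain's negative set with
#' [assemble_negatives()].  With `paper_sizes = TRUE` (default) the class
#' sizes are 115 SH3, 140 WW and 165 PDZ positives plus 120 background
#' peptides, giving unbalanced negative sets of 425/400/375.
#'
#' With `disjoint = TRUE` (default) the generator guarantees by rejection
#' sampling that no negative of a domain is an exact string match to any
#' positive of the same domain (comparing the window-length projections of
#' every peptide).  Exact-matching methods then have, by construction, zero
#' false positives on these bundles.
#'
#' @param n_pos named integer vector of positive-set sizes (ignored when
#'   `paper_sizes = TRUE`).
#' @param n_background background peptides (default 120).
#' @param signal_strength template probability mass, shared by the three
#'   classes (default 0.9).
#' @param c_terminal_prob C-terminal probability for PDZ positives.
#' @param balance_mode `"unbalanced"` or `"balanced"`.
#' @param paper_sizes use the 115/140/165 + 120 class sizes (default).
#' @param disjoint enforce the negative/positive disjointness guarantee.
#' @param seed RNG seed; the whole set is reproducible from it.
#' @param max_tries rejection-sampling bound per draw (error if exceeded).
#' @return named list (`SH3`, `WW`, `PDZ`) of [dataset_bundle()]s, with the
#'   background entries attached as attribute `"background"`.
#' @export
generate_bundle <- function(n_pos = c(SH3 = 115L, WW = 140L, PDZ = 165L),
                            n_background = 120L, signal_strength = 0.9,
                            c_terminal_prob = 0.9,
                            balance_mode = "unbalanced",
                            paper_sizes = TRUE, disjoint = TRUE,
                            seed = NULL, max_tries = 1000L) {
  if (paper_sizes) {
    n_pos <- c(SH3 = 115L, WW = 140L, PDZ = 165L)
    n_background <- 120L
  }
  stopifnot(all(DOMAIN_CLASSES %in% names(n_pos)))
  with_seed(seed, {
    # Projections of a peptide onto the two window lengths; disjointness is
    # enforced on both so re-cut cross-class negatives can never collide.
    proj <- function(seq6) list(p6 = seq6, p4 = substring(seq6, 3L, 6L))
    seen6 <- list(SH3 = character(0), WW = character(0), PDZ = character(0))
    seen4 <- seen6
    draw_class <- function(domain, n) {
      spec <- generator_spec(domain, 1L, signal_strength, c_terminal_prob)
      out <- NULL
      for (i in seq_len(n)) {
        for (try in seq_len(max_tries)) {
          e <- generate_class(spec)
          pr <- proj(e$ext_sequence)
          clash <- disjoint &&
            (pr$p6 %in% unlist(seen6[setdiff(DOMAIN_CLASSES, domain)]) ||
             pr$p4 %in% unlist(seen4[setdiff(DOMAIN_CLASSES, domain)]) ||
             pr$p6 %in% seen6[[domain]] || pr$p4 %in% seen4[[domain]])
          if (!clash) break
          if (try == max_tries)
            stop("rejection sampling exceeded ", max_tries,
                 " tries for class ", domain)
        }
        seen6[[domain]] <<- c(seen6[[domain]], pr$p6)
        seen4[[domain]] <<- c(seen4[[domain]], pr$p4)
        out <- rbind(out, e)
      }
      out$protein_id <- paste0("syn_", domain, "_", seq_len(n))
      class(out) <- c("ligand_entries", "data.frame")
      out
    }
    positives <- setNames(
      lapply(DOMAIN_CLASSES, function(d) draw_class(d, n_pos[[d]])),
      DOMAIN_CLASSES)
    # Background: uniform 6-mers (4-mer use re-cuts the last 4 residues),
    # rejected against every class's positives when disjoint.
    bg_seqs <- character(0)
    while (length(bg_seqs) < n_background) {
      cand <- uniform_peptides(n_background - length(bg_seqs), 6L)
      if (disjoint) {
        pr <- proj(cand)
        keep <- !(pr$p6 %in% unlist(seen6)) & !(pr$p4 %in% unlist(seen4))
        cand <- cand[keep]
      }
      bg_seqs <- c(bg_seqs, cand)
    }
    background <- ligand_entries(
      sequence = bg_seqs, domain_class = "background",
      protein_id = paste0("syn_bg_", seq_len(n_background)),
      start = NA_integer_, is_c_terminal = FALSE, ext_sequence = bg_seqs)
    bundles <- setNames(lapply(DOMAIN_CLASSES, function(d) {
      neg <- assemble_negatives(d, positives, background, balance_mode,
                                seed = NULL)
      pos <- fit_to_length(positives[[d]], domain_window(d))
      dataset_bundle(d, pos, neg, balance_mode)
    }), DOMAIN_CLASSES)
    attr(bundles, "background") <- background
    bundles
  })
}

#' Generate random proteins with planted ligand peptides
#'
#' Uniform-random protein sequences with known peptides embedded at
#' recorded coordinates, as ground truth for scanner round-trips.  PDZ
#' peptides are planted flush with the C-terminus; others at a uniform
#' random offset.  Embedded peptides are assigned round-robin, one per
#' protein in cycle.
#'
#' @param n number of proteins.
#' @param length_range integer range of protein lengths (default
#'   c(50, 200)).
#' @param embedded optional data.frame with columns `peptide` and
#'   `domain_class`, the peptides to plant.
#' @param seed RNG seed.
#' @return list with `records` (list of [seq_record()]) and `truth`
#'   (data.frame `protein_id`, `start`, `end`, `peptide`, `domain_class`;
#'   1-based inclusive coordinates).
#' @export
generate_proteins <- function(n, length_range = c(50L, 200L),
                              embedded = NULL, seed = NULL) {
  stopifnot(n >= 1L, length(length_range) == 2L)
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste0(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""),
      character(1))
    ids <- sprintf("synprot_%03d", seq_len(n))
    truth <- NULL
    if (!is.null(embedded) && nrow(embedded) > 0L) {
      for (j in seq_len(nrow(embedded))) {
        i <- ((j - 1L) %% n) + 1L
        pep <- toupper(embedded$peptide[j])
        m <- nchar(pep)
        if (m > lens[i])
          stop("embedded peptide '", pep, "' longer than protein ", ids[i])
        start <- if (identical(embedded$domain_class[j], "PDZ"))
          lens[i] - m + 1L else sample.int(lens[i] - m + 1L, 1L)
        substr(seqs[i], start, start + m - 1L) <- pep
        truth <- rbind(truth, data.frame(
          protein_id = ids[i], start = start, end = start + m - 1L,
          peptide = pep, domain_class = embedded$domain_class[j]))
      }
    }
    records <- mapply(seq_record, ids, seqs, SIMPLIFY = FALSE,
                      USE.NAMES = FALSE)
    list(records = records,
         truth = truth %||% data.frame(protein_id = character(0),
                                       start = integer(0), end = integer(0),
                                       peptide = character(0),
                                       domain_class = character(0)))
  })
}

#' Write planted-peptide ground truth as a BED-like TSV
#'
#' Columns `protein_id`, `start`, `end` (1-based inclusive), `peptide`,
#' `domain_class`.
#'
#' @param truth the `truth` component of [generate_proteins()].
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
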