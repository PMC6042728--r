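# Whole-sequence scanning: window extraction, per-method prediction and
# the combined union report.

#' Configure a sequence scan
#'
#' Selects the domain, the prediction methods to run, their thresholds and
#' the resources each method needs.  An error is raised at construction if
#' a selected method's resource is missing.
#'
#' @param domain_class `"SH3"`, `"WW"` or `"PDZ"`.
#' @param methods non-empty subset of `c("SVM", "PSSM", "RES", "MIM")`.
#' @param svm_model an [svm_train()] model (required for `"SVM"`).
#' @param pssm a [build_pssm()] matrix (required for `"PSSM"`).
#' @param regex_lib a [regex_library()] (default: the domain's built-in
#'   defaults) for `"RES"`.
#' @param instance_lib an [instance_library()] (required for `"MIM"`).
#' @param svm_threshold decision threshold for SVM calls (default 0.00).
#' @param pssm_threshold threshold for PSSM calls (default 1, i.e. more
#'   likely than uniform background in `"background_odds"` mode).
#' @param server_limits enforce the web-style input quota in [cli_main()]
#'   (at most 10 sequences, each at least 6 residues).
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(domain_class,
                        methods = c("SVM", "PSSM", "RES", "MIM"),
                        svm_model = NULL, pssm = NULL,
                        regex_lib = NULL, instance_lib = NULL,
                        svm_threshold = 0, pssm_threshold = 1,
                        server_limits = FALSE) {
  domain_class <- match.arg(domain_class, DOMAIN_CLASSES)
  methods <- match.arg(methods, c("SVM", "PSSM", "RES", "MIM"),
                       several.ok = TRUE)
  if ("SVM" %in% methods && !inherits(svm_model, "svm_model"))
    stop("method SVM selected but no svm_model supplied")
  if ("PSSM" %in% methods && !inherits(pssm, "pssm"))
    stop("method PSSM selected but no pssm matrix supplied")
  if ("RES" %in% methods && is.null(regex_lib))
    regex_lib <- default_regex_library(domain_class)
  if ("MIM" %in% methods && !inherits(instance_lib, "instance_library"))
    stop("method MIM selected but no instance_lib supplied")
  structure(list(domain_class = domain_class, methods = methods,
                 svm_model = svm_model, pssm = pssm,
                 regex_lib = regex_lib, instance_lib = instance_lib,
                 svm_threshold = svm_threshold,
                 pssm_threshold = pssm_threshold,
                 server_limits = server_limits),
            class = "scan_config")
}

# Map match spans onto the length-L window that covers them (clamped to the
# sequence); returns window start positions.
covering_window_start <- function(start, end, L, seq_len) {
  w <- pmin(start, seq_len - L + 1L)
  w <- pmax(w, end - L + 1L)  # long matches: cover the match end
  pmax(w, 1L)
}

#' Scan sequences with the selected methods and combine the results
#'
#' Every length-L window of every record is evaluated by each selected
#' method; a window appears in the output if ANY method calls it (union
#' semantics).  Rows are ordered by record and window position and carry
#' all four method columns: SVM and PSSM scores where those methods fired
#' (`NA` otherwise), the matched instance and regex pattern for MIM/RES,
#' and `n_methods_agreeing`, the number of selected methods calling the
#' window.  Only the terminal window of each record has its C-terminal
#' flag set (which feeds the PDZ SVM features).  Records shorter than the
#' window length are skipped with a warning.
#'
#' @param records list of [seq_record()]s (a single record is accepted).
#' @param config a [scan_config()].
#' @return data.frame with columns `parent_id`, `start`, `end`,
#'   `sequence`, `svm_score`, `pssm_score`, `mim_instance`, `res_pattern`,
#'   `n_methods_agreeing`.
#' @export
scan_sequences <- function(records, config) {
  stopifnot(inherits(config, "scan_config"))
  if (inherits(records, "seq_record")) records <- list(records)
  L <- domain_window(config$domain_class)
  out <- lapply(records, function(rec) {
    if (rec$length < L) {
      warning("record '", rec$id, "' is shorter than the window length ",
              L, "; skipped")
      return(NULL)
    }
    if (!rec$valid) {
      warning("record '", rec$id, "' contains non-standard residues (",
              paste(rec$invalid_chars, collapse = ","), "); skipped")
      return(NULL)
    }
    win <- windows(rec, L)
    win$svm_score <- NA_real_
    win$pssm_score <- NA_real_
    win$mim_instance <- NA_character_
    win$res_pattern <- NA_character_
    called <- matrix(FALSE, nrow(win), 4,
                     dimnames = list(NULL, c("SVM", "PSSM", "RES", "MIM")))
    if ("SVM" %in% config$methods) {
      sc <- svm_decision(config$svm_model, win$sequence, win$is_c_terminal)
      hit <- sc >= config$svm_threshold
      win$svm_score[hit] <- sc[hit]
      called[, "SVM"] <- hit
    }
    if ("PSSM" %in% config$methods) {
      sc <- predict(config$pssm, win$sequence)
      hit <- sc >= config$pssm_threshold
      win$pssm_score[hit] <- sc[hit]
      called[, "PSSM"] <- hit
    }
    if ("RES" %in% config$methods) {
      hits <- res_scan(rec, config$regex_lib)
      if (nrow(hits) > 0L) {
        ws <- covering_window_start(hits$start, hits$end, L, rec$length)
        for (i in seq_along(ws)) {
          w <- ws[i]
          win$res_pattern[w] <- if (is.na(win$res_pattern[w]))
            hits$matched_pattern[i] else
            paste(unique(c(strsplit(win$res_pattern[w], ",")[[1]],
                           hits$matched_pattern[i])), collapse = ",")
          called[w, "RES"] <- TRUE
        }
      }
    }
    if ("MIM" %in% config$methods) {
      hits <- mim_match(rec, config$instance_lib)
      if (nrow(hits) > 0L) {
        ws <- covering_window_start(hits$start, hits$end, L, rec$length)
        for (i in seq_along(ws)) {
          w <- ws[i]
          win$mim_instance[w] <- if (is.na(win$mim_instance[w]))
            hits$matched_pattern[i] else
            paste(unique(c(strsplit(win$mim_instance[w], ",")[[1]],
                           hits$matched_pattern[i])), collapse = ",")
          called[w, "MIM"] <- TRUE
        }
      }
    }
    win$n_methods_agreeing <- rowSums(called)
    win[win$n_methods_agreeing > 0L,
        c("parent_id", "start", "end", "sequence", "svm_score",
          "pssm_score", "mim_instance", "res_pattern",
          "n_methods_agreeing"), drop = FALSE]
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L)
    return(data.frame(parent_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      svm_score = numeric(0), pssm_score = numeric(0),
                      mim_instance = character(0),
                      res_pattern = character(0),
                      n_methods_agreeing = integer(0)))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

#' Peptide-level binding call
#'
#' Union rule for a whole (possibly variable-length) peptide: the peptide
#' is called a binder iff scanning it yields at least one window hit from
#' any selected method.
#'
#' @param record a [seq_record()] (or a bare peptide string).
#' @param config a [scan_config()].
#' @return logical.
#' @export
peptide_level_call <- function(record, config) {
  if (is.character(record)) record <- seq_record("query", record)
  nrow(scan_sequences(list(record), config)) > 0L
}
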