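# The 20 standard amino acids in fixed alphabetical order.  All feature
# vectors, PSSM rows and generator distributions use this ordering.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Per-domain scanning window lengths: 6-mers for SH3 and WW, 4-mers for PDZ.
DOMAIN_WINDOW <- c(SH3 = 6L, WW = 6L, PDZ = 4L)

DOMAIN_CLASSES <- names(DOMAIN_WINDOW)

#' Window length used for a domain class
#'
#' @param domain one of `"SH3"`, `"WW"`, `"PDZ"`.
#' @return integer window length (6 for SH3/WW, 4 for PDZ).
#' @export
#' @examples
#' domain_window("PDZ")
domain_window <- function(domain) {
  domain <- match.arg(domain, DOMAIN_CLASSES)
  DOMAIN_WINDOW[[domain]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
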