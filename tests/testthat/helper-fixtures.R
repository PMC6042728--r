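# Shared fixtures, built in code at test time.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptides <- function(n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste0(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
}

# A small strong-signal bundle set (reduced class sizes) for quick tests.
small_bundles <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_bundle(n_pos = c(SH3 = 30L, WW = 35L, PDZ = 40L),
                                n_background = 30L, signal_strength = 0.9,
                                paper_sizes = FALSE, seed = 424242)
    cache
  }
})

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
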