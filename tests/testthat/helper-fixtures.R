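# "CTAG" repeats are an inert spacer: palindromic under reverse complement,
# GC = 0.5, no ATG, and a stop codon within every 12 nt in all six frames —
# so no ORF can start in or span a spacer.
spacer <- function(n_nt) {
  stopifnot(n_nt %% 4 == 0)
  paste(rep("CTAG", n_nt / 4), collapse = "")
}

random_orf <- function(n_nt, seed) {
  stopifnot(n_nt %% 3 == 0)
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  body <- character(n_nt / 3 - 2)
  for (i in seq_along(body)) {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
      if (!cd %in% stops) break
    }
    body[i] <- cd
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}
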