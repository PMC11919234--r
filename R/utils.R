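# Internal helpers shared across modules.

# Commercial rounding (half away from zero), used where published percentages
# were clearly rounded half-up (69 from 69.23) rather than banker's-rounded.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stream-specific RNG seed (< 2^31) from one master seed so that
# independent simulation stages are independently reproducible.
deriveSeed <- function(seed, stream) {
  # double-precision arithmetic stays exact below 2^53; reduce before coercing
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + 97 * stream) %%
               2147483647)
}

# Random DNA of length n under the current RNG state.
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random DNA containing no stop-codon trinucleotide (TAA/TAG/TGA) in any frame,
# so a planted in-frame pseudoexon cannot introduce a premature stop.
stopFreeDna <- function(n) {
  repeat {
    s <- randomDna(n)
    if (!grepl("TAA|TAG|TGA", s)) return(s)
  }
}
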