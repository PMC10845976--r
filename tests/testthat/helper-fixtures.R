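# small fixtures shared across tests, built in code

# a compact template for fast tests: 5+6+5 motif residues
tiny_template <- function(seed = 1L) {
  domain_template(motif1 = "ACDEF", motif2 = "GHIKLM", motif3 = "NPQRS",
                  linker_length_range = c(4L, 8L),
                  spacer_length_range = c(2L, 4L), rng_seed = seed)
}

# a gapless toy alignment of near-identical rows
toy_alignment <- function() {
  seed_alignment(
    ids = c("r1", "r2", "r3", "r4", "r5"),
    rows = c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKL",
             "ACDEFGWIKL", "ACDEFGHIKL")
  )
}

# profile built from n identical copies of one sequence
identity_profile <- function(sequence, n_rows = 5L, ...) {
  build_profile(seed_alignment(ids = sprintf("r%d", seq_len(n_rows)),
                               rows = rep(sequence, n_rows)), ...)
}

# encode residues as 0-based indices into aa_alphabet()
aa_codes <- function(sequence) {
  match(strsplit(sequence, "")[[1]], aa_alphabet()) - 1L
}

random_aa <- function(n, seed = NULL) {
  draw <- function() paste(sample(aa_alphabet(), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
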