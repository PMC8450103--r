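# Shared fixtures, built once per test run.  Everything is generated in
# code under fixed seeds; nothing is loaded from disk.

FS <- make_fixture_set(1)

# a small well-determined hairpin model used across unit tests
tiny_hairpin <- function() {
  train_cm(seed_alignment(
    c("a", "b", "c", "d"),
    c("GGGCAAAGCCC", "GGGCATAGCCC", "GGGCAAAGCCC", "GGACAAAGTCC"),
    "<<<<...>>>>", meta = list(name = "hairpin")))
}

TINY <- tiny_hairpin()

# deterministic random DNA
rand_dna <- function(n) paste(sample(DNA_BASES_T, n, replace = TRUE),
                              collapse = "")
DNA_BASES_T <- c("A", "C", "G", "T")
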