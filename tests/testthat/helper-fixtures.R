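# Shared fixtures, built once per test run (all deterministic).

ref_fixture <- aid_loop_amplicon()
panel_fixture <- build_library_panel(ref_fixture)
barcodes_fixture <- default_generation_barcodes()

# A population object over arbitrary codon counts (for selection oracles).
make_population <- function(counts, generation = 0L) {
  structure(list(counts = counts, generation = as.integer(generation)),
            class = "population")
}

# Brute-force minimum residue-to-DNA distance, O(n^2) loop.
brute_min_dist <- function(xyz, res_idx, dna_idx) {
  best <- Inf
  for (i in res_idx) for (j in dna_idx)
    best <- min(best, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  best
}
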