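# Shared fixtures built in code.

core_indices <- aaindex_core()

# A single-index, zero-noise planted design: affinity exactly linear in the
# Grantham-polarity feature at every scanned position.
planted_single <- list(list(accession = "GRAR740102", weight = 2,
                            positions = c(6L, 9L, 13L, 17L, 21L)))

zero_noise_dataset <- function(seed = 1L, version_hint = "v1",
                               planted = planted_single) {
  simulate_conmem(seed = seed, noise_sd = 0, planted = planted,
                  version_hint = version_hint)
}

# Minimal AAindex1 text with one record, values 1..20 in I-line order.
aaindex_text_1to20 <- function(accession = "TEST000101") {
  paste(c(paste("H", accession),
          "D synthetic test index",
          "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
          paste(sprintf("%.1f", 1:10), collapse = "  "),
          paste(sprintf("%.1f", 11:20), collapse = "  "),
          "//"), collapse = "\n")
}

# Random heavy-atom trajectory: n_res residues x n_atoms atoms x n_frames.
random_trajectory <- function(n_res = 2L, n_atoms = 5L, n_frames = 10L,
                              seed = 42L, box = NULL, spread = 6) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    res <- lapply(seq_len(n_res), function(r)
      matrix(runif(n_atoms * 3, 0, spread), n_atoms, 3))
    names(res) <- paste0("R", seq_len(n_res))
    res
  })
  helix_trajectory(frames, box = box)
}
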