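# Small randomized fixture builders shared across test files.

random_transcripts <- function(n, targets, off_flags, seed,
                               n_cells = 5, n_rounds = 4) {
  set.seed(seed)
  idx <- sample(seq_along(targets), n, replace = TRUE)
  data.frame(target = targets[idx],
             x = runif(n, 0, 50), y = runif(n, 0, 50), z = 0,
             rounds_used = sample(c(n_rounds, n_rounds - 1), n, TRUE,
                                  prob = c(0.8, 0.2)),
             source_spot_ids = as.character(seq_len(n)),
             is_off_target = off_flags[idx],
             cell_id = sample(seq_len(n_cells), n, TRUE))
}
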