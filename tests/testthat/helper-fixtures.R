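# Rating table with an exact number of correct trials per rater; wrong
# labels are placed on an ordinally adjacent stage.
table_with_correct_counts <- function(n_frames, correct_per_rater) {
  ref <- rep_len(1:7, n_frames)
  tab <- tibble::tibble(embryo_id = "E1",
                        frame_id = sprintf("F%04d", seq_len(n_frames)),
                        reference = ref)
  for (r in names(correct_per_rater)) {
    k <- correct_per_rater[[r]]
    lab <- ref
    wrong <- seq_len(n_frames) > k
    lab[wrong] <- ifelse(ref[wrong] == 7L, 6L, ref[wrong] + 1L)
    tab[[r]] <- lab
  }
  tab
}
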