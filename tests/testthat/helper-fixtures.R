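# Shared small fixtures, built in code. The tiny configuration keeps every
# structural test fast; models with random (untrained) weights are used for
# all invariance and wiring checks that do not require learning.

tiny_config <- function(...) {
  dti_config(profile = "desk", n_d = 16L, theta_p = 16L, d_model = 8L,
             d_k = 8L, groups_drug = 2L, groups_protein = 2L,
             ca_reduction = 4L, head_dims = c(8L, 4L), dropout = 0,
             batch_size = 8L, ...)
}

untrained_model <- function(cfg = tiny_config(), seed = 7L) {
  set.seed(seed)
  structure(list(theta = dtifuse:::init_params(cfg), config = cfg,
                 history = NULL, best_epoch = 0L,
                 metrics = list(), checkpoint_version = 1L),
            class = "dti_model")
}

tiny_records <- function(n = 8L, seed = 3L) {
  rule <- planted_rule(noise_rate = 0)
  drugs <- generate_drugs(n, seed = seed, with_motif = 0.5, max_atoms = 14L)
  prots <- generate_proteins(n, seed = seed + 1L, length_range = c(12L, 14L),
                             with_motif = 0.5)
  label_pairs(drugs, prots, rule, seed = seed + 2L)
}
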