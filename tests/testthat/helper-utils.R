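with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}
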