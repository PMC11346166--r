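# Shared tiny fixtures; everything is generated in code at test time.

tiny_genotype <- function() {
  genotype(list(block_config("0110", 8L)), list(block_config("0010", 8L)))
}

# depth-1, single-branch, SE-off genotype whose parameter count is
# hand-computable layer by layer
minimal_genotype <- function() {
  genotype(list(block_config("0001", 8L)), list(block_config("0001", 8L)))
}

tiny_split <- function(n_train = 2L, n_val = 1L, n_test = 1L,
                       n_slices = 8L, size = 32L, seed = 77L) {
  generate_cohort(n_train, n_val, n_test, n_slices = n_slices, size = size,
                  seed = seed)
}

# an oracle "model" that returns the ground truth of the subject under
# evaluation; used to check the metric plumbing end to end
oracle_model <- function(subject) {
  structure(list(subject = subject), class = "oracle_model")
}

predict.oracle_model <- function(object, x, ...) {
  normalize_ct(object$subject$target_hu)
}
registerS3method("predict", "oracle_model", predict.oracle_model,
                 envir = asNamespace("stats"))
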