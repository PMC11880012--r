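# Small in-code fixtures shared across test files.

# A tiny but fully structured dataset: 6 classes, 2 exemplars per class
# (so both video sets exist), 4 subjects, 60 voxels of which 20 planted.
tiny_config <- function(seed = 303L, ...) {
  args <- list(n_classes = 6L, n_stimuli_per_class = 2L, n_subjects = 4L,
               n_voxels = 60L, n_reliable_voxels = 20L,
               d0 = 8L, d1 = 12L,
               prototype_spread = 1, within_class_jitter = 0.05,
               noise_sd = 0.4, subject_gain_sd = 0.1,
               n_runs = 4L, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

tiny_dataset <- function(seed = 303L, ...) {
  simulate_dataset(tiny_config(seed = seed, ...))
}

# Brute-force Pearson correlation straight from the covariance formula;
# the independent oracle for split-half r.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  if (sx == 0 || sy == 0) return(0)
  sxy / (sx * sy)
}

# Hand-rolled subject container around explicit run matrices.
manual_betas <- function(runs, table, subject_id = "s1") {
  subject_betas(subject_id, runs, table)
}

# A minimal one-set stimulus table with n stimuli, one per category.
simple_table <- function(n) {
  stimulus_table(sprintf("s%02d", seq_len(n)), seq_len(n))
}
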