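# shared fixtures: small phantom sets and desk-size model configs, memoized so
# expensive objects are built once per test run

.fixture_env <- new.env()

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

small_phantom_cfg <- function(n_subjects = 30, ...) {
  phantom_config(image_size = 32, n_subjects = n_subjects, noise_sd = 5, seed = 7, ...)
}

small_records <- function() {
  memo("small_records", function() {
    split_dataset(generate_phantoms(small_phantom_cfg(n_subjects = 40)), seed = 3, by = "gender")
  })
}

tiny_model_cfg <- function(dropout_rate = 0, ...) {
  model_config(
    input_size = 32, filters = c(2, 3, 4), embedding_len = 4,
    n_classes = 2, dropout_rate = dropout_rate, ...
  )
}

tiny_model <- function() {
  memo("tiny_model", function() build_model(tiny_model_cfg(), seed = 11))
}

# a gender-separable phantom set at 32 px for learnability tests
gender_records <- function() {
  memo("gender_records", function() {
    cfg <- phantom_config(
      image_size = 32, n_subjects = 80, gender_geometry_effect = 0.4,
      noise_sd = 5, disease_prevalence = 0, seed = 21
    )
    split_dataset(generate_phantoms(cfg), seed = 4, by = "gender")
  })
}

with_seed_matrix <- function(seed, m, n) {
  set.seed(seed)
  matrix(runif(m * n, 0, 255), m, n)
}

task_targets_for_test <- function(records, task) {
  chestnet:::task_targets(records, task)
}

# small Ver_ORG / Ver_NMF pair with disease labels, for protocol tests
transfer_versions <- function() {
  memo("transfer_versions", function() {
    cfg <- phantom_config(
      image_size = 32, n_subjects = 60, gender_geometry_effect = 0.4,
      disease_prevalence = 0.25, noise_sd = 5, seed = 31
    )
    rec <- split_dataset(generate_phantoms(cfg), seed = 6, by = "gender")
    list(
      Ver_ORG = make_version_org(rec),
      Ver_NMF = make_version_nmf(
        rec, nmf_config(kappa = 6, max_iter = 15, seed = 2),
        clahe_config(nt = c(4, 4))
      )
    )
  })
}
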