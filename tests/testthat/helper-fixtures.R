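# Small in-code fixtures shared across test files.

tiny_experiment <- function(seed = 11, n_per_cell = 3, n_metabolites = 40,
                            n_annotated = 30, n_pathways = 4,
                            active = "PW01", group_effect = 2, ...) {
  simulate_experiment(
    design_spec(n_per_cell = n_per_cell, seed = seed),
    effect_spec(n_metabolites = n_metabolites, n_annotated = n_annotated,
                n_pathways = n_pathways, pathway_size_range = c(3, 5),
                active_pathways = active, group_effect = group_effect, ...),
    seed = seed)
}

# two-class gaussian matrix with optional planted mean shifts
two_class_data <- function(n_per_class = 10, p = 50, shift = 0, n_shifted = 0,
                           seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
    if (n_shifted > 0) {
      m[seq_len(n_per_class), seq_len(n_shifted)] <-
        m[seq_len(n_per_class), seq_len(n_shifted)] + shift
    }
    m <- scale(m)
  })
  ids <- sprintf("M%03d", seq_len(p))
  samp <- sprintf("S%03d", seq_len(2 * n_per_class))
  labels <- tibble::tibble(sample_id = samp,
                           class = rep(c("a", "b"), each = n_per_class))
  list(scaled = as_scaled_tbl(m, ids, samp), labels = labels)
}

# balanced 4-group x 4-time null design with iid gaussian values
null_anova_samples <- function(n_per_cell = 3) {
  tidyr::expand_grid(age_group = c("young", "aged"),
                     intervention = c("sham", "clp"),
                     timepoint = c("0", "4", "8", "12"),
                     rep = seq_len(n_per_cell)) |>
    dplyr::mutate(sample_id = sprintf("S%03d", dplyr::row_number()),
                  subject_id = sample_id, batch = "B01") |>
    dplyr::select(sample_id, subject_id, age_group, intervention, timepoint, batch)
}
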