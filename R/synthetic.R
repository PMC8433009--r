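#' Factorial study design specification
#'
#' Describes the animal experiment to emulate: two age groups crossed with
#' surgical interventions and sacrifice timepoints, each animal contributing
#' a paired retro-orbital ("RO") pre-intervention plasma sample and (if it
#' survives to sacrifice) one post-intervention sample. Animals randomized to
#' `"baseline"` (immediate sacrifice) are sacrificed at 0 h only.
#'
#' @param n_per_cell animals per (age, intervention, timepoint) cell; >= 1.
#' @param age_levels age group labels; the last level carries the simulated
#'   age effect (default `c("young", "aged")`).
#' @param interventions intervention labels among `"baseline"`, `"sham"`,
#'   `"clp"`.
#' @param timepoints_h strictly increasing sacrifice times in hours.
#' @param attrition_prob per-animal probability of intraprocedural death
#'   (post-intervention sample lost, RO sample retained). Either a single
#'   number or a data frame with columns `age_group`, `intervention`, `prob`.
#' @param n_batches number of analytical batches; animals are assigned
#'   round-robin and both samples of an animal share a batch.
#' @param seed integer seed; the generated annotation is a pure function of
#'   `(spec, seed)`.
#' @return an object of class `design_spec`.
#' @seealso [generate_design()]
#' @export
design_spec <- function(n_per_cell = 3,
                        age_levels = c("young", "aged"),
                        interventions = c("sham", "clp"),
                        timepoints_h = c(0, 4, 8, 12),
                        attrition_prob = 0,
                        n_batches = 1,
                        seed = 1L) {
  if (n_per_cell < 1) abort("`n_per_cell` must be >= 1.")
  if (is.unsorted(timepoints_h, strictly = TRUE)) {
    abort("`timepoints_h` must be strictly increasing.")
  }
  probs <- if (is.data.frame(attrition_prob)) attrition_prob$prob else attrition_prob
  if (any(probs < 0 | probs > 1)) abort("`attrition_prob` must lie in [0, 1].")
  bad <- setdiff(interventions, c("baseline", "sham", "clp"))
  if (length(bad)) abort(sprintf("Unknown interventions: %s", paste(bad, collapse = ", ")))
  structure(list(n_per_cell = as.integer(n_per_cell), age_levels = age_levels,
                 interventions = interventions, timepoints_h = timepoints_h,
                 attrition_prob = attrition_prob, n_batches = as.integer(n_batches),
                 seed = as.integer(seed)),
            class = "design_spec")
}

attrition_lookup <- function(prob, age_group, intervention) {
  if (is.data.frame(prob)) {
    key <- paste(prob$age_group, prob$intervention)
    p <- setNames(prob$prob, key)[paste(age_group, intervention)]
    p[is.na(p)] <- 0
    unname(p)
  } else {
    rep(prob, length(age_group))
  }
}

#' Generate a sample annotation table from a design specification
#'
#' One animal per (age, intervention, timepoint, replicate); every animal gets
#' an RO pre-intervention row, and a post-intervention row unless removed by
#' attrition. Deterministic given `spec$seed`.
#'
#' @param spec a [design_spec()].
#' @return sample annotation tibble with columns `sample_id`, `subject_id`,
#'   `age_group`, `intervention`, `timepoint` (character; `"RO"` or hours),
#'   `batch`.
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  animals <- tidyr::expand_grid(
    age_group = spec$age_levels,
    intervention = spec$interventions,
    timepoint = as.character(spec$timepoints_h),
    replicate = seq_len(spec$n_per_cell)
  )
  # immediate-sacrifice animals exist only at the first timepoint
  animals <- animals[!(animals$intervention == "baseline" &
                         animals$timepoint != as.character(spec$timepoints_h[1])), ]
  animals$subject_id <- sprintf("A%04d", seq_len(nrow(animals)))
  animals$batch <- sprintf("B%02d", ((seq_len(nrow(animals)) - 1L) %% spec$n_batches) + 1L)
  died <- withr::with_seed(spec$seed, {
    p <- attrition_lookup(spec$attrition_prob, animals$age_group, animals$intervention)
    runif(nrow(animals)) < p
  })
  ro <- animals |>
    mutate(timepoint = "RO", sample_id = paste0(.data$subject_id, "_RO"))
  post <- animals[!died, ] |>
    mutate(sample_id = paste0(.data$subject_id, "_T", .data$timepoint))
  bind_rows(ro, post) |>
    arrange(.data$subject_id, .data$timepoint != "RO") |>
    select("sample_id", "subject_id", "age_group", "intervention",
           "timepoint", "batch") |>
    as_tibble()
}

#' Effect specification for the synthetic metabolome
#'
#' Defines the metabolite universe (how many features, how many carry KEGG or
#' HMDB annotation, superfamily mix), a pathway library drawn over the
#' annotated features, and log2-scale effects confined to designated active
#' pathways. Defaults mirror a plasma panel of 834 identifiable metabolites of
#' which 566 are KEGG/HMDB-annotated.
#'
#' Effects (all on the log2 scale, applied only to members of active
#' pathways): `group_effect` shifts the last age level at every sample;
#' `time_slope` adds a linear drift in t/12 over the post-intervention time
#' course; `interaction_effect` adds an age-by-time term; `clp_effect` shifts
#' post-intervention CLP samples, giving sepsis-specific signal for
#' CLP-versus-sham comparisons. Scalars are recycled over active pathways; a
#' `pathway_effects` tibble (`pathway_id` plus any of the four effect columns)
#' overrides them per pathway.
#'
#' @param n_metabolites total number of features.
#' @param n_annotated number carrying a KEGG/HMDB id; `<= n_metabolites`.
#' @param superfamily_proportions named probabilities summing to 1.
#' @param n_pathways number of pathways to draw.
#' @param pathway_size_range inclusive (min, max) member counts.
#' @param active_pathways character ids (`"PW01"`, ...) of pathways carrying
#'   effects.
#' @param group_effect,time_slope,interaction_effect,clp_effect log2 effect
#'   magnitudes (see Details).
#' @param pathway_effects optional per-pathway override tibble.
#' @param baseline_log2_mean_range (min, max) of per-metabolite baseline
#'   log2 abundance.
#' @param noise_sd_log2 residual standard deviation on the log2 scale; > 0.
#' @param missing_prob probability that an entry is missing completely at
#'   random.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(n_metabolites = 834,
                        n_annotated = 566,
                        superfamily_proportions = c(
                          lipid = 0.40, amino_acid = 0.25, carbohydrate = 0.10,
                          cofactor_vitamin = 0.10, nucleotide = 0.08,
                          xenobiotic = 0.07),
                        n_pathways = 20,
                        pathway_size_range = c(5, 15),
                        active_pathways = character(),
                        group_effect = 1.5,
                        time_slope = 0,
                        interaction_effect = 0,
                        clp_effect = 0,
                        pathway_effects = NULL,
                        baseline_log2_mean_range = c(10, 20),
                        noise_sd_log2 = 0.5,
                        missing_prob = 0) {
  if (n_annotated > n_metabolites) abort("`n_annotated` must be <= `n_metabolites`.")
  if (abs(sum(superfamily_proportions) - 1) > 1e-8) {
    abort("`superfamily_proportions` must sum to 1.")
  }
  if (noise_sd_log2 <= 0) abort("`noise_sd_log2` must be > 0.")
  if (missing_prob < 0 || missing_prob > 1) abort("`missing_prob` must lie in [0, 1].")
  eff <- c(group_effect, time_slope, interaction_effect, clp_effect)
  if (any(!is.finite(eff))) abort("Effect magnitudes must be finite.")
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_annotated = as.integer(n_annotated),
                 superfamily_proportions = superfamily_proportions,
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = pathway_size_range,
                 active_pathways = active_pathways,
                 group_effect = group_effect, time_slope = time_slope,
                 interaction_effect = interaction_effect, clp_effect = clp_effect,
                 pathway_effects = pathway_effects,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 noise_sd_log2 = noise_sd_log2, missing_prob = missing_prob),
            class = "effect_spec")
}

#' Generate a pathway library and metabolite annotation
#'
#' Exactly `n_annotated` metabolites receive KEGG-style (and for a subset
#' HMDB) identifiers; pathways draw members only from the annotated features;
#' superfamilies are sampled from the stated proportions. Overlap between
#' pathways is permitted.
#'
#' @param spec an [effect_spec()].
#' @param seed integer seed.
#' @return list with `annotation` (tibble: `metabolite_id`, `display_name`,
#'   `superfamily`, `kegg_id`, `hmdb_id`) and `pathways` (tibble:
#'   `pathway_id`, `description`, list-column `members`).
#' @export
generate_pathway_library <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "effect_spec"))
  p <- spec$n_metabolites
  if (spec$n_pathways > 0 && spec$pathway_size_range[2] > spec$n_annotated) {
    abort(sprintf("Max pathway size (%d) exceeds the number of annotated metabolites (%d).",
                  spec$pathway_size_range[2], spec$n_annotated))
  }
  withr::with_seed(seed, {
    ids <- sprintf("M%04d", seq_len(p))
    superfamily <- sample(names(spec$superfamily_proportions), p, replace = TRUE,
                          prob = spec$superfamily_proportions)
    annotated <- sort(sample.int(p, spec$n_annotated))
    kegg <- rep(NA_character_, p)
    hmdb <- rep(NA_character_, p)
    kegg[annotated] <- sprintf("C%05d", annotated)
    with_hmdb <- annotated[runif(length(annotated)) < 0.6]
    hmdb[with_hmdb] <- sprintf("HMDB%07d", with_hmdb)
    annotation <- tibble(
      metabolite_id = ids,
      display_name = paste0("metabolite-", seq_len(p)),
      superfamily = superfamily,
      kegg_id = kegg, hmdb_id = hmdb)
    if (spec$n_pathways > 0) {
      size_opts <- seq(spec$pathway_size_range[1], spec$pathway_size_range[2])
      sizes <- if (length(size_opts) == 1) rep(size_opts, spec$n_pathways) else
        sample(size_opts, spec$n_pathways, replace = TRUE)
      members <- lapply(sizes, function(k) sort(sample(ids[annotated], k)))
      pathways <- tibble(
        pathway_id = sprintf("PW%02d", seq_len(spec$n_pathways)),
        description = paste0("synthetic pathway ", seq_len(spec$n_pathways)),
        members = members)
    } else {
      pathways <- tibble(pathway_id = character(), description = character(),
                         members = list())
    }
  })
  list(annotation = annotation, pathways = pathways)
}

# per-active-pathway effect table, scalars recycled, overrides applied
pathway_effect_table <- function(spec, pathways) {
  missing_pw <- setdiff(spec$active_pathways, pathways$pathway_id)
  if (length(missing_pw)) {
    abort(sprintf("Active pathways not in library: %s", paste(missing_pw, collapse = ", ")))
  }
  eff <- tibble(pathway_id = spec$active_pathways,
                group_effect = spec$group_effect,
                time_slope = spec$time_slope,
                interaction_effect = spec$interaction_effect,
                clp_effect = spec$clp_effect)
  ov <- spec$pathway_effects
  if (!is.null(ov)) {
    for (col in intersect(names(ov), names(eff)[-1])) {
      idx <- match(ov$pathway_id, eff$pathway_id)
      eff[[col]][idx[!is.na(idx)]] <- ov[[col]][!is.na(idx)]
    }
  }
  eff
}

#' Simulate a peak-area matrix with known ground truth
#'
#' Log-normal abundance model: for sample i and metabolite j,
#' `log2(x_ij) = baseline_j + effects + Normal(0, noise_sd_log2)`, with the
#' group, time, interaction and CLP effects applied only to members of active
#' pathways (see [effect_spec()]). RO samples sit at t = 0 and precede the
#' intervention, so they carry the age effect but no intervention effect.
#' Values are exponentiated to strictly positive peak areas; missing entries
#' are then injected completely at random.
#'
#' @param design sample annotation from [generate_design()].
#' @param library pathway library/annotation from [generate_pathway_library()].
#' @param spec the [effect_spec()].
#' @param seed integer seed.
#' @return list with `matrix` (wide peak-area tibble) and `truth` (list:
#'   `active_pathway_ids`, `affected_metabolite_ids`, per-metabolite `effects`
#'   tibble).
#' @export
simulate_peak_areas <- function(design, library, spec, seed = 1L) {
  stopifnot(inherits(spec, "effect_spec"))
  ann <- library$annotation
  pw <- library$pathways
  ids <- ann$metabolite_id
  p <- length(ids)
  n <- nrow(design)
  eff_tbl <- pathway_effect_table(spec, pw)
  active_members <- pw$members[match(spec$active_pathways, pw$pathway_id)]
  affected <- sort(unique(unlist(active_members)))
  # per-metabolite effect vectors; first containing active pathway wins
  ge <- ts <- ie <- ce <- rep(0, p)
  for (i in rev(seq_along(spec$active_pathways))) {
    idx <- match(active_members[[i]], ids)
    ge[idx] <- eff_tbl$group_effect[i]
    ts[idx] <- eff_tbl$time_slope[i]
    ie[idx] <- eff_tbl$interaction_effect[i]
    ce[idx] <- eff_tbl$clp_effect[i]
  }
  grp <- as.numeric(design$age_group == spec_age_level(design))
  post <- design$timepoint != "RO"
  t_frac <- ifelse(post, suppressWarnings(as.numeric(design$timepoint)) / 12, 0)
  clp <- as.numeric(post & design$intervention == "clp")
  vals <- withr::with_seed(seed, {
    baseline <- runif(p, spec$baseline_log2_mean_range[1], spec$baseline_log2_mean_range[2])
    mu <- matrix(baseline, n, p, byrow = TRUE) +
      outer(grp, ge) + outer(t_frac, ts) + outer(grp * t_frac, ie) + outer(clp, ce)
    x <- 2^(mu + matrix(rnorm(n * p, sd = spec$noise_sd_log2), n, p))
    if (spec$missing_prob > 0) {
      x[matrix(runif(n * p) < spec$missing_prob, n, p)] <- NA_real_
    }
    x
  })
  colnames(vals) <- ids
  rownames(vals) <- design$sample_id
  truth <- list(
    active_pathway_ids = spec$active_pathways,
    affected_metabolite_ids = affected,
    effects = tibble(metabolite_id = ids, group = ge, time = ts,
                     interaction = ie, clp = ce))
  list(matrix = pa_tibble(vals), truth = truth)
}

# age level that carries the group effect: "aged" when present, else the last
spec_age_level <- function(design) {
  lv <- unique(design$age_group)
  if ("aged" %in% lv) "aged" else lv[length(lv)]
}

#' Simulate a complete factorial metabolomics experiment
#'
#' Convenience wrapper chaining [generate_design()],
#' [generate_pathway_library()] and [simulate_peak_areas()] with sub-seeds
#' derived from `seed`.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @param seed integer master seed (defaults to the design's seed).
#' @return list with `samples`, `annotation`, `pathways`, `matrix`, `truth`.
#' @examples
#' sim <- simulate_experiment(design_spec(n_per_cell = 2),
#'                            effect_spec(n_metabolites = 40, n_annotated = 30,
#'                                        n_pathways = 4,
#'                                        pathway_size_range = c(3, 5),
#'                                        active_pathways = "PW01"))
#' dim(sim$matrix)
#' @export
simulate_experiment <- function(design, effects, seed = design$seed) {
  design <- design
  design$seed <- as.integer(seed)
  samples <- generate_design(design)
  library <- generate_pathway_library(effects, seed = seed + 1L)
  sim <- simulate_peak_areas(samples, library, effects, seed = seed + 2L)
  list(samples = samples, annotation = library$annotation,
       pathways = library$pathways, matrix = sim$matrix, truth = sim$truth)
}
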