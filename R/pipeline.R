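#' Preprocess a cohort for feature building
#'
#' The standard preprocessing chain applied to the whole cohort before
#' the development/test split: text policies (negation, family-note
#' exclusion), spelling normalization of text entities, and removal of
#' events supported by a single patient.
#'
#' @param cohort an [ehr_cohort()].
#' @param negation_policy `"exclude"` (default) or `"separate"`.
#' @param family_exclusion drop family-heading notes? Default `TRUE`.
#' @param normalize run edit-distance spelling normalization? Default
#'   `TRUE`.
#' @param prune_rare remove single-patient events? Default `TRUE`.
#' @return A list: `cohort` (processed), `normalization_map` (or
#'   `NULL`), `removed` (rare-event table or `NULL`).
#' @export
preprocess_cohort <- function(cohort, negation_policy = "exclude",
                              family_exclusion = TRUE, normalize = TRUE,
                              prune_rare = TRUE) {
  cohort <- apply_text_policies(cohort, negation_policy = negation_policy,
                                family_exclusion = family_exclusion)
  map <- NULL
  if (normalize) {
    vocab <- surface_vocabulary(cohort)
    if (length(vocab)) {
      map <- build_groups(vocab)
      cohort <- apply_normalization(cohort, map)
    }
  }
  removed <- NULL
  if (prune_rare) {
    pr <- remove_rare_events(cohort)
    cohort <- pr$cohort
    removed <- pr$removed
  }
  list(cohort = cohort, normalization_map = map, removed = removed)
}

#' Run the full synthetic-cohort study
#'
#' Convenience wrapper chaining the whole pipeline on generated data:
#' cohort generation, cohort selection, preprocessing, stratified
#' development/test split, and the time-censored classifier sweep.
#'
#' @param config an [ehr_config()] for the generator.
#' @param specs classifier configurations.
#' @param cutoffs censoring grid (days before diagnosis).
#' @param rep_config an [ehr_representation()].
#' @param dev_fraction development-set fraction (default 0.2).
#' @param ranking_method filter ranking method (default `"ttest"`).
#' @param seed top-level seed for the split and cross-validation.
#' @param n_folds cross-validation folds.
#' @return A list: `cohort`, `ground_truth`, `prep` (preprocessing
#'   outputs), `dev`, `test`, `results` (the `ehr_sweep`), `manifest`.
#' @export
run_study <- function(config = ehr_config(),
                      specs = default_classifier_specs(),
                      cutoffs = c(1L, 344L),
                      rep_config = ehr_representation(),
                      dev_fraction = 0.2,
                      ranking_method = "ttest",
                      seed = 1L, n_folds = 10) {
  gen <- generate_cohort(config)
  cohort <- select_cohort(gen$cohort)
  prep <- preprocess_cohort(cohort)
  split <- split_dev_test(prep$cohort, dev_fraction = dev_fraction,
                          seed = seed)
  results <- sweep_evaluation(split$dev, split$test, specs = specs,
                              cutoffs = cutoffs, rep_config = rep_config,
                              ranking_method = ranking_method, seed = seed,
                              n_folds = n_folds)
  list(cohort = prep$cohort, ground_truth = gen$ground_truth, prep = prep,
       dev = split$dev, test = split$test, results = results,
       manifest = run_manifest(config, seed))
}
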