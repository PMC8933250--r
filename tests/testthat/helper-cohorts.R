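# Small cohort builders shared across test files.

tiny_cfg <- function(n_subjects = 20, n_nodes = 8, pos = 2, neg = 2,
                     effect = 0.7, seed = 1, ...) {
  sim_config(n_subjects = n_subjects, n_nodes = n_nodes,
             n_planted_positive = pos, n_planted_negative = neg,
             effect_size = effect, seed = seed, ...)
}

nuisance <- function(cohort) {
  cohort$phenotypes[c("age", "duration", "gender")]
}

# recall/precision of recovered masks against the planted truth
recovery <- function(fit, truth) {
  tp <- cpmr:::mask_indices(truth$positive)
  tn <- cpmr:::mask_indices(truth$negative)
  mp <- cpmr:::mask_indices(fit$positive_mask)
  mn <- cpmr:::mask_indices(fit$negative_mask)
  hits <- length(intersect(tp, mp)) + length(intersect(tn, mn))
  list(recall = hits / (length(tp) + length(tn)),
       precision = if (length(mp) + length(mn)) hits / (length(mp) + length(mn))
                   else NA_real_)
}
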