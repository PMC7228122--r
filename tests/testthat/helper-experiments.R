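# The scaled-down retrieval study shared by the end-to-end tests:
# 60 images/class at 64x64, 5 stratified folds, both metrics, k in
# {1,3,5,7,9}. Cached so the deep/baseline/null comparisons reuse one run.

study_images <- function(separability) {
  cached(paste0("study_sep", separability),
         generate_dataset(synth_spec(n_per_class = 60,
                                     separability = separability,
                                     seed = 207)))
}

study_report <- function(method, separability = 1) {
  cached(paste0("study_", method, "_sep", separability), {
    cfg <- experiment_config(
      method = method, n_folds = 5,
      train_cfg = train_config(epochs = 40, seed = 7),
      seed = 7)
    run_experiment(study_images(separability), cfg)
  })
}

mean_accuracy_at <- function(report, metric_name, k_val) {
  s <- report$summary
  s$mean_accuracy[s$metric == metric_name & s$k == k_val]
}
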