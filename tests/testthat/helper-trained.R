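# Heavy shared fixture: the reduced scorer (4 blocks, 8 filters) trained on
# 200 synthetic pairs under the standard study conditions, with 20 held-out
# pairs. Built once per test run, on first use.
.trained_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (is.null(.trained_env$fit)) {
    ds <- generate_dataset(220, pair_spec(), seed = 11)
    train <- ds$samples[1:200]
    holdout <- ds$samples[201:220]
    scorer <- build_scorer(scorer_config(n_blocks = 4, n_filters = 8),
                           seed = 42)
    cfg <- train_config(warmup_epochs = 1, decay_epochs = 9,
                        max_epochs = 10, early_stop_patience = 3, seed = 7)
    fit <- train_scorer(scorer, train, holdout, cfg)
    .trained_env$fit <- fit
    .trained_env$holdout <- holdout
  }
  list(fit = .trained_env$fit, holdout = .trained_env$holdout)
}
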