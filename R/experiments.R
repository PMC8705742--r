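#' Desk-scale experiment harnesses
#'
#' These functions bundle the package's end-to-end experiments at a size
#' a single CPU handles in minutes: a synthetic benchmark is simulated,
#' curated with the standard normalize-then-filter pipeline, split by
#' identity, and used to pretrain/fine-tune/evaluate the encoder. They
#' are the basis of the reproducibility script and of the end-to-end
#' tests.
#'
#' @name experiments
NULL

# small encoder + training recipe shared by the desk-scale experiments;
# augmentation uses the temporal transforms (pace + crop) whose parameter
# sets are fully specified, which at this data scale train stably (the
# stochastic spatial corruptions mainly pay off at corpus scale)
.desk_encoder <- function()
  encoder_config(channels = c(16, 32), temporal_kernel = 9L,
                 strides = c(1L, 2L), embedding_dim = 16L, hidden_dim = 64L)

.desk_augment <- function()
  augment_config(squeeze_range = c(1, 1), p_mirror = 0, p_timeflip = 0,
                 p_joint_dropout = 0, p_frame_dropout = 0)

#' Simulate and curate a benchmark with an identity split
#'
#' @param seed Seed for the simulation.
#' @param n_ids,runs_per_id,angles Benchmark layout.
#' @param n_eval_ids Number of identities held out for evaluation.
#' @return List with `dataset` (curated, normalized), `train_ids`,
#'   `eval_ids`, `identities` (per-tracklet), and the filter `report`.
#' @export
curated_benchmark <- function(seed, n_ids = 20L, runs_per_id = 4L,
                              angles = c(0, 45), n_eval_ids = 10L) {
  set.seed(derive_seed(seed, "benchmark"))
  bench <- make_benchmark(n_ids = n_ids, runs_per_id = runs_per_id,
                          angles = angles)
  ds <- normalize_dataset(bench$dataset)
  res <- apply_filters(ds)
  ids <- vapply(unname(res$dataset$tracklets), function(t)
    as.character(t$meta$identity), character(1))
  uid <- sort(unique(ids))
  list(dataset = res$dataset,
       identities = ids,
       train_ids = uid[seq_len(length(uid) - n_eval_ids)],
       eval_ids = uid[(length(uid) - n_eval_ids + 1):length(uid)],
       report = res$report)
}

#' End-to-end identity recovery experiment
#'
#' The scaled-down recognition experiment: simulate a clean benchmark,
#' pretrain the small encoder with the supervised contrastive objective
#' on the training identities' tracklets (tracklet ids as labels,
#' two-crop views, temperature `tau`), then run the cross-view
#' gallery/probe protocol on the held-out identities with the frozen
#' encoder.
#'
#' @param seed Controls simulation, initialization and batching.
#' @param epochs Pretraining epochs.
#' @param tau Contrastive temperature.
#' @param n_ids,runs_per_id,angles,n_eval_ids Passed to
#'   [curated_benchmark()].
#' @return List with `rank1` (mean cross-view rank-1 accuracy on the
#'   held-out identities), `per_angle`, `chance` (1 / number of
#'   evaluation identities), `model`, `bench` and the pretraining
#'   `loss_trace`.
#' @export
identity_recovery_run <- function(seed, epochs = 40L, tau = 0.01,
                                  n_ids = 20L, runs_per_id = 4L,
                                  angles = c(0, 45), n_eval_ids = 10L) {
  bench <- curated_benchmark(seed, n_ids, runs_per_id, angles, n_eval_ids)
  train_ds <- tracklet_dataset(
    unname(bench$dataset$tracklets)[bench$identities %in% bench$train_ids])
  tc <- train_config(tau = tau, sources_per_batch = 16L, lr = 1e-3,
                     epochs = epochs, seed = derive_seed(seed, "pretrain"))
  fit <- pretrain(train_ds, .desk_encoder(), tc, .desk_augment())
  ev <- direct_transfer_eval(fit$model, bench$dataset, bench$eval_ids,
                             bench$train_ids, seed = derive_seed(seed, "eval"))
  list(rank1 = ev$mean, per_angle = ev$per_angle,
       chance = 1 / length(bench$eval_ids),
       model = fit$model, bench = bench, loss_trace = fit$loss_trace)
}

#' Pretraining-benefit experiment (few-shot fine-tuning)
#'
#' Compares fine-tuning from a pretrained checkpoint against fine-tuning
#' from random initialization on a fresh benchmark, at a small run
#' fraction per identity, repeated over seeds and averaged — the few-shot
#' protocol.
#'
#' @param pretrained A pretrained `gait_encoder` (e.g. from
#'   [identity_recovery_run()]).
#' @param seed Base seed for the fresh benchmark and repetitions.
#' @param fraction Fraction of each identity's runs used for
#'   fine-tuning.
#' @param n_repeats Seeded repetitions (each resamples the run subset
#'   and re-initializes the random baseline).
#' @param epochs Fine-tuning epochs.
#' @return List with `pretrained_mean`, `random_mean`, per-repeat
#'   vectors, and the benchmark used.
#' @export
pretraining_benefit_run <- function(pretrained, seed, fraction = 0.10,
                                    n_repeats = 5L, epochs = 10L) {
  stopifnot(inherits(pretrained, "gait_encoder"))
  bench <- curated_benchmark(derive_seed(seed, "bench2"))
  train_idx <- bench$identities %in% bench$train_ids
  train_ds <- tracklet_dataset(unname(bench$dataset$tracklets)[train_idx])
  train_ids <- bench$identities[train_idx]
  acc_pre <- numeric(n_repeats)
  acc_rnd <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    s <- derive_seed(seed, paste0("fewshot", r))
    tc <- train_config(tau = 0.01, sources_per_batch = 16L, lr = 1e-3,
                       epochs = epochs, seed = s)
    ft_pre <- finetune(pretrained, train_ds, train_ids, fraction, tc,
                       .desk_augment())
    set.seed(derive_seed(s, "init"))
    rnd <- init_encoder(pretrained$config, pretrained$graph)
    ft_rnd <- finetune(rnd, train_ds, train_ids, fraction, tc,
                       .desk_augment())
    acc_pre[r] <- direct_transfer_eval(ft_pre$model, bench$dataset,
                                       bench$eval_ids, bench$train_ids,
                                       seed = s)$mean
    acc_rnd[r] <- direct_transfer_eval(ft_rnd$model, bench$dataset,
                                       bench$eval_ids, bench$train_ids,
                                       seed = s)$mean
  }
  list(pretrained_mean = mean(acc_pre), random_mean = mean(acc_rnd),
       pretrained = acc_pre, random = acc_rnd, bench = bench)
}

#' Pretraining-pool-size experiment
#'
#' Direct-transfer accuracy for encoders pretrained on growing fractions
#' of the synthetic corpus, averaged over seeded repetitions — the
#' dataset-size trend experiment.
#'
#' @param seed Base seed.
#' @param fractions Pool fractions.
#' @param n_repeats Repetitions per fraction.
#' @param epochs Pretraining epochs per run.
#' @return The data frame from [pretraining_size_curve()].
#' @export
size_trend_run <- function(seed, fractions = c(0.1, 0.5, 1),
                           n_repeats = 5L, epochs = 15L) {
  bench <- curated_benchmark(derive_seed(seed, "bench3"))
  pool <- tracklet_dataset(
    unname(bench$dataset$tracklets)[bench$identities %in% bench$train_ids])
  tc <- train_config(tau = 0.01, sources_per_batch = 16L, lr = 1e-3,
                     epochs = epochs, seed = 1L)
  pretraining_size_curve(pool, bench$dataset, bench$eval_ids,
                         fractions = fractions, enc_cfg = .desk_encoder(),
                         cfg = tc, aug = .desk_augment(),
                         n_repeats = n_repeats, seed = seed)
}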