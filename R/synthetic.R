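#' Synthetic Ct data configuration
#'
#' The generator emulates a two-group microRNA card experiment: per-feature
#' baseline Ct drawn around `baseline_mean` with spread `feature_sd`, a
#' per-sample technical shift (`sample_shift_sd`), a fixed expression
#' effect of `spike_ddct` cycles on `n_spiked` features in the target group
#' (alternating sign), i.i.d. measurement noise (`noise_sd`), and
#' missing-not-at-random dropout: a value above `missing_threshold` is
#' missing with probability rising linearly from 0 at the threshold to 1
#' at threshold + 5 cycles (low abundance fails to amplify). A small
#' fraction of wells additionally carries a "Failed" quality flag.
#'
#' Defaults mirror a 384-feature card with 8 + 8 samples, 25-cycle
#' baseline, 3-cycle biological spread, 1-cycle technical shifts,
#' 0.5-cycle noise and a 35-cycle detection limit.
#'
#' @param n_features number of features on the card.
#' @param n_samples_per_group samples per group (two groups).
#' @param baseline_mean,feature_sd baseline Ct distribution (cycles).
#' @param sample_shift_sd per-sample technical offset SD (cycles).
#' @param noise_sd measurement noise SD (cycles).
#' @param n_spiked number of differentially expressed features.
#' @param spike_ddct absolute effect size (cycles) of spiked features.
#' @param missing_threshold Ct above which dropout begins (cycles).
#' @param fail_flag_rate probability a well is flagged "Failed".
#' @param seed RNG seed.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_features = 384L, n_samples_per_group = 8L,
                             baseline_mean = 25, feature_sd = 3,
                             sample_shift_sd = 1, noise_sd = 0.5,
                             n_spiked = 20L, spike_ddct = 2,
                             missing_threshold = 35, fail_flag_rate = 0.02,
                             seed = 1L) {
  stopifnot(n_spiked <= n_features, feature_sd >= 0, sample_shift_sd >= 0,
            noise_sd >= 0, fail_flag_rate >= 0, fail_flag_rate <= 1)
  structure(list(n_features = as.integer(n_features),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 baseline_mean = baseline_mean, feature_sd = feature_sd,
                 sample_shift_sd = sample_shift_sd, noise_sd = noise_sd,
                 n_spiked = as.integer(n_spiked), spike_ddct = spike_ddct,
                 missing_threshold = missing_threshold,
                 fail_flag_rate = fail_flag_rate, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic Ct dataset
#'
#' Draws a dataset from the model of [synthetic_config()]:
#' `Ct_gs = baseline_g + shift_s + spike_g * [s in target] + noise_gs`,
#' then applies the MNAR dropout and failure flags. With `out_dir` given,
#' writes one Plain-dialect report per sample (feature, Ct or
#' "Undetermined", flag), a `treatment.tsv`, and a `truth.json` with the
#' generating parameters, per-sample shifts and the spiked feature set.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir optional directory for the Plain-dialect files.
#' @return List with `dataset` (a [ct_dataset()]), `treatment`
#'   (a [treatment_map()]), `truth` (baselines, shifts, signed spikes,
#'   pre-dropout matrix), and `files` (paths, when written).
#' @export
generate_synthetic <- function(cfg = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  G <- cfg$n_features; n <- cfg$n_samples_per_group
  feats <- sprintf("miR-%03d", seq_len(G))
  samples <- c(sprintf("cal%02d.txt", seq_len(n)),
               sprintf("tar%02d.txt", seq_len(n)))
  groups <- rep(c("CTRL", "CASE"), each = n)
  baseline <- rnorm(G, cfg$baseline_mean, cfg$feature_sd)
  shift <- rnorm(2L * n, 0, cfg$sample_shift_sd)
  spike <- numeric(G)
  spiked <- if (cfg$n_spiked > 0L) sample.int(G, cfg$n_spiked) else integer()
  if (length(spiked))
    spike[spiked] <- cfg$spike_ddct * rep_len(c(1, -1), length(spiked))
  in_target <- as.numeric(groups == "CASE")
  ct_true <- outer(baseline, shift, `+`) +
    outer(spike, in_target) +
    matrix(rnorm(G * 2L * n, 0, cfg$noise_sd), G)
  ct_true <- pmax(ct_true, 0)
  p_miss <- pmin(1, pmax(0, (ct_true - cfg$missing_threshold) / 5))
  miss <- matrix(runif(G * 2L * n) < p_miss, G)
  flags <- matrix(ifelse(runif(G * 2L * n) < cfg$fail_flag_rate,
                         "Failed", "Passed"), G)
  ct <- ct_true
  ct[miss] <- NA_real_
  tm <- treatment_map(samples, groups)
  ds <- ct_dataset(ct, feature_names = feats, sample_names = samples,
                   flags = flags)
  truth <- list(baseline = baseline, shift = setNames(shift, samples),
                spike = setNames(spike, feats),
                spiked_features = feats[sort(spiked)],
                ct_pre_dropout = ct_true, config = unclass(cfg))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (j in seq_along(samples)) {
      val <- ifelse(is.na(ct[, j]), "Undetermined", format_ct_value(ct[, j]))
      p <- file.path(out_dir, samples[j])
      writeLines(paste(feats, val, flags[, j], sep = "\t"), p)
      files <- c(files, p)
    }
    tp <- file.path(out_dir, "treatment.tsv")
    writeLines(c("SampleName\tTreatment", paste(samples, groups, sep = "\t")),
               tp)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(config = unclass(cfg), spiked_features = truth$spiked_features,
           shift = as.list(truth$shift)),
      truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, tp, truth_path)
  }
  list(dataset = ds, treatment = tm, truth = truth, files = files)
}
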