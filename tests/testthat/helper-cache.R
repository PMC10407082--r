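# heavy simulation products shared across test files, computed once per
# test session
.cache <- new.env(parent = emptyenv())

cached_steady <- function(profile = "DCM", duration = 8) {
  key <- paste0("steady_", profile, "_", duration)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- run_steady(experiment_config(builtin_profile(profile)),
                                duration = duration)
  .cache[[key]]
}

cached_ramp <- function(profile = "DCM", speed = 2800) {
  key <- paste0("ramp_", profile, "_", speed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- hypovolemia_ramp(
      experiment_config(builtin_profile(profile)), speed)
  .cache[[key]]
}

cached_protocol <- function() {
  if (is.null(.cache$protocol))
    .cache$protocol <- full_protocol()
  .cache$protocol
}

cached_report <- function() {
  if (is.null(.cache$report)) {
    ds <- cached_protocol()
    feats <- dataset_features(ds)
    thr <- calibrate_thresholds(feats, ds$beats$suction)
    .cache$report <- list(dataset = ds, features = feats,
                          thresholds = thr,
                          report = generate_report(ds, thr))
  }
  .cache$report
}
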