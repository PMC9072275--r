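# End-to-end replica pipeline: simulate a study, estimate every recording
# with the engine, and compare the two methods.

# Deterministic polynomial string hash, 8 hex digits; stamps outputs with
# the configuration they came from.
string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

config_hash <- function(cfg, seed) {
  string_hash(paste0(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
                     "#", seed))
}

#' Run the full simulate-estimate-compare replica study
#'
#' Simulates a study ([simulate_study()]), runs the estimation engine
#' ([run_vog()]) on every recording to fill the `vog_pd` column, and builds
#' the agreement report ([build_report()]). Byte-stable for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Master integer seed.
#' @param control A [vog_control()].
#' @return A list with `study` (completed table), `report`
#'   ([build_report()] result), `truth` (per-recording true skew, PD),
#'   `estimates` (list of [run_vog()] results), `config_hash` and `seed`.
#' @export
replicate_study <- function(cfg = sim_config(), seed = 1L,
                            control = vog_control()) {
  sim <- simulate_study(cfg, seed)
  est <- lapply(sim$recordings, function(rec) {
    suppressWarnings(run_vog(rec$trace, rec$schedule, control = control))
  })
  sim$study$vog_pd <- vapply(est, function(e) e$skew_pd, numeric(1))
  truth <- vapply(sim$recordings, function(r) r$truth$true_skew_pd, numeric(1))
  list(study = sim$study,
       report = build_report(sim$study),
       truth = truth,
       estimates = est,
       config_hash = config_hash(cfg, seed),
       seed = as.integer(seed))
}
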