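## Pipeline orchestration: a single JSON-configurable run of
## featurize -> tICA -> k-means -> MSM (+ CK) -> PCCA+ -> angle
## distributions -> KS table -> RMSF, with a manifest recording the config
## hash and per-stage seeds.

#' Build and validate a pipeline configuration
#'
#' Defaults mirror the standard CDR3-ensemble protocol: tICA lag 10 ns with
#' 2 components, 150 k-means microstates, MSM lag 10 ns, 300 K, clustering
#' cutoff 1.2 A.
#'
#' @param input list describing the input; either
#'   `list(topology = <pdb path>, trajectory = <path>, frame_interval = ns)`
#'   or `list(synthetic = <spec list>)` (see details in the vignette).
#' @param selections named list of region definitions; each entry is
#'   `list(chain_id = , residue_range = c(lo, hi))`. Required names:
#'   `CDR3_alpha`, `CDR3_beta`, `V_alpha`, `V_beta`, `CDR_loops_alpha`,
#'   `CDR_loops_beta`.
#' @param tica_lag_ns tICA lag time, ns.
#' @param n_components retained tICA components.
#' @param k number of k-means microstates.
#' @param msm_lag_ns MSM lag time, ns.
#' @param n_macro PCCA+ macrostates (<= k).
#' @param temperature K.
#' @param cluster_cutoff average-linkage RMSD cutoff, Angstrom.
#' @param ck_multiples CK lag multiples.
#' @param seed master seed (per-stage seeds fan out from it).
#' @param output_dir artifact directory.
#' @return validated config object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, selections, tica_lag_ns = 10,
                            n_components = 2, k = 150, msm_lag_ns = 10,
                            n_macro = 4, temperature = 300,
                            cluster_cutoff = 1.2, ck_multiples = 1:5,
                            seed = 1, output_dir = tempfile("tcrmsm_run_")) {
  cfg <- list(input = input, selections = selections,
              tica_lag_ns = tica_lag_ns, n_components = n_components,
              k = k, msm_lag_ns = msm_lag_ns, n_macro = n_macro,
              temperature = temperature, cluster_cutoff = cluster_cutoff,
              ck_multiples = as.integer(ck_multiples), seed = as.integer(seed),
              output_dir = output_dir)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  req <- c("CDR3_alpha", "CDR3_beta", "V_alpha", "V_beta",
           "CDR_loops_alpha", "CDR_loops_beta")
  if (is.null(cfg$input)) stop("config: input is required")
  if (is.null(cfg$input$synthetic)) {
    miss <- setdiff(req, names(cfg$selections))
    if (length(miss))
      stop("config: missing selection definition(s): ",
           paste(miss, collapse = ", "))
  }
  if (cfg$tica_lag_ns <= 0 || cfg$msm_lag_ns <= 0)
    stop("config: lag times must be positive")
  if (cfg$k < cfg$n_macro)
    stop("config: k (", cfg$k, ") must be >= n_macro (", cfg$n_macro, ")")
  if (cfg$temperature <= 0) stop("config: temperature must be positive")
  invisible(TRUE)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

selection_from_cfg <- function(name, s) {
  region_selection(name, s$chain_id, unlist(s$residue_range))
}

resolve_pipeline_input <- function(cfg) {
  if (!is.null(cfg$input$synthetic)) {
    s <- cfg$input$synthetic
    hmm <- hmm_dihedral_spec(
      transition = matrix(unlist(s$transition), nrow = length(s$targets),
                          byrow = TRUE),
      psi_means = matrix(unlist(s$psi_means), nrow = length(s$targets),
                         byrow = TRUE),
      emission_sd = s$emission_sd %||% 12,
      n_frames = s$n_frames %||% 5000,
      frame_interval = s$frame_interval %||% 1,
      seed = stage_seed(cfg$seed, 1))
    gen <- generate_coupled_trajectory(hmm, unlist(s$targets),
                                       angle_jitter_sd = s$angle_jitter_sd %||% 0.5,
                                       coupled = isTRUE(s$coupled %||% TRUE))
    list(traj = gen$trajectory,
         feature_selections = gen$feature_selections,
         angle_selections = gen$angle_selections,
         hidden = gen$hidden)
  } else {
    topo <- read_pdb(cfg$input$topology)
    traj <- read_trajectory(cfg$input$trajectory, topo,
                            frame_interval = cfg$input$frame_interval %||% 1)
    sel <- function(nm) selection_from_cfg(nm, cfg$selections[[nm]])
    list(traj = traj,
         feature_selections = list(cdr3_alpha = sel("CDR3_alpha"),
                                   cdr3_beta = sel("CDR3_beta")),
         angle_selections = list(cdr_alpha = sel("CDR_loops_alpha"),
                                 v_alpha = sel("V_alpha"),
                                 v_beta = sel("V_beta"),
                                 cdr_beta = sel("CDR_loops_beta")),
         hidden = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Stages, in order: featurize, tICA, k-means microstating, MSM estimation,
#' Chapman-Kolmogorov validation, PCCA+ macrostates, interdomain-angle
#' distributions, pairwise KS table, per-macrostate RMSF. Every artifact is
#' written under the config's output directory together with a manifest
#' (config hash, seeds, stage outputs). Re-running with the same config
#' reproduces identical outputs.
#'
#' @param config a `pipeline_config` or path to its JSON form.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }
  message("stage 1/8: featurize")
  inp <- stage("featurize", resolve_pipeline_input(config))
  fm <- stage("featurize",
              psi_phi_features(inp$traj, inp$feature_selections))
  export_csv(fm, out("features.csv"))
  manifest$stages$featurize <- "features.csv"

  message("stage 2/8: tICA")
  tica_model <- stage("tica", fit_tica(fm, lag = config$tica_lag_ns,
                                       n_components = config$n_components))
  proj <- predict(tica_model, fm)
  export_tica(tica_model, out("tica.json"))
  fes <- free_energy_surface(proj[, 1:min(2, ncol(proj)), drop = FALSE],
                             temperature = config$temperature)
  export_fes(fes, out("fes.csv"))
  manifest$stages$tica <- c("tica.json", "fes.csv")

  message("stage 3/8: k-means microstates")
  micro <- stage("kmeans",
                 kmeans_microstates(proj, k = config$k,
                                    seed = stage_seed(config$seed, 3),
                                    frame_interval = inp$traj$frame_interval))
  utils::write.csv(data.frame(frame = seq_along(micro$assignment),
                              microstate = micro$assignment),
                   out("microstates.csv"), row.names = FALSE)
  manifest$stages$kmeans <- "microstates.csv"

  message("stage 4/8: MSM estimation")
  lag_frames <- max(1L, as.integer(round(config$msm_lag_ns /
                                           inp$traj$frame_interval)))
  if (abs(lag_frames * inp$traj$frame_interval - config$msm_lag_ns) > 1e-9)
    message("MSM lag rounded to ", lag_frames, " frames")
  counts <- stage("msm", count_transitions(micro$assignment, lag_frames))
  model <- stage("msm", estimate_msm(counts,
                                     lag = lag_frames * inp$traj$frame_interval))
  jsonlite::write_json(list(transition_matrix = model$transition_matrix,
                            stationary = model$stationary,
                            active_set = model$active_set,
                            lag_ns = model$lag),
                       out("msm.json"), digits = NA, matrix = "rowmajor")
  manifest$stages$msm <- "msm.json"

  message("stage 5/8: PCCA+ macrostates")
  macro <- stage("pcca", pcca_plus(model, config$n_macro))
  gap_msg <- if (is.finite(macro$spectral_gap_ratio %||% NA))
    signif(macro$spectral_gap_ratio, 3) else "NA"
  message("PCCA+ spectral-gap advisory: ratio ", gap_msg,
          " at n_macro = ", config$n_macro)
  assignment <- frames_to_macrostates(macro, micro$assignment)
  utils::write.csv(data.frame(frame = seq_along(assignment),
                              macrostate = assignment),
                   out("macrostates.csv"), row.names = FALSE)
  manifest$stages$pcca <- "macrostates.csv"

  message("stage 6/8: Chapman-Kolmogorov")
  ck <- stage("ck", chapman_kolmogorov(micro$assignment, model, macro,
                                       lag_frames = lag_frames,
                                       multiples = config$ck_multiples,
                                       seed = stage_seed(config$seed, 6)))
  export_ck(ck, out("ck.csv"))
  manifest$stages$ck <- "ck.csv"

  message("stage 7/8: interdomain angles + KS")
  ang <- stage("angles", do.call(interdomain_torsion,
                                 c(list(inp$traj), inp$angle_selections)))
  export_csv(ang, out("angles.csv"))
  dists <- stage("angles", macrostate_angle_distributions(ang, assignment))
  utils::write.csv(dists$summary, out("angle_summary.csv"), row.names = FALSE)
  kst <- stage("ks", pairwise_ks_table(dists))
  export_ks_table(kst, out("ks_table.csv"))
  manifest$stages$angles <- c("angles.csv", "angle_summary.csv")
  manifest$stages$ks <- "ks_table.csv"

  message("stage 8/8: per-macrostate RMSF")
  rmsf_rows <- list()
  for (m in sort(unique(assignment[!is.na(assignment)]))) {
    fr <- which(assignment == m)
    if (length(fr) < 2) next
    r <- stage("rmsf", rmsf(inp$traj, inp$feature_selections$cdr3_alpha,
                            frames = fr))
    r$macrostate <- m
    rmsf_rows[[length(rmsf_rows) + 1]] <- r
  }
  rmsf_tab <- do.call(rbind, rmsf_rows)
  utils::write.csv(rmsf_tab, out("rmsf.csv"), row.names = FALSE)
  manifest$stages$rmsf <- "rmsf.csv"

  manifest$status <- "ok"
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(features = fm, tica = tica_model, projections = proj,
                 microstates = micro, msm = model, macrostates = macro,
                 assignment = assignment, ck = ck, angles = ang,
                 distributions = dists, ks = kst, rmsf = rmsf_tab,
                 hidden = inp$hidden, manifest = manifest,
                 output_dir = config$output_dir))
}

#' End-to-end parameter-recovery benchmark on synthetic HMM trajectories
#'
#' Generates hidden-Markov dihedral trajectories with a known 3-state
#' chain, runs featurize -> tICA -> k-means -> MSM -> PCCA+, aligns
#' macrostates to hidden states by majority vote, and reports the
#' recovered stationary probabilities and slowest implied timescale
#' against the generating truth.
#'
#' @param transition hidden transition matrix (default: a metastable
#'   3-state chain).
#' @param n_frames frames per trajectory.
#' @param seeds integer vector of generator seeds (one experiment each).
#' @param k microstates for k-means.
#' @param lag_frames tICA and MSM lag, frames.
#' @param n_res loop length used for the synthetic backbone.
#' @param emission_sd dihedral emission noise, degrees.
#' @return data.frame with one row per seed: `max_pi_error` (max absolute
#'   error of the aligned macrostate stationary probabilities),
#'   `timescale_rel_error` (relative error of the slowest implied
#'   timescale), `aligned` (whether macrostates map 1:1 onto hidden states).
#' @export
hmm_recovery_experiment <- function(transition = NULL, n_frames = 50000,
                                    seeds = 1:5, k = 50, lag_frames = 10,
                                    n_res = 6, emission_sd = 15) {
  if (is.null(transition))
    transition <- matrix(c(0.98, 0.015, 0.005,
                           0.01, 0.98, 0.01,
                           0.005, 0.015, 0.98), 3, 3, byrow = TRUE)
  n_h <- nrow(transition)
  ev <- eigen(t(transition))
  pi_true <- Re(ev$vectors[, which.max(Re(ev$values))])
  pi_true <- pi_true / sum(pi_true)
  lam <- sort(Re(eigen(transition)$values), decreasing = TRUE)
  t_slow_true <- -lag_frames / log(lam[2]^lag_frames)   # = -1 / log(lam[2])
  ## well-separated psi basins per hidden state
  basin <- c(-60, 120, -160, 60, 0)[seq_len(n_h)]
  psi_means <- matrix(basin, n_h, n_res)
  if (n_h >= 3)  # give the third state a mixed signature
    psi_means[3, ] <- rep(c(-60, 120), length.out = n_res)
  rows <- lapply(seeds, function(seed) {
    spec <- hmm_dihedral_spec(transition, psi_means,
                              emission_sd = emission_sd,
                              n_frames = n_frames, seed = seed)
    g <- generate_hmm_trajectory(spec)
    fm <- psi_phi_features(g$trajectory,
                           region_selection("custom", "A", c(1, n_res)))
    tm <- fit_tica(fm, lag = lag_frames, n_components = 2)
    km <- kmeans_microstates(predict(tm, fm), k = k, seed = seed)
    m <- estimate_msm(count_transitions(km$assignment, lag_frames),
                      lag = lag_frames)
    mac <- pcca_plus(m, n_h)
    fr_mac <- frames_to_macrostates(mac, km$assignment)
    map <- vapply(seq_len(n_h), function(a) {
      tab <- table(g$hidden[fr_mac == a])
      as.integer(names(which.max(tab)))
    }, 1L)
    aligned <- length(unique(map)) == n_h
    pi_rec <- rep(NA_real_, n_h)
    if (aligned) pi_rec[map] <- mac$macro_stationary
    its <- implied_timescales(m, 1)$timescale_ns[1]
    data.frame(seed = seed,
               max_pi_error = if (aligned) max(abs(pi_rec - pi_true)) else NA,
               timescale_rel_error = abs(its - t_slow_true) / t_slow_true,
               aligned = aligned)
  })
  out <- do.call(rbind, rows)
  attr(out, "pi_true") <- pi_true
  attr(out, "t_slow_true") <- t_slow_true
  out
}
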