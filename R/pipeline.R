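# End-to-end wild-type vs. mutant comparison: flexibility profiles -> chain
# stiffness; interaction energies -> blocked-closed equilibrium; four
# parameter sets (wt, gamma-only, kbc-only, combined) -> steady-state
# force-pCa curves and twitches -> Hill fits and twitch metrics.

#' Pipeline configuration
#'
#' @param out_dir Output directory for intermediate artifacts, or `NULL` to
#'   keep everything in memory.
#' @param seed Integer master seed recorded in every output.
#' @param baseline_delta,span,center,width Synthetic flexibility-profile
#'   geometry (degrees / residues); the mutant adds a localized bump of
#'   `mut_amplitude` degrees at `center`. The default amplitude is solved so
#'   the mutant/WT stiffness ratio equals `gamma_mut / gamma_wt`.
#' @param gamma_wt Wild-type effective chain stiffness used in the
#'   regulatory model, kJ mol^-1 rad^-2.
#' @param gamma_mut Mutant stiffness target, kJ mol^-1 rad^-2.
#' @param mut_amplitude Mutant bump amplitude, degrees.
#' @param energy_table Path to the interaction-energy summary table; default
#'   is the table shipped with the package.
#' @param kbc_ref Wild-type blocked-closed equilibrium constant.
#' @param temperature Kelvin for the Gibbs mapping.
#' @param pca_grid pCa grid of the steady-state sweep.
#' @param n_trajectories,n_repeats Monte-Carlo sizes for the filament runs.
#' @param twitch_duration,stim_time Twitch protocol timing, s.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL,
                            seed = 1L,
                            baseline_delta = 3,
                            span = 142L,
                            center = 108L,
                            width = 5,
                            gamma_wt = 60,
                            gamma_mut = 31.6,
                            mut_amplitude = NULL,
                            energy_table = system.file("extdata",
                                                       "interaction_energies.tsv",
                                                       package = "thinfilament"),
                            kbc_ref = 0.76,
                            temperature = 300,
                            pca_grid = c(9, 7.5, 7, 6.75, 6.5, 6.25, 6,
                                         5.75, 5.5, 5, 4.5),
                            n_trajectories = 48L,
                            n_repeats = 1L,
                            twitch_duration = 2.5,
                            stim_time = 1) {
  if (is.null(mut_amplitude)) {
    mut_amplitude <- calibrate_bump_amplitude(gamma_mut / gamma_wt,
                                              baseline_delta, span,
                                              center, width)
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         baseline_delta = baseline_delta, span = span, center = center,
         width = width, gamma_wt = gamma_wt, gamma_mut = gamma_mut,
         mut_amplitude = mut_amplitude, energy_table = energy_table,
         kbc_ref = kbc_ref, temperature = temperature, pca_grid = pca_grid,
         n_trajectories = as.integer(n_trajectories),
         n_repeats = as.integer(n_repeats),
         twitch_duration = twitch_duration, stim_time = stim_time),
    class = "pipeline_config"
  )
}

# Hash of the scientific configuration; the output directory is excluded so
# that re-running the same analysis elsewhere yields an identical report.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full comparison pipeline
#'
#' Executes, in order: (1) synthetic flexibility profiles and the chain
#' stiffness fits for wild type and mutant; (2) the interaction-energy
#' summaries and the Gibbs mapping of the mutant blocked-closed equilibrium
#' constant; (3) stochastic filament simulations (steady-state force-pCa
#' sweep and isometric twitch) for the four parameter sets wt, gamma_only,
#' kbc_only, combined; (4) Hill fits and twitch metrics, plus mutant/WT
#' ratios. Deterministic for a fixed config (including seed).
#'
#' @param config A [pipeline_config()].
#' @return An object of class `comparison_report`: nested list with elements
#'   `chain` (per-genotype stiffness fits), `energetics` (the
#'   `equilibrium_mapping`), `presets` (per-preset parameters, force-pCa
#'   curve, Hill fit, twitch metrics), `ratios` (combined-mutant / WT), and
#'   `provenance` (seed, config hash).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  save_to <- function(name, writer, obj) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      writer(obj, file.path(config$out_dir, name))
    }
  }

  # --- stage 1: chain mechanics -------------------------------------------
  prof_wt <- generate_flexibility_profile(config$baseline_delta, config$span,
                                          config$center, config$width,
                                          amplitude = 0, noise_sd = 0,
                                          genotype = "wt")
  prof_mut <- generate_flexibility_profile(config$baseline_delta, config$span,
                                           config$center, config$width,
                                           amplitude = config$mut_amplitude,
                                           noise_sd = 0, genotype = "s215l")
  fits <- lapply(list(wt = prof_wt, s215l = prof_mut), function(p) {
    fit_effective_stiffness(chain_energy_curve(stiffness_from_flexibility(p)))
  })
  stiffness_ratio <- fits$s215l$gamma / fits$wt$gamma
  save_to("flexibility_wt.tsv", write_flexibility_profile, prof_wt)
  save_to("flexibility_s215l.tsv", write_flexibility_profile, prof_mut)

  # --- stage 2: energetics -------------------------------------------------
  summaries <- read_energy_table(config$energy_table)
  genos <- unique(vapply(summaries, `[[`, "", "genotype"))
  if (length(genos) != 2L) stopf("energy table must contain exactly 2 genotypes")
  ref_geno <- genos[1L]
  mut_geno <- genos[2L]
  de_ref <- bc_energy_difference(summaries[[paste0(ref_geno, ".B")]],
                                 summaries[[paste0(ref_geno, ".C")]])
  de_mut <- bc_energy_difference(summaries[[paste0(mut_geno, ".B")]],
                                 summaries[[paste0(mut_geno, ".C")]])
  mapping <- map_kbc(config$kbc_ref, de_ref, de_mut, config$temperature)
  kbc_mut <- round(mapping$kbc_mut, 2)
  save_to("kbc_mapping.json", write_equilibrium_mapping, mapping)

  # --- stage 3: filament simulations --------------------------------------
  gamma_mut_model <- config$gamma_wt * stiffness_ratio
  param_sets <- list(
    wt         = model_parameters(kbc = config$kbc_ref, gamma = config$gamma_wt),
    gamma_only = model_parameters(kbc = config$kbc_ref, gamma = gamma_mut_model),
    kbc_only   = model_parameters(kbc = kbc_mut, gamma = config$gamma_wt),
    combined   = model_parameters(kbc = kbc_mut, gamma = gamma_mut_model)
  )
  protocol <- calcium_protocol("transient", stim_time = config$stim_time)
  presets <- vector("list", length(param_sets))
  names(presets) <- names(param_sets)
  for (i in seq_along(param_sets)) {
    nm <- names(param_sets)[i]
    p <- param_sets[[i]]
    curve <- force_pca_curve(p, config$pca_grid,
                             n_trajectories = config$n_trajectories,
                             seed = config$seed + 100L * i)
    hill <- fit_hill(curve$pca, force_to_velocity(curve$force))
    tw <- simulate_twitch(p, protocol, duration = config$twitch_duration,
                          n_trajectories = config$n_trajectories,
                          n_repeats = config$n_repeats,
                          seed = config$seed + 100L * i + 50L)
    met <- twitch_metrics(tw, smooth = 9L)
    presets[[i]] <- list(name = nm, kbc = p$kbc, gamma = p$gamma,
                         curve = curve, hill = hill, twitch = tw,
                         metrics = met)
    if (!is.null(config$out_dir)) {
      save_to(sprintf("steady_%s.tsv", nm),
              function(obj, path) utils::write.table(obj, path, sep = "\t",
                                                     row.names = FALSE,
                                                     quote = FALSE),
              curve)
      save_to(sprintf("twitch_%s.tsv", nm), write_trajectory, tw)
    }
  }

  mw <- presets$combined$metrics
  mv <- presets$wt$metrics
  ratios <- list(
    peak_force = mw$peak_force / mv$peak_force,
    diastolic_force = mw$diastolic_force / mv$diastolic_force,
    time_to_peak = mw$time_to_peak / mv$time_to_peak,
    rt50 = mw$rt50 / mv$rt50,
    fti = mw$fti / mv$fti,
    pca50_shift = presets$combined$hill$pca50 - presets$wt$hill$pca50
  )

  report <- structure(
    list(chain = list(fits = fits, stiffness_ratio = stiffness_ratio,
                      gamma_model = c(wt = config$gamma_wt,
                                      mutant = gamma_mut_model)),
         energetics = mapping,
         kbc_mut = kbc_mut,
         presets = presets,
         ratios = ratios,
         provenance = list(seed = config$seed, config_hash = hash)),
    class = "comparison_report"
  )
  if (!is.null(config$out_dir)) {
    write_report(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' Tabulate per-parameter effects relative to wild type
#'
#' Summarizes how each observable changes under the gamma-only, kbc-only and
#' combined parameter sets, as ratios (pCa50 as a difference) to the
#' wild-type run of the same report.
#'
#' @param report A `comparison_report` from [run_pipeline()].
#' @return Data frame: one row per preset, columns `preset`, `vmax_ratio`,
#'   `pca50_shift`, `n_hill_ratio`, `peak_force_ratio`,
#'   `diastolic_force_ratio`, `time_to_peak_ratio`, `rt50_ratio`,
#'   `fti_ratio`.
#' @export
decompose_effects <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  wt <- report$presets$wt
  need <- c("wt", "gamma_only", "kbc_only", "combined")
  missing <- setdiff(need, names(report$presets))
  if (length(missing)) stopf("report is missing runs: %s",
                             paste(missing, collapse = ", "))
  rows <- lapply(report$presets[need], function(p) {
    data.frame(
      preset = p$name,
      vmax_ratio = p$hill$vmax / wt$hill$vmax,
      pca50_shift = p$hill$pca50 - wt$hill$pca50,
      n_hill_ratio = p$hill$n_hill / wt$hill$n_hill,
      peak_force_ratio = p$metrics$peak_force / wt$metrics$peak_force,
      diastolic_force_ratio = p$metrics$diastolic_force / wt$metrics$diastolic_force,
      time_to_peak_ratio = p$metrics$time_to_peak / wt$metrics$time_to_peak,
      rt50_ratio = p$metrics$rt50 / wt$metrics$rt50,
      fti_ratio = p$metrics$fti / wt$metrics$fti
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a comparison report as JSON
#'
#' Trajectories and curves are embedded as arrays; provenance (seed, config
#' hash) is carried along.
#'
#' @param report A `comparison_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  slim <- list(
    chain = list(
      gamma_wt = report$chain$fits$wt$gamma,
      gamma_s215l = report$chain$fits$s215l$gamma,
      stiffness_ratio = report$chain$stiffness_ratio,
      gamma_model = as.list(report$chain$gamma_model)
    ),
    energetics = unclass(report$energetics),
    kbc_mut = report$kbc_mut,
    presets = lapply(report$presets, function(p) {
      list(name = p$name, kbc = p$kbc, gamma = p$gamma,
           curve = p$curve,
           hill = p$hill[c("vmax", "pca50", "n_hill", "converged")],
           metrics = unclass(p$metrics))
    }),
    ratios = report$ratios,
    provenance = report$provenance
  )
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
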