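# Blocked/closed state energetics: summarizing interaction-energy frame
# ensembles and mapping the mutant's change in the blocked-to-closed energy
# difference onto a mutant blocked-closed equilibrium constant through the
# Gibbs relation K = exp(-dG / RT).

#' Construct an interaction-energy summary
#'
#' Mean +/- SD actin-tropomyosin (plus troponin I in the blocked state)
#' interaction energy for one genotype and regulatory state.
#'
#' @param genotype Label.
#' @param state `"B"` or `"C"`.
#' @param mean Mean energy, kcal/mol.
#' @param sd Frame standard deviation, kcal/mol; `>= 0`.
#' @param n_frames Frame count.
#' @return An object of class `energy_summary`.
#' @export
energy_summary <- function(genotype, state, mean, sd, n_frames) {
  state <- match.arg(state, c("B", "C"))
  check_scalar_number(mean, "mean")
  check_scalar_number(sd, "sd")
  if (sd < 0) stopf("`sd` must be >= 0")
  structure(
    list(genotype = as.character(genotype), state = state,
         mean = mean, sd = sd, n_frames = as.integer(n_frames)),
    class = "energy_summary"
  )
}

#' Summarize an energy frame ensemble
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator).
#'
#' @param ensemble An [energy_frames()] object.
#' @return An [energy_summary()].
#' @export
summarize_frames <- function(ensemble) {
  stopifnot(inherits(ensemble, "energy_frames"))
  energy_summary(ensemble$genotype, ensemble$state,
                 mean(ensemble$values), stats::sd(ensemble$values),
                 ensemble$n_frames)
}

#' Blocked-to-closed interaction-energy difference
#'
#' Returns `mean(C) - mean(B)` in kcal/mol. Both summaries must belong to the
#' same genotype. Because the blocked-state energy includes the stabilizing
#' troponin I contacts, the raw means are negative and the difference is
#' positive when the blocked state is the more favorable one: it is the
#' energetic cost of leaving the blocked state.
#'
#' @param summary_b Blocked-state [energy_summary()].
#' @param summary_c Closed-state [energy_summary()].
#' @return Energy difference, kcal/mol.
#' @export
bc_energy_difference <- function(summary_b, summary_c) {
  stopifnot(inherits(summary_b, "energy_summary"),
            inherits(summary_c, "energy_summary"))
  if (summary_b$state != "B" || summary_c$state != "C") {
    stopf("arguments must be the B-state and C-state summaries, in that order")
  }
  if (summary_b$genotype != summary_c$genotype) {
    stopf("genotype mismatch: '%s' vs '%s'", summary_b$genotype, summary_c$genotype)
  }
  summary_c$mean - summary_b$mean
}

#' Map an interaction-energy change onto the blocked-closed equilibrium
#'
#' Given the reference (wild-type) blocked-closed equilibrium constant, the
#' Gibbs relation gives `dG_ref = -RT log(kbc_ref)`. The mutant free energy
#' is scaled proportionally by the ratio of the mutant to reference
#' blocked-to-closed interaction-energy differences, and the relation is
#' inverted: `kbc_mut = exp(-dG_mut / RT) = kbc_ref ^ scale`. The temperature
#' cancels algebraically in `kbc_mut`; it only affects the reported free
#' energies.
#'
#' @param kbc_ref Reference equilibrium constant; `> 0`.
#' @param delta_e_ref Reference blocked-to-closed energy difference,
#'   kcal/mol; nonzero.
#' @param delta_e_mut Mutant blocked-to-closed energy difference, kcal/mol.
#' @param temperature Kelvin; `> 0`. Used for the dG fields only.
#' @return An object of class `equilibrium_mapping`: list with `kbc_ref`,
#'   `delta_e_ref`, `delta_e_mut`, `scale`, `delta_g_ref`, `delta_g_mut`
#'   (kcal/mol), `temperature`, `kbc_mut`.
#' @export
map_kbc <- function(kbc_ref, delta_e_ref, delta_e_mut, temperature = 300) {
  check_scalar_number(kbc_ref, "kbc_ref")
  if (kbc_ref <= 0) stopf("`kbc_ref` must be > 0")
  check_scalar_number(delta_e_ref, "delta_e_ref")
  if (delta_e_ref == 0) stopf("`delta_e_ref` is zero: the scaling ratio is undefined")
  check_scalar_number(delta_e_mut, "delta_e_mut")
  check_scalar_number(temperature, "temperature")
  if (temperature <= 0) stopf("`temperature` must be > 0 K")
  rt <- .R_KCAL * temperature
  delta_g_ref <- -rt * log(kbc_ref)
  scale <- delta_e_mut / delta_e_ref
  delta_g_mut <- scale * delta_g_ref
  structure(
    list(kbc_ref = kbc_ref, delta_e_ref = delta_e_ref,
         delta_e_mut = delta_e_mut, scale = scale,
         delta_g_ref = delta_g_ref, delta_g_mut = delta_g_mut,
         temperature = temperature,
         kbc_mut = exp(-delta_g_mut / rt)),
    class = "equilibrium_mapping"
  )
}

#' Read an interaction-energy summary table
#'
#' Tab-separated columns `genotype`, `state`, `mean`, `sd`, `n_frames`
#' (energies in kcal/mol). The package ships such a table for the wild-type
#' and S215L blocked/closed states under
#' `system.file("extdata", "interaction_energies.tsv", package = "thinfilament")`.
#'
#' @param path File path.
#' @return A named list of [energy_summary()] objects, names
#'   `"<genotype>.<state>"`.
#' @export
read_energy_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    energy_summary(df$genotype[i], df$state[i], df$mean[i], df$sd[i], df$n_frames[i])
  })
  names(out) <- paste(df$genotype, df$state, sep = ".")
  out
}

#' @rdname map_kbc
#' @param mapping An `equilibrium_mapping`.
#' @param path Output JSON path.
#' @export
write_equilibrium_mapping <- function(mapping, path) {
  jsonlite::write_json(
    c(unclass(mapping),
      list(units = list(energies = "kcal/mol", temperature = "K"))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
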