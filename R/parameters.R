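# Rate and coupling constants of the 24-state regulatory-unit model.

#' Model parameters for the thin-filament regulatory model
#'
#' Rate constants and coupling parameters of the stochastic 24-state
#' regulatory-unit model. Defaults are the wild-type calibration; the
#' mutation acts through `kbc` (blocked-closed equilibrium constant) and
#' `gamma` (effective tropomyosin chain stiffness).
#'
#' @param k_ca_plus Ca2+ association rate onto troponin C, uM^-1 s^-1.
#' @param k_ca_minus Ca2+ dissociation rate, s^-1 (attenuated by `lambda`
#'   while the switch peptide is bound, which keeps the Ca/switch-peptide
#'   thermodynamic cycle consistent).
#' @param k_sp_plus Troponin I switch-peptide binding rate to troponin C,
#'   s^-1 (multiplied by `lambda` when Ca is not bound).
#' @param k_sp_minus Switch-peptide unbinding rate, s^-1 (multiplied by
#'   `lambda` while the inhibitory peptide is released, closing that cycle).
#' @param k_ip_plus Inhibitory-peptide release rate from actin, s^-1
#'   (multiplied by `lambda` when the switch peptide is unbound).
#' @param k_ip_minus Inhibitory-peptide rebinding rate to actin, s^-1.
#' @param k_md_plus,k_md_minus Myosin attachment/detachment rates, s^-1;
#'   their ratio sets the closed-open equilibrium of tropomyosin.
#' @param k_ref_bc Reference rate of the blocked-closed tropomyosin
#'   transition, s^-1.
#' @param kbc Blocked-closed equilibrium constant (dimensionless): 0.76 for
#'   the wild type, 0.97 for S215L via the Gibbs mapping.
#' @param f_xy Reference rate of myosin-coupled tropomyosin transitions,
#'   s^-1.
#' @param delta_split Thermodynamic split factor in `[0, 1]` partitioning a
#'   free-energy change between forward and reverse tropomyosin rates.
#' @param lambda Weak-coupling factor (dimensionless) for troponin-domain
#'   transitions occurring out of their permissive context.
#' @param eta Dimensionless scale of the blocked position's azimuthal
#'   offset below the closed position (the model's angular unit is 2 degrees
#'   per count, so the default places B 18 degrees from C).
#' @param mu Dimensionless scale of the myosin-bound position's azimuthal
#'   offset above the closed position, same unit.
#' @param gamma Effective tropomyosin chain stiffness, kJ mol^-1 rad^-2:
#'   60 for the wild type, 31.6 for S215L.
#' @param n_units Number of regulatory units in series (26).
#' @param temperature Kelvin, used to express chain strain in thermal units.
#' @return An object of class `model_parameters` (named list).
#' @export
model_parameters <- function(k_ca_plus = 350,
                             k_ca_minus = 1000,
                             k_sp_plus = 180,
                             k_sp_minus = 300,
                             k_ip_plus = 620,
                             k_ip_minus = 225,
                             k_md_plus = 550,
                             k_md_minus = 225,
                             k_ref_bc = 675,
                             kbc = 0.76,
                             f_xy = 225,
                             delta_split = 0.48,
                             lambda = 0.008,
                             eta = 9,
                             mu = 9,
                             gamma = 60,
                             n_units = 26L,
                             temperature = 310) {
  p <- list(k_ca_plus = k_ca_plus, k_ca_minus = k_ca_minus,
            k_sp_plus = k_sp_plus, k_sp_minus = k_sp_minus,
            k_ip_plus = k_ip_plus, k_ip_minus = k_ip_minus,
            k_md_plus = k_md_plus, k_md_minus = k_md_minus,
            k_ref_bc = k_ref_bc, kbc = kbc, f_xy = f_xy,
            delta_split = delta_split, lambda = lambda,
            eta = eta, mu = mu, gamma = gamma,
            n_units = as.integer(n_units), temperature = temperature)
  rates <- c("k_ca_plus", "k_ca_minus", "k_sp_plus", "k_sp_minus",
             "k_ip_plus", "k_ip_minus", "k_md_plus", "k_md_minus",
             "k_ref_bc", "f_xy")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0) stopf("`%s` must be >= 0", nm)
  }
  if (p$kbc <= 0) stopf("`kbc` must be > 0")
  if (p$delta_split < 0 || p$delta_split > 1) stopf("`delta_split` must be in [0, 1]")
  if (p$lambda < 0) stopf("`lambda` must be >= 0")
  if (p$gamma < 0) stopf("`gamma` must be >= 0")
  if (p$n_units < 1L) stopf("`n_units` must be >= 1")
  if (p$temperature <= 0) stopf("`temperature` must be > 0 K")
  class(p) <- "model_parameters"
  p
}

#' Parameter presets for the wild-type vs. mutant decomposition
#'
#' Four presets factorizing the mutation's two predicted effects:
#' `"wt"` (kbc 0.76, gamma 60), `"s215l"` (0.97, 31.6), `"gamma_only"`
#' (0.76, 31.6) and `"kbc_only"` (0.97, 60).
#'
#' @param preset Preset name.
#' @param ... Overrides passed on to [model_parameters()].
#' @return A [model_parameters()] object.
#' @export
preset_parameters <- function(preset = c("wt", "s215l", "gamma_only", "kbc_only"),
                              ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    wt         = list(kbc = 0.76, gamma = 60),
    s215l      = list(kbc = 0.97, gamma = 31.6),
    gamma_only = list(kbc = 0.76, gamma = 31.6),
    kbc_only   = list(kbc = 0.97, gamma = 60)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(model_parameters, args)
}
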