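#' Simulate an SPR dataset with known kinetic truth
#'
#' Seeded generator for a binding-kinetics recovery study: a 1:1 Langmuir
#' sensorgram over a serial dilution (default 5-point five-fold from 100
#' nM, injected single-cycle without regeneration) plus the generating
#' truth record. Identical arguments and seed reproduce the dataset
#' byte-for-byte.
#'
#' @param kon,koff,rmax Generating kinetics (1/(nM s), 1/s, RU).
#' @param top_conc Top analyte concentration (nM).
#' @param n_conc Number of concentrations.
#' @param dilution Serial dilution factor.
#' @param mode Assay format; see [simulate_sensorgram()].
#' @param noise_sd Gaussian noise (RU).
#' @param seed Integer seed.
#' @param ... Further arguments to [simulate_sensorgram()].
#' @return List with \code{sensorgram} and \code{truth} (kon, koff, kd,
#'   rmax, t_half).
#' @export
generate_spr_dataset <- function(kon = 1e-3, koff = 5e-3, rmax = 100,
                                 top_conc = 100, n_conc = 5, dilution = 5,
                                 mode = c("single-cycle", "multi-cycle"),
                                 noise_sd = 1, seed = 1L, ...) {
  mode <- match.arg(mode)
  conc <- top_conc / dilution^((n_conc - 1):0)
  sg <- simulate_sensorgram(kon, koff, rmax, conc, noise_sd = noise_sd,
                            seed = seed, mode = mode,
                            dissoc_s = if (mode == "single-cycle") 300 else 120,
                            ...)
  list(sensorgram = sg,
       truth = list(kon = kon, koff = koff, kd = koff / kon, rmax = rmax,
                    t_half = log(2) / koff, conc = conc, noise_sd = noise_sd,
                    seed = seed))
}

#' Simulate cellular degradation data with known truth
#'
#' Seeded generator for dose-response and time-course recovery studies on
#' the percent-of-control scale. The dose response is a 10-point 1:3
#' titration (descending from \code{top_conc}) drawn from a 4PL curve, or,
#' with \code{hook = TRUE}, from the exact ternary equilibrium: degradation
#' is taken proportional to the ternary complex from [hook_curve()], so POC
#' rises again at the highest doses. The time course is a one-phase decay
#' from 100 POC whose fitted curve crosses 50 POC at \code{t_half}.
#'
#' @param dc50 True DC50 (nM); must lie inside the titration for
#'   uncensored scenarios.
#' @param dmax True maximal degradation (percent).
#' @param hill Hill slope of the 4PL truth.
#' @param top_conc,n_doses,dilution Titration design.
#' @param t_half True degradation half-life (min).
#' @param times Time-course sampling times (min).
#' @param noise_sd Gaussian POC noise.
#' @param hook Use the equilibrium hook curve as the dose-response truth.
#' @param eq [eq_params()] for the hook truth (default: matched 100 nM
#'   affinities, cooperativity 10).
#' @param l_total,t_total Totals for the hook truth (nM).
#' @param seed Integer seed.
#' @return List with \code{dose_response} (conc_nM, poc),
#'   \code{time_course} (time_min, poc) and \code{truth}.
#' @export
generate_degradation_dataset <- function(dc50 = 8, dmax = 98, hill = 1,
                                         top_conc = 10000, n_doses = 10,
                                         dilution = 3, t_half = 36.5,
                                         times = seq(0, 240, by = 20),
                                         noise_sd = 3, hook = FALSE,
                                         eq = NULL, l_total = 10,
                                         t_total = 2500, seed = 1L) {
  conc <- top_conc / dilution^(0:(n_doses - 1))
  conc <- sort(conc)
  if (hook) {
    if (is.null(eq)) eq <- eq_params(k_lp = 100, k_tp = 100, alpha = 10)
    lpt <- hook_curve(l_total, t_total, conc, eq)$LPT
    poc_true <- 100 - dmax * lpt / max(lpt)
  } else {
    x <- log10(conc)
    bottom <- 100 - dmax
    poc_true <- bottom + (100 - bottom) / (1 + 10^(hill * (x - log10(dc50))))
  }
  plateau <- 100 - dmax
  k <- log((100 - plateau) / (50 - plateau)) / t_half
  tc_true <- plateau + (100 - plateau) * exp(-k * times)
  noise <- with_seed(seed,
                     stats::rnorm(length(conc) + length(times), sd = noise_sd))
  list(
    dose_response = data.frame(conc_nM = conc,
                               poc = poc_true + noise[seq_along(conc)]),
    time_course = data.frame(time_min = times,
                             poc = tc_true + noise[-seq_along(conc)]),
    truth = list(dc50 = if (hook) NA_real_ else dc50, dmax = dmax,
                 hill = hill, t_half = t_half, k = k,
                 initial_rate = 100 * 0.693 / t_half, hook = hook,
                 noise_sd = noise_sd, seed = seed))
}

#' Toy ternary complex with analytically known surface burial
#'
#' A minimal three-component model built from equal-radius spheres on a
#' line: one ligase atom at the origin, one pseudo-PROTAC atom bridging at
#' \code{spacing}, one target atom at \code{2 * spacing}. With the default
#' geometry only adjacent expanded spheres overlap, so every buried area
#' follows the spherical-cap closed form: each adjacent pair buries
#' \code{2 * 2 pi R h} with \code{R = radius + probe} and
#' \code{h = R - spacing/2}, the two proteins are mutually disjoint (zero
#' protein-protein burial), and the total burial is protein-PROTAC only.
#' The analytic values are attached as \code{truth}.
#'
#' @param radius Atom van der Waals radius (Angstrom).
#' @param spacing Adjacent-atom distance (Angstrom); the defaults keep
#'   non-adjacent atoms disjoint at probe 1.4.
#' @param probe Probe radius used for the analytic truth.
#' @param jitter_sd Seeded Gaussian coordinate jitter (Angstrom); the
#'   analytic truth applies only at 0.
#' @param seed Integer seed for the jitter.
#' @return List with \code{model} ([structure_model()]) and \code{truth}
#'   (list with \code{bsa_total}, \code{bsa_protein_protein},
#'   \code{bsa_protein_protac}, \code{sasa_complex}, \code{sasa_single}).
#' @export
generate_toy_complex <- function(radius = 1.6, spacing = 4.0, probe = 1.4,
                                 jitter_sd = 0, seed = 1L) {
  r_ext <- radius + probe
  if (spacing >= 2 * r_ext)
    warning("adjacent spheres do not overlap: burial truth is 0")
  if (2 * spacing < 2 * r_ext)
    warning("non-adjacent spheres overlap: cap-formula truth invalid")
  xyz <- cbind(x = c(0, spacing, 2 * spacing), y = 0, z = 0)
  if (jitter_sd > 0)
    xyz <- xyz + with_seed(seed, matrix(stats::rnorm(9, sd = jitter_sd), 3L))
  model <- structure_model(element = rep("C", 3L),
                           x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                           component = c("ligase", "protac", "target"),
                           radius = rep(radius, 3L))
  h <- max(0, r_ext - spacing / 2)
  pair_burial <- 2 * 2 * pi * r_ext * h
  sphere <- 4 * pi * r_ext^2
  truth <- list(
    sasa_single = sphere,
    sasa_complex = 3 * sphere - 2 * pair_burial,
    bsa_total = 2 * pair_burial,
    bsa_protein_protein = 0,
    bsa_protein_protac = 2 * pair_burial,
    exact = jitter_sd == 0)
  list(model = model, truth = truth)
}
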