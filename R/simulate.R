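# Synthetic fluorometer: seeded generators for every input the analysis
# consumes, each with attached ground truth. The emission model is purely
# linear mixing -- intensity = F_Don * donor_shape + F_Acc * acceptor_shape
# with F_Acc = F_AccFRET + F_AccDirect -- plus additive i.i.d. Gaussian noise
# per wavelength (the simplest model consistent with PMT readout at fixed
# voltage).

#' Simulation configuration for the synthetic fluorometer
#'
#' @param seed integer seed driving all randomness.
#' @param noise_sd additive Gaussian intensity noise SD (a.u.), >= 0.
#' @param wavelength_nm emission grid (nm).
#' @param excitation_list excitation wavelengths (nm); the end-point protocol
#'   default is the nine-wavelength series 433 down to 400 nm.
#' @param donor_amplitude total donor-channel scale (a.u.) at the peak of the
#'   donor excitation-efficiency curve.
#' @param direct_max_amount directly-excited acceptor amplitude (a.u.) under
#'   515 nm excitation; scaled to other excitations by the acceptor
#'   direct-excitation profile.
#' @param f_r_apo absolute FRET ratio of the apo (cation-free) sensor; the
#'   additive site model operates in signal-change space, so this offset
#'   anchors condition-level ratios at the sensor's resting FRET (default
#'   0.25, the scale observed for the CFP--TnC--YFP sensor with no divalent
#'   cations bound). It cancels from every end-point difference.
#' @param mode `"hill"` (titration responses from an explicit Hill-type
#'   parameter set) or `"site-additive"` (responses from per-site occupancy
#'   times per-site contributions). Exactly one of `model_params` /
#'   `site_params` must be supplied, matching `mode`.
#' @param model_params for `mode = "hill"`: a named list of parameters for
#'   [hill_force_curve()], [hill_curve()] or [double_hill_curve()].
#' @param site_params for `mode = "site-additive"`: a list with a
#'   [site_contributions] object (`contributions`) and per-site affinities
#'   (`p50`, named) and Hill slopes (`n`, named, default 1).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, noise_sd = 0,
                              wavelength_nm = seq(445, 610, by = 1),
                              excitation_list = c(433, 424, 420, 418, 414,
                                                  410, 408, 404, 400),
                              donor_amplitude = 100,
                              direct_max_amount = 20,
                              f_r_apo = 0.25,
                              mode = c("hill", "site-additive"),
                              model_params = NULL, site_params = NULL) {
  mode <- match.arg(mode)
  stopifnot(noise_sd >= 0, length(excitation_list) >= 1,
            all(diff(wavelength_nm) > 0), donor_amplitude > 0)
  if (mode == "hill" && !is.null(site_params))
    stop("mode 'hill' takes model_params; site_params must be absent")
  if (mode == "site-additive" && !is.null(model_params))
    stop("mode 'site-additive' takes site_params; model_params must be absent")
  structure(list(seed = seed, noise_sd = noise_sd,
                 wavelength_nm = wavelength_nm,
                 excitation_list = excitation_list,
                 donor_amplitude = donor_amplitude,
                 direct_max_amount = direct_max_amount,
                 f_r_apo = f_r_apo,
                 mode = mode, model_params = model_params,
                 site_params = site_params),
            class = "simulation_config")
}

#' Simulate one emission scan of the two-fluorophore sensor
#'
#' Generates `donor_amplitude * donor_shape + (f_r * donor_amplitude +
#' acceptor_direct_amount) * acceptor_shape` plus Gaussian noise. The
#' generating amplitudes (`f_don`, `f_acc_fret`, `f_acc_direct`, `f_r`) are
#' attached as `$truth` for testing.
#'
#' @param f_r true FRET ratio (dimensionless, >= 0).
#' @param donor_amplitude donor amplitude at this excitation (a.u., > 0).
#' @param excitation_nm excitation wavelength (nm).
#' @param refs a [make_reference_spectra()] object.
#' @param acceptor_direct_amount directly-excited acceptor amplitude at this
#'   excitation (a.u.).
#' @param noise_sd Gaussian intensity noise SD (a.u.).
#' @param seed optional seed (local to this call).
#' @param condition,construct_id labels carried on the scan.
#' @return A [new_spectrum()] object.
#' @export
simulate_spectrum <- function(f_r, donor_amplitude, excitation_nm, refs,
                              acceptor_direct_amount = 0, noise_sd = 0,
                              seed = NULL, condition = NA_character_,
                              construct_id = NA_character_) {
  stopifnot(inherits(refs, "reference_spectra"),
            donor_amplitude > 0, f_r >= 0, acceptor_direct_amount >= 0,
            noise_sd >= 0)
  refs$acceptor_direct_profile(excitation_nm)  # domain check
  f_acc_fret <- f_r * donor_amplitude
  f_acc <- f_acc_fret + acceptor_direct_amount
  intensity <- donor_amplitude * refs$donor + f_acc * refs$acceptor
  if (noise_sd > 0)
    intensity <- intensity +
      with_seed(seed, stats::rnorm(length(intensity), sd = noise_sd))
  new_spectrum(refs$wavelength_nm, intensity, excitation_nm,
               condition = condition, construct_id = construct_id,
               truth = list(f_don = donor_amplitude, f_acc = f_acc,
                            f_acc_fret = f_acc_fret,
                            f_acc_direct = acceptor_direct_amount,
                            f_r = f_r))
}

#' Simulate an acceptor-only control scan
#'
#' The control construct carries only the acceptor, so its emission is the
#' acceptor shape scaled by the direct-excitation amount at 515 nm times the
#' direct-excitation profile at the requested excitation.
#'
#' @inheritParams simulate_spectrum
#' @param amount_at_direct_max directly-excited acceptor amplitude (a.u.)
#'   under 515 nm excitation, > 0.
#' @return A [new_spectrum()] object (condition `"acceptor-only"`).
#' @export
simulate_acceptor_only <- function(excitation_nm, amount_at_direct_max, refs,
                                   noise_sd = 0, seed = NULL,
                                   construct_id = "acceptor-only") {
  stopifnot(amount_at_direct_max > 0)
  amount <- amount_at_direct_max * refs$acceptor_direct_profile(excitation_nm)
  intensity <- amount * refs$acceptor
  if (noise_sd > 0)
    intensity <- intensity +
      with_seed(seed, stats::rnorm(length(intensity), sd = noise_sd))
  new_spectrum(refs$wavelength_nm, intensity, excitation_nm,
               condition = "acceptor-only", construct_id = construct_id,
               truth = list(f_don = 0, f_acc = amount, f_acc_fret = 0,
                            f_acc_direct = amount, f_r = 0))
}

endpoint_conditions <- c("chelated", "saturated", "rechelated")

# Sites occupied in each condition of the 3-step end-point protocol, and the
# ion whose contributions apply. Conditions 1 and 3 are constructed equal
# (reversibility is built into the generative model).
endpoint_occupancy <- function(active_sites, ion_protocol) {
  cdom <- intersect(active_sites, c("III", "IV"))
  switch(ion_protocol,
    "Ca-in-EDTA" = list(
      chelated   = list(ion = "Ca", sites = character(0)),
      saturated  = list(ion = "Ca", sites = active_sites),
      rechelated = list(ion = "Ca", sites = character(0))),
    "Mg-in-EDTA" = list(
      chelated   = list(ion = "Mg", sites = character(0)),
      saturated  = list(ion = "Mg", sites = cdom),
      rechelated = list(ion = "Mg", sites = character(0))),
    "Ca-in-Mg/EGTA" = list(
      chelated   = list(ion = "Mg", sites = cdom),
      saturated  = list(ion = "Ca", sites = active_sites),
      rechelated = list(ion = "Mg", sites = cdom)),
    stop("unknown ion_protocol: ", ion_protocol))
}

#' Simulate a complete end-point titration experiment
#'
#' Generates the 3-condition protocol (chelated, then saturating cation, then
#' re-chelated) for one construct: sample scans at every excitation
#' wavelength, a 515 nm-excitation sample scan per condition (used to
#' normalise the direct-excitation correction), and acceptor-only control
#' scans at every excitation wavelength plus 515 nm. The condition-level true
#' \eqn{F_R} follows the additive site model: baseline plus the sum of the
#' contributions of the sites occupied in that condition. Conditions 1 and 3
#' share the same truth, so reversibility holds by construction.
#'
#' @param construct a row of [ctv_constructs()] (or any list with
#'   `construct_id` and `active_sites`).
#' @param contributions a [site_contributions] object for the protocol's ion;
#'   for `"Ca-in-Mg/EGTA"` a list with elements `Ca` and `Mg`.
#' @param ion_protocol `"Ca-in-EDTA"`, `"Mg-in-EDTA"` or `"Ca-in-Mg/EGTA"`.
#' @param config a [simulation_config()].
#' @return An object of class `endpoint_dataset`: `spectra` (list over
#'   conditions x excitations), `sample_at_direct_max` (per condition),
#'   `controls` (acceptor-only, per excitation incl. 515 nm), and `truth`
#'   (per-condition true \eqn{F_R} and the implied `delta_fr`).
#' @export
simulate_endpoint_experiment <- function(construct, contributions,
                                         ion_protocol = c("Ca-in-EDTA",
                                                          "Ca-in-Mg/EGTA",
                                                          "Mg-in-EDTA"),
                                         config = simulation_config()) {
  ion_protocol <- match.arg(ion_protocol)
  active <- if (is.data.frame(construct)) construct$active_sites[[1]]
            else construct$active_sites
  construct_id <- if (is.data.frame(construct)) construct$construct_id[1]
                  else construct$construct_id

  contrib_for <- function(ion) {
    x <- if (inherits(contributions, "site_contributions")) contributions
         else contributions[[ion]]
    if (is.null(x) || !inherits(x, "site_contributions") || x$ion != ion)
      stop("protocol '", ion_protocol, "' needs ", ion,
           " contributions; none supplied")
    x
  }

  occ <- endpoint_occupancy(active, ion_protocol)
  true_fr <- vapply(occ, function(o) {
    ct <- contrib_for(o$ion)
    sites <- intersect(o$sites, names(ct$contributions))
    config$f_r_apo + ct$baseline + sum(ct$contributions[sites])
  }, numeric(1))
  if (any(true_fr < 0))
    stop("additive model yields negative true F_R for construct ",
         construct_id, "; raise f_r_apo or adjust contributions")

  refs <- make_reference_spectra(wavelength_nm = config$wavelength_nm)
  eff <- refs$donor_excitation_efficiency(config$excitation_list)
  prof <- refs$acceptor_direct_profile(config$excitation_list)

  rng_master <- as.integer(config$seed)
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    (rng_master * 1000L + k) %% .Machine$integer.max
  }

  spectra <- list()
  sample_at_max <- list()
  for (cond in endpoint_conditions) {
    for (i in seq_along(config$excitation_list)) {
      ex <- config$excitation_list[i]
      sp <- simulate_spectrum(
        f_r = true_fr[[cond]],
        donor_amplitude = config$donor_amplitude * eff[i],
        excitation_nm = ex, refs = refs,
        acceptor_direct_amount = config$direct_max_amount * prof[i],
        noise_sd = config$noise_sd, seed = next_seed(),
        condition = cond, construct_id = construct_id)
      spectra[[paste(cond, ex, sep = "_")]] <- sp
    }
    # 515 nm excitation: donor efficiency is exactly 0 there, so the scan is
    # purely directly-excited acceptor -- simulate as an acceptor-only scan
    # of the sample itself.
    sm <- simulate_acceptor_only(refs$direct_peak_nm,
                                 config$direct_max_amount, refs,
                                 noise_sd = config$noise_sd,
                                 seed = next_seed(),
                                 construct_id = construct_id)
    sm$condition <- cond
    sample_at_max[[cond]] <- sm
  }

  ctrl_ex <- c(config$excitation_list, refs$direct_peak_nm)
  controls <- lapply(ctrl_ex, function(ex)
    simulate_acceptor_only(ex, config$direct_max_amount, refs,
                           noise_sd = config$noise_sd, seed = next_seed()))
  names(controls) <- as.character(ctrl_ex)

  structure(list(
    spectra = spectra, sample_at_direct_max = sample_at_max,
    controls = controls, refs = refs,
    construct_id = construct_id, ion_protocol = ion_protocol,
    excitation_list = config$excitation_list,
    truth = list(f_r = true_fr,
                 delta_fr = unname(true_fr["saturated"] -
                   0.5 * (true_fr["chelated"] + true_fr["rechelated"])))
  ), class = "endpoint_dataset")
}

site_additive_response <- function(pX, site_params) {
  ct <- site_params$contributions
  stopifnot(inherits(ct, "site_contributions"))
  p50 <- site_params$p50
  n <- site_params$n
  if (is.null(n)) n <- stats::setNames(rep(1, length(p50)), names(p50))
  if (!all(names(ct$contributions) %in% names(p50)))
    stop("site-additive mode needs a p50 for every contributing site")
  occ <- vapply(names(ct$contributions), function(s)
    1 / (1 + 10^(n[[s]] * (pX - p50[[s]]))), numeric(length(pX)))
  ct$baseline + as.numeric(occ %*% ct$contributions)
}

titration_truth_curve <- function(config, pX) {
  if (config$mode == "site-additive")
    return(site_additive_response(pX, config$site_params))
  p <- config$model_params
  req <- function(nm) {
    if (is.null(p[[nm]]))
      stop("hill mode: missing model parameter '", nm, "'")
    p[[nm]]
  }
  if (!is.null(p$model) && p$model == "force")
    hill_force_curve(pX, req("p50"), req("n"))
  else if (!is.null(p$f_max2) || identical(p$model, "double"))
    double_hill_curve(pX, req("f_min"), req("f_max1"), req("n1"),
                      req("p50_1"), req("f_max2"), req("n2"), req("p50_2"))
  else
    hill_curve(pX, req("f_min"), req("f_max"), req("n"), req("p50"))
}

#' Simulate a full-range titration series
#'
#' Evaluates the configured response model (an explicit Hill-type curve, or
#' the additive per-site occupancy model) on a pX grid and adds i.i.d.
#' Gaussian noise per observation; generating parameters are attached as
#' `$truth`.
#'
#' @param config a [simulation_config()]; `mode`, `model_params`/
#'   `site_params`, `noise_sd` and `seed` are used.
#' @param pX_grid free-ion \eqn{-\log_{10}} concentrations at which responses
#'   are observed.
#' @param replicates number of replicate observations per pX (>= 1).
#' @param ion,response_kind,construct_id labels carried on the series.
#' @return An object of class `titration_series`: a data frame
#'   (`pX`, `response`, `replicate`) with attributes `ion`, `response_kind`,
#'   `construct_id` and `truth`.
#' @export
simulate_titration <- function(config, pX_grid, replicates = 1,
                               ion = "Ca", response_kind = "fret_ratio",
                               construct_id = "CTV-TnC WT") {
  stopifnot(replicates >= 1, all(is.finite(pX_grid)))
  mu <- titration_truth_curve(config, pX_grid)
  df <- data.frame(pX = rep(pX_grid, times = replicates),
                   response = rep(mu, times = replicates),
                   replicate = rep(seq_len(replicates), each = length(pX_grid)))
  if (config$noise_sd > 0)
    df$response <- df$response +
      with_seed(config$seed, stats::rnorm(nrow(df), sd = config$noise_sd))
  titration_series(df, ion = ion, response_kind = response_kind,
                   construct_id = construct_id,
                   truth = list(mode = config$mode,
                                model_params = config$model_params,
                                site_params = config$site_params,
                                noise_sd = config$noise_sd))
}

#' Titration series container
#'
#' @param data data frame with columns `pX`, `response` and optionally
#'   `replicate`.
#' @param ion `"Ca"` or `"Mg"`.
#' @param response_kind `"fret_ratio"` or `"normalized_force"`.
#' @param construct_id label.
#' @param truth optional generator ground truth.
#' @return The data frame with class `titration_series` and metadata
#'   attributes.
#' @export
titration_series <- function(data, ion = c("Ca", "Mg"),
                             response_kind = c("fret_ratio",
                                               "normalized_force"),
                             construct_id = NA_character_, truth = NULL) {
  ion <- match.arg(ion)
  response_kind <- match.arg(response_kind)
  stopifnot(is.data.frame(data), all(c("pX", "response") %in% names(data)),
            all(is.finite(data$pX)), all(is.finite(data$response)))
  if (is.null(data$replicate)) data$replicate <- 1L
  structure(data, ion = ion, response_kind = response_kind,
            construct_id = construct_id, truth = truth,
            class = c("titration_series", "data.frame"))
}

#' Simulate a sedimentation-coefficient distribution
#'
#' Sum of Gaussian peaks
#' \eqn{f(x) = \sum A_0 \exp(-0.5((x - s)/\delta)^2)} evaluated on an s grid,
#' plus optional Gaussian noise.
#'
#' @param peaks data frame (or list of lists) with columns/fields `a0`,
#'   `mean` (Svedberg) and `delta` (Svedberg, > 0); may have zero rows.
#' @param s_grid sedimentation-coefficient grid (S).
#' @param noise_sd Gaussian noise SD on the relative frequency.
#' @param seed optional seed.
#' @return A data frame with columns `s` and `frequency`.
#' @export
simulate_auc_distribution <- function(peaks, s_grid, noise_sd = 0,
                                      seed = NULL) {
  if (!is.data.frame(peaks))
    peaks <- do.call(rbind, lapply(peaks, as.data.frame))
  if (is.null(peaks) || nrow(peaks) == 0) {
    freq <- numeric(length(s_grid))
  } else {
    stopifnot(all(c("a0", "mean", "delta") %in% names(peaks)))
    if (any(peaks$delta <= 0)) stop("Gaussian peak width delta must be > 0")
    if (any(peaks$mean < min(s_grid) | peaks$mean > max(s_grid)))
      stop("peak means must lie inside the s grid")
    freq <- rowSums(vapply(seq_len(nrow(peaks)), function(i)
      peaks$a0[i] * exp(-0.5 * ((s_grid - peaks$mean[i]) / peaks$delta[i])^2),
      numeric(length(s_grid))))
  }
  if (noise_sd > 0)
    freq <- freq + with_seed(seed, stats::rnorm(length(freq), sd = noise_sd))
  data.frame(s = s_grid, frequency = freq)
}
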