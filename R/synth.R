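# Seedable synthetic-spectrum generator with a ground-truth ledger.
#
# Construction guarantees the PULCON relation: every signal's area, as
# integrated by the quantification convention (Riemann sum over the
# assigned region's included-minus-excluded grid points), equals
# response * C * n_protons / MW with one proportionality constant
# (`response`, the simulated ERETIC factor) shared by all components. The
# generator therefore defines each analyte operationally by its integration
# window, exactly as the sum-parameter method does.

#' Synthetic component
#'
#' Ground-truth ingredient of a simulated spectrum: a set of signals
#' (Lorentzian/Gaussian lines or broad humps) with proton counts, plus the
#' molecular weight and concentration that fix the target areas.
#'
#' `signals` is a data frame with columns `center` (ppm), `n_protons`
#' (fractional values allowed, e.g. multiplet lines), `shape`
#' (`"lorentzian"`, `"gaussian"` or `"hump"`), `width` (HWHM in ppm for
#' lines; ignored for humps) and optionally `norm_region` (name of the
#' integration region whose mask defines this signal's area). Hump signals
#' draw `hump_lines` Lorentzian sub-lines with HWHM in `hump_width_range`
#' and positions from the weighted sub-regions in `hump_profile`
#' (data frame with columns `lo`, `hi`, `weight`).
#'
#' @param name Component name.
#' @param signals Signal data frame (see Details).
#' @param mw Molecular weight (g/mol).
#' @param concentration Concentration in g/L.
#' @param hump_profile,hump_lines,hump_width_range Hump morphology controls.
#' @return An object of class `synthetic_component`.
#' @export
synthetic_component <- function(name, signals, mw, concentration,
                                hump_profile = NULL, hump_lines = 60L,
                                hump_width_range = c(0.02, 0.2)) {
  stopifnot(is.data.frame(signals), all(c("center", "n_protons", "shape",
                                          "width") %in% names(signals)))
  if (!"norm_region" %in% names(signals)) signals$norm_region <- NA_character_
  if (any(signals$width <= 0 & signals$shape != "hump"))
    stop("signal widths must be > 0", call. = FALSE)
  if (!is.numeric(mw) || mw <= 0) stop("mw must be > 0", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  structure(list(name = name, signals = signals, mw = mw,
                 concentration = concentration,
                 hump_profile = hump_profile,
                 hump_lines = as.integer(hump_lines),
                 hump_width_range = hump_width_range),
            class = "synthetic_component")
}

#' Expand a binomial multiplet into signal rows
#'
#' Builds `npeaks` Lorentzian lines around `center`, spaced by the coupling
#' constant and weighted 1:(n-1) binomially, carrying fractional proton
#' counts that sum to `n_protons`.
#'
#' @param center Multiplet center (ppm).
#' @param n_protons Total protons of the multiplet.
#' @param npeaks Number of lines (2 = doublet, 3 = triplet, ...).
#' @param j_hz Coupling constant in Hz (default 7.6).
#' @param sfo Spectrometer frequency in MHz (default 400.13).
#' @param width Line HWHM in ppm.
#' @param norm_region Region name for area normalization.
#' @return Signal data frame for [synthetic_component()].
#' @export
multiplet_rows <- function(center, n_protons, npeaks, j_hz = 7.6,
                           sfo = 400.13, width = 0.0015,
                           norm_region = NA_character_) {
  k <- 0:(npeaks - 1)
  wts <- choose(npeaks - 1, k)
  wts <- wts / sum(wts)
  data.frame(center = center + (k - (npeaks - 1) / 2) * j_hz / sfo,
             n_protons = n_protons * wts,
             shape = "lorentzian", width = width,
             norm_region = norm_region)
}

#' Simulation recipe
#'
#' Complete description of a synthetic measurement: components, solvent
#' artifacts, receiver noise, grid, seed and sample preparation.
#'
#' Solvent artifacts (areas in intensity x ppm units, scaled by `response`):
#' residual CHCl3 at 7.26 ppm with 13C satellites at +/- 0.261 ppm (the
#' one-bond 1H-13C coupling of 209 Hz at 400 MHz; 0.55 % of the parent area
#' each, natural abundance), residual water at 1.53 ppm, and TMS at 0.00 ppm.
#'
#' @param components List of [synthetic_component()]s.
#' @param prep A [sample_prep()] (default 50 mg in 1.5 mL).
#' @param noise_sd Additive white-noise SD in intensity units, or
#'   `"calibrated"` for [calibrated_noise_sd()].
#' @param grid `c(ppm_min, ppm_max, points)`; default 12 to -2 ppm with
#'   131072 points (the real-spectrum size of the emulated acquisition).
#' @param seed Integer RNG seed (`NULL` uses the current RNG state).
#' @param response Simulated ERETIC factor (proportionality between
#'   concentration per proton and area), default 1.
#' @param chcl3_area,water_area,tms_area Solvent artifact areas relative to
#'   `response`; set to 0 to disable.
#' @param c13_satellites Logical, add CHCl3 13C satellites.
#' @param line_support Rendered lines are clipped to
#'   `max(line_support, 10 * HWHM)` ppm around their center and renormalized,
#'   so distant windows are independent by construction (real Lorentzian
#'   tails extend much further; see the methods vignette). Default 0.25.
#' @param series_id,sample_id Identifiers.
#' @return An object of class `simulation_recipe`.
#' @export
simulation_recipe <- function(components, prep = sample_prep(50, 1.5),
                              noise_sd = 0,
                              grid = c(-2, 12, 131072),
                              seed = NULL, response = 1,
                              chcl3_area = 0.01, water_area = 0.005,
                              tms_area = 0.01, c13_satellites = TRUE,
                              line_support = 0.25,
                              series_id = NA_character_,
                              sample_id = NA_character_) {
  stopifnot(is.list(components))
  if (identical(noise_sd, "calibrated")) noise_sd <- calibrated_noise_sd(response)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (grid[2] <= grid[1] || grid[3] < 16)
    stop("grid must be c(ppm_min, ppm_max, points) with ppm_max > ppm_min",
         call. = FALSE)
  structure(list(components = components, prep = prep, noise_sd = noise_sd,
                 grid = grid, seed = seed, response = response,
                 chcl3_area = chcl3_area, water_area = water_area,
                 tms_area = tms_area, c13_satellites = c13_satellites,
                 line_support = line_support,
                 series_id = series_id, sample_id = sample_id),
            class = "simulation_recipe")
}

#' Calibrated receiver-noise preset
#'
#' Noise SD chosen so that the chrysene limit of detection of a standard
#' measurement (50 mg sample in 1.5 mL, 3x-noise-SD height criterion with a
#' 0.002 ppm reference line) equals 0.05 g/100 g, consistent with the
#' emulated instrument's reported sub-0.1 g/100 g detection limits. Inverts
#' the LOD formula of [estimate_lod()].
#'
#' @param response Simulated ERETIC factor of the series.
#' @param lod_target Target chrysene LOD in g/100 g (default 0.05).
#' @param prep Assumed [sample_prep()] (default 50 mg / 1.5 mL).
#' @param ref_hwhm Reference line HWHM in ppm (default 0.002).
#' @return Noise SD in intensity units.
#' @export
calibrated_noise_sd <- function(response = 1, lod_target = 0.05,
                                prep = sample_prep(50, 1.5),
                                ref_hwhm = 0.002) {
  mw <- 228.29; n <- 2   # chrysene window constants
  c_lod <- lod_target * prep$sample_mass / (100 * prep$solution_volume)
  i_lod <- c_lod * response * n / mw
  i_lod / (3 * pi * ref_hwhm)
}

# Unit-area lineshapes on the ppm grid.
lorentz_density <- function(ppm, center, hwhm)
  (hwhm / pi) / ((ppm - center)^2 + hwhm^2)
gauss_density <- function(ppm, center, hwhm) {
  s <- hwhm / sqrt(2 * log(2))
  exp(-(ppm - center)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
}

# Scale a rendered shape so its Riemann sum over `mask` equals `area`.
normalize_to_mask <- function(dens, mask, step, area) {
  got <- sum(dens[mask]) * step
  if (got <= 0) stop("signal has no area inside its normalization region",
                     call. = FALSE)
  dens * (area / got)
}

#' Simulate a 1D spectrum from a recipe
#'
#' Renders every component signal on the grid with its area fixed by the
#' PULCON construction (see [synthetic_component()]), adds solvent artifacts
#' and seeded white noise, and attaches a ground-truth ledger (attribute
#' `ground_truth`: per-component concentration in g/L and mass fraction in
#' g/100 g). Identical recipes with the same seed produce bitwise-identical
#' spectra.
#'
#' @param recipe A [simulation_recipe()].
#' @param regions Region scheme used for signal-area normalization.
#' @return A [spectrum1d()] with attribute `ground_truth`.
#' @export
simulate_spectrum <- function(recipe, regions = default_regions()) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  if (!is.null(recipe$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(recipe$seed)
  }
  npts <- recipe$grid[3]
  ppm <- seq(recipe$grid[2], recipe$grid[1], length.out = npts)  # descending
  step <- abs(ppm[2] - ppm[1])
  y <- numeric(npts)
  # fake spectrum object for region masks during normalization
  region_mask_on_axis <- function(region) {
    m <- rep(FALSE, npts)
    for (w in region$windows) m <- m | (ppm > w[2] & ppm <= w[1])
    for (e in region$exclusions) m <- m & !(ppm > e[2] & ppm <= e[1])
    m
  }
  K <- recipe$response
  # compact-support line: unit-area density clipped around its center so
  # distant integration windows stay independent by construction
  clipped_line <- function(shape_fun, center, hwhm, support = NULL) {
    d <- shape_fun(ppm, center, hwhm)
    d[abs(ppm - center) > (support %||% max(recipe$line_support, 10 * hwhm))] <- 0
    d
  }
  for (comp in recipe$components) {
    if (comp$concentration == 0) next
    sig <- comp$signals
    for (i in seq_len(nrow(sig))) {
      target <- K * comp$concentration * sig$n_protons[i] / comp$mw
      shape <- sig$shape[i]
      if (shape == "hump") {
        prof <- comp$hump_profile
        if (is.null(prof)) stop("hump signal requires a hump_profile", call. = FALSE)
        nl <- comp$hump_lines
        bin <- sample.int(nrow(prof), nl, replace = TRUE, prob = prof$weight)
        centers <- stats::runif(nl, prof$lo[bin], prof$hi[bin])
        widths <- stats::runif(nl, comp$hump_width_range[1], comp$hump_width_range[2])
        areas <- stats::rgamma(nl, shape = 2)
        areas <- areas / sum(areas)
        # hump sub-lines are truncated at twice their width: far Lorentzian
        # tails of broad lines would otherwise smear ambiguous "baseline-like"
        # intensity across the whole axis, which no baseline estimator (or
        # manual integrator) could separate from the baseline proper
        dens <- numeric(npts)
        for (j in seq_len(nl))
          dens <- dens + areas[j] * clipped_line(lorentz_density, centers[j],
                                                widths[j],
                                                support = max(0.1, 2 * widths[j]))
      } else {
        ctr <- sig$center[i]
        if (ctr > max(ppm) || ctr < min(ppm))
          stop(sprintf("signal at %.3f ppm outside grid [%g, %g]",
                       ctr, min(ppm), max(ppm)), call. = FALSE)
        dens <- switch(shape,
                       lorentzian = clipped_line(lorentz_density, ctr, sig$width[i]),
                       gaussian = clipped_line(gauss_density, ctr, sig$width[i]),
                       stop("unknown lineshape: ", shape, call. = FALSE))
      }
      nr <- sig$norm_region[i]
      mask <- if (!is.na(nr) && nr %in% names(regions))
        region_mask_on_axis(regions[[nr]]) else rep(TRUE, npts)
      # narrow lines bound to a region are confined to it entirely, so the
      # window captures the whole signal by construction; humps keep their
      # natural extent (their truth is defined by the in-window area)
      if (shape != "hump") dens[!mask] <- 0
      y <- y + normalize_to_mask(dens, mask, step, target)
    }
  }
  # solvent artifacts (areas relative to the response constant)
  if (recipe$tms_area > 0)
    y <- y + normalize_to_mask(clipped_line(lorentz_density, 0.0, 0.0012),
                               rep(TRUE, npts), step, K * recipe$tms_area)
  if (recipe$chcl3_area > 0) {
    a <- K * recipe$chcl3_area
    y <- y + normalize_to_mask(clipped_line(lorentz_density, 7.26, 0.0008),
                               rep(TRUE, npts), step, a)
    if (recipe$c13_satellites) {
      off <- 209 / (2 * 400.13)   # one-bond 1H-13C coupling, ppm at 400 MHz
      for (s in c(-1, 1))
        y <- y + normalize_to_mask(clipped_line(lorentz_density, 7.26 + s * off, 0.0008),
                                   rep(TRUE, npts), step, 0.0055 * a)
    }
  }
  if (recipe$water_area > 0)
    y <- y + normalize_to_mask(clipped_line(lorentz_density, 1.53, 0.004),
                               rep(TRUE, npts), step, K * recipe$water_area)
  if (recipe$noise_sd > 0)
    y <- y + stats::rnorm(npts, 0, recipe$noise_sd)

  spec <- spectrum1d(ppm, y, spectrometer_freq = 400.13, scans = 32L,
                     receiver_gain = 1, prep = recipe$prep,
                     series_id = recipe$series_id, sample_id = recipe$sample_id,
                     processing_log = sprintf("simulate_spectrum(seed=%s, noise_sd=%g)",
                                              recipe$seed %||% "NULL",
                                              recipe$noise_sd))
  gt <- do.call(rbind, lapply(recipe$components, function(comp) {
    data.frame(component = comp$name, mw = comp$mw,
               conc_g_l = comp$concentration,
               mass_fraction = comp$concentration *
                 recipe$prep$solution_volume / recipe$prep$sample_mass * 100,
               n_protons = sum(comp$signals$n_protons))
  }))
  attr(spec, "ground_truth") <- gt
  attr(spec, "response") <- K
  spec
}

#' Simulate a quantification reference (quantref) spectrum
#'
#' Tetrachloronitrobenzene (singlet in 7.83-7.64 ppm, N=1) and ethylbenzene
#' (aromatic multiplet 7.23-7.11 N=3, quartet 2.75-2.54 N=2, triplet
#' 1.35-1.13 N=3) at 5.0 g/L each, i.e. 50 mg of each compound in 10 mL.
#'
#' @param seed Integer seed.
#' @param noise_sd Noise SD or `"calibrated"`.
#' @param tcnb_conc,eb_conc Concentrations in g/L.
#' @param ... Passed to [simulation_recipe()].
#' @return A [spectrum1d()] with ground-truth ledger.
#' @export
simulate_quantref <- function(seed = NULL, noise_sd = 0,
                              tcnb_conc = 5.0, eb_conc = 5.0, ...) {
  tcnb <- synthetic_component(
    "tetrachloronitrobenzene",
    data.frame(center = 7.735, n_protons = 1, shape = "lorentzian",
               width = 0.002, norm_region = "quantref_tcnb"),
    mw = 260.89, concentration = tcnb_conc)
  eb <- synthetic_component(
    "ethylbenzene",
    rbind(
      do.call(rbind, lapply(c(7.15, 7.17, 7.21), function(ctr)
        data.frame(center = ctr, n_protons = 1, shape = "lorentzian",
                   width = 0.0015, norm_region = "quantref_eb_m"))),
      multiplet_rows(2.645, 2, npeaks = 4, norm_region = "quantref_eb_q"),
      multiplet_rows(1.24, 3, npeaks = 3, norm_region = "quantref_eb_t")),
    mw = 106.17, concentration = eb_conc)
  # idealized clean solvent: the calibration windows must carry nothing but
  # the reference signals, so the four per-signal factors agree by construction
  recipe <- simulation_recipe(list(tcnb, eb), prep = sample_prep(100, 10),
                              noise_sd = noise_sd, seed = seed,
                              water_area = 0, chcl3_area = 0,
                              sample_id = "quantref", ...)
  simulate_spectrum(recipe)
}

#' Simulate the cyclohexane control solution
#'
#' Cyclohexane singlet (1.53-1.36 ppm window, N = 12) at the nominal control
#' concentration, in clean CDCl3 (no residual-water artifact).
#'
#' @param seed Integer seed.
#' @param conc_mg_l Concentration in mg/L (default 2500).
#' @param noise_sd Noise SD or `"calibrated"`.
#' @param ... Passed to [simulation_recipe()].
#' @return A [spectrum1d()] with ground-truth ledger.
#' @export
simulate_control <- function(seed = NULL, conc_mg_l = 2500, noise_sd = 0, ...) {
  cyclohexane <- synthetic_component(
    "cyclohexane",
    data.frame(center = 1.43, n_protons = 12, shape = "lorentzian",
               width = 0.002, norm_region = "control_cyclohexane"),
    mw = 84.16, concentration = conc_mg_l / 1000)
  recipe <- simulation_recipe(list(cyclohexane), prep = sample_prep(50, 1.5),
                              noise_sd = noise_sd, seed = seed,
                              water_area = 0, sample_id = "control", ...)
  simulate_spectrum(recipe)
}

# PAH4 signal tables: the quantified multiplet sits inside its integration
# window (norm_region); remaining aromatic protons land elsewhere in the
# aromatic region, as in real spectra.
.pah4_components <- function() list(
  chrysene = function(conc) synthetic_component("chrysene", data.frame(
    center = c(8.73, 8.62, 7.98, 7.62),
    n_protons = c(2, 2, 4, 4),
    shape = "lorentzian", width = 0.002,
    norm_region = c("chrysene", NA, NA, NA)), mw = 228.29, concentration = conc),
  benzo_a_pyrene = function(conc) synthetic_component("benzo[a]pyrene", data.frame(
    center = c(9.02, 8.30, 8.15, 7.85),
    n_protons = c(2, 3, 3, 4),
    shape = "lorentzian", width = 0.002,
    norm_region = c("benzo_a_pyrene", NA, NA, NA)), mw = 252.32, concentration = conc),
  benz_a_anthracene = function(conc) synthetic_component("benz[a]anthracene", data.frame(
    center = c(9.16, 8.33, 7.95, 7.60),
    n_protons = c(1, 4, 3, 4),
    shape = "lorentzian", width = 0.002,
    norm_region = c("benz_a_anthracene", NA, NA, NA)), mw = 228.29, concentration = conc),
  benzo_b_fluoranthene = function(conc) synthetic_component("benzo[b]fluoranthene", data.frame(
    center = c(7.415, 8.40, 8.05, 7.70),
    n_protons = c(2, 3, 3, 4),
    shape = "lorentzian", width = 0.002,
    norm_region = c("benzo_b_fluoranthene", NA, NA, NA)), mw = 252.32, concentration = conc))

#' Simulate a mineral-oil-like sample
#'
#' A broad saturates hump over 0.2-3.0 ppm (CH2/CH3 sub-maxima, decalin
#' equivalents) and an aromatics hump over 6.5-9.2 ppm (weighted toward
#' 6.8-7.2 ppm, naphthalene equivalents), each built from dozens of
#' overlapping Lorentzians, plus optional PAH4 spikes and solvent artifacts.
#' The humps are a morphological stand-in for real petrolatum spectra, not a
#' chemically realistic spin-system simulation.
#'
#' @param mosh_fraction Saturates mass fraction in g/100 g (>= 0).
#' @param moah_fraction Aromatics mass fraction in g/100 g (>= 0).
#' @param pah4_spikes Named numeric vector of PAH4 mass fractions in
#'   g/100 g; names among `chrysene`, `benzo_a_pyrene`, `benz_a_anthracene`,
#'   `benzo_b_fluoranthene`.
#' @param seed Integer seed.
#' @param noise_sd Noise SD or `"calibrated"` (default).
#' @param prep A [sample_prep()] (default 50 mg / 1.5 mL).
#' @param other_fraction Mass fraction of a glycerol-equivalent "other
#'   compounds" signal at 3.0-6.5 ppm (default 0).
#' @param ... Passed to [simulation_recipe()].
#' @return A [spectrum1d()] with ground-truth ledger.
#' @export
simulate_mineral_oil <- function(mosh_fraction, moah_fraction,
                                 pah4_spikes = NULL, seed = NULL,
                                 noise_sd = "calibrated",
                                 prep = sample_prep(50, 1.5),
                                 other_fraction = 0, ...) {
  stopifnot(mosh_fraction >= 0, moah_fraction >= 0)
  mf_to_conc <- function(mf) mf * prep$sample_mass / (100 * prep$solution_volume)
  comps <- list()
  if (mosh_fraction > 0)
    comps$mosh <- synthetic_component(
      "mosh_hump",
      data.frame(center = 1.3, n_protons = 18, shape = "hump", width = NA,
                 norm_region = "mosh"),
      mw = 138.25, concentration = mf_to_conc(mosh_fraction),
      hump_profile = data.frame(lo = c(0.80, 1.10, 1.45), hi = c(1.05, 1.45, 2.20),
                                weight = c(0.30, 0.55, 0.15)),
      hump_lines = 80L)
  if (moah_fraction > 0)
    comps$moah <- synthetic_component(
      "moah_hump",
      data.frame(center = 7.0, n_protons = 8, shape = "hump", width = NA,
                 norm_region = "moah"),
      mw = 128.17, concentration = mf_to_conc(moah_fraction),
      hump_profile = data.frame(lo = c(6.60, 6.80, 7.30, 7.60, 8.30),
                                hi = c(6.80, 7.20, 7.50, 8.30, 9.05),
                                weight = c(0.15, 0.50, 0.10, 0.15, 0.10)),
      hump_lines = 60L)
  if (other_fraction > 0)
    comps$other <- synthetic_component(
      "other_glycerol",
      data.frame(center = c(3.6, 3.7, 3.8), n_protons = c(2, 2, 1),
                 shape = "lorentzian", width = 0.004, norm_region = "other"),
      mw = 92.09, concentration = mf_to_conc(other_fraction))
  if (!is.null(pah4_spikes)) {
    makers <- .pah4_components()
    for (nm in names(pah4_spikes)) {
      if (!nm %in% names(makers))
        stop("unknown PAH4 spike: ", nm, call. = FALSE)
      comps[[nm]] <- makers[[nm]](mf_to_conc(pah4_spikes[[nm]]))
    }
  }
  recipe <- simulation_recipe(comps, prep = prep, noise_sd = noise_sd,
                              seed = seed, sample_id = "mineral_oil", ...)
  simulate_spectrum(recipe)
}

#' Simulate a chrysene reference solution
#'
#' A chrysene-only solution at a given mass fraction (default 0.55 g/100 g,
#' the validation reference level) in clean CDCl3.
#'
#' @param mass_fraction Chrysene mass fraction in g/100 g.
#' @param seed Integer seed.
#' @param noise_sd Noise SD or `"calibrated"` (default).
#' @param prep A [sample_prep()].
#' @param ... Passed to [simulation_recipe()].
#' @return A [spectrum1d()] with ground-truth ledger.
#' @export
simulate_chrysene_reference <- function(mass_fraction = 0.55, seed = NULL,
                                        noise_sd = "calibrated",
                                        prep = sample_prep(50, 1.5), ...) {
  conc <- mass_fraction * prep$sample_mass / (100 * prep$solution_volume)
  comp <- .pah4_components()$chrysene(conc)
  recipe <- simulation_recipe(list(comp), prep = prep, noise_sd = noise_sd,
                              seed = seed, sample_id = "chrysene_ref", ...)
  simulate_spectrum(recipe)
}
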