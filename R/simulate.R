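#' Simulation configuration for synthetic DDA runs
#'
#' Parameters of the synthetic spectrum generator. Defaults state the
#' emulated acquisition: precursor mass error Normal with 2 ppm sd (the
#' catalog's observed accuracies all lie within 5 ppm), fragment m/z jitter
#' 0.003 Da sd (2-decimal printed fragments from a 60,000-resolution
#' instrument), 10 uniform noise peaks per spectrum over the 100-600 Th MS2
#' scan range, retention-time jitter 0.05 min, and a 5% relative-abundance
#' floor below which no true fragment is drawn.
#'
#' @param ppm_jitter_sd Precursor m/z jitter sd in ppm (>= 0).
#' @param fragment_mz_jitter_sd Fragment m/z jitter sd in Da (>= 0).
#' @param n_noise_peaks_per_spectrum Noise peaks added per spectrum.
#' @param noise_mz_range MS2 scan range for noise peaks, Th.
#' @param n_decoy_features Number of decoy (non-betalain) spectra per run.
#' @param rt_jitter_sd Retention-time jitter sd in minutes.
#' @param base_peak_intensity Base-peak intensity in arbitrary units.
#' @param min_fragment_rel_intensity Relative-abundance floor for true
#'   fragments, fraction of base peak.
#' @param adversarial_decoys If TRUE, decoy peaks are placed exactly at core
#'   ions instead of avoiding them, to probe the screen's specificity limit.
#' @param seed Integer seed; fully determines a run.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(ppm_jitter_sd = 2,
                       fragment_mz_jitter_sd = 0.003,
                       n_noise_peaks_per_spectrum = 10,
                       noise_mz_range = c(100, 600),
                       n_decoy_features = 0,
                       rt_jitter_sd = 0.05,
                       base_peak_intensity = 1e6,
                       min_fragment_rel_intensity = 0.05,
                       adversarial_decoys = FALSE,
                       seed = 1L) {
  stopifnot(ppm_jitter_sd >= 0, fragment_mz_jitter_sd >= 0,
            rt_jitter_sd >= 0, n_noise_peaks_per_spectrum >= 0,
            n_decoy_features >= 0, length(noise_mz_range) == 2L,
            noise_mz_range[1] < noise_mz_range[2],
            min_fragment_rel_intensity >= 0, min_fragment_rel_intensity < 1)
  structure(list(ppm_jitter_sd = ppm_jitter_sd,
                 fragment_mz_jitter_sd = fragment_mz_jitter_sd,
                 n_noise_peaks_per_spectrum = n_noise_peaks_per_spectrum,
                 noise_mz_range = noise_mz_range,
                 n_decoy_features = n_decoy_features,
                 rt_jitter_sd = rt_jitter_sd,
                 base_peak_intensity = base_peak_intensity,
                 min_fragment_rel_intensity = min_fragment_rel_intensity,
                 adversarial_decoys = adversarial_decoys,
                 seed = as.integer(seed)),
            class = "sim_config")
}

all_core_mz <- function(ions = core_ion_set()) {
  unique(c(ions$betalain_core, ions$aglycone, ions$decarboxy_marker,
           ions$dehydro_marker, ions$betacyanin_support,
           ions$betaxanthin_marker))
}

# uniform draws over `range` excluding +/- `guard` around `avoid`, by
# rejection; the avoided windows are a tiny fraction of the range.
runif_avoiding <- function(n, range, avoid, guard = 0.05) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(n - length(out), range[1], range[2])
    ok <- !vapply(x, function(v) any(abs(v - avoid) < guard), logical(1))
    out <- c(out, x[ok])
  }
  out
}

# log-uniform intensities in [floor, 1] * base; with floor 0 the lower
# decade is capped at 1e-3 to keep draws finite.
rintensity <- function(n, floor_frac, base) {
  lo <- log(max(floor_frac, 1e-3))
  base * exp(stats::runif(n, lo, 0))
}

#' Simulate one DDA MS/MS spectrum from a catalog record
#'
#' The precursor is the record's theoretical [M+H]+ with multiplicative
#' Gaussian error (`ppm_jitter_sd`); each printed fragment becomes one peak
#' with additive Gaussian m/z jitter and log-uniform intensity at or above
#' the relative-abundance floor; noise peaks are drawn uniformly over the
#' scan range avoiding 0.05 Da windows around the true fragments; rt is the
#' catalog rt plus Gaussian jitter. Uses the current RNG state — seed via
#' `set.seed()` or use [simulate_run()] for a fully seeded run.
#'
#' @param record One-row slice of a `betalain_catalog`.
#' @param cfg A [sim_config()].
#' @return An `msms_spectrum` with id `"truth:<name>"`.
#' @export
simulate_spectrum <- function(record, cfg = sim_config()) {
  if (inherits(record, "data.frame")) {
    stopifnot(nrow(record) == 1L)
    frags <- record$fragment_mz[[1]]
    theo <- record$computed_mz
    rt0 <- record$rt_min
    name <- record$name
  } else {
    frags <- record$fragment_mz
    theo <- record$computed_mz
    rt0 <- record$rt_min
    name <- record$name
  }
  frags <- unique(frags)
  if (!length(frags)) stop("record ", sQuote(name), " has no fragments")
  pre <- theo * (1 + stats::rnorm(1, 0, cfg$ppm_jitter_sd * 1e-6))
  fmz <- frags + stats::rnorm(length(frags), 0, cfg$fragment_mz_jitter_sd)
  fint <- rintensity(length(frags), cfg$min_fragment_rel_intensity,
                     cfg$base_peak_intensity)
  fint[which.max(fint)] <- cfg$base_peak_intensity  # pin the base peak
  nn <- cfg$n_noise_peaks_per_spectrum
  if (nn > 0) {
    nmz <- runif_avoiding(nn, cfg$noise_mz_range, frags, 0.05)
    # noise sits below the survey floor so it cannot create fingerprints
    nint <- stats::runif(nn, 0, 0.8 * cfg$min_fragment_rel_intensity *
                               cfg$base_peak_intensity)
    fmz <- c(fmz, nmz); fint <- c(fint, nint)
  }
  rt <- rt0 + stats::rnorm(1, 0, cfg$rt_jitter_sd)
  msms_spectrum(pre, rt, fmz, fint, id = paste0("truth:", name))
}

simulate_decoy <- function(cfg, ions = core_ion_set()) {
  pre <- stats::runif(1, 250, 900)
  rt <- stats::runif(1, 0.5, 12)
  np <- max(cfg$n_noise_peaks_per_spectrum, 6L)
  if (cfg$adversarial_decoys) {
    mz <- sample(all_core_mz(ions), min(np, length(all_core_mz(ions))))
  } else {
    mz <- runif_avoiding(np, cfg$noise_mz_range, all_core_mz(ions), 0.05)
  }
  int <- rintensity(np, 0.05, cfg$base_peak_intensity)
  msms_spectrum(pre, rt, mz, int, id = "truth:decoy")
}

#' Simulate a synthetic DDA run from a catalog
#'
#' One spectrum per catalog record (in catalog order) followed by
#' `cfg$n_decoy_features` decoy spectra whose peaks avoid all diagnostic
#' ions (or sit exactly on them in adversarial mode). Spectrum titles encode
#' ground truth (`truth:<name>` / `truth:decoy`) for downstream scoring.
#' The run is fully determined by `cfg$seed`.
#'
#' @param catalog A `betalain_catalog`.
#' @param cfg A [sim_config()].
#' @param mgf_path Optional path; when given the run is also written as MGF.
#' @return List of `msms_spectrum` (records first, then decoys).
#' @export
simulate_run <- function(catalog, cfg = sim_config(), mgf_path = NULL) {
  stopifnot(inherits(catalog, "betalain_catalog"))
  if (!nrow(catalog)) stop("empty catalog")
  set.seed(cfg$seed)
  spectra <- lapply(seq_len(nrow(catalog)), function(i)
    simulate_spectrum(catalog[i, ], cfg))
  if (cfg$n_decoy_features > 0)
    spectra <- c(spectra,
                 lapply(seq_len(cfg$n_decoy_features),
                        function(i) simulate_decoy(cfg)))
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  spectra
}
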