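#' Construct an MS/MS spectrum
#'
#' A feature-resolved MS/MS spectrum: precursor m/z (assumed [M+H]+, charge
#' +1), retention time in minutes, and a peak list. Peaks are stored sorted
#' ascending by m/z; intensities must be non-negative and at least one peak
#' is required.
#'
#' @param precursor_mz Precursor m/z in Th (> 0).
#' @param rt Retention time in minutes (NA allowed).
#' @param mz Numeric vector of fragment m/z values.
#' @param intensity Numeric vector of intensities (same length as `mz`);
#'   defaults to 1 for pre-filtered peak lists.
#' @param id Optional spectrum title/identifier.
#' @return An object of class `msms_spectrum` (a list with the fields above).
#' @examples
#' msms_spectrum(551.1483, 3.46, c(389.09, 345.10), c(100, 40))
#' @export
msms_spectrum <- function(precursor_mz, rt = NA_real_, mz, intensity = NULL,
                          id = NULL) {
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number")
  if (!length(mz)) stop("a spectrum needs at least one peak")
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  if (length(intensity) != length(mz))
    stop("mz and intensity lengths differ")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  o <- order(mz)
  structure(list(precursor_mz = precursor_mz, rt = rt,
                 mz = mz[o], intensity = intensity[o], id = id),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat("<msms_spectrum> precursor ", sprintf("%.4f", x$precursor_mz),
      if (!is.na(x$rt)) sprintf(" @ %.2f min", x$rt), ", ",
      length(x$mz), " peaks",
      if (!is.null(x$id)) paste0(" [", x$id, "]"), "\n", sep = "")
  invisible(x)
}

#' Diagnostic (core) ion sets of betalains
#'
#' The fragment ions used to screen and classify betalain MS/MS spectra.
#' `betalain_core` are the eight low-mass ions mapping to the shared
#' betalamic-acid/pyridine core (m/z 211.07, 194.04, 179.08, 178.05, 166.05,
#' 138.05, 132.04, 106.06); 211.07 is additionally diagnostic of
#' betaxanthins. The aglycone ion 389.09 marks intact betacyanins; 345.10
#' (aglycone - CO2) marks decarboxylated and 343.09 (aglycone - CO2 - H2)
#' dehydrogenated betacyanin derivatives. `betacyanin_support` are further
#' ions specific to betacyanin structural sections.
#'
#' All values can be overridden for other instruments or calibrations.
#'
#' @param betalain_core,betacyanin_support Numeric m/z vectors.
#' @param aglycone,decarboxy_marker,dehydro_marker,betaxanthin_marker Scalars.
#' @return List of class `core_ion_set`.
#' @export
core_ion_set <- function(
    betalain_core = c(211.07, 194.04, 179.08, 178.05, 166.05, 138.05, 132.04,
                      106.06),
    aglycone = 389.09,
    decarboxy_marker = 345.10,
    dehydro_marker = 343.09,
    betacyanin_support = c(299.10, 297.08, 281.09, 269.09, 255.11, 253.09,
                           176.07, 150.05),
    betaxanthin_marker = 211.07) {
  structure(list(betalain_core = betalain_core,
                 aglycone = aglycone,
                 decarboxy_marker = decarboxy_marker,
                 dehydro_marker = dehydro_marker,
                 betacyanin_support = betacyanin_support,
                 betaxanthin_marker = betaxanthin_marker),
            class = "core_ion_set")
}

#' Match target ions in a spectrum
#'
#' A target matches when some peak lies within `mz_tol` of it and that
#' peak's intensity is at least `min_rel_intensity` of the base peak. Each
#' target matches at most once (the nearest qualifying peak wins).
#'
#' @param spectrum An `msms_spectrum`.
#' @param targets Numeric vector of target m/z values.
#' @param mz_tol Absolute m/z tolerance in Da (default 0.01; the catalog
#'   prints fragments at 2 decimals from a 60,000-resolution instrument).
#' @param min_rel_intensity Relative-abundance floor as a fraction of the
#'   base peak (default 0: take the peak list as pre-filtered).
#' @return Logical vector along `targets` (TRUE = matched), with the matched
#'   peak m/z as attribute `peak_mz` (NA where unmatched).
#' @examples
#' sp <- msms_spectrum(551.15, 3.4, c(389.091, 345.099), c(10, 100))
#' match_ions(sp, c(389.09, 343.09))
#' @export
match_ions <- function(spectrum, targets, mz_tol = 0.01,
                       min_rel_intensity = 0) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  if (mz_tol <= 0) stop("mz_tol must be positive")
  if (min_rel_intensity < 0 || min_rel_intensity >= 1)
    stop("min_rel_intensity must be in [0, 1)")
  if (!length(spectrum$mz)) stop("empty spectrum")
  floor_i <- min_rel_intensity * max(spectrum$intensity)
  keep <- spectrum$intensity >= floor_i
  mz <- spectrum$mz[keep]
  hit <- logical(length(targets))
  peak <- rep(NA_real_, length(targets))
  if (length(mz)) {
    for (i in seq_along(targets)) {
      d <- abs(mz - targets[i])
      j <- which.min(d)
      if (d[j] <= mz_tol) {
        hit[i] <- TRUE
        peak[i] <- mz[j]
      }
    }
  }
  attr(hit, "peak_mz") <- peak
  hit
}

#' Classify an MS/MS spectrum by betalain diagnostic ions
#'
#' Decision rules, applied in order:
#' 1. fewer than `min_core` core ions matched -> `not-betalain`;
#' 2. aglycone 389.09 matched -> `betacyanin`;
#' 3. 345.10 matched -> `betacyanin-derivative-decarboxy`;
#' 4. 343.09 matched -> `betacyanin-derivative-dehydro`;
#' 5. 211.07 matched and precursor <= `betaxanthin_max_mz` -> `betaxanthin`;
#' 6. otherwise `ambiguous`.
#'
#' The default `min_core = 2` keeps the weakest catalog records (some print
#' only two core ions) while rejecting random decoys;
#' `betaxanthin_max_mz = 450` reflects that betaxanthin [M+H]+ masses map up
#' to ~400 Th, with margin. The 5% relative-abundance floor reproduces the
#' ion survey convention; set it to 0 for pre-filtered peak lists.
#'
#' @inheritParams match_ions
#' @param ions A [core_ion_set()].
#' @param min_core Minimum number of matched core ions (default 2).
#' @param min_rel_intensity Relative-abundance floor (default 0.05).
#' @param betaxanthin_max_mz Precursor cutoff for the betaxanthin call.
#' @return List of class `fingerprint_result`: `class_call`, `matched_core`,
#'   `matched_support`, `matched_markers` (named logical for
#'   aglycone/decarboxy/dehydro/betaxanthin markers), `evidence_score`
#'   (fraction of core+support ions matched, in [0,1]).
#' @export
classify_spectrum <- function(spectrum, ions = core_ion_set(), min_core = 2,
                              mz_tol = 0.01, min_rel_intensity = 0.05,
                              betaxanthin_max_mz = 450) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  core_hit <- match_ions(spectrum, ions$betalain_core, mz_tol, min_rel_intensity)
  sup_hit <- match_ions(spectrum, ions$betacyanin_support, mz_tol, min_rel_intensity)
  markers <- c(aglycone = ions$aglycone, decarboxy = ions$decarboxy_marker,
               dehydro = ions$dehydro_marker, betaxanthin = ions$betaxanthin_marker)
  mk_hit <- match_ions(spectrum, markers, mz_tol, min_rel_intensity)
  names(mk_hit) <- names(markers)
  call <- if (sum(core_hit) < min_core) "not-betalain"
    else if (mk_hit[["aglycone"]]) "betacyanin"
    else if (mk_hit[["decarboxy"]]) "betacyanin-derivative-decarboxy"
    else if (mk_hit[["dehydro"]]) "betacyanin-derivative-dehydro"
    else if (mk_hit[["betaxanthin"]] && spectrum$precursor_mz <= betaxanthin_max_mz)
      "betaxanthin"
    else "ambiguous"
  structure(list(
    class_call = call,
    matched_core = ions$betalain_core[core_hit],
    matched_support = ions$betacyanin_support[sup_hit],
    matched_markers = as.logical(mk_hit) |> stats::setNames(names(markers)),
    n_core = sum(core_hit),
    evidence_score = (sum(core_hit) + sum(sup_hit)) /
      (length(core_hit) + length(sup_hit))
  ), class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat("<fingerprint_result> ", x$class_call, " (", x$n_core, " core ions, ",
      "evidence ", sprintf("%.2f", x$evidence_score), ")\n", sep = "")
  invisible(x)
}

#' Screen a run of MS/MS spectra for betalain candidates
#'
#' Classifies every spectrum and keeps those whose class call is not
#' `not-betalain` — the in-silico analogue of selecting XIC features that
#' harbor the betalain core ions as product ions.
#'
#' @param spectra List of `msms_spectrum`.
#' @inheritParams classify_spectrum
#' @return data.frame sorted by rt then precursor m/z: `index` (position in
#'   `spectra`), `id`, `precursor_mz`, `rt`, `class_call`, `n_core`,
#'   `evidence_score`. Rejected spectra are recorded in attribute `rejected`
#'   (indices with reasons).
#' @export
screen_run <- function(spectra, ions = core_ion_set(), min_core = 2,
                       mz_tol = 0.01, min_rel_intensity = 0.05,
                       betaxanthin_max_mz = 450) {
  if (!length(spectra)) {
    out <- data.frame(index = integer(0), id = character(0),
                      precursor_mz = numeric(0), rt = numeric(0),
                      class_call = character(0), n_core = integer(0),
                      evidence_score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "rejected") <- data.frame(index = integer(0), reason = character(0))
    return(out)
  }
  res <- lapply(spectra, classify_spectrum, ions = ions, min_core = min_core,
                mz_tol = mz_tol, min_rel_intensity = min_rel_intensity,
                betaxanthin_max_mz = betaxanthin_max_mz)
  out <- data.frame(
    index = seq_along(spectra),
    id = vapply(spectra, function(s) if (is.null(s$id)) NA_character_ else s$id,
                character(1)),
    precursor_mz = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
    rt = vapply(spectra, `[[`, numeric(1), "rt"),
    class_call = vapply(res, `[[`, character(1), "class_call"),
    n_core = vapply(res, `[[`, integer(1), "n_core"),
    evidence_score = vapply(res, `[[`, numeric(1), "evidence_score"),
    stringsAsFactors = FALSE
  )
  rejected <- out[out$class_call == "not-betalain", c("index", "id"), drop = FALSE]
  rejected$reason <- sprintf("fewer than %d core ions", min_core)
  out <- out[out$class_call != "not-betalain", , drop = FALSE]
  out <- out[order(out$rt, out$precursor_mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "fingerprints") <- res
  out
}

# ---- MGF and peak-list I/O -------------------------------------------------

#' Read a Mascot generic format (MGF) file
#'
#' Minimal MGF reader for DDA-style MS/MS: BEGIN IONS/END IONS blocks with
#' PEPMASS, optional RTINSECONDS and TITLE headers, and "m/z intensity" peak
#' lines. Retention time is converted to minutes.
#'
#' @param path MGF file.
#' @return List of `msms_spectrum`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_hdr <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_hdr]
    key <- toupper(sub("=.*$", "", hdr))
    val <- sub("^[^=]*=", "", hdr)
    pep <- val[key == "PEPMASS"]
    if (!length(pep)) stop("MGF spectrum without PEPMASS")
    pre <- as.numeric(strsplit(trimws(pep[1]), "[[:space:]]+")[[1]][1])
    rt <- if (any(key == "RTINSECONDS"))
      as.numeric(val[key == "RTINSECONDS"][1]) / 60 else NA_real_
    title <- if (any(key == "TITLE")) val[key == "TITLE"][1] else NULL
    peaks <- block[!is_hdr & nzchar(trimws(block))]
    pm <- do.call(rbind, lapply(strsplit(trimws(peaks), "[[:space:]]+"),
                                function(x) as.numeric(x[1:2])))
    msms_spectrum(pre, rt, pm[, 1], pm[, 2], id = title)
  })
}

#' Write spectra as MGF
#'
#' @param spectra List of `msms_spectrum`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(s$id)) writeLines(paste0("TITLE=", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.3f", s$rt * 60), con)
    writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a plain peak-list file
#'
#' Two-column delimited "m/z intensity" table preceded by a header line
#' `# precursor_mz=<mz> rt=<minutes>` (rt optional).
#'
#' @param path Peak-list file.
#' @return An `msms_spectrum`.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("peak-list file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[1]
  if (!grepl("precursor_mz=", hdr))
    stop("peak list must start with '# precursor_mz=<mz> [rt=<min>]'")
  pre <- as.numeric(sub(".*precursor_mz=([0-9.eE+-]+).*", "\\1", hdr))
  rt <- if (grepl("rt=", hdr))
    as.numeric(sub(".*rt=([0-9.eE+-]+).*", "\\1", hdr)) else NA_real_
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !startsWith(trimws(body), "#")]
  pm <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:],;\t]+"),
                              function(x) as.numeric(x[1:2])))
  msms_spectrum(pre, rt, pm[, 1], pm[, 2], id = basename(path))
}
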