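class_call_category <- function(class_call) {
  switch(class_call,
    "betacyanin" = "betacyanin",
    "betacyanin-derivative-decarboxy" = "betacyanin-derivative",
    "betacyanin-derivative-dehydro" = "betacyanin-derivative",
    "betaxanthin" = "betaxanthin",
    NA_character_  # ambiguous / not-betalain constrain nothing
  )
}

# A fingerprint class call contradicts a record when both map to a definite
# category and the categories differ. Betalamic acid (which classifies
# "ambiguous" under the marker rules) and intact betacyanins are both
# compatible with a "betacyanin" call through the aglycone ion.
class_agrees <- function(class_call, record_category) {
  cc <- class_call_category(class_call)
  if (is.na(cc)) return(TRUE)
  if (record_category == "betalamic-acid") return(cc == "betacyanin")
  cc == record_category
}

#' Annotate one screened feature against the catalog
#'
#' Candidate records are those whose theoretical [M+H]+ lies within
#' `ppm_tol` of the observed precursor (after the optional global
#' recalibration offset). Candidates are scored by fragment coverage — the
#' fraction of the record's (deduplicated) printed fragment list matched in
#' the spectrum at `mz_tol` — and ranked by coverage (desc), then |ppm|
#' (asc), then catalog id (deterministic tie-break). A candidate whose
#' category contradicts the fingerprint class call is demoted below all
#' agreeing candidates. Among top candidates sharing one formula, the
#' retention-time isomer rule ([resolve_isomers()]) picks the accepted
#' record; exact rt ties yield no acceptance (`ambiguous_rt`).
#'
#' @param spectrum An `msms_spectrum` (its precursor and rt are used unless
#'   overridden via `precursor_mz`/`rt`).
#' @param fingerprint A `fingerprint_result` for the spectrum, or NULL to
#'   compute one with defaults.
#' @param catalog A `betalain_catalog`.
#' @param ppm_tol Precursor tolerance in ppm (default 5: every catalog
#'   record's printed accuracy lies within [-4.9, -0.48] ppm).
#' @param mz_tol Fragment tolerance in Da (default 0.01).
#' @param recal_ppm Global recalibration offset in ppm added to the
#'   theoretical m/z before comparison (default 0; not applied
#'   automatically even though the catalog's uniformly negative ppm suggests
#'   a calibration bias).
#' @param precursor_mz,rt Optional overrides.
#' @return List of class `annotation_result`: `precursor_mz`, `rt`,
#'   `class_call`, `candidates` (ranked data.frame with `id`, `name`, `ppm`,
#'   `coverage`, `n_matched_fragments`, `class_agreement`), and `accepted`
#'   (one-row data.frame or NULL) plus `status`.
#' @export
annotate_feature <- function(spectrum, fingerprint = NULL, catalog,
                             ppm_tol = 5, mz_tol = 0.01, recal_ppm = 0,
                             precursor_mz = spectrum$precursor_mz,
                             rt = spectrum$rt) {
  stopifnot(inherits(catalog, "betalain_catalog"))
  if (!nrow(catalog)) stop("empty catalog")
  if (ppm_tol <= 0) stop("ppm_tol must be positive")
  if (is.null(fingerprint))
    fingerprint <- classify_spectrum(spectrum)
  theo <- catalog$computed_mz * (1 + recal_ppm * 1e-6)
  ppm <- ppm_error(precursor_mz, theo)
  cand_idx <- which(abs(ppm) <= ppm_tol)
  result <- function(candidates, accepted, status) {
    structure(list(precursor_mz = precursor_mz, rt = rt,
                   class_call = fingerprint$class_call,
                   candidates = candidates, accepted = accepted,
                   status = status),
              class = "annotation_result")
  }
  empty <- data.frame(id = integer(0), name = character(0),
                      formula = character(0), rt_catalog = numeric(0),
                      ppm = numeric(0), coverage = numeric(0),
                      n_matched_fragments = integer(0),
                      class_agreement = logical(0), category = character(0),
                      stringsAsFactors = FALSE)
  if (!length(cand_idx)) return(result(empty, NULL, "no-candidate"))

  cov <- vapply(cand_idx, function(i) {
    frags <- unique(catalog$fragment_mz[[i]])
    if (!length(frags)) return(c(0, 0))
    hit <- match_ions(spectrum, frags, mz_tol = mz_tol)
    c(mean(hit), sum(hit))
  }, numeric(2))
  agree <- vapply(cand_idx, function(i)
    class_agrees(fingerprint$class_call, catalog$category[i]), logical(1))
  cand <- data.frame(
    id = catalog$id[cand_idx],
    name = catalog$name[cand_idx],
    formula = catalog$formula[cand_idx],
    rt_catalog = catalog$rt_min[cand_idx],
    ppm = ppm[cand_idx],
    coverage = cov[1, ],
    n_matched_fragments = as.integer(cov[2, ]),
    class_agreement = agree,
    category = catalog$category[cand_idx],
    stringsAsFactors = FALSE
  )
  # demote class-contradicting candidates below all agreeing ones
  o <- order(!cand$class_agreement, -cand$coverage, abs(cand$ppm), cand$id)
  cand <- cand[o, , drop = FALSE]
  rownames(cand) <- NULL

  top <- cand[1, ]
  group <- cand[cand$formula == top$formula &
                cand$class_agreement == top$class_agreement &
                cand$coverage == top$coverage, , drop = FALSE]
  pick <- resolve_isomers(group, rt)
  if (is.null(pick)) return(result(cand, NULL, "ambiguous_rt"))
  status <- if (pick$class_agreement) "accepted" else "accepted_class_mismatch"
  result(cand, pick, status)
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result> ", sprintf("%.4f", x$precursor_mz),
      if (!is.na(x$rt)) sprintf(" @ %.2f min", x$rt), ": ", sep = "")
  if (!is.null(x$accepted))
    cat(x$accepted$name, sprintf(" (%.2f ppm)", x$accepted$ppm), "\n", sep = "")
  else cat(x$status, "\n")
  invisible(x)
}

#' Resolve same-formula isomer candidates by retention time
#'
#' Epimers (betanin/isobetanin and kin) share formula and fragment list but
#' separate chromatographically — the iso (15R) epimer elutes later on
#' C18 reversed phase. Among candidates sharing one formula the record whose
#' catalog rt is nearest the feature rt wins; an exact tie yields NULL
#' (report ambiguity rather than guess). When catalog rts are absent, the
#' non-"Iso" name is taken to elute earlier; with an unknown feature rt the
#' single candidate (if any) is returned.
#'
#' @param candidates data.frame with at least `name` and `rt_catalog`.
#' @param rt Feature retention time in minutes (NA allowed).
#' @return One-row data.frame (the chosen candidate) or NULL when ambiguous.
#' @export
resolve_isomers <- function(candidates, rt) {
  if (!nrow(candidates)) return(NULL)
  if (nrow(candidates) == 1L) return(candidates[1, ])
  if (!is.na(rt) && !all(is.na(candidates$rt_catalog))) {
    d <- abs(candidates$rt_catalog - rt)
    d[is.na(d)] <- Inf
    best <- which(d - min(d) < 1e-9)  # tolerance for float ties
    if (length(best) > 1L) return(NULL)
    return(candidates[best, ])
  }
  # no usable rt: earlier-eluting convention -- non-iso before iso
  is_iso <- grepl("^iso", tolower(candidates$name))
  if (sum(!is_iso) == 1L) return(candidates[!is_iso, ][1, ])
  NULL
}

#' Annotate a screened run
#'
#' Runs [annotate_feature()] for every row of a [screen_run()] table.
#'
#' @param spectra The spectrum list that was screened.
#' @param screened Output of [screen_run()] on `spectra`.
#' @param catalog A `betalain_catalog`.
#' @inheritParams annotate_feature
#' @return List of `annotation_result`, one per screened row.
#' @export
annotate_run <- function(spectra, screened, catalog, ppm_tol = 5,
                         mz_tol = 0.01, recal_ppm = 0) {
  fps <- attr(screened, "fingerprints")
  lapply(seq_len(nrow(screened)), function(k) {
    i <- screened$index[k]
    annotate_feature(spectra[[i]],
                     fingerprint = if (!is.null(fps)) fps[[i]],
                     catalog = catalog, ppm_tol = ppm_tol, mz_tol = mz_tol,
                     recal_ppm = recal_ppm)
  })
}

#' Tabular annotation report
#'
#' One row per accepted annotation, mirroring the catalog's columns:
#' compound name, observed rt, relative rt, formula, theoretical and
#' observed m/z, ppm, matched-fragment count, coverage and class call. The
#' relative rt is computed against the run's own betanin feature when one
#' was accepted; otherwise against the catalog reference rt, and the report
#' attribute `rt_reference` says which was used. An optional `area` vector
#' (pre-integrated peak areas, same order as `annotations`) is passed
#' through verbatim; no integration is performed.
#'
#' @param annotations List of `annotation_result`.
#' @param catalog The catalog used for annotation.
#' @param area Optional numeric vector of peak areas.
#' @return data.frame of accepted annotations (attribute `rt_reference`
#'   is `"run"` or `"catalog"`).
#' @export
annotation_report <- function(annotations, catalog, area = NULL) {
  stopifnot(inherits(catalog, "betalain_catalog"))
  acc <- !vapply(annotations, function(a) is.null(a$accepted), logical(1))
  ref_name <- attr(catalog, "reference_compound")
  rows <- lapply(which(acc), function(k) {
    a <- annotations[[k]]
    data.frame(
      name = a$accepted$name,
      rt = a$rt,
      formula = a$accepted$formula,
      theoretical_mz = round_half_away(
        catalog$computed_mz[match(a$accepted$id, catalog$id)], 4),
      observed_mz = round_half_away(a$precursor_mz, 4),
      ppm = round_half_away(a$accepted$ppm, 2),
      n_matched_fragments = a$accepted$n_matched_fragments,
      coverage = a$accepted$coverage,
      class_call = a$class_call,
      area = if (is.null(area)) NA_real_ else area[k],
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), rt = numeric(0), formula = character(0),
               theoretical_mz = numeric(0), observed_mz = numeric(0),
               ppm = numeric(0), n_matched_fragments = integer(0),
               coverage = numeric(0), class_call = character(0),
               area = numeric(0), stringsAsFactors = FALSE)
  run_ref_rt <- out$rt[match(ref_name, out$name)]
  if (length(run_ref_rt) == 1L && !is.na(run_ref_rt)) {
    out$relative_rt <- round_half_away(relative_rt(out$rt, run_ref_rt), 2)
    rt_reference <- "run"
  } else {
    cat_ref_rt <- catalog$rt_min[match(ref_name, catalog$name)]
    if (length(cat_ref_rt) == 1L && !is.na(cat_ref_rt)) {
      out$relative_rt <- round_half_away(relative_rt(out$rt, cat_ref_rt), 2)
    } else {
      out$relative_rt <- NA_real_
    }
    rt_reference <- "catalog"
  }
  o <- order(out$rt, out$observed_mz)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rt_reference") <- rt_reference
  out
}
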