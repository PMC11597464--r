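#' Betalain class taxonomy and framework ions
#'
#' The class framework of betalains used by the catalog. Betacyanins are the
#' red-violet glycosylated (possibly acylated) conjugates of betanidin; each
#' betacyanin class carries a characteristic intact framework ion ([M+H]+ of
#' the unmodified class representative). Betaxanthins are betalamic acid
#' condensed with an amino acid or amine and are grouped by side-chain
#' chemistry; they carry no framework ion beyond the shared diagnostic
#' fragment at m/z 211.07. The betacyanin aglycone frame (betanidin) is
#' m/z 389.0979 and is exposed as the `aglycone_mz` attribute.
#'
#' @return data.frame with columns `class`, `parent`
#'   (betacyanin/betaxanthin/betalamic-acid) and `framework_mz` (NA where the
#'   class has none); attribute `aglycone_mz` = 389.0979.
#' @examples
#' betalain_classes()
#' @export
betalain_classes <- function() {
  df <- data.frame(
    class = c("betanin-type", "amaranthin-type", "melocactin-type",
              "apiocactin-type", "gomphrenin-type", "glabranin-type",
              "unknown-type",
              "hydrophobic", "polar-uncharged", "positively-charged",
              "negatively-charged", "special",
              "betalamic-acid"),
    parent = c(rep("betacyanin", 7), rep("betaxanthin", 5), "betalamic-acid"),
    framework_mz = c(551.1508, 727.1829, 713.2036, 683.1930, 551.1508,
                     713.2036, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(df, "aglycone_mz") <- 389.0979
  df
}

#' Path to a bundled data file
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
betalains_extdata <- function(file = "red_pitaya_betalains.tsv") {
  path <- system.file("extdata", file, package = "betalains")
  if (!nzchar(path)) stop("bundled file not found: ", file)
  path
}

parse_fragment_list <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

catalog_columns <- c("id", "printed_label", "name", "category", "class",
                     "formula", "rt_min", "relative_rt", "theoretical_mz",
                     "observed_mz", "ppm", "fragments", "tentative",
                     "reference")

#' Load a betalain catalog
#'
#' Reads a tab-separated catalog (UTF-8, header row) into a
#' `betalain_catalog`. The bundled fixture transcribes the 86 betalains
#' identified in red pitaya (*Hylocereus costaricensis*), including their
#' printed fragment-ion lists, verbatim; the schema also accepts additional
#' records (a `source` column tags provenance).
#'
#' On load each record's formula is parsed and its theoretical [M+H]+ is
#' recomputed; records whose stated `theoretical_mz` deviates by more than
#' `mz_check_tol` are flagged with a warning (not dropped). `(name, rt_min)`
#' pairs must be unique.
#'
#' @param path TSV file; defaults to the bundled red pitaya catalog.
#' @param reference_compound Name of the retention-time reference (the
#'   compound whose rt defines relative rt), default `"Betanin"`.
#' @param mz_check_tol Consistency tolerance in Da for the formula-vs-m/z
#'   check (default 0.0005).
#' @return A `betalain_catalog`: a data.frame with the schema columns, plus
#'   list columns `fragment_mz` (parsed numeric fragment lists, duplicates
#'   kept as printed) and `derivative_ops` (see [parse_derivative_ops()]),
#'   columns `parent` and `is_derivative`, and numeric `computed_mz`.
#' @examples
#' cat86 <- load_catalog()
#' nrow(cat86)
#' @export
load_catalog <- function(path = betalains_extdata(),
                         reference_compound = "Betanin",
                         mz_check_tol = 5e-4) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          encoding = "UTF-8")
  missing <- setdiff(catalog_columns, names(df))
  if (length(missing))
    stop("catalog schema mismatch; missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df)) {
    key <- paste(df$name, df$rt_min)
    if (anyDuplicated(key))
      stop("duplicate (name, rt) pairs in catalog: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    comps <- lapply(df$formula, parse_formula)
    df$computed_mz <- vapply(comps, protonated_mz, numeric(1))
    bad <- abs(df$computed_mz - df$theoretical_mz) > mz_check_tol
    if (any(bad))
      warning(sum(bad), " record(s) with formula/theoretical m/z disagreement",
              " beyond ", mz_check_tol, " Da: ",
              paste(df$name[bad], collapse = ", "))
    df$fragment_mz <- lapply(df$fragments, parse_fragment_list)
    cls <- betalain_classes()
    df$parent <- cls$parent[match(df$class, cls$class)]
    if (anyNA(df$parent))
      stop("unknown class label(s): ",
           paste(unique(df$class[is.na(df$parent)]), collapse = ", "))
    df$derivative_ops <- lapply(df$name, parse_derivative_ops)
    # category is authoritative: the unknowns' decarboxylated forms are
    # derivatives although their names carry no decarboxy/neo/xan marker
    df$is_derivative <- df$category == "betacyanin-derivative"
  } else {
    df$computed_mz <- numeric(0)
    df$fragment_mz <- list()
    df$parent <- character(0)
    df$derivative_ops <- list()
    df$is_derivative <- logical(0)
  }
  structure(df, class = c("betalain_catalog", "data.frame"),
            reference_compound = reference_compound, path = path)
}

#' @export
print.betalain_catalog <- function(x, ...) {
  cat("<betalain_catalog> ", nrow(x), " records (",
      sum(x$parent == "betacyanin"), " betacyanin, ",
      sum(x$parent == "betaxanthin"), " betaxanthin, ",
      sum(x$parent == "betalamic-acid"), " betalamic acid)\n", sep = "")
  invisible(x)
}

#' Parse derivative operations from a compound name
#'
#' Betacyanin derivatives are decarboxylated (one CO2 per event; positional
#' prefixes such as 2-/15-/17- are nominal, mass is position-independent)
#' and/or dehydrogenated (one H2 per event; the "xan" prefix denotes
#' 2,3-dehydro and "neo" denotes 14,15-dehydro). `"bidecarboxy"` and
#' `"tridecarboxy"` count as 2 and 3 decarboxylations; the variant spelling
#' "descarboxy" is accepted as printed in the source table.
#'
#' @param name Compound name.
#' @return Character vector of ops drawn from
#'   `c("decarboxy", "dehydro-2,3", "dehydro-14,15")`, possibly with
#'   repetition; empty for an unmodified compound.
#' @examples
#' parse_derivative_ops("2,17-bidecarboxy-xanneobetanin")
#' @export
parse_derivative_ops <- function(name) {
  s <- tolower(name)
  ops <- character(0)
  k <- if (grepl("tridecarboxy|tridescarboxy", s)) 3L
       else if (grepl("bidecarboxy|bidescarboxy", s)) 2L
       else if (grepl("de[cs]?s?carboxy", s)) 1L
       else 0L
  ops <- c(ops, rep("decarboxy", k))
  # "xan" marks 2,3-dehydro; guard against the class word "betaxanthin"
  if (grepl("xan", sub("bx$", "", sub("betaxanthin", "", s))))
    ops <- c(ops, "dehydro-2,3")
  if (grepl("neo", s)) ops <- c(ops, "dehydro-14,15")
  ops
}

#' Relative retention time
#'
#' Retention time divided by that of the reference compound (betanin) in the
#' same run: a column-independent elution descriptor. Reported to 2 decimals
#' in the catalog; this function does not round.
#'
#' @param rt Retention time(s) in minutes.
#' @param reference_rt Reference retention time in minutes, > 0.
#' @return rt / reference_rt.
#' @examples
#' round_half_away(relative_rt(6.59, 3.43), 2)  # 1.92 (isobetanin)
#' @export
relative_rt <- function(rt, reference_rt) {
  if (any(reference_rt <= 0)) stop("reference retention time must be positive")
  rt / reference_rt
}

#' Catalog summary statistics
#'
#' Record counts by parent, class and category, the m/z range, and the count
#' of tentative identifications. The `abstract_partition` entry folds
#' betalamic acid into the betacyanins, reproducing the
#' betacyanin / betacyanin-derivative / betaxanthin partition used in the
#' source's summary (the bucket for betalamic acid is not defined there; this
#' is the convention that reproduces its totals).
#'
#' @param catalog A `betalain_catalog`.
#' @return List with elements `n`, `by_parent`, `by_class`, `by_category`,
#'   `pct_parent`, `mz_range`, `n_tentative`, `abstract_partition`.
#' @examples
#' catalog_stats(load_catalog())$by_parent
#' @export
catalog_stats <- function(catalog) {
  stopifnot(inherits(catalog, "betalain_catalog"))
  tab <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    stats::setNames(as.integer(t), names(t))
  }
  cls <- betalain_classes()
  by_parent <- tab(catalog$parent, unique(cls$parent))
  by_class <- tab(catalog$class, cls$class)
  by_category <- tab(catalog$category,
                     c("betacyanin", "betacyanin-derivative", "betaxanthin",
                       "betalamic-acid"))
  ap <- c(
    betacyanin = unname(by_category["betacyanin"] + by_category["betalamic-acid"]),
    `betacyanin-derivative` = unname(by_category["betacyanin-derivative"]),
    betaxanthin = unname(by_category["betaxanthin"])
  )
  list(
    n = nrow(catalog),
    by_parent = by_parent,
    by_class = by_class,
    by_category = by_category,
    pct_parent = if (nrow(catalog)) 100 * by_parent / nrow(catalog) else by_parent,
    mz_range = if (nrow(catalog)) range(catalog$theoretical_mz) else c(NA_real_, NA_real_),
    n_tentative = sum(catalog$tentative == 1),
    abstract_partition = ap
  )
}

#' Validate a catalog against recomputation
#'
#' Per-record consistency checks: (1) theoretical [M+H]+ recomputed from the
#' formula vs the stated value (`mz_tol`, default 0.0005 Da); (2) the stated
#' ppm mass accuracy vs ppm recomputed from the record's observed and stated
#' theoretical m/z, compared after rounding to 2 decimals (`ppm_tol`,
#' default 0.05) — the stated accuracies derive from the printed 4-decimal
#' theoretical values, which at three rounding-boundary records differ from
#' full-precision recomputation by 1e-4 Th, so the stated theoretical
#' (already validated against the formula by check 1) is the correct base;
#' (3) the stated relative rt vs recomputation against the reference
#' compound (`rel_rt_tol`, default 0.01).
#'
#' @param catalog A `betalain_catalog`.
#' @param mz_tol,ppm_tol,rel_rt_tol Tolerances as above.
#' @return data.frame with one row per record: deltas and pass flags
#'   (`mz_ok`, `ppm_ok`, `rel_rt_ok`; NA where the record lacks the input),
#'   plus attribute `summary` with overall counts.
#' @examples
#' v <- validate_catalog(load_catalog())
#' attr(v, "summary")
#' @export
validate_catalog <- function(catalog, mz_tol = 5e-4, ppm_tol = 0.05,
                             rel_rt_tol = 0.01) {
  stopifnot(inherits(catalog, "betalain_catalog"))
  n <- nrow(catalog)
  computed <- catalog$computed_mz
  mz_delta <- computed - catalog$theoretical_mz
  mz_ok <- abs(mz_delta) <= mz_tol

  ppm_re <- ppm_error(catalog$observed_mz, catalog$theoretical_mz)
  ppm_delta <- round_half_away(ppm_re, 2) - catalog$ppm
  ppm_ok <- ifelse(is.na(catalog$observed_mz) | is.na(catalog$ppm),
                   NA, abs(ppm_delta) <= ppm_tol)

  ref <- attr(catalog, "reference_compound")
  ref_rt <- catalog$rt_min[match(ref, catalog$name)]
  if (length(ref_rt) == 1L && !is.na(ref_rt)) {
    rel <- round_half_away(relative_rt(catalog$rt_min, ref_rt), 2)
    rel_delta <- rel - catalog$relative_rt
    rel_ok <- abs(rel_delta) <= rel_rt_tol
  } else {
    rel_delta <- rep(NA_real_, n)
    rel_ok <- rep(NA, n)
  }
  out <- data.frame(
    id = catalog$id, name = catalog$name,
    mz_delta = mz_delta, mz_ok = mz_ok,
    ppm_recomputed = ppm_re, ppm_delta = ppm_delta, ppm_ok = ppm_ok,
    rel_rt_delta = rel_delta, rel_rt_ok = rel_ok,
    stringsAsFactors = FALSE
  )
  attr(out, "summary") <- c(
    n = n,
    mz_pass = sum(mz_ok, na.rm = TRUE),
    ppm_pass = sum(ppm_ok, na.rm = TRUE),
    ppm_checked = sum(!is.na(ppm_ok)),
    rel_rt_pass = sum(rel_ok, na.rm = TRUE)
  )
  out
}

derivative_prefix <- function(ops) {
  k <- sum(ops == "decarboxy")
  pre <- c("", "decarboxy-", "bidecarboxy-", "tridecarboxy-")[k + 1L]
  if ("dehydro-2,3" %in% ops) pre <- paste0(pre, "xan")
  if ("dehydro-14,15" %in% ops) pre <- paste0(pre, "neo")
  pre
}

#' Enumerate decarboxylated / dehydrogenated derivatives
#'
#' Applies derivative operations to an unmodified betacyanin: each
#' `"decarboxy"` subtracts CO2 and each dehydrogenation (`"dehydro-2,3"` aka
#' "xan", `"dehydro-14,15"` aka "neo") subtracts H2 from the formula. The
#' position of the lost carboxyl (C2/C15/C17) affects the name only, never
#' the mass: MS cannot localize the decarboxylation. The derivative's
#' theoretical m/z is recomputed from the modified formula.
#'
#' @param base A single-row `betalain_catalog` slice (or list) with at least
#'   `name`, `formula` and `class`; must not itself be a derivative.
#' @param ops Either a character vector of ops (one derivative), or a list of
#'   such vectors (one derivative per element). Ops drawn from
#'   `c("decarboxy", "dehydro-2,3", "dehydro-14,15")`; at most 3
#'   decarboxylations.
#' @param names Optional character vector of names for the derivatives;
#'   defaults to a conventional prefix (e.g. `"bidecarboxy-xanbetanin"`).
#' @return data.frame with columns `name`, `formula`, `theoretical_mz`
#'   (4 decimals), `class`, `category`, `n_decarboxy`, `n_dehydro`.
#' @examples
#' betanin <- load_catalog()[3, ]
#' enumerate_derivatives(betanin, list("decarboxy", "dehydro-14,15"))
#' @export
enumerate_derivatives <- function(base, ops, names = NULL) {
  if (inherits(base, "data.frame")) {
    stopifnot(nrow(base) == 1L)
    base <- as.list(base)
    if (is.list(base$fragment_mz)) base$fragment_mz <- base$fragment_mz[[1]]
  }
  if (length(parse_derivative_ops(base$name)))
    stop("base compound ", sQuote(base$name), " is itself a derivative")
  if (!is.list(ops)) ops <- list(ops)
  valid <- c("decarboxy", "dehydro-2,3", "dehydro-14,15")
  comp0 <- as_composition(base$formula)
  base_name <- sub("^(.)", "\\L\\1", base$name, perl = TRUE)
  out <- lapply(seq_along(ops), function(i) {
    op <- ops[[i]]
    if (length(op) && !all(op %in% valid))
      stop("unknown derivative op(s): ",
           paste(setdiff(op, valid), collapse = ", "))
    k <- sum(op == "decarboxy")
    if (k > 3L) stop("at most 3 decarboxylations are supported")
    j <- sum(op != "decarboxy")
    comp <- comp0
    if (k) comp <- compose_subtract(comp, composition(C = k, O = 2 * k))
    if (j) comp <- compose_subtract(comp, composition(H = 2 * j))
    nm <- if (!is.null(names)) names[i]
          else if (!length(op)) base$name
          else paste0(derivative_prefix(op), base_name)
    data.frame(
      name = nm,
      formula = format(comp),
      theoretical_mz = round_half_away(protonated_mz(comp), 4),
      class = base$class,
      category = if (length(op)) "betacyanin-derivative" else "betacyanin",
      n_decarboxy = k, n_dehydro = j,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Betaxanthin condensation
#'
#' Betaxanthins arise from the condensation of betalamic acid (C9H9NO5) with
#' the amino or imino group of an amino acid or amine, with loss of one
#' water. Given the amine's composition, returns the conjugate and its
#' theoretical [M+H]+.
#'
#' @param amine Composition or formula string of the free amino acid/amine;
#'   must contain at least one N and the H/O needed for the water loss.
#' @param name Compound name, conventionally `"<Amino acid>-bx"`.
#' @param class Betaxanthin class label (default `"hydrophobic"`).
#' @return One-row data.frame with `name`, `formula`, `theoretical_mz`
#'   (4 decimals), `class`, `category`, `parent`.
#' @examples
#' condense_betaxanthin("C5H10N2O3", "Glutamine-bx")  # 340.1139
#' @export
condense_betaxanthin <- function(amine, name, class = "hydrophobic") {
  amine <- as_composition(amine)
  if (!("N" %in% names(amine)) || amine[["N"]] < 1)
    stop("amine must contain at least one nitrogen")
  comp <- compose_subtract(compose_add("C9H9NO5", amine), "H2O")
  data.frame(
    name = name,
    formula = format(comp),
    theoretical_mz = round_half_away(protonated_mz(comp), 4),
    class = class,
    category = "betaxanthin",
    parent = "betaxanthin",
    stringsAsFactors = FALSE
  )
}

#' Load a neutral-loss table
#'
#' Named residue losses used by multistage-MS interpretation: glycosyl and
#' acyl residues seen on betacyanins (glucosyl, glucuronosyl,
#' pentosyl/apiosyl, malonyl, hydroxymethylglutaryl, feruloyl, coumaroyl,
#' sulfo) plus the small losses CO2, H2 and H2O. Each entry's stated mass is
#' validated against its formula within 1e-4 Da. Glutaryl shares the pentosyl
#' formula (C5H8O4): a ~132 Da loss is reported with both candidates rather
#' than forcing a single call.
#'
#' @param path TSV with columns `name`, `formula`, `mass`; defaults to the
#'   bundled table.
#' @return data.frame `name`, `formula`, `mass` (monoisotopic, Da) of class
#'   `neutral_loss_table`.
#' @examples
#' neutral_losses()
#' @export
neutral_losses <- function(path = betalains_extdata("neutral_losses.tsv")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula", "mass") %in% names(df)))
  exact <- vapply(df$formula, monoisotopic_mass, numeric(1))
  if (any(abs(exact - df$mass) > 1e-4))
    stop("neutral-loss table mass/formula disagreement: ",
         paste(df$name[abs(exact - df$mass) > 1e-4], collapse = ", "))
  df$mass <- unname(exact)
  structure(df, class = c("neutral_loss_table", "data.frame"))
}
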