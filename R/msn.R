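#' Construct a multistage-MS precursor chain
#'
#' An ordered chain of precursor m/z values from successive MSn stages,
#' parent first (e.g. MS2 -> MS3 -> MS4 selections such as
#' 827.2353 -> 695.1930 -> 551.1508 -> 389.0979). The chain must be strictly
#' decreasing with at least two stages. Activation metadata (e.g. "CID35")
#' is free text and never affects interpretation.
#'
#' @param mz Numeric vector of stage m/z values, parent first.
#' @param activation Optional character vector of per-transition activation
#'   labels (length `length(mz) - 1`, recycled if scalar).
#' @return Object of class `msn_chain`.
#' @export
msn_chain <- function(mz, activation = NULL) {
  if (length(mz) < 2L) stop("an MSn chain needs at least two stages")
  if (any(diff(mz) >= 0))
    stop("chain m/z values must be strictly decreasing")
  if (!is.null(activation))
    activation <- rep_len(as.character(activation), length(mz) - 1L)
  structure(list(mz = mz, activation = activation), class = "msn_chain")
}

#' @export
print.msn_chain <- function(x, ...) {
  cat("<msn_chain> ", paste(sprintf("%.4f", x$mz), collapse = " -> "), "\n",
      sep = "")
  invisible(x)
}

#' Interpret an MSn chain as successive neutral losses
#'
#' For each consecutive pair of stages the mass difference is computed
#' exactly and looked up in the neutral-loss table; every in-tolerance
#' candidate is reported, sorted by absolute deviation (ties keep table
#' order, so isobaric residues such as pentosyl/glutaryl are both listed).
#' The default tolerance 0.005 Da separates glucuronosyl from feruloyl
#' (176.0321 vs 176.0473) while accommodating 3-decimal printed inputs.
#'
#' @param chain An `msn_chain` (or numeric vector, coerced).
#' @param losses A [neutral_losses()] table.
#' @param tol Loss-assignment tolerance in Da (default 0.005).
#' @return data.frame of class `loss_assignments`, one row per transition:
#'   `from_mz`, `to_mz`, `delta`, `best` (loss name or `"unassigned"`),
#'   `best_formula`, `best_dev_mda` (|delta - loss| in mDa), plus list
#'   column `candidates` (each a data.frame name/formula/dev_mda).
#' @examples
#' interpret_chain(c(827.2353, 695.1930, 551.1508, 389.0979))
#' @export
interpret_chain <- function(chain, losses = neutral_losses(), tol = 0.005) {
  if (!inherits(chain, "msn_chain")) chain <- msn_chain(chain)
  if (tol <= 0) stop("tol must be positive")
  n <- length(chain$mz) - 1L
  rows <- lapply(seq_len(n), function(i) {
    delta <- chain$mz[i] - chain$mz[i + 1L]
    dev <- abs(delta - losses$mass)
    in_tol <- which(dev <= tol)
    in_tol <- in_tol[order(dev[in_tol])]
    cands <- data.frame(name = losses$name[in_tol],
                        formula = losses$formula[in_tol],
                        dev_mda = 1000 * dev[in_tol],
                        stringsAsFactors = FALSE)
    list(from_mz = chain$mz[i], to_mz = chain$mz[i + 1L], delta = delta,
         best = if (nrow(cands)) cands$name[1] else "unassigned",
         best_formula = if (nrow(cands)) cands$formula[1] else NA_character_,
         best_dev_mda = if (nrow(cands)) cands$dev_mda[1] else NA_real_,
         candidates = cands)
  })
  out <- data.frame(
    from_mz = vapply(rows, `[[`, numeric(1), "from_mz"),
    to_mz = vapply(rows, `[[`, numeric(1), "to_mz"),
    delta = vapply(rows, `[[`, numeric(1), "delta"),
    best = vapply(rows, `[[`, character(1), "best"),
    best_formula = vapply(rows, `[[`, character(1), "best_formula"),
    best_dev_mda = vapply(rows, `[[`, numeric(1), "best_dev_mda"),
    stringsAsFactors = FALSE
  )
  out$candidates <- lapply(rows, `[[`, "candidates")
  class(out) <- c("loss_assignments", "data.frame")
  out
}

#' Propose a parent composition from a terminal match and assigned losses
#'
#' Multistage unknown characterization: when the terminal stage of an MSn
#' chain matches a catalog record (typically the aglycone betanidin at
#' 389.0979 or betanin at 551.1508) and every neutral loss along the chain
#' has been assigned a residue, the parent composition is the terminal
#' formula plus the sum of the lost residues. The theoretical [M+H]+ of the
#' proposal is compared back to the parent m/z as a consistency check.
#'
#' @param parent_mz Observed parent [M+H]+.
#' @param assignments A `loss_assignments` table; every row must have an
#'   assigned best candidate.
#' @param terminal_formula Formula (string or composition) of the compound
#'   matched at the terminal stage.
#' @return List: `composition` (elem_comp), `formula`, `theoretical_mz`
#'   (4 decimals), `ppm_vs_parent`.
#' @examples
#' a <- interpret_chain(c(827.2353, 695.1930, 551.1508, 389.0979))
#' propose_composition(827.2353, a, "C18H16N2O8")$formula  # C35H42N2O21
#' @export
propose_composition <- function(parent_mz, assignments, terminal_formula) {
  stopifnot(inherits(assignments, "loss_assignments"))
  if (any(assignments$best == "unassigned"))
    stop("cannot propose a composition: unassigned neutral loss at delta ",
         paste(sprintf("%.4f", assignments$delta[assignments$best == "unassigned"]),
               collapse = ", "))
  comp <- as_composition(terminal_formula)
  for (f in assignments$best_formula) comp <- compose_add(comp, f)
  theo <- protonated_mz(comp)
  list(composition = comp,
       formula = format(comp),
       theoretical_mz = round_half_away(theo, 4),
       ppm_vs_parent = ppm_error(parent_mz, theo))
}
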