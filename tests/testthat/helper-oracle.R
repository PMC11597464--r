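# Independent oracles kept deliberately separate from the package code
# paths they check.

# Hand-summed monoisotopic masses from an independently typed table
# (IUPAC 2021 values), element-by-element loop.
oracle_mass <- function(counts) {
  tab <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
           S = 31.97207069)
  total <- 0
  for (el in names(counts)) total <- total + counts[[el]] * tab[[el]]
  total
}
oracle_proton <- 1.00727646688

# Direct set-intersection implementation of the diagnostic-ion decision
# rules, applied to a printed fragment string -- no spectra, no matching
# machinery.
oracle_class <- function(frag_str, precursor, tol = 0.01) {
  f <- as.numeric(strsplit(frag_str, ";", fixed = TRUE)[[1]])
  has <- function(x) any(abs(f - x) <= tol)
  core <- c(211.07, 194.04, 179.08, 178.05, 166.05, 138.05, 132.04, 106.06)
  n_core <- sum(vapply(core, has, logical(1)))
  if (n_core < 2) return("not-betalain")
  if (has(389.09)) return("betacyanin")
  if (has(345.10)) return("betacyanin-derivative-decarboxy")
  if (has(343.09)) return("betacyanin-derivative-dehydro")
  if (has(211.07) && precursor <= 450) return("betaxanthin")
  "ambiguous"
}

# random small compositions over CHNOS for property tests
random_comp <- function() {
  n <- sample(1:5, 1)
  el <- sample(c("C", "H", "N", "O", "S"), n)
  composition(stats::setNames(sample(0:30, n, replace = TRUE), el))
}

load_fixture <- function() load_catalog(betalains_extdata())
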