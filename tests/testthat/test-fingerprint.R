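cat86 <- load_fixture()

noiseless_run <- function() {
  cfg <- sim_config(ppm_jitter_sd = 0, fragment_mz_jitter_sd = 0,
                    rt_jitter_sd = 0, n_noise_peaks_per_spectrum = 0, seed = 1)
  simulate_run(cat86, cfg)
}

test_that("msms_spectrum validates and sorts its peaks", {
  sp <- msms_spectrum(551.15, 3.4, c(345.1, 194.04, 389.09), c(2, 1, 3))
  expect_equal(sp$mz, c(194.04, 345.1, 389.09))
  expect_equal(sp$intensity, c(1, 2, 3))
  expect_error(msms_spectrum(-1, 1, 100), "positive")
  expect_error(msms_spectrum(551, 1, numeric(0)), "at least one peak")
  expect_error(msms_spectrum(551, 1, 100, -1), "non-negative")
})

test_that("match_ions matches within tolerance above the abundance floor", {
  sp <- msms_spectrum(551.15, 3.4,
                      mz = c(389.091, 345.0995, 194.038, 150.2),
                      intensity = c(100, 3, 50, 80))
  hit <- match_ions(sp, c(389.09, 345.10, 194.04, 343.09), mz_tol = 0.01)
  expect_equal(unclass(hit)[1:4], c(TRUE, TRUE, TRUE, FALSE),
               ignore_attr = TRUE)
  # 5% floor removes the 3%-intensity peak at 345.0995
  hit5 <- match_ions(sp, c(345.10), mz_tol = 0.01, min_rel_intensity = 0.05)
  expect_false(any(hit5))
  expect_error(match_ions(sp, 100, mz_tol = 0), "positive")
  # betanin printed list vs the 8 core ions: independent set-intersection
  # oracle gives 5 (211.07 and 179.08 absent; 106.6 as printed is 0.54 off)
  bet <- cat86[cat86$name == "Betanin", ]
  sp_bet <- msms_spectrum(551.1508, 3.43, unique(bet$fragment_mz[[1]]))
  core <- core_ion_set()$betalain_core
  expect_equal(sum(match_ions(sp_bet, core, 0.01)), 5)
  # glutamine-bx printed list carries the betaxanthin marker 211.07
  glx <- cat86[cat86$name == "Glutamine-bx", ]
  sp_glx <- msms_spectrum(340.1139, 1.2, unique(glx$fragment_mz[[1]]))
  expect_true(any(match_ions(sp_glx, 211.07, 0.01)))
})

test_that("match_ions is monotone in mz_tol", {
  set.seed(3)
  targets <- core_ion_set()$betalain_core
  for (i in 1:10) {
    sp <- msms_spectrum(500, 5, runif(40, 100, 600), runif(40, 1, 100))
    prev <- rep(FALSE, length(targets))
    for (tol in c(0.002, 0.01, 0.05, 0.2)) {
      hit <- as.logical(match_ions(sp, targets, mz_tol = tol))
      expect_true(all(hit | !prev))  # enlarging tol never unmatches
      prev <- hit
    }
  }
})

test_that("classifier agrees with the rule oracle on all 86 printed records", {
  spectra <- noiseless_run()
  got <- vapply(spectra, function(s) classify_spectrum(s)$class_call, character(1))
  expected <- mapply(oracle_class, cat86$fragments, cat86$theoretical_mz)
  expect_equal(unname(got), unname(expected))
  # the published marker semantics, spelled out
  expect_equal(got[cat86$name == "Betanin"], "betacyanin", ignore_attr = TRUE)
  expect_equal(got[cat86$name == "2-decarboxy-betanin"],
               "betacyanin-derivative-decarboxy", ignore_attr = TRUE)
  expect_equal(got[cat86$name == "2-decarboxy-xanbetanin"],
               "betacyanin-derivative-dehydro", ignore_attr = TRUE)
  expect_equal(got[cat86$name == "Tryptophan-bx"], "betaxanthin",
               ignore_attr = TRUE)
  expect_true(all(got[cat86$parent == "betaxanthin"] == "betaxanthin"))
  # records with the aglycone ion are never called derivative, and vice versa
  has389 <- vapply(cat86$fragment_mz, function(f) any(abs(f - 389.09) <= 0.01),
                   logical(1))
  expect_true(all(got[has389] == "betacyanin"))
  expect_false(any(got[!has389] == "betacyanin"))
})

test_that("the four rule-exception records are reported, not misclassified", {
  spectra <- noiseless_run()
  got <- vapply(spectra, function(s) classify_spectrum(s)$class_call, character(1))
  exceptions <- c("2-decarboxy-xanneobetanin",
                  "2,15,17-tridecarboxy-neobetanin",
                  "2,17-bidecarboxy-xanneobetanin",
                  "2,15,17-tridecarboxy-xanneobetanin")
  idx <- match(exceptions, cat86$name)
  # rows 31/35/41 print fewer than 2 core ions -> not-betalain (and land in
  # the screen's rejected table); row 29 prints exactly 2 -> ambiguous
  expect_equal(unname(got[idx]),
               c("ambiguous", "not-betalain", "not-betalain", "not-betalain"))
  scr <- screen_run(spectra)
  rejected <- attr(scr, "rejected")
  expect_setequal(sub("^truth:", "", rejected$id), exceptions[2:4])
  # none of the four is assigned a definite (wrong) class
  expect_false(any(got[idx] %in% c("betacyanin", "betaxanthin",
                                   "betacyanin-derivative-decarboxy",
                                   "betacyanin-derivative-dehydro")))
})

test_that("screening keeps betalains, drops decoys, sorts by rt", {
  cfg <- sim_config(ppm_jitter_sd = 0, fragment_mz_jitter_sd = 0,
                    rt_jitter_sd = 0, n_noise_peaks_per_spectrum = 10,
                    n_decoy_features = 25, seed = 42)
  spectra <- simulate_run(cat86, cfg)
  scr <- screen_run(spectra)
  expect_equal(nrow(scr), 83)  # 86 records minus the 3 core-poor rows
  expect_false(any(grepl("decoy", scr$id)))
  expect_true(!is.unsorted(scr$rt))
  expect_true(all(scr$evidence_score >= 0 & scr$evidence_score <= 1))
  # empty run
  empty <- screen_run(list())
  expect_equal(nrow(empty), 0)
})

test_that("decoys avoiding core-ion windows never classify as betalain", {
  cfg <- sim_config(n_decoy_features = 40, seed = 9)
  spectra <- simulate_run(cat86[1, ], cfg)  # 1 record + 40 decoys
  decoys <- spectra[-1]
  calls <- vapply(decoys, function(s) classify_spectrum(s)$class_call,
                  character(1))
  expect_true(all(calls == "not-betalain"))
  # adversarial decoys sitting exactly on core ions DO pass the screen:
  # the specificity limit of a fragment-only fingerprint
  cfg2 <- sim_config(n_decoy_features = 10, adversarial_decoys = TRUE, seed = 9)
  adv <- simulate_run(cat86[1, ], cfg2)[-1]
  calls2 <- vapply(adv, function(s) classify_spectrum(s)$class_call, character(1))
  expect_true(all(calls2 != "not-betalain"))
})

test_that("MGF round-trips spectra and peak lists read back", {
  cfg <- sim_config(n_decoy_features = 2, seed = 5)
  spectra <- simulate_run(cat86[1:4, ], cfg)
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, f)
  back <- read_mgf(f)
  expect_equal(length(back), 6)
  expect_equal(back[[2]]$precursor_mz, spectra[[2]]$precursor_mz,
               tolerance = 1e-6)
  expect_equal(back[[2]]$mz, spectra[[2]]$mz, tolerance = 1e-6)
  expect_equal(back[[2]]$rt, spectra[[2]]$rt, tolerance = 1e-4)
  expect_equal(back[[2]]$id, spectra[[2]]$id)

  pl <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# precursor_mz=551.1483 rt=3.46",
               "389.09 100", "345.10 40"), pl)
  sp <- read_peaklist(pl)
  expect_equal(sp$precursor_mz, 551.1483)
  expect_equal(sp$rt, 3.46)
  expect_equal(length(sp$mz), 2)
})
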