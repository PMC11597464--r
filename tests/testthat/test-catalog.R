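cat86 <- load_fixture()

test_that("bundled catalog loads with 86 consistent records", {
  expect_s3_class(cat86, "betalain_catalog")
  expect_equal(nrow(cat86), 86)
  expect_equal(cat86$name[cat86$id == 3], "Betanin")
  expect_equal(cat86$rt_min[cat86$id == 3], 3.43)
  expect_equal(cat86$theoretical_mz[cat86$id == 3], 551.1508)
  # duplicate printed label 75 resolved by sequential internal ids
  expect_equal(sum(cat86$printed_label == 75), 2)
  expect_equal(anyDuplicated(cat86$id), 0)
})

test_that("empty and malformed catalogs are handled", {
  hdr <- paste(c("id", "printed_label", "name", "category", "class",
                 "formula", "rt_min", "relative_rt", "theoretical_mz",
                 "observed_mz", "ppm", "fragments", "tentative",
                 "reference"), collapse = "\t")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(hdr, f)
  expect_equal(nrow(load_catalog(f)), 0)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tname", f2)
  expect_error(load_catalog(f2), "schema mismatch")
  expect_error(load_catalog(tempfile()), "not found")
})

test_that("catalog statistics reproduce the published partitions", {
  s <- catalog_stats(cat86)
  expect_equal(s$n, 86)
  expect_equal(unname(s$by_parent["betaxanthin"]), 19)
  expect_equal(unname(s$abstract_partition),
               c(31, 36, 19))  # betacyanins (incl. betalamic acid), derivatives, betaxanthins
  expect_equal(sum(s$by_class), s$n)       # classes partition the records
  expect_equal(sum(s$by_category), s$n)
  expect_equal(sum(s$pct_parent), 100, tolerance = 1e-9)
})

test_that("validate_catalog reproduces theoretical m/z, ppm and relative rt", {
  v <- validate_catalog(cat86)
  s <- attr(v, "summary")
  expect_equal(unname(s["mz_pass"]), 86)       # formula -> [M+H]+ within 0.0005 Da
  expect_equal(unname(s["ppm_pass"]), 86)      # ppm column within 0.05 after rounding
  expect_equal(unname(s["ppm_checked"]), 86)
  expect_equal(unname(s["rel_rt_pass"]), 86)   # relative rt within 0.01
})

test_that("a corrupted formula is flagged for exactly that record", {
  df <- utils::read.delim(betalains_extdata(), sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  df$formula[df$name == "Isobetanin"] <- "C24H27N2O13"  # one extra H
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(bad <- load_catalog(f), "Isobetanin")
  v <- validate_catalog(bad)
  expect_equal(v$name[!v$mz_ok], "Isobetanin")
})

test_that("derivative mass shifts are 43.9898 (CO2) and 2.0157 (H2) per event", {
  co2 <- monoisotopic_mass("CO2")
  h2 <- monoisotopic_mass("H2")
  expect_equal(co2, 43.9898, tolerance = 1e-4)
  expect_equal(h2, 2.0157, tolerance = 1e-4)
  # independent of base compound
  for (nm in c("Betanin", "Phyllocactin", "Hylocerenin", "Gomphrenin-I")) {
    base <- cat86[cat86$name == nm, ]
    d <- enumerate_derivatives(base, list("decarboxy", "dehydro-14,15"))
    expect_equal(base$computed_mz - protonated_mz(d$formula[1]), co2,
                 tolerance = 1e-9, label = nm)
    expect_equal(base$computed_mz - protonated_mz(d$formula[2]), h2,
                 tolerance = 1e-9, label = nm)
  }
})

test_that("derivative enumeration reproduces printed catalog m/z", {
  betanin <- cat86[cat86$name == "Betanin", ]
  cases <- list(
    list(ops = "decarboxy", formula = "C23H26N2O11", mz = 507.1609),
    list(ops = "dehydro-14,15", formula = "C24H24N2O13", mz = 549.1351),
    list(ops = c("decarboxy", "decarboxy", "dehydro-2,3"),
         formula = "C22H24N2O9", mz = 461.1555),
    list(ops = c("decarboxy", "dehydro-2,3"),
         formula = "C23H24N2O11", mz = 505.1453)
  )
  for (cs in cases) {
    d <- enumerate_derivatives(betanin, list(cs$ops))
    expect_equal(d$formula, cs$formula)
    expect_equal(d$theoretical_mz, cs$mz, tolerance = 1e-4)
  }
  # identity, guard rails
  expect_equal(enumerate_derivatives(betanin, list(character(0)))$name, "Betanin")
  expect_error(enumerate_derivatives(betanin, rep("decarboxy", 4)), "at most 3")
  expect_error(enumerate_derivatives(cat86[cat86$name == "Neobetanin", ],
                                     "decarboxy"), "itself a derivative")
  # adding the lost CO2/H2 back onto every one of the 36 derivative rows
  # recovers the mass of an intact compound actually present in the catalog
  co2 <- monoisotopic_mass("CO2"); h2 <- monoisotopic_mass("H2")
  intact_mz <- cat86$computed_mz[!cat86$is_derivative]
  for (i in which(cat86$is_derivative)) {
    ops <- cat86$derivative_ops[[i]]
    k <- sum(ops == "decarboxy"); j <- sum(ops != "decarboxy")
    if (k + j == 0) { k <- 1; j <- 0 }  # unknowns: mono-decarboxy forms
    shifted <- cat86$computed_mz[i] + k * co2 + j * h2
    expect_true(any(abs(intact_mz - shifted) < 1e-4),
                label = paste(cat86$name[i], "maps to an intact base"))
  }
})

test_that("conjugate additions onto betanin reproduce printed frameworks", {
  betanin <- "C24H26N2O13"
  pairs <- list(
    list(res = "C3H2O3", mz = 637.1512),   # malonyl -> phyllocactin
    list(res = "C6H8O4", mz = 695.1930),   # hydroxymethylglutaryl -> hylocerenin
    list(res = "C9H6O2", mz = 697.1875),   # coumaroyl -> lampranthin-I
    list(res = "C10H8O3", mz = 727.1981),  # feruloyl -> lampranthin-II
    list(res = "SO3", mz = 631.1076),      # sulfo -> prebetanin
    list(res = "C6H10O5", mz = 713.2036),  # glucosyl -> melocactin
    list(res = "C5H8O4", mz = 683.1930),   # apiosyl -> apiocactin
    list(res = "C6H8O6", mz = 727.1829)    # glucuronosyl -> amaranthin frame
  )
  for (p in pairs)
    expect_equal(protonated_mz(compose_add(betanin, p$res)), p$mz,
                 tolerance = 2e-4, label = p$res)
})

test_that("betaxanthin condensation reproduces printed conjugates", {
  cases <- list(
    list(amine = "C5H10N2O3", name = "Glutamine-bx", mz = 340.1139),
    list(amine = "C2H5NO2", name = "Glycine-bx", mz = 269.0768),
    list(amine = "C11H12N2O2", name = "Tryptophan-bx", mz = 398.1347)
  )
  for (cs in cases) {
    r <- condense_betaxanthin(cs$amine, cs$name)
    expect_equal(r$theoretical_mz, cs$mz, tolerance = 1e-4, label = cs$name)
    expect_equal(r$parent, "betaxanthin")
  }
  expect_error(condense_betaxanthin("C6H12O6", "x"), "nitrogen")
})

test_that("relative retention time matches the printed column", {
  expect_equal(round_half_away(relative_rt(6.59, 3.43), 2), 1.92)
  expect_equal(round_half_away(relative_rt(5.83, 3.43), 2), 1.70)
  expect_equal(relative_rt(3.43, 3.43), 1)
  expect_error(relative_rt(5, 0), "positive")
})

test_that("class taxonomy carries the published framework ions", {
  cls <- betalain_classes()
  fw <- stats::setNames(cls$framework_mz, cls$class)
  expect_equal(unname(fw[c("betanin-type", "amaranthin-type", "melocactin-type",
                           "apiocactin-type", "gomphrenin-type", "glabranin-type")]),
               c(551.1508, 727.1829, 713.2036, 683.1930, 551.1508, 713.2036))
  expect_equal(attr(cls, "aglycone_mz"), 389.0979)
  # framework ions are consistent with formula arithmetic from betanin
  expect_equal(unname(fw["betanin-type"]),
               round_half_away(protonated_mz("C24H26N2O13"), 4))
})

test_that("derivative-op name parsing follows the xan/neo conventions", {
  expect_equal(parse_derivative_ops("17-decarboxy-betanin"), "decarboxy")
  expect_equal(parse_derivative_ops("2,17-bidecarboxy-xanneobetanin"),
               c("decarboxy", "decarboxy", "dehydro-2,3", "dehydro-14,15"))
  expect_equal(parse_derivative_ops("2-descarboxy-phyllocactin"), "decarboxy")
  expect_equal(parse_derivative_ops("Neobetanin"), "dehydro-14,15")
  expect_equal(parse_derivative_ops("Betanin"), character(0))
  expect_equal(parse_derivative_ops("Tryptophan-bx"), character(0))
})

test_that("neutral-loss table is formula-consistent", {
  nl <- neutral_losses()
  expect_true(all(c("glucosyl", "pentosyl", "hydroxymethylglutaryl",
                    "CO2", "H2", "H2O") %in% nl$name))
  for (i in seq_len(nrow(nl)))
    expect_equal(nl$mass[i], monoisotopic_mass(nl$formula[i]), tolerance = 1e-4)
  # the two near-isobars that motivate the 0.005 Da tolerance
  expect_lt(abs(abs(nl$mass[nl$name == "glucuronosyl"] -
                    nl$mass[nl$name == "feruloyl"]) - 0.0152), 2e-4)
})
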