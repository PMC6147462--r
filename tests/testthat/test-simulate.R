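nonzero_patterns <- function(iso, group) {
  m <- aggregate(conc_mM ~ pattern, data = iso[iso$group == group, ], FUN = mean)
  sort(m$pattern[m$conc_mM > 1e-12])
}

test_that("config validation rejects out-of-range fields", {
  expect_error(sim_config(glucose_c1_fraction = 1.2), "\\[0,1\\]")
  expect_error(sim_config(turns = 0), "turns")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(glucose_flux_scale = c(CTL = 1)), "every group")
})

test_that("one-turn single-tracer runs label only the first-turn classes", {
  # glucose route: Glu C4, GABA C2, Ala/Lac C3 (lactate mirrors alanine:
  # both are position-preserving exits from the same pyruvate pool)
  glc <- run_two_compartment(sim_config(turns = 1, acetate_c12_fraction = 0,
                                        dilution = 0, cv = 0, n_replicates = 2))
  expect_setequal(nonzero_patterns(glc$iso, "CTL"),
                  c("[4-13C]Glu", "[2-13C]GABA", "[3-13C]Ala", "[3-13C]Lac"))

  # acetate route: Glu/Gln C4,C5 and GABA C1,C2 via the Gln shuttle
  ace <- run_two_compartment(sim_config(turns = 1, glucose_c1_fraction = 0,
                                        dilution = 0, cv = 0, n_replicates = 2))
  expect_setequal(nonzero_patterns(ace$iso, "CTL"),
                  c("[4,5-13C]Glu", "[4,5-13C]Gln", "[1,2-13C]GABA"))
})

test_that("replicate noise behaves as configured", {
  # CV = 0: replicates identical
  res <- run_two_compartment(sim_config(cv = 0, n_replicates = 2))
  iso <- res$iso
  r1 <- iso[iso$replicate == "CTL_1", ]
  r2 <- iso[iso$replicate == "CTL_2", ]
  expect_equal(r1$conc_mM[order(r1$pattern)], r2$conc_mM[order(r2$pattern)])

  # identical group scales: expected percent change ~ 0 (up to noise)
  cfg <- sim_config(glucose_flux_scale = c(CTL = 1, KO = 1),
                    acetate_flux_scale = c(CTL = 1, KO = 1),
                    cv = 0.05, n_replicates = 20, seed = 11)
  cmp <- compare_groups(run_two_compartment(cfg)$iso, "CTL", "KO")
  glu4 <- cmp$pct_change[cmp$pattern == "[4-13C]Glu"]
  expect_lt(abs(glu4), 10)

  # same seed reproduces exactly
  a <- run_two_compartment(sim_config(seed = 5))
  b <- run_two_compartment(sim_config(seed = 5))
  expect_equal(a$iso$conc_mM, b$iso$conc_mM)
  expect_equal(attr(a$iso, "seed"), 5L)
})

test_that("label mass is fully accounted for across observable classes", {
  cfg <- sim_config(turns = 4, cv = 0, n_replicates = 2)
  dists <- neurotracer:::compartment_distributions(cfg, "CTL")
  for (met in names(dists)) {
    cls <- neurotracer:::aggregate_to_classes(dists[[met]], met)
    labeled_mass <- 1 - pattern_prob(dists[[met]], integer(0))
    expect_equal(sum(cls$prob), labeled_mass, tolerance = 1e-9)
    expect_true(all(cls$prob >= 0))
  }
})

test_that("simulated totals cap the summed isotopomer concentrations", {
  res <- run_two_compartment(sim_config(cv = 0, n_replicates = 2))
  enr <- suppressMessages(fractional_enrichment(res$iso, res$totals))
  sums <- aggregate(enrichment_pct ~ group + replicate + metabolite, data = enr, FUN = sum)
  expect_true(all(sums$enrichment_pct <= 100 + 1e-9))
})

test_that("peak synthesis applies calibration, multiplet and IS rules", {
  cal <- test_calibration(slope = 100, intercept = 5)
  iso <- isotopomer_table(c("CTL", "CTL"), "r1",
                          c("[4,5-13C]Glu", "[3-13C]Ala"), c(0.4, 0))
  pk <- simulate_peaks(iso, cal, is_area_ref = 1000, seed = 1, cv = 0)
  # doubly labeled adjacent pattern: doublets at both carbons
  glu <- pk[pk$metabolite == "Glu", ]
  expect_setequal(glu$carbon, c(4L, 5L))
  expect_identical(unique(glu$multiplet), "doublet")
  expect_identical(pk$multiplet[pk$metabolite == "Ala"], "singlet")
  # zero concentration -> area equals the intercept
  expect_equal(pk$area[pk$metabolite == "Ala"], 5)
  expect_equal(glu$area, rep(0.4 * 100 + 5, 2))
  # missing calibration errors
  naa <- isotopomer_table("CTL", "r1", "[6-13C]NAA", 0.1)
  expect_error(simulate_peaks(naa, cal), "missing calibration")
})
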