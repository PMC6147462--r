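tab1 <- table1_as_isotopomer_table()

test_that("cycling ratios and utilization indices match hand arithmetic", {
  # CTL means: ([3]Glu - [1,2]Glu)/[4]Glu = (1.147 - 0.378)/1.489
  expect_equal(glucose_cycling_ratio(tab1, "CTL", "Glu"),
               (1.147 - 0.378) / 1.489, tolerance = 1e-12)
  # [1,2]Glu/[4,5]Glu = 0.378/0.427
  expect_equal(acetate_cycling_ratio(tab1, "CTL", "Glu"),
               0.378 / 0.427, tolerance = 1e-12)
  # [4,5]Glu/[4]Glu and [1,2]GABA/[2]GABA
  expect_equal(acetate_vs_glucose_index(tab1, "CTL", "Glu"),
               0.427 / 1.489, tolerance = 1e-12)
  expect_equal(acetate_vs_glucose_index(tab1, "CTL", "GABA"),
               0.099 / 0.337, tolerance = 1e-12)
  # Gln variant denominator is glutamate C4 as printed; matched flag switches
  expect_equal(glucose_cycling_ratio(tab1, "CTL", "Gln"),
               (0.521 - 0.222) / 1.489, tolerance = 1e-12)
  expect_equal(glucose_cycling_ratio(tab1, "CTL", "Gln", matched_denominator = TRUE),
               (0.521 - 0.222) / 0.506, tolerance = 1e-12)
})

test_that("ratios are invariant under uniform rescaling and guard degeneracies", {
  scaled <- isotopomer_table(tab1$group, tab1$replicate, tab1$pattern,
                             tab1$conc_mM * 2.5)
  for (f in list(function(x) glucose_cycling_ratio(x, "CTL"),
                 function(x) acetate_cycling_ratio(x, "CTL"),
                 function(x) acetate_vs_glucose_index(x, "CTL", "GABA"))) {
    expect_equal(f(scaled), f(tab1), tolerance = 1e-12)
  }
  # [3] == [1,2] gives 0; missing pattern and zero denominator error
  eq <- isotopomer_table(rep("g", 3), "r",
                         c("[3-13C]Glu", "[1,2-13C]Glu", "[4-13C]Glu"),
                         c(0.5, 0.5, 1.0))
  expect_equal(glucose_cycling_ratio(eq, "g"), 0)
  expect_error(glucose_cycling_ratio(tab1, "nope"), "not present")
  zero <- isotopomer_table(rep("g", 3), "r",
                           c("[3-13C]Glu", "[1,2-13C]Glu", "[4-13C]Glu"),
                           c(0.5, 0.4, 0))
  expect_error(glucose_cycling_ratio(zero, "g"), "denominator")
})

test_that("percent change and the glycolytic index are plain relative changes", {
  expect_equal(percent_change(1.489, 1.940), 30.289, tolerance = 1e-3)
  expect_equal(percent_change(0.280, 0.040), -85.714, tolerance = 1e-3)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "zero control")
  expect_equal(percent_change(0.10, 0.12), 20, tolerance = 1e-9)

  ala <- isotopomer_table(c("CTL", "KO"), "r", "[3-13C]Ala", c(0.10, 0.12))
  expect_equal(glycolytic_index(ala, "CTL", "KO"), 20, tolerance = 1e-9)
  # generator: label delivery scales linearly in the flux scale
  cfg <- sim_config(cv = 0, n_replicates = 2,
                    glucose_flux_scale = c(CTL = 1, KO = 1.25))
  expect_equal(glycolytic_index(run_two_compartment(cfg)$iso, "CTL", "KO"),
               25, tolerance = 1e-9)
})

test_that("two-sample t matches the reference implementation", {
  set.seed(99)
  for (i in 1:10) {
    a <- rnorm(6, sd = runif(1, 0.5, 2))
    b <- rnorm(7, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    s <- two_tailed_t(a, b, flavor = "student")
    ref_s <- t.test(a, b, var.equal = TRUE)
    expect_equal(s$t, unname(ref_s$statistic), tolerance = 1e-12)
    expect_equal(s$p, ref_s$p.value, tolerance = 1e-12)
    w <- two_tailed_t(a, b, flavor = "welch")
    ref_w <- t.test(a, b)
    expect_equal(w$p, ref_w$p.value, tolerance = 1e-12)
    expect_equal(w$df, unname(ref_w$parameter), tolerance = 1e-9)
  }
  # Student and Welch agree when group SDs and sizes are equal
  s <- two_tailed_t(list(mean = 1, sd = 0.5, n = 6), list(mean = 2, sd = 0.5, n = 6),
                    "student")
  w <- two_tailed_t(list(mean = 1, sd = 0.5, n = 6), list(mean = 2, sd = 0.5, n = 6),
                    "welch")
  expect_equal(s$p, w$p, tolerance = 1e-12)
})

test_that("summary-statistics t reproduces frozen reference values", {
  # mean 1.489 sd 0.17 n 4 vs mean 1.940 sd 0.09 n 4
  # (scipy.stats.ttest_ind_from_stats, frozen)
  s <- two_tailed_t(list(mean = 1.489, sd = 0.17, n = 4),
                    list(mean = 1.940, sd = 0.09, n = 4), "student")
  expect_equal(s$t, -4.6892747091, tolerance = 1e-9)
  expect_equal(s$p, 0.003363372544, tolerance = 1e-9)
  w <- two_tailed_t(list(mean = 1.489, sd = 0.17, n = 4),
                    list(mean = 1.940, sd = 0.09, n = 4), "welch")
  expect_equal(w$p, 0.006800357056, tolerance = 1e-9)

  # degenerate and separation cases
  d <- two_tailed_t(list(mean = 1, sd = 0, n = 4), list(mean = 1, sd = 0, n = 4))
  expect_equal(d$p, 1)
  expect_true(d$degenerate)
  big <- two_tailed_t(list(mean = 0, sd = 1, n = 1000),
                      list(mean = 1, sd = 1, n = 1000))
  expect_lt(big$p, 1e-10)
  expect_error(two_tailed_t(1, c(1, 2)), "n >= 2")
})

test_that("group comparison tables carry means, change, p and flags", {
  t1 <- table1_isotopomers()
  cmp <- compare_groups_summary(
    data.frame(pattern = t1$pattern, mean_control = t1$mean_ctl,
               disp_control = t1$disp_ctl, mean_treated = t1$mean_ko,
               disp_treated = t1$disp_ko),
    n = 4, dispersion_kind = "sd")
  expect_equal(nrow(cmp), 37L)
  row <- cmp[cmp$pattern == "[4-13C]Glu", ]
  expect_equal(row$pct_change, 30.289, tolerance = 1e-3)
  expect_true(row$sig_05 && row$sig_01)

  # SEM reading inflates the SDs by sqrt(n)
  cmp_sem <- compare_groups_summary(
    data.frame(pattern = "[4-13C]Glu", mean_control = 1.489, disp_control = 0.17,
               mean_treated = 1.940, disp_treated = 0.09),
    n = 4, dispersion_kind = "sem")
  expect_equal(cmp_sem$sd_control, 0.34)
  expect_equal(cmp_sem$p, 0.057478282489, tolerance = 1e-9)

  # replicate-level path with BH adjustment
  res <- run_two_compartment(sim_config(seed = 2))
  cmp2 <- compare_groups(res$iso, "CTL", "KO", bh = TRUE)
  expect_true(all(cmp2$p_adj >= cmp2$p - 1e-12))
  expect_true(all(cmp2$p >= 0 & cmp2$p <= 1))
})

test_that("SUV and pAKT ratios are direct formulas with input guards", {
  expect_equal(suv(2, 10, 20), 4)
  expect_equal(suv(0.5, 10, 20), 1)
  expect_error(suv(2, 10, 0), "> 0")
  expect_equal(pakt_ratio(5, 10), 0.5)
  expect_equal(pakt_ratio(0, 10), 0)
  expect_equal(pakt_ratio(2 * 3, 2 * 8), pakt_ratio(3, 8))
  expect_error(pakt_ratio(1, 0), "> 0")
})
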