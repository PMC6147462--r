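# Unit + property tests for the carbon-fate engine, checked against the
# molecule-level enumeration oracle in helper-oracles.R.

test_that("glycolysis map splits glucose into the two triose halves", {
  glc_c1 <- pool_dist_from_patterns(6L, list(1L), 1)
  pyr <- glycolysis_map(glc_c1)
  expect_equal(pattern_prob(pyr, 3L), 0.5)
  expect_equal(pattern_prob(pyr, integer(0)), 0.5)

  glc_c6 <- pool_dist_from_patterns(6L, list(6L), 1)
  expect_equal(pattern_prob(glycolysis_map(glc_c6), 3L), 0.5)

  expect_equal(pattern_prob(glycolysis_map(pool_dist(6L)), integer(0)), 1)
})

test_that("PDH releases pyruvate C1 and renumbers C2/C3", {
  expect_equal(pattern_prob(pdh_step(pool_dist_from_patterns(3L, list(3L), 1)), 2L), 1)
  expect_equal(pattern_prob(pdh_step(pool_dist_from_patterns(3L, list(1L), 1)),
                            integer(0)), 1)
  full <- pdh_step(pool_dist_from_patterns(3L, list(c(1L, 2L, 3L)), 1))
  expect_equal(pattern_prob(full, c(1L, 2L)), 1)
})

test_that("first TCA turn puts acetyl label at oxoglutarate C4/C5 only", {
  ac2 <- pool_dist_from_patterns(2L, list(2L), 1)
  t1 <- tca_turn(ac2, pool_dist(4L))
  expect_equal(pattern_prob(t1$og, 4L), 1)

  ac12 <- pool_dist_from_patterns(2L, list(c(1L, 2L)), 1)
  expect_equal(pattern_prob(tca_turn(ac12, pool_dist(4L))$og, c(4L, 5L)), 1)
})

test_that("second turn after C4 labeling yields OG C2 or C3 with equal probability", {
  ac2 <- pool_dist_from_patterns(2L, list(2L), 1)
  t1 <- tca_turn(ac2, pool_dist(4L))
  t2 <- tca_turn(pool_dist(2L), t1$oaa_next)
  expect_equal(pattern_prob(t2$og, 2L), 0.5)
  expect_equal(pattern_prob(t2$og, 3L), 0.5)
})

test_that("downstream amino acid maps follow the stated carbon fates", {
  glu45 <- pool_dist_from_patterns(5L, list(c(4L, 5L)), 1)
  expect_equal(pattern_prob(glu_to_gaba(glu45), c(1L, 2L)), 1)
  glu4 <- pool_dist_from_patterns(5L, list(4L), 1)
  expect_equal(pattern_prob(glu_to_gaba(glu4), 2L), 1)
  glu1 <- pool_dist_from_patterns(5L, list(1L), 1)
  expect_equal(pattern_prob(glu_to_gaba(glu1), integer(0)), 1)

  oaa23 <- pool_dist_from_patterns(4L, list(c(2L, 3L)), 1)
  expect_equal(pattern_prob(oaa_to_asp(oaa23), c(2L, 3L)), 1)

  og45 <- pool_dist_from_patterns(5L, list(c(4L, 5L)), 1)
  expect_equal(pattern_prob(og_to_glu(og45, 0), c(4L, 5L)), 1)
  expect_equal(pattern_prob(og_to_glu(og45, 1), integer(0)), 1)
  half <- og_to_glu(og45, 0.5)
  expect_equal(pattern_prob(half, c(4L, 5L)), 0.5)
  expect_equal(pattern_prob(half, integer(0)), 0.5)
})

test_that("every operation conserves probability and label atoms", {
  set.seed(42)
  for (i in 1:20) {
    glc <- random_pool_dist(6L)
    pyr <- glycolysis_map(glc)
    expect_equal(sum(pyr), 1, tolerance = 1e-9)
    # each triose keeps half the glucose label in expectation
    expect_equal(expected_label_count(pyr), expected_label_count(glc) / 2,
                 tolerance = 1e-9)

    ac <- pdh_step(pyr)
    co2 <- sum(as.numeric(pyr)[c(2, 4, 6, 8)])   # states with C1 labeled
    expect_equal(expected_label_count(ac), expected_label_count(pyr) - co2,
                 tolerance = 1e-9)

    oaa <- random_pool_dist(4L)
    turn <- tca_turn(ac, oaa)
    expect_equal(sum(turn$og), 1, tolerance = 1e-9)
    expect_equal(sum(turn$oaa_next), 1, tolerance = 1e-9)
    # condensation loses OAA C1; OG->succinate loses OG C1
    oaa_c1 <- sum(as.numeric(oaa)[seq(2, 16, by = 2)])
    expect_equal(expected_label_count(turn$og),
                 expected_label_count(ac) + expected_label_count(oaa) - oaa_c1,
                 tolerance = 1e-9)
    og_c1 <- sum(as.numeric(turn$og)[seq(2, 32, by = 2)])
    expect_equal(expected_label_count(turn$oaa_next),
                 expected_label_count(turn$og) - og_c1, tolerance = 1e-9)
  }
})

test_that("post-turn OAA is invariant under end-to-end carbon reversal", {
  set.seed(7)
  for (i in 1:20) {
    turn <- tca_turn(random_pool_dist(2L), random_pool_dist(4L))
    rev_oaa <- neurotracer:::reverse_dist(turn$oaa_next)
    expect_equal(as.numeric(turn$oaa_next), as.numeric(rev_oaa), tolerance = 1e-12)
  }
})

test_that("engine matches the molecule-level enumeration oracle for <= 3 turns", {
  # pure tracers: glucose route (acetyl C2 labeled with prob 1/2 via the
  # triose coin) and acetate route (acetyl fully labeled)
  routes <- list(
    glucose = list(engine_acetyl = pdh_step(glycolysis_map(
                     pool_dist_from_patterns(6L, list(1L), 1))),
                   oracle_acetyl = list(
                     list(labels = c(FALSE, TRUE), prob = 0.5),
                     list(labels = c(FALSE, FALSE), prob = 0.5))),
    acetate = list(engine_acetyl = acetate_to_acetyl(
                     pool_dist_from_patterns(2L, list(c(1L, 2L)), 1)),
                   oracle_acetyl = list(
                     list(labels = c(TRUE, TRUE), prob = 1))))
  for (route in routes) {
    oracle <- oracle_tca(route$oracle_acetyl, turns = 3L)
    oaa <- pool_dist(4L)
    for (t in 1:3) {
      turn <- tca_turn(route$engine_acetyl, oaa)
      expect_lt(tvd(dist_to_named(turn$og), oracle$og[[t]]), 1e-9)
      expect_lt(tvd(dist_to_named(turn$oaa_next), oracle$oaa[[t]]), 1e-9)
      oaa <- turn$oaa_next
    }
  }
})

test_that("natural-abundance mixing adds independent 1.1% label", {
  dist <- neurotracer:::add_natural_abundance(pool_dist(2L), p = 0.011)
  expect_equal(pattern_prob(dist, integer(0)), (1 - 0.011)^2, tolerance = 1e-12)
  expect_equal(pattern_prob(dist, 1L), 0.011 * (1 - 0.011), tolerance = 1e-12)
  expect_equal(pattern_prob(dist, c(1L, 2L)), 0.011^2, tolerance = 1e-12)
})
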