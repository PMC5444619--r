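# Golden-value checks of the empirical rule registry (hand-evaluated
# polynomials and piecewise branches) and the species reaction rules.

test_that("shear-stress adhesion rules reproduce hand-evaluated values", {
  # neutrophil quadratic at 0.5 Pa: 1300 (0.26 0.25 - 0.8 0.5 + 0.63)
  expect_equal(eval_rule("NEUTROPHIL", "WSS", 0.5), 383.5)
  # outside the printed domain the rules are identically zero
  expect_equal(eval_rule("NEUTROPHIL", "WSS", 2.0), 0)
  expect_equal(eval_rule("MONOCYTE", "WSS", 1.05), 0)
  expect_equal(eval_rule("LYMPHOCYTE", "WSS", 0.45), 0)
  expect_equal(eval_rule("LYMPHOCYTE", "WSS", 0.03), 0)
})

test_that("cytokine adhesion rules reproduce hand-evaluated values", {
  # TNF-alpha linear branch at 0.5 U/ml: 1180 x 0.0996 x 0.5
  expect_equal(eval_rule("NEUTROPHIL", "TNFA", 0.5), 58.764)
  # same sigmoid shared by all three types
  expect_equal(eval_rule("MONOCYTE", "TNFA", 0.5),
               eval_rule("LYMPHOCYTE", "TNFA", 0.5))
  # IL-1beta sigmoid at 0.04 (hand evaluation)
  f <- 1900 * (0.10 + 0.19 * (1 - exp(-28.29 * 0.04^1.46)))
  expect_equal(eval_rule("NEUTROPHIL", "IL1B", 0.04), f)
})

test_that("healthy shear (1.4 Pa) is outside every adhesion domain", {
  for (ty in LEUK_TYPES) {
    expect_equal(eval_rule(ty, "WSS", 1.4), 0)
  }
  # pathway activation ordering: lymphocyte < 0.41, monocyte < 1.0,
  # neutrophil < 1.2
  expect_gt(eval_rule("NEUTROPHIL", "WSS", 1.1), 0)
  expect_equal(eval_rule("MONOCYTE", "WSS", 1.1), 0)
  expect_gt(eval_rule("MONOCYTE", "WSS", 0.9), 0)
  expect_equal(eval_rule("LYMPHOCYTE", "WSS", 0.9), 0)
  expect_gt(eval_rule("LYMPHOCYTE", "WSS", 0.3), 0)
})

test_that("transmigration fractions follow the stiffness rules", {
  expect_equal(tem_fraction(3, "MONOCYTE"), 0.78 * 9 + 4.8 * 3 + 51.06)
  expect_equal(tem_fraction(3, "MONOCYTE"), 72.48)
  expect_equal(tem_fraction(6, "MONOCYTE"), 95)
  expect_equal(tem_fraction(6, "NEUTROPHIL"), 91)
  expect_equal(tem_fraction(3, "NEUTROPHIL"), 9.18 * 3 + 46.96)
  expect_equal(tem_fraction(3, "LYMPHOCYTE"), tem_fraction(3, "MONOCYTE"))
  # below-domain stiffness clamps to the lower edge
  expect_equal(tem_fraction(0.5, "MONOCYTE"), tem_fraction(1, "MONOCYTE"))
})

test_that("cytokine production follows the per-cell rates", {
  inc <- produce_cytokines(list(NEUTROPHIL = 1))
  expect_equal(inc$TNFA, 5e-6)
  expect_equal(inc$IL1B, 5e-7)
  expect_equal(inc$IL10, 0)
  inc2 <- produce_cytokines(list(MONOCYTE = 2))
  expect_equal(inc2$TNFA, 1.34e-3)
  expect_equal(produce_cytokines(list())$TNFA, 0)
  # M1 macrophages produce at monocyte rates; foam cells are silent
  inc3 <- produce_cytokines(list(M1 = 1, FOAM = 10))
  expect_equal(inc3$TNFA, 6.7e-4)
  inc4 <- produce_cytokines(list(M1 = 1, FOAM = 10), extended = FALSE)
  expect_equal(inc4$TNFA, 0)
  # M2 contribute IL-10 at the lymphocyte rate
  expect_equal(produce_cytokines(list(M2 = 2))$IL10, 7.5e-5)
})

test_that("IL-10 clears pro-inflammatory cytokines linearly", {
  cl <- il10_clearance(tnfa = 1, il1b = 1, il10 = 0)
  expect_equal(cl$TNFA, 1)
  expect_equal(cl$IL1B, 1)
  cl10 <- il10_clearance(tnfa = 1, il1b = 1, il10 = 10)
  expect_equal(cl10$IL1B, 0.904)
  expect_equal(cl10$TNFA, 0.905)
  # huge IL-10 clamps at zero rather than going negative
  expect_equal(il10_clearance(1, 1, 1000)$TNFA, 0)
})

test_that("shear-gated LDL influx follows the wall polynomial", {
  r0 <- ldl_wall_influx(0, c0_blood = 1000)
  expect_equal(r0$cw, 1150)               # constant term 1.15
  expect_equal(r0$influx, 0.7 * r0$cw)
  # monotone decreasing over the physiological 0-2 Pa range
  grid <- ldl_wall_influx(seq(0, 2, by = 0.01))$cw
  expect_true(all(diff(grid) < 0))
  # influx is always 70% of the wall-surface concentration
  r <- ldl_wall_influx(seq(0, 10, by = 0.5))
  expect_equal(r$influx, 0.7 * r$cw)
})

test_that("LDL oxidation moves 1.2% per tick and decays geometrically", {
  ox <- oxidize_ldl(1000, 0)
  expect_equal(ox$LDL, 988)
  expect_equal(ox$OXLDL, 12)
  expect_equal(oxidize_ldl(0, 5)$OXLDL, 5)
  ldl <- 1000
  for (t in 1:20) ldl <- oxidize_ldl(ldl, 0)$LDL
  expect_equal(ldl, 1000 * 0.988^20)
})

test_that("cell volumes and blood composition match the stated values", {
  expect_equal(unname(AGENT_VOLUME_UM3[["NEUTROPHIL"]]), 904.78, tolerance = 1e-4)
  expect_equal(unname(AGENT_VOLUME_UM3[["MONOCYTE"]]), 7238.23, tolerance = 1e-4)
  expect_equal(unname(AGENT_VOLUME_UM3[["FOAM"]]), 8181.23, tolerance = 1e-4)
  expect_equal(sum(BLOOD_CONC_PER_MM3), 7000 * 0.973)
  expect_equal(unname(BLOOD_CONC_PER_MM3[["NEUTROPHIL"]]) * 0.1^3, 4.34)
})
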