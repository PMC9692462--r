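cfg1 <- audit_config(printed_decimals = 1)

test_that("theorem1_check flags the vitamins rows and passes exact sets", {
  v <- read_descriptor_table(fixture("vitamins_aqueous.csv"))
  f <- theorem1_check(v, cfg1)
  expect_true(all(f$verdict == "fail"))
  expect_equal(f$residual, c(1210.0, 1139.0, 1132.5, 1118.0, 1116.5))
  # exact synthetic set: residual 0, pass
  g <- generate_consistent(2, 2, "water", seed = 3)
  fg <- theorem1_check(g$descriptors, cfg1)
  expect_true(all(fg$verdict == "pass") && all(abs(fg$residual) < 1e-9))
  # indeterminate when no sums computable
  f0 <- theorem1_check(as_descriptor_table(data.frame(
    molecule_id = "x", site_id = "", medium = "gas", unit = "kJ/mol",
    BDE = 350)), cfg1)
  expect_equal(f0$verdict, "indeterminate")
})

test_that("theorem1_check from components matches printed-cell arithmetic", {
  a <- fill_molecule_ip(read_descriptor_table(fixture("atv_methanol.csv")))
  f <- theorem1_check(a[1, ], cfg1, prefer = "components")
  expect_equal(f$residual, -0.1)           # 129.4 - (23.8 + 105.7)
  expect_equal(f$tolerance, 0.2)           # 4 rounded one-decimal terms
  expect_equal(f$verdict, "pass")
})

test_that("site invariance passes ATV, fails the vitamins table", {
  a <- fill_molecule_ip(read_descriptor_table(fixture("atv_methanol.csv")))
  fa <- theorem2_site_invariance(a, cfg1)
  expect_equal(fa$verdict, "pass")
  expect_equal(fa$residual, 0)  # reported offset column: all 38.1
  v <- read_descriptor_table(fixture("vitamins_aqueous.csv"))
  fv <- theorem2_site_invariance(v, cfg1)
  expect_equal(fv$verdict, "fail")
  expect_equal(fv$residual, 93.0)  # 1386.0 - 1293.0
  expect_equal(theorem2_site_invariance(v[1, ], cfg1)$verdict, "pass")
})

test_that("reference check separates gas-consistent from wrong-medium rows", {
  p <- read_descriptor_table(fixture("peonidin.csv"))
  f <- theorem2_reference_check(p, audit_config(printed_decimals = 2))
  expect_equal(f$verdict, c("pass", "fail"))
  expect_equal(f$residual[1], 313.75 - 314.7, tolerance = 1e-9)
  expect_equal(f$residual[2], 313.95 - 32.8, tolerance = 1e-9)
  # synthetic set built from the catalog IPH: residual ~0
  g <- generate_consistent(2, 1, "water", seed = 5)
  fg <- theorem2_reference_check(
    g$descriptors, audit_config(functional = "B3LYP", basis = "6-311++G(d,p)"))
  expect_true(all(fg$verdict == "pass") && all(abs(fg$residual) < 1e-6))
  # no reference resolvable -> indeterminate
  f0 <- theorem2_reference_check(g$descriptors, audit_config())
  expect_true(all(f0$verdict == "indeterminate"))
})

test_that("infer_medium ranks candidates and honors the half-gap rule", {
  cand <- utils::read.csv(fixture("vitamins_candidates.csv"), comment.char = "#")
  r <- infer_medium(1309.0, cand)
  expect_equal(r$medium[1], "gas")
  expect_true(attr(r, "matched"))
  exact <- infer_medium(155.6, cand)
  expect_equal(exact$deviation[1], 0)
  # seeded recovery: noise well below half the minimum candidate gap
  set.seed(17)
  for (i in 1:100) {
    truth <- sample(seq_len(nrow(cand)), 1)
    obs <- cand$iph_kj[truth] + stats::runif(1, -1, 1)
    rr <- infer_medium(obs, cand)
    expect_equal(rr$medium[1], cand$medium[truth])
    expect_true(attr(rr, "matched"))
  }
  # near-degenerate candidates (water vs methanol ~0.3 kJ/mol apart at
  # B3LYP/6-311++G(d,p)): a 1 kJ/mol deviation must not assert a match
  full <- media_candidates("B3LYP", "6-311++G(d,p)")
  amb <- infer_medium(full$iph_kj[full$medium == "water"] + 1, full)
  expect_false(attr(amb, "matched"))
})

test_that("audit_table diagnoses the vitamins table as gas mislabeled aqueous", {
  v <- read_descriptor_table(fixture("vitamins_aqueous.csv"))
  cand <- utils::read.csv(fixture("vitamins_candidates.csv"), comment.char = "#")
  rep <- audit_table(v, cfg1, candidates = cand)
  f <- rep$findings
  expect_equal(sum(f$check == "T1" & f$verdict == "fail"), 5)
  expect_equal(f$verdict[f$check == "T2_site_invariance"], "fail")
  expect_equal(unname(rep$inferred_medium["water"]), "gas")
  expect_true(all(f$diagnosis[f$check == "T2_reference" & f$verdict == "fail"]
                  == "medium_mismatch_suspected"))
  # uncertainty-bearing cells parsed as mean +/- half-range
  expect_equal(v$SETPT[1], 1742.0)
  expect_equal(v$SETPT_half[1], 2.0)
})

test_that("vitamin B3 tables pass with per-protocol references; the
           criticized row fails", {
  b <- read_descriptor_table(fixture("vitb3_descriptors.csv"))
  rep <- audit_table(b, cfg1, candidates = media_candidates("B3LYP",
                                                            "6-311G(d,p)"))
  f <- rep$findings
  own <- f$check == "T1" & f$row <= 8
  expect_true(all(f$verdict[own] == "pass"))
  crit <- f$check == "T1" & f$row == 9
  expect_equal(f$verdict[crit], "fail")
  expect_equal(f$residual[crit], 1134)
  # the criticized row's offset points at gas, not water
  ref9 <- f$check == "T2_reference" & f$row == 9
  expect_equal(f$verdict[ref9], "fail")
  # own rows satisfy the reference check against their per-row IPH
  expect_true(all(f$verdict[f$check == "T2_reference" & f$row <= 8] == "pass"))
})

test_that("clean fixtures never flag; injected faults always flag at 2x tol", {
  tol <- 0.5
  cfgA <- audit_config(tolerance_mode = "absolute", absolute_tol = tol,
                       functional = "B3LYP", basis = "6-311++G(d,p)")
  for (seed in 1:50) {
    g <- generate_consistent(3, 2, "water", seed = seed)
    clean <- audit_table(g$descriptors, cfgA)
    expect_equal(sum(clean$findings$verdict == "fail"), 0)
    row <- (seed %% 6) + 1
    inj <- inject_violation(g$descriptors, "t1_offset", 2 * tol + 0.01, rows = row)
    rep <- audit_table(inj$table, cfgA)
    flagged <- rep$findings$row[rep$findings$check == "T1" &
                                rep$findings$verdict == "fail"]
    expect_equal(flagged, inj$truth$row)
    # below half tolerance: never flagged
    tiny <- inject_violation(g$descriptors, "t1_offset", 0.4 * tol, rows = row)
    rt <- audit_table(tiny$table, cfgA)
    expect_equal(sum(rt$findings$check == "T1" &
                     rt$findings$verdict == "fail"), 0)
  }
})

test_that("unit mix-ups and medium mislabels get the right diagnosis", {
  g <- generate_consistent(2, 2, "water", seed = 11)
  cfgA <- audit_config(tolerance_mode = "absolute", absolute_tol = 0.5,
                       functional = "B3LYP", basis = "6-311++G(d,p)")
  mix <- inject_violation(g$descriptors, "unit_mixup", rows = 3)
  fm <- audit_table(mix$table, cfgA)$findings
  bad <- fm$check == "T1" & fm$row == 3
  expect_equal(fm$verdict[bad], "fail")
  expect_equal(fm$diagnosis[bad], "unit_mixup_suspected")
  mis <- inject_violation(g$descriptors, "medium_mislabel", rows = 1:4,
                          to_medium = "gas")
  fmed <- audit_table(mis$table, cfgA)$findings
  ref <- fmed$check == "T2_reference" & fmed$row %in% 1:4
  expect_true(all(fmed$verdict[ref] == "fail"))
  expect_true(all(fmed$diagnosis[ref] == "medium_mismatch_suspected"))
})

test_that("verdicts survive whole-table unit conversion", {
  g <- generate_consistent(2, 2, "methanol", seed = 23)
  inj <- inject_violation(g$descriptors, "t1_offset", 3, rows = 2)
  cfg_kj <- audit_config(tolerance_mode = "absolute", absolute_tol = 1,
                         functional = "B3LYP", basis = "6-311++G(d,p)")
  rep_kj <- audit_table(inj$table, cfg_kj)
  dk <- inj$table
  f <- energy_constants()$kcal_in_kJ
  for (col in c("BDE", "IP", "PDE", "PA", "ETE", "SETPT", "SPLET",
                "SETPT_calc", "SPLET_calc"))
    dk[[col]] <- dk[[col]] / f
  dk$unit <- "kcal/mol"
  rep_kcal <- audit_table(dk, cfg_kj)  # absolute_tol converts with the unit
  key <- function(r) paste(r$findings$scope, r$findings$row, r$findings$check,
                           r$findings$verdict)
  expect_identical(key(rep_kj), key(rep_kcal))
})
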