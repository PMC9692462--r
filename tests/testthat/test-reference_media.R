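test_that("H-atom lookup resolves methods and basis degeneracy groups", {
  expect_equal(as.numeric(lookup_h_atom("B3LYP", "6-311++G(d,p)")), -0.499896)
  # non-diffuse variant collapses onto the singly-diffuse value
  expect_equal(as.numeric(lookup_h_atom("B3LYP", "6-311G(d,p)")), -0.499795)
  expect_equal(as.numeric(lookup_h_atom("M052x", "6-31+G(d,p)")), -0.495545)
  # star notation and extra polarization are aliases
  expect_equal(as.numeric(lookup_h_atom("B3LYP", "6-311G**")), -0.499795)
  expect_equal(as.numeric(lookup_h_atom("B3LYP", "6-311++G(3df,3pd)")),
               -0.499896)
  # spin-treatment prefixes normalize away
  expect_equal(as.numeric(lookup_h_atom("ROB3LYP", "6-311++G(d,p)")),
               -0.499896)
  expect_error(lookup_h_atom("HF", "STO-3G"), "available")
  # all shipped H-atom enthalpies in the physical window
  cat <- media_catalog()
  expect_true(all(cat$h_atom$hartree > -0.51 & cat$h_atom$hartree < -0.49))
})

test_that("iph reproduces headline gas and water values", {
  expect_equal(round_printed(as.numeric(iph("B3LYP", "6-311++G(d,p)", "gas")), 1),
               1321.8)
  expect_equal(round_printed(as.numeric(iph("B3LYP", "6-311++G(d,p)", "water")), 1),
               164.9)
  expect_equal(round_printed(as.numeric(
    iph("B3LYP", "6-31+G(d,p)", "methanol", unit = "kcal/mol")), 1), 38.1)
  # a medium with all-zero solvation equals gas
  cat <- media_catalog()
  cat$media <- rbind(cat$media, data.frame(
    name = "vacuumish", dH_solv_proton = 0, dH_solv_electron = 0,
    dH_solv_hatom = 0, provenance = "test"))
  expect_equal(as.numeric(iph("M062x", "6-31++G(d,p)", "vacuumish", catalog = cat)),
               as.numeric(iph("M062x", "6-31++G(d,p)", "gas")))
})

test_that("iph reproduces every shipped printed cell in three units", {
  printed <- utils::read.csv(fixture("iph_reference_printed.csv"),
                             comment.char = "#", stringsAsFactors = FALSE)
  printed$basis <- gsub("d.p", "d,p", printed$basis, fixed = TRUE)
  # the printed PBE0/6-311+G(d,p) rows duplicate B3LYP and contradict the
  # PBE0 H-atom enthalpy; they are excluded as a known typo in the source
  printed <- printed[!(printed$functional == "PBE0" &
                       printed$basis == "6-311+G(d,p)"), ]
  for (i in seq_len(nrow(printed))) {
    p <- printed[i, ]
    kj <- as.numeric(iph(p$functional, p$basis, p$medium))
    # the water M062x/6-31+G(d,p) kJ cell prints 150.1, inconsistent with
    # its own kcal cell (35.9 * 4.184 = 150.2) and with the gas-row chain
    # (1307.1 - 1156.9 = 150.2): a last-digit misprint we must NOT match
    misprint <- p$medium == "water" && p$functional == "M062x" &&
      p$basis == "6-31+G(d,p)"
    if (misprint) {
      expect_gt(abs(kj - p$kJ_mol), 0.06)
      expect_lt(abs(kj - p$kcal_mol * 4.184), 0.06)
    } else {
      expect_lt(abs(kj - p$kJ_mol), 0.06,
                label = paste(p$medium, p$functional, p$basis, "kJ"))
    }
    kcal <- as.numeric(convert_energy(kj, "kcal/mol", from = "kJ/mol"))
    expect_lt(abs(kcal - p$kcal_mol), 0.06)
    ev <- as.numeric(convert_energy(kj, "eV", from = "kJ/mol"))
    # flat 0.06 in each printed unit; a handful of printed eV cells chain
    # through rounded kcal values and sit ~0.0015 eV off the exact chain
    expect_lt(abs(ev - p$eV), 0.06)
    expect_lt(abs(ev - p$eV), 0.002)
  }
})

test_that("solvation shift is method-independent and iph always positive", {
  cat <- media_catalog()
  methods <- catalog_contents(cat)$methods
  for (med in cat$media$name) {
    shifts <- apply(methods, 1, function(m)
      as.numeric(iph(m[["functional"]], m[["basis"]], "gas")) -
      as.numeric(iph(m[["functional"]], m[["basis"]], med)))
    expect_lt(diff(range(shifts)), 1e-9)
    m <- get_medium(med, cat)
    expect_equal(unname(shifts[1]),
                 -(m$dH_solv_proton + m$dH_solv_electron - m$dH_solv_hatom))
    for (i in seq_len(nrow(methods)))
      expect_gt(as.numeric(iph(methods$functional[i], methods$basis[i], med)), 0)
  }
})

test_that("catalog enumerates shipped media and accepts JSON overrides", {
  cc <- catalog_contents()
  expect_setequal(cc$media, c("gas", "benzene", "toluene", "ethanol",
                              "methanol", "water"))
  b <- get_medium("benzene")
  expect_equal(c(b$dH_solv_proton, b$dH_solv_electron, b$dH_solv_hatom),
               c(-904.9, -17.5, 6.4))
  over <- read_catalog(fixture("example_catalog.json"))
  expect_equal(length(catalog_contents(over)$media), 7)
  expect_gt(as.numeric(iph("B3LYP", "6-311++G(d,p)", "dmso", catalog = over)), 0)
  expect_error(get_medium("acetone"), "available")
})

test_that("alternative proton-hydration variant shifts only the water entry", {
  alt <- media_catalog(proton_variant = "alt1022")
  dflt <- media_catalog()
  shift <- as.numeric(iph("B3LYP", "6-311++G(d,p)", "water", catalog = alt)) -
           as.numeric(iph("B3LYP", "6-311++G(d,p)", "water", catalog = dflt))
  expect_equal(shift, -1022 - (-1058.9))
  expect_equal(as.numeric(iph("B3LYP", "6-311++G(d,p)", "methanol", catalog = alt)),
               as.numeric(iph("B3LYP", "6-311++G(d,p)", "methanol", catalog = dflt)))
})

test_that("koopmans annex is present, read-only reference data", {
  k <- koopmans_annex()
  expect_true(all(c("medium", "functional", "kJ_mol") %in% names(k)))
  expect_gt(nrow(k), 50)
  # the point of carrying it: Koopmans estimates are far from the real IPH
  gas <- k[k$medium == "gas" & k$functional == "B3LYP" &
           k$basis == "6-311++G(d.p)", ]
  expect_gt(abs(gas$kJ_mol[1] - as.numeric(iph("B3LYP", "6-311++G(d,p)", "gas"))),
            400)
})
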