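test_that("rat defaults carry the liver microsomal scaling constants", {
  rat <- rat_phys()
  expect_equal(rat$mppgl, 44.8)
  expect_equal(
    rat$enzymes$ref_conc_pmol_per_mg[rat$enzymes$enzyme == "CYP3A2"], 101)
  expect_equal(rat$body_weight, 0.25)
})

test_that("an identity override reproduces the default model", {
  a <- load_physiology("rat", 0.25)
  b <- load_physiology("rat", 0.25, list(mppgl = 44.8))
  b$provenance <- a$provenance # only the provenance log may differ
  expect_equal(a, b)
})

test_that("bundled human organ volumes account for the body weight", {
  hum <- load_physiology("human", 70)
  total <- sum(hum$organs$volume_ml) + sum(hum$blood)
  expect_lt(abs(total - 70 * 1000) / (70 * 1000), 0.05)
})

test_that("venous return equals cardiac output for both species", {
  for (sp in c("rat", "human")) {
    phys <- load_physiology(sp)
    org <- phys$organs
    inflow <- sum(org$flow_ml_h[org$organ != "lung"])
    expect_lt(abs(inflow - phys$cardiac_output_ml_h) /
                phys$cardiac_output_ml_h, 1e-9)
  }
  # rebalancing after a flow override preserves the invariant
  phys <- load_physiology("rat", overrides = list("organ.muscle.flow_frac" = 0.35))
  org <- phys$organs
  expect_lt(abs(sum(org$flow_ml_h[org$organ != "lung"]) -
                  phys$cardiac_output_ml_h) / phys$cardiac_output_ml_h, 1e-9)
})

test_that("organ volumes and flows scale monotonically with body weight", {
  bw <- c(0.15, 0.25, 0.4, 0.6)
  models <- lapply(bw, function(w) load_physiology("rat", w))
  for (organ in c("liver", "muscle", "adipose")) {
    vols <- vapply(models, function(m)
      m$organs$volume_ml[m$organs$organ == organ], numeric(1))
    flows <- vapply(models, function(m)
      m$organs$flow_ml_h[m$organs$organ == organ], numeric(1))
    expect_true(all(diff(vols) > 0))
    expect_true(all(diff(flows) > 0))
  }
})

test_that("physiology serialization round-trips losslessly", {
  phys <- load_physiology("rat", 0.3, list(mppgl = 40))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_physiology(phys, path)
  back <- read_physiology(path)
  expect_equal(back, phys)
})

test_that("invalid species, overrides and values are rejected by name", {
  expect_error(load_physiology("dog"), "rat")
  expect_error(load_physiology("rat", overrides = list(nonsense = 1)),
               "nonsense")
  expect_error(load_physiology("rat", overrides = list("organ.liver.volume_ml" = -1)),
               "organ.liver.volume_ml")
  expect_error(load_physiology("rat", -0.25), "body_weight")
})

test_that("enzyme abundance is the product of the printed scaling factors", {
  # 101 pmol/mg x 44.8 mg/g x 10 g liver
  rat <- load_physiology("rat", overrides = list("organ.liver.volume_ml" = 10))
  expect_equal(organ_enzyme_abundance(rat, "CYP3A2", "liver"), 45248)
  # zero relative expression gives zero abundance
  expect_equal(organ_enzyme_abundance(rat, "CYP3A2", "muscle"), 0)
  # linear in organ mass
  rat2 <- load_physiology("rat", overrides = list("organ.liver.volume_ml" = 20))
  expect_equal(organ_enzyme_abundance(rat2, "CYP3A2", "liver"),
               2 * organ_enzyme_abundance(rat, "CYP3A2", "liver"))
  expect_error(organ_enzyme_abundance(rat, "CYP9Z9", "liver"), "enzyme")
  expect_error(organ_enzyme_abundance(rat, "CYP3A2", "paw"), "organ")
})
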