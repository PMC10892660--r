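test_that("bundled compound definitions load with their table values", {
  s <- sxg()
  expect_equal(s$molecular_weight, 315.41)
  expect_equal(s$logd74, -0.7)
  expect_equal(s$fraction_unbound$rat, 0.82)
  expect_equal(s$fraction_unbound$human, 1)
  n <- ncd()
  expect_equal(n$molecular_weight, 479.59)
  expect_equal(n$fraction_unbound$human, 0.01)
  ki <- Filter(function(x) x$species == "rat", n$inhibitions)[[1]]
  expect_equal(ki$ki_um, 0.39)
  # printed cm/s unit is carried explicitly and reinterpretable
  expect_equal(n$cellular_permeability$unit, "cm/s")
  n2 <- read_compound("nicardipine",
                      cellular_permeability_unit_hint = "1e-6 cm/s")
  expect_equal(pbpkddi:::cellular_permeability_cm_h(n2),
               pbpkddi:::cellular_permeability_cm_h(n) * 1e-6)
})

test_that("compound validation rejects out-of-range parameters", {
  mk <- function(...) {
    args <- utils::modifyList(list(
      name = "x", molecular_weight_g_mol = 100, lipophilicity_logd74 = 0,
      pka = 7, compound_type = "base", solubility_mg_per_ml = 1,
      fraction_unbound = list(rat = 0.5),
      intestinal_permeability_1e6_cm_s = 1,
      cellular_permeability = list(value = 1, unit = "cm/s")), list(...))
    do.call(compound, args)
  }
  expect_s3_class(mk(), "pbpk_compound")
  expect_error(mk(molecular_weight_g_mol = -1), "molecular_weight")
  expect_error(mk(fraction_unbound = list(rat = 1.2)), "fraction_unbound")
  expect_error(mk(cellular_permeability = list(value = 1, unit = "m/s")),
               "unit")
  expect_error(mk(compound_type = "zwitterion"), "compound_type")
  expect_error(mk(inhibitions = list(list(enzyme = "CYP3A4", ki_um = -1,
                                          mechanism = "competitive"))),
               "ki_um")
})

test_that("Weibull dissolution is anchored at 50% and matches the CDF", {
  tb <- list(kind = "tablet", dissolution_shape = 0.68,
             dissolution_time_min = 120.5)
  expect_equal(dissolved_fraction(tb, 120.5), 0.5)
  expect_equal(dissolved_fraction(tb, 241), 0.6706119217, tolerance = 1e-9)
  tb2 <- list(kind = "tablet", dissolution_shape = 1.18,
              dissolution_time_min = 5.59)
  expect_equal(dissolved_fraction(tb2, 0), 0)
  expect_equal(dissolved_fraction(tb2, 5.59), 0.5)
  sol <- list(kind = "solution")
  expect_equal(dissolved_fraction(sol, c(0, 0.1, 100)), c(0, 1, 1))
  expect_error(dissolved_fraction(tb, -1), "nonnegative")
})

test_that("dissolved fraction is nondecreasing for random Weibull shapes", {
  set.seed(42)
  for (i in 1:25) {
    form <- list(kind = "tablet",
                 dissolution_shape = stats::runif(1, 0.2, 4),
                 dissolution_time_min = stats::runif(1, 1, 500))
    tt <- sort(stats::runif(50, 0, 1000))
    f <- dissolved_fraction(form, tt)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
    # ~complete at t where (t/T50)^shape = 100 half-lives
    t_big <- form$dissolution_time_min * 100^(1 / form$dissolution_shape)
    expect_gt(dissolved_fraction(form, t_big), 0.999)
  }
})

test_that("a water-only tissue partitions 1:1 for a neutral logD-0 probe", {
  phys <- load_physiology("rat", overrides = list(
    "organ.muscle.f_water" = 1, "organ.muscle.f_lipid" = 0,
    "organ.muscle.f_protein" = 0))
  kp <- partition_coefficients(toy_compound(logd = 0, fu = 1), phys)
  expect_equal(kp$kp[kp$organ == "muscle"], 1, tolerance = 1e-6)
})

test_that("adipose partitioning increases strictly with lipophilicity", {
  phys <- rat_phys()
  kps <- vapply(seq(0, 5, by = 0.5), function(ld) {
    k <- partition_coefficients(toy_compound(logd = ld), phys)
    k$kp[k$organ == "adipose"]
  }, numeric(1))
  expect_true(all(diff(kps) > 0))
})

test_that("hydrophilic saxagliptin partitions less into fat than muscle", {
  kp <- partition_coefficients(sxg(), rat_phys())
  expect_lt(kp$kp[kp$organ == "adipose"], kp$kp[kp$organ == "muscle"])
})

test_that("partition coefficients ignore organ size and accept overrides", {
  phys <- rat_phys()
  scaled <- load_physiology("rat", overrides = stats::setNames(
    as.list(phys$organs$volume_ml * 3),
    paste0("organ.", phys$organs$organ, ".volume_ml")))
  k1 <- partition_coefficients(sxg(), phys)
  k2 <- partition_coefficients(sxg(), scaled)
  expect_equal(k1$kp, k2$kp)
  k3 <- partition_coefficients(sxg(), phys, overrides = c(liver = 2.5))
  expect_equal(k3$kp[k3$organ == "liver"], 2.5)
  expect_equal(k3$source[k3$organ == "liver"], "override")
  expect_error(partition_coefficients(sxg(), phys, overrides = c(tail = 1)),
               "unknown organ")
  expect_match(attr(k1, "method"), "tissue-composition")
})
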