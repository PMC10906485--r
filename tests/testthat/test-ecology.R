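test_that("acuity unit conversion to cycles per degree", {
  expect_equal(to_cpd(1, "mar_arcmin"), 30)
  expect_equal(to_cpd(0.5, "mar_arcmin"), 60)
  expect_equal(to_cpd(10, "cpd"), 10)
  expect_equal(to_cpd(1, "mar_deg"), 0.5)
  expect_equal(to_cpd(180 / pi, "cycles_per_radian"), 1)
  expect_error(to_cpd(10, "furlongs"), "arg")
  expect_error(to_cpd(-1, "cpd"), "positive")

  # round trip: cpd -> MAR arcmin -> cpd
  x <- c(4.6, 15.8, 143)
  expect_equal(to_cpd(30 / x, "mar_arcmin"), x, tolerance = 1e-12)
})

test_that("record selection prefers RGC, then recency, then highest acuity", {
  rec <- function(method, year, acuity) {
    data.frame(species = "Tyto alba", method = method, source_year = year,
               acuity_cpd = acuity, stringsAsFactors = FALSE)
  }
  both <- rbind(rec("behavioral", 2001, 10), rec("RGC", 1990, 8))
  expect_equal(select_record(both)$method, "RGC")
  expect_equal(select_record(both)$source_year, 1990)

  rgc2 <- rbind(rec("RGC", 1990, 8), rec("RGC", 2010, 9))
  expect_equal(select_record(rgc2)$source_year, 2010)

  tie <- rbind(rec("RGC", 2010, 8), rec("RGC", 2010, 12))
  expect_equal(select_record(tie)$acuity_cpd, 12)

  single <- rec("behavioral", 1999, 5)
  expect_equal(select_record(single), single)
  expect_error(select_record(single[0, ]), "no candidate")
  expect_error(select_record(rbind(rec("RGC", 2000, 1),
                                   within(rec("RGC", 2000, 1),
                                          species <- "Columba livia"))),
               "multiple species")
})

test_that("habitat classifier applies the strict 70% rule", {
  expect_equal(classify_habitat(c(understory = 50, mid_high = 30,
                                  ground = 20)), "complex")
  expect_equal(classify_habitat(c(ground = 60, understory = 40)),
               "generalist")
  expect_equal(classify_habitat(c(ground = 70, aerial = 30)), "generalist")
  expect_equal(classify_habitat(c(ground = 71, aerial = 29)), "horizon")
  expect_equal(classify_habitat(c(aerial = 40, open_water = 35,
                                  canopy = 25)), "open")
  expect_error(classify_habitat(c(ground = 80, aerial = 30)), "> 100")
  expect_error(classify_habitat(c(treetop = 80)), "unknown")

  # permutation invariance in strata ordering
  pct <- c(understory = 45, mid_high = 30, ground = 25)
  set.seed(501)
  for (i in 1:5) {
    expect_equal(classify_habitat(sample(pct)), classify_habitat(pct))
  }
})

test_that("at most one habitat class can exceed the threshold", {
  set.seed(511)
  strata <- c("understory", "mid_high", "aerial", "open_water", "ground",
              "water_surface", "canopy")
  for (rep in 1:50) {
    raw <- runif(7)
    pct <- setNames(100 * raw / sum(raw), strata)
    sums <- c(complex = sum(pct[c("understory", "mid_high")]),
              open = sum(pct[c("aerial", "open_water")]),
              horizon = sum(pct[c("ground", "water_surface", "canopy")]))
    expect_lte(sum(sums > 70), 1)
    cls <- classify_habitat(pct)
    if (any(sums > 70)) expect_equal(cls, names(sums)[sums > 70])
    else expect_equal(cls, "generalist")
  }
})

test_that("light classifier: nocturnal override, keyword tables, majority, ties", {
  expect_equal(classify_light("grassland", nocturnal = TRUE), "low")
  expect_equal(classify_light("desert"), "high")
  expect_equal(classify_light(c("forest edge", "secondary forest")), "medium")
  expect_equal(classify_light(c("mangrove", "heathland", "desert")), "low")
  expect_equal(classify_light(c("desert", "mangrove")), "medium")  # tie
  expect_equal(classify_light("Pelagic ocean"), "high")  # case-insensitive
  expect_error(classify_light("volcano"), "unclassified")
})

test_that("diet classifier applies the 50% dominance rule with omnivore fallback", {
  expect_equal(classify_diet(c(plants = 60, invertebrates = 30,
                               vertebrates_scavenged = 10)), "plants")
  expect_equal(classify_diet(c(plants = 40, invertebrates = 30,
                               vertebrates_scavenged = 30)), "omnivore")
  expect_equal(classify_diet(c(plants = 50, invertebrates = 50,
                               vertebrates_scavenged = 0)), "omnivore")
  expect_equal(classify_diet(c(plants = 50, invertebrates = 30,
                               vertebrates_scavenged = 20)), "plants")
  expect_error(classify_diet(c(plants = -5, invertebrates = 50,
                               vertebrates_scavenged = 0)), "non-negative")

  # raw EltonTraits-style scores are aggregated first
  raw <- c(fruit = 30, seed = 30, inv = 20, vend = 10, scav = 10)
  expect_equal(classify_diet(raw), "plants")
  agg <- aggregate_diet(raw)
  expect_equal(unname(agg), c(60, 20, 20))
})

test_that("prey mobility splits live prey from plants and carrion", {
  expect_equal(classify_prey_mobility(c(fruit = 100)), "immobile")
  expect_equal(classify_prey_mobility(c(scav = 100)), "immobile")
  expect_equal(classify_prey_mobility(c(inv = 100)), "mobile")
  expect_equal(classify_prey_mobility(c(vend = 60, fruit = 40)), "mobile")
  expect_error(classify_prey_mobility(c(inv = 50, fruit = 50)), "tie")
  expect_error(classify_prey_mobility(c(inv = 0, fruit = 0)), "zero")
})

test_that("foraging mode is decided by the primary maneuver", {
  expect_equal(classify_foraging("sallying"), "far")
  expect_equal(classify_foraging(c("pecking", "kicking/scratching")), "near")
  expect_equal(classify_foraging(c("scavenging", "gleaning")), "far")
  expect_equal(classify_foraging(c("gleaning", "scavenging")), "near")
  expect_equal(classify_foraging("Pursuit diving"), "far")
  expect_error(classify_foraging("hovering"), "hovering")
  expect_error(classify_foraging(character(0)), "no foraging")
})

test_that("classifiers are pure: identical input gives identical output", {
  pct <- c(understory = 72, ground = 28)
  kw <- c("forest edge")
  raw <- c(inv = 55, fruit = 45)
  man <- c("gleaning", "sallying")
  p1 <- ecology_profile(pct, kw, FALSE, raw, man)
  p2 <- ecology_profile(pct, kw, FALSE, raw, man)
  expect_identical(p1, p2)
  expect_equal(p1$habitat_class, "complex")
  expect_equal(p1$light_class, "medium")
  expect_equal(p1$diet_class, "invertebrates")
  expect_equal(p1$prey_mobility, "mobile")
  expect_equal(p1$foraging_mode, "near")
})
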