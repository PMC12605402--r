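mk_ped <- function(cows, birth = "2014-01-01") {
  as_pedigree(data.frame(individual = cows, sire = NA, dam = NA,
                         sex = "F", birth_date = birth))
}

cv_row <- function(dam, date, parity, outcome = "live", twin = FALSE,
                   sex = "F", sire = "S1", calf = paste0("c", date)) {
  data.table::data.table(dam = dam, sire = sire, calf = calf,
                         date = as.Date(date), parity = parity,
                         calf_sex = sex, outcome = outcome, twin = twin)
}

test_that("stillbirth derivation: coding, twins, filters, hand count", {
  ped <- mk_ped(c("d1", "d2", "d3", "d4"))
  cv <- rbind(
    cv_row("d1", "2016-03-01", 0, "died_within_24h"),
    cv_row("d1", "2017-03-10", 1, "live"),
    cv_row("d2", "2016-04-01", 0, "stillborn", twin = TRUE),
    cv_row("d3", "2016-05-01", 0, "abortion"),
    cv_row("d4", "2016-06-01", 0, "died_during_calving"))
  out <- derive_stillbirth(cv, ped)
  # died_within_24h is a stillbirth -> value 0
  expect_equal(out[animal == "d1" & parity == 0, value], 0L)
  expect_equal(out[animal == "d1" & parity == 1, value], 1L)
  # twin calving absent
  expect_false("d2" %in% out$animal)
  # abortion is not a stillbirth record
  expect_false("d3" %in% out$animal)
  expect_equal(out[animal == "d4", value], 0L)

  # unknown outcome -> validation error
  bad <- cv_row("d1", "2016-03-01", 0, "vanished")
  expect_error(derive_stillbirth(bad, ped), "unknown outcome")
})

test_that("stillbirth derivation: hand count of a 10-record toy set", {
  # 10 calvings: 2 twins, 1 first-calving at 19 months, 1 abortion
  # -> 6 survive
  ped <- as_pedigree(data.frame(
    individual = c("a", "b", "c", "d"), sire = NA, dam = NA, sex = "F",
    birth_date = as.Date(c("2014-01-01", "2014-01-01", "2014-01-01",
                           "2015-08-15"))))
  cv <- rbind(
    cv_row("a", "2016-03-01", 0),                      # keep (afc 25m)
    cv_row("a", "2017-03-01", 1),                      # keep
    cv_row("a", "2018-03-01", 2, twin = TRUE),         # twin
    cv_row("b", "2016-06-01", 0, "stillborn"),         # keep
    cv_row("b", "2017-06-01", 1),                      # keep
    cv_row("b", "2018-06-01", 2, "abortion"),          # abortion
    cv_row("c", "2016-09-01", 0, twin = TRUE),         # twin
    cv_row("c", "2017-09-01", 1),                      # keep (afc by
    cv_row("c", "2018-09-01", 2),                      #  2nd/3rd kept)
    cv_row("d", "2017-03-20", 0))                      # afc 19 months
  out <- derive_stillbirth(cv, ped)
  expect_equal(nrow(out), 6L)
  expect_false("d" %in% out$animal)
})

test_that("max_calvings caps the calvings per dam", {
  ped <- mk_ped("d1")
  cv <- do.call(rbind, lapply(1:6, function(k) {
    cv_row("d1", sprintf("%d-03-01", 2015 + k), k - 1)
  }))
  expect_equal(nrow(derive_stillbirth(cv, ped, max_calvings = 4L)), 4L)
  expect_equal(nrow(derive_stillbirth(cv, ped, max_calvings = 5L)), 5L)
})

ins_row <- function(cow, date, lact = 0L, tech = "t1") {
  data.table::data.table(cow = cow, date = as.Date(date),
                         technician = tech, lactation = lact)
}

test_that("fertility derivation: CR coding and editing limits", {
  ped <- mk_ped("c1", birth = "2014-01-01")
  # one insemination, calving 280 d later -> CR 1, AIS 1, IFL 0
  ins <- ins_row("c1", "2016-02-01")
  cv <- cv_row("c1", as.character(as.Date("2016-02-01") + 280), 0)
  out <- derive_fertility(ins, cv, ped)
  expect_equal(out[trait == "CR", value], 1)
  expect_equal(out[trait == "AIS", value], 1)
  expect_equal(out[trait == "IFL", value], 0)

  # two inseminations 30 d apart, calving 280 d after the second -> CR 0
  ins2 <- rbind(ins_row("c1", "2016-02-01"),
                ins_row("c1", "2016-03-02"))
  cv2 <- cv_row("c1", as.character(as.Date("2016-03-02") + 280), 0)
  out2 <- derive_fertility(ins2, cv2, ped)
  expect_equal(out2[trait == "CR", value], 0)
  expect_equal(out2[trait == "IFL", value], 30)
  expect_equal(out2[trait == "AIS", value], 2)

  # gestation 250 d -> excluded
  cv3 <- cv_row("c1", as.character(as.Date("2016-02-01") + 250), 0)
  out3 <- derive_fertility(ins_row("c1", "2016-02-01"), cv3, ped)
  expect_equal(nrow(out3), 0L)

  # inseminated but never calved -> CR 0
  out4 <- derive_fertility(ins_row("c1", "2016-02-01"), cv[0], ped)
  expect_equal(out4[trait == "CR", value], 0)

  # unknown cow id -> warning + skip
  expect_warning(derive_fertility(ins_row("ghost", "2016-02-01"),
                                  cv[0], ped),
                 "unknown")
})

test_that("fertility derivation: lactation gating and CI window", {
  ped <- mk_ped("c1", birth = "2014-01-01")
  d0 <- as.Date("2016-02-01")
  calv1 <- d0 + 280
  ins_l1 <- calv1 + 70
  calv2 <- ins_l1 + 281
  ins <- rbind(ins_row("c1", d0, 0L),
               ins_row("c1", ins_l1, 1L))
  cv <- rbind(cv_row("c1", as.character(calv1), 0),
              cv_row("c1", as.character(calv2), 1))
  out <- derive_fertility(ins, cv, ped)
  ci <- out[trait == "CI"]
  expect_equal(nrow(ci), 1L)
  expect_equal(ci$value, as.numeric(calv2 - calv1))
  expect_equal(ci$parity, 1L)

  # lactation-2 records need lactation-1 information
  ins_l2_only <- rbind(ins_row("c1", d0, 0L),
                       ins_row("c1", calv2 + 70, 2L))
  cv_l2 <- rbind(cv_row("c1", as.character(calv1), 0),
                 cv_row("c1", as.character(calv2), 1))
  out2 <- derive_fertility(ins_l2_only, cv_l2, ped)
  expect_false(2L %in% out2$parity)
})

test_that("NRR56: rules for returns, double records, early calvers", {
  ped <- mk_ped("c1")
  cv0 <- cv_row("c1", "2030-01-01", 0)[0]
  # single insemination -> 1
  out <- derive_nrr56(ins_row("c1", "2016-02-01"), cv0, ped)
  expect_equal(out$value, 1L)
  # re-insemination at day 30 -> 0
  out2 <- derive_nrr56(rbind(ins_row("c1", "2016-02-01"),
                             ins_row("c1", "2016-03-02")), cv0, ped)
  expect_equal(out2$value, 0L)
  # re-insemination at day 2 is discarded: record stays 1
  out3 <- derive_nrr56(rbind(ins_row("c1", "2016-02-01"),
                             ins_row("c1", "2016-02-03")), cv0, ped)
  expect_equal(out3$value, 1L)
  # re-insemination at day 56 is outside the 3-55 return window
  out4 <- derive_nrr56(rbind(ins_row("c1", "2016-02-01"),
                             ins_row("c1", as.character(
                               as.Date("2016-02-01") + 56))), cv0, ped)
  expect_equal(out4$value, 1L)
  # first-insemination-to-calving < 266 d removes the record
  cv <- cv_row("c1", as.character(as.Date("2016-02-01") + 250), 0)
  out5 <- derive_nrr56(ins_row("c1", "2016-02-01"), cv, ped)
  expect_equal(nrow(out5), 0L)
})

test_that("class-minimum enforcement reaches the brute-force fixed
           point, including cascades", {
  tab <- data.table::data.table(
    animal = sprintf("a%02d", 1:29),
    herd = c(rep("h1", 10), rep("h2", 9), rep("h3", 10)),
    value = 1)
  out <- enforce_class_minimum(tab, "herd", 10L)
  expect_equal(sort(unique(out$herd)), c("h1", "h3"))

  # min_n = 1 is the identity
  expect_equal(nrow(enforce_class_minimum(tab, "herd", 1L)), 29L)

  # cascade across two class systems enforced jointly: removing a small
  # joint cell can push another cell under the limit. Brute-force oracle
  # iterates the same rule on a plain data.frame.
  set.seed(42)
  tab2 <- data.table::data.table(
    herd = sample(c("h1", "h2", "h3"), 60, TRUE),
    year = sample(c("y1", "y2"), 60, TRUE), value = 1)
  out2 <- enforce_class_minimum(tab2, c("herd", "year"), 10L)
  oracle <- as.data.frame(tab2)
  repeat {
    cnt <- table(paste(oracle$herd, oracle$year))
    bad <- names(cnt)[cnt < 10]
    if (!length(bad)) break
    oracle <- oracle[!(paste(oracle$herd, oracle$year) %in% bad), ]
  }
  expect_equal(nrow(out2), nrow(oracle))
  expect_equal(sort(paste(out2$herd, out2$year)),
               sort(paste(oracle$herd, oracle$year)))
  expect_warning(enforce_class_minimum(tab2[1:5], c("herd", "year"),
                                       10L),
                 "every record")
})

test_that("infertility phenotype classes", {
  cv <- cv_row("cowA", "2016-03-01", 0)
  cu <- data.table::data.table(cow = c("cowB", "cowC"),
                               reason = c("infertility", "lameness"))
  out <- derive_infertility(cv, cu)
  expect_equal(out[animal == "cowA", value], 1)
  expect_equal(out[animal == "cowB", value], 0)
  expect_false("cowC" %in% out$animal)
})

test_that("derived values satisfy the trait range invariants on random
           synthetic records", {
  params <- sim_params(n_founders = 80L, n_generations = 2L,
                       sires_per_generation = 8L,
                       offspring_per_sire = 15L, n_chromosomes = 1L,
                       markers_per_chromosome = 30L, seed = 77)
  ped <- simulate_pedigree(params)
  pg <- simulate_genotypes(ped, params, list())
  ph <- simulate_phenotypes(ped, pg, list(), params)
  sb <- derive_stillbirth(ph$calvings, ped)
  expect_true(all(sb$value %in% c(0L, 1L)))
  fert <- derive_fertility(ph$inseminations, ph$calvings, ped)
  expect_true(all(fert[trait == "CR", value] %in% c(0, 1)))
  expect_true(all(fert[trait == "CI", value] >= 280 &
                    fert[trait == "CI", value] <= 600))
  expect_true(all(fert[trait == "AIS", value] >= 1 &
                    fert[trait == "AIS", value] <= 8))
  expect_true(all(fert[trait == "IFL", value] >= 0 &
                    fert[trait == "IFL", value] <= 365))
  nr <- derive_nrr56(ph$inseminations, ph$calvings, ped)
  expect_true(all(nr$value %in% c(0L, 1L)))
  expect_true(all(nr$parity %in% 0:3))
})
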