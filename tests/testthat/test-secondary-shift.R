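test_that("secondary shifts are observed minus random coil, with the Gly convention", {
  tab <- coil_table("ADGT")
  prof <- secondary_shifts(tab)
  expect_equal(prof$raw_index, rep(0, 4))  # identity case

  # hand subtraction: +2 on Ala CA
  tab2 <- tab
  tab2$shift_ppm[tab2$residue_type == "A" & tab2$atom == "CA"] <-
    tab2$shift_ppm[tab2$residue_type == "A" & tab2$atom == "CA"] + 2
  prof2 <- secondary_shifts(tab2)
  expect_equal(prof2$d_ca[prof2$residue_type == "A"], 2.0)
  expect_equal(prof2$raw_index[prof2$residue_type == "A"], 2.0)

  # Gly has no CB and raises no error; its index reduces to d_ca
  expect_equal(prof$d_cb[prof$residue_type == "G"], 0)

  # residue without CA stays in the table but undefined
  tab3 <- tab[!(tab$residue_type == "T" & tab$atom == "CA"), ]
  class(tab3) <- class(tab)
  prof3 <- secondary_shifts(tab3)
  expect_true(is.na(prof3$raw_index[prof3$residue_type == "T"]))
})

test_that("secondary_shifts rejects unknown residues and absurd shifts", {
  bad <- shift_table(1, "A", "CA", 52.5)
  bad$residue_type <- "X"
  expect_error(secondary_shifts(bad), "unknown residue type")
  expect_error(shift_table(1, "A", "CA", 300), "column mix-up")
  expect_error(shift_table(1, "G", "CB", 30), "glycine")
  expect_error(shift_table(c(1, 1), "A", c("CA", "CA"), c(52, 53)),
               "duplicate")
})

test_that("three-residue smoothing averages the available window", {
  # interior residue gets the full 3-point mean; the termini average the
  # two members that exist
  expect_equal(unname(smooth_index(c("10" = 0, "11" = 3, "12" = 0))),
               c(1.5, 1, 1.5))
  # constant run stays constant everywhere, including the termini
  run <- stats::setNames(rep(2.5, 6), 20:25)
  expect_equal(unname(smooth_index(run)), rep(2.5, 6))
  # a lone residue degenerates to itself
  expect_equal(unname(smooth_index(c("7" = 4))), 4)
  # a gap-adjacent residue averages over what exists
  gap <- c("1" = 3, "2" = 0, "4" = 6)
  expect_equal(unname(smooth_index(gap)), c(1.5, 1.5, 6))
  # residue with no own value stays undefined
  withna <- c("1" = 1, "2" = NA, "3" = 1)
  expect_true(is.na(smooth_index(withna)[2]))
})

test_that("smoothing is linear over defined residues", {
  set.seed(11)
  for (rep in 1:5) {
    idx <- sort(sample(1:40, 15))
    x <- stats::setNames(rnorm(15), idx)
    y <- stats::setNames(rnorm(15), idx)
    expect_equal(smooth_index(x + y), smooth_index(x) + smooth_index(y))
  }
})

test_that("classification follows the sign rule with a deadband", {
  sm <- c("1" = -2, "2" = 0.3, "3" = 2, "4" = NA)
  expect_equal(unname(classify_secondary(sm, 0.7)),
               c("strand", "coil", "helix", "undefined"))
  # zero deadband: only exact zero can be coil
  set.seed(3)
  sm2 <- stats::setNames(c(rnorm(20), 0), 1:21)
  lab <- classify_secondary(sm2, 0)
  expect_true(all(lab[sm2 > 0] == "helix"))
  expect_true(all(lab[sm2 < 0] == "strand"))
  expect_equal(unname(lab[21]), "coil")
  expect_error(classify_secondary(sm, -1), ">= 0")
})

test_that("a chemokine-like synthetic profile is recovered at structured residues", {
  for (noise in c(0, 1)) {
    g <- gen_shift_table(noise_sd = noise, seed = 42)
    prof <- secondary_structure_profile(g$table)
    structured <- as.integer(names(g$truth)[g$truth != "coil"])
    got <- prof$label[match(structured, prof$residue_index)]
    acc <- mean(got == g$truth[as.character(structured)])
    expect_gte(acc, if (noise == 0) 1 else 0.9)
  }
})
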