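test_that("flip-angle train respects bounds, segments, and overrides", {
  train <- build_flip_angle_train(train_config())
  expect_length(train, 1000)
  expect_gte(min(train), 3.2)
  expect_lte(max(train), 60)
  segs <- attr(train, "segment")
  expect_equal(as.integer(table(segs)[c("FISP", "FLASH")]), c(500L, 500L))
  expect_equal(segs[250], "FISP")
  expect_equal(segs[251], "FLASH")
  expect_equal(segs[501], "FISP")
  expect_equal(segs[751], "FLASH")
  const <- build_flip_angle_train(train_config(custom = rep(10, 1000)))
  expect_true(all(const == 10))
  expect_error(build_flip_angle_train(train_config(custom = rep(90, 1000))),
               "outside")
})

test_that("plain program has the protocol structure", {
  prog <- assemble_program(build_flip_angle_train(train_config()))
  ev <- prog$events
  expect_equal(sum(ev$kind == "excite"), 1000)
  expect_equal(prog$n_readouts, 1000)
  expect_equal(sum(ev$kind == "delay" & ev$crush), 3)   # segment breaks
  expect_equal(prog$tr, 7.5)
  expect_equal(prog$te, 3.5)
  expect_equal(sequence_duration_tr(prog), 1000 + 150)
})

test_that("saturation blocks are scheduled and counted per the protocol", {
  train <- build_flip_angle_train(train_config())
  p25 <- assemble_program(train, mrf_schedule("SpaSatMRF_25"))
  expect_equal(sum(p25$events$kind == "saturation_spatial") / 2, 40)
  expect_equal(sequence_duration_tr(p25), 1150 + 40 * 2)
  pall <- assemble_program(train, mrf_schedule("AllSatMRF_10"))
  expect_equal(sum(pall$events$kind == "saturation_chemical"), 100)
  expect_equal(sequence_duration_tr(pall) - 1150, 100 * 4)
  # inserting blocks never changes the readout count
  expect_equal(p25$n_readouts, 1000)
  expect_equal(pall$n_readouts, 1000)
})

test_that("all five protocol variants build and differ only in saturation", {
  progs <- lapply(c("MRF", "SpaSatMRF_25", "SpaSatMRF_10", "FatSatMRF_10",
                    "AllSatMRF_10"), build_sequence)
  for (p in progs) expect_equal(p$n_readouts, 1000)
  base_ex <- progs[[1]]$events$flip[progs[[1]]$events$kind == "excite"]
  for (p in progs[-1]) {
    ex <- p$events$flip[p$events$kind == "excite"]
    expect_equal(ex, base_ex)
    sat <- p$events$kind %in% c("saturation_spatial", "saturation_chemical")
    expect_gt(sum(sat), 0)
  }
  durs <- vapply(progs, sequence_duration_tr, numeric(1))
  expect_equal(durs, c(1150, 1230, 1350, 1550, 1550))
})

test_that("saturation-block moments match the block duration on every axis", {
  for (nm in c("SpaSatMRF_25", "FatSatMRF_10")) {
    prog <- build_sequence(nm, train_config(lengths = rep(50, 4)))
    ev <- prog$events
    sched <- prog$schedule
    blocks <- which(ev$kind == "delay" & !ev$crush & ev$duration > 0)
    starts <- blocks[seq(1, length(blocks), by = 2)]
    for (b in starts) {
      upto <- which(ev$time > ev$time[b] &
                    ev$time <= ev$time[b] + sched$block_tr * prog$tr &
                    ev$kind == "gradient")
      expect_equal(sum(ev$m_slice[upto]), sched$block_tr)
      expect_equal(sum(ev$m_phase[upto]), 0)   # balanced pair
      expect_equal(sum(ev$m_read[upto]), 0)
    }
  }
})

test_that("radial angle formula: zero-index case, increments, distinctness", {
  expect_equal(radial_angle(0, 0, 1), pi)
  expect_equal(radial_angle(0, 0, 4), pi)
  # consecutive readouts in one shot: constant increment plus alternating pi
  th <- 111.25 * pi / 180
  a <- radial_angle(0:9, 2, 4)
  d <- (diff(a) - pi * rep(c(-1, 1), 5)[1:9]) %% (2 * pi)
  expect_equal(d, rep((4 * th) %% (2 * pi), 9), tolerance = 1e-12)
  # distinctness: the printed golden angle is rational (111.25 = 445/4 deg),
  # so the 4 x 250 spoke set folds onto fewer angles; exact integer oracle
  # in quarter-degrees gives the reference count
  k <- 0:999
  p <- (k %/% 4) %% 2
  exact <- length(unique((445L * k + 720L * (1L - p)) %% 1440L))
  expect_equal(exact, 288)
  angs <- unlist(lapply(0:3, function(l) radial_angle(0:249, l, 4)))
  expect_length(angs, 1000)
  snapped <- round(angs * 720 / pi) %% 1440   # snap to quarter-degrees
  expect_equal(length(unique(snapped)), exact)
})

test_that("band and chemical-window membership decide saturation", {
  sched <- saturation_schedule(25, 2, spatial = TRUE, chemical = FALSE,
                               band_positions = list(
                                 c(center = 80, thickness = 40)))
  water <- spin_system(1000, 80)
  expect_true(band_affects_spin(sched, water, position = 70))
  expect_false(band_affects_spin(sched, water, position = 40))
  chem <- saturation_schedule(10, 4, spatial = FALSE, chemical = TRUE)
  fat <- spin_system(300, 70, delta_f = -440, population = "fat")
  expect_true(band_affects_spin(chem, fat, position = 0))
  expect_false(band_affects_spin(chem, water, position = 0))
  expect_false(band_affects_spin(NULL, fat))
  expect_equal(saturation_hits(chem, fat), c(spatial = FALSE, chemical = TRUE))
})

test_that("schedule and program invariants are enforced", {
  expect_error(saturation_schedule(25, 3), "block_tr")
  expect_error(saturation_schedule(2, 4), "period_tr")
  expect_error(saturation_schedule(25, 2, band_thickness = 200), "150")
  expect_error(assemble_program(short_train(10), tr = 3, te = 3.5),
               "te must be smaller")
  expect_equal(sequence_duration_tr(
    sequence_program(data.frame(kind = character(0), time = numeric(0),
                                duration = numeric(0)),
                     tr = 7.5, te = 3.5, validate = FALSE)), 0)
})

test_that("event listing exports round-trip through CSV", {
  prog <- assemble_program(short_train(5), mrf_schedule("SpaSatMRF_10"))
  tab <- program_event_table(prog)
  expect_s3_class(tab, "tbl_df")
  path <- withr::local_tempfile(fileext = ".csv")
  write_program_csv(prog, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(prog$events))
  expect_equal(back$kind, prog$events$kind)
})
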