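test_that("equilibrium state has unit z at the zero configuration only", {
  st <- equilibrium_state("slice", 10)
  expect_equal(epg_z(st, 0), 1 + 0i)
  expect_equal(sum(Mod(st$Z)), 1)
  expect_equal(sum(Mod(st$F)), 0)
  st2 <- equilibrium_state(c("slice", "phase"), 5)
  expect_equal(epg_z(st2, c(0, 0)), 1 + 0i)
  expect_equal(acquire(st2), 0 + 0i)
  expect_error(equilibrium_state("slice", 0), "max_order")
})

test_that("basic RF rotations: excitation and refocusing", {
  st <- rf_rotation(equilibrium_state("slice", 6), 90, 0)
  expect_equal(Mod(epg_f_plus(st, 0)), 1, tolerance = 1e-12)
  expect_equal(Mod(epg_z(st, 0)), 0, tolerance = 1e-12)
  # perfect refocusing mirrors the transverse order
  st2 <- equilibrium_state("slice", 6)
  st2$F[6 + 1 + 3] <- 1 + 0i          # F(+3) = 1
  st2$Z[] <- 0
  st3 <- rf_rotation(st2, 180, 0)
  expect_equal(Mod(epg_f_plus(st3, -3)), 1, tolerance = 1e-12)
})

test_that("arbitrary RF rotation matches the isochromat rotation oracle", {
  for (seed in 1:3) {
    st <- random_state(seed = seed)
    flip <- c(37, 113, 211)[seed]
    phase <- c(13, 251, 77)[seed]
    got <- rf_rotation(st, flip, phase)
    want <- rf_oracle(st, flip, phase)
    expect_lt(max(Mod(got$F - want$F)), 1e-10)
    expect_lt(max(Mod(got$Z - want$Z)), 1e-10)
  }
})

test_that("RF rotation conserves the total magnetisation norm", {
  for (seed in 1:5) {
    st <- random_state(seed = seed)
    n0 <- state_norm2(st)
    st2 <- rf_rotation(st, runif(1, 0, 360), runif(1, 0, 360))
    expect_equal(state_norm2(st2), n0, tolerance = 1e-12)
  }
})

test_that("gradient shifts compose, invert, and leave z untouched", {
  st <- random_state(seed = 4)
  fwd <- gradient_shift(st, "slice", 1)
  back <- gradient_shift(fwd, "slice", -1)
  K <- st$max_order[[1]]
  keep <- abs(-K:K) < K
  expect_equal(back$F[keep], st$F[keep])
  expect_equal(fwd$Z, st$Z)
  two <- gradient_shift(st, "slice", 2)
  twice <- gradient_shift(gradient_shift(st, "slice", 1), "slice", 1)
  expect_equal(two$F, twice$F)
  expect_error(gradient_shift(st, "phase", 1), "not tracked")
})

test_that("relaxation follows the closed-form exponentials", {
  sp <- spin_system(1000, 100, delta_f = 40)
  st <- rf_rotation(equilibrium_state("slice", 4), 90, 0)
  expect_equal(relax(st, sp, 0)$F, st$F)
  half <- relax(st, sp, 100 * log(2))
  expect_equal(Mod(epg_f_plus(half, 0)), 0.5, tolerance = 1e-12)
  # off-resonance phase and decay together
  expect_equal(epg_f_plus(relax(st, sp, 10), 0),
               epg_f_plus(st, 0) * exp(-10 / 100) *
                 exp(-2i * pi * 40 * 10 * 1e-3), tolerance = 1e-12)
  # long interval recovers equilibrium
  rec <- relax(st, sp, 1e7)
  expect_equal(epg_z(rec, 0), 1 + 0i, tolerance = 1e-12)
  expect_equal(sum(Mod(rec$F)), 0, tolerance = 1e-12)
  expect_error(relax(st, sp, -1), "non-negative")
})

test_that("acquire returns the rho-scaled zero-order transverse state", {
  expect_equal(acquire(equilibrium_state("slice", 4)), 0 + 0i)
  sp <- spin_system(1000, 100, rho = 2i)
  st <- rf_rotation(equilibrium_state("slice", 4), 90, 0)
  expect_equal(Mod(acquire(st, sp)), 2, tolerance = 1e-12)
})

test_that("saturation module saturates in-band spins and is transparent otherwise", {
  sp <- spin_system(1000, 80)
  eq <- equilibrium_state(c("slice", "phase"), c(8, 4))
  sat <- apply_saturation_module(eq, 90, duration = 15,
                                 spoil_steps_per_axis = c(slice = 2L),
                                 spin = sp, affects_spin = TRUE)
  # longitudinal store reduced to within-block regrowth, no acquired signal
  expect_lt(Mod(epg_z(sat, c(0, 0))), 1 - exp(-15 / 1000) + 1e-9)
  expect_equal(Mod(acquire(sat)), 0)
  # transverse energy parked at nonzero phase orders
  f <- sat$F
  f[, sat$max_order[["phase"]] + 1] <- 0    # zero-phase column
  expect_gt(sum(Mod(f)^2), 0.5)
  # transparency: equals relax + slice shift of an empty block
  st <- rf_rotation(eq, 35, 10)
  a <- apply_saturation_module(st, 90, duration = 15,
                               spoil_steps_per_axis = c(slice = 2L),
                               spin = sp, affects_spin = FALSE)
  b <- gradient_shift(relax(st, sp, 15), "slice", 2)
  expect_equal(a$F, b$F, tolerance = 1e-12)
  expect_equal(a$Z, b$Z, tolerance = 1e-12)
  expect_error(apply_saturation_module(st, 90, duration = 0, spin = sp,
                                       affects_spin = TRUE), "positive")
})

test_that("single-echo fingerprint matches the closed form", {
  prog <- decay_program(3.5)
  fp <- simulate_fingerprint(prog, spin_system(1e7, 100))
  expect_equal(Mod(fp[1]), exp(-3.5 / 100), tolerance = 1e-9)
})

test_that("inversion recovery changes sign near T1 log(2)", {
  t1 <- 600
  prog <- ir_program(n = 60, tr = 20, te = 0.5)
  fp <- simulate_fingerprint(prog, spin_system(t1, 100))
  # signal along -i; recover the longitudinal sign
  mz <- Re(1i * fp)
  flip_idx <- which(diff(sign(mz)) > 0)[1]
  times <- prog$events$time[prog$events$kind == "readout"]
  expect_lt(abs(times[flip_idx] - t1 * log(2)), 60)
})

test_that("zero rho yields an all-zero fingerprint", {
  prog <- assemble_program(short_train(10))
  fp <- simulate_fingerprint(prog, spin_system(1000, 80, rho = 0))
  expect_equal(max(Mod(fp)), 0)
})

test_that("compiled and reference engines agree exactly", {
  prog <- assemble_program(short_train(15), mrf_schedule("SpaSatMRF_10"))
  sp <- spin_system(900, 70, b1_scale = 0.9, delta_f = 15)
  a <- simulate_fingerprint(prog, sp, max_order = 24, engine = "cpp")
  b <- simulate_fingerprint(prog, sp, max_order = 24, engine = "R")
  expect_lt(max(Mod(a - b)), 1e-13)
})

test_that("EPG signal equals the isochromat-ensemble mean (integer spoilers)", {
  prog <- assemble_program(short_train(15), mrf_schedule("SpaSatMRF_10"))
  for (sp in list(spin_system(1000, 60),
                  spin_system(700, 80, b1_scale = 0.85, delta_f = 30))) {
    fp <- simulate_fingerprint(prog, sp, max_order = 32)
    iso <- isochromat_fingerprint(prog, sp, n_isochromats = 128)
    expect_lt(max(Mod(fp - iso)) / max(Mod(fp)), 1e-6)
  }
})

test_that("FLASH quadratic RF spoiling differs from FISP and from ideal spoiling", {
  tc <- train_config(lengths = c(30, 30), segments = c("FISP", "FLASH"),
                     peaks = c(40, 40))
  prog <- assemble_program(build_flip_angle_train(tc))
  sp <- spin_system(1000, 80)
  lit <- simulate_fingerprint(prog, sp)
  ideal <- simulate_fingerprint(prog, sp, ideal_spoiling = TRUE)
  expect_equal(lit[1:30], ideal[1:30], tolerance = 1e-12)  # FISP untouched
  expect_gt(max(Mod(lit[31:60] - ideal[31:60])), 1e-4)     # FLASH differs
})

test_that("doubling the truncation order leaves tissue-range signals unchanged", {
  prog <- assemble_program(short_train(25), mrf_schedule("SpaSatMRF_25"))
  sp <- spin_system(1500, 60)
  a <- simulate_fingerprint(prog, sp, max_order = 64)
  b <- simulate_fingerprint(prog, sp, max_order = 128)
  expect_lt(max(Mod(a - b)), 1e-9)
  expect_lt(attr(a, "dropped"), 1e-8)
})
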