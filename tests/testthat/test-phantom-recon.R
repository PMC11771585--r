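test_that("flow phantom construction and seeded reproducibility", {
  ph <- make_flow_phantom(48)
  expect_length(ph$regions, 3)
  expect_equal(vapply(ph$regions, `[[`, "", "name"),
               c("body", "tube_upper", "tube_lower"))
  expect_equal(ph$pixel_mm, 240 / 48)
  # disjoint masks
  overlap <- Reduce(`+`, lapply(ph$regions, function(r) r$mask + 0L))
  expect_lte(max(overlap), 1)
  expect_error(make_flow_phantom(48, tube_offset_mm = 130),
               "outside the field of view")
  prog <- assemble_program(short_train(10))
  k1 <- simulate_radial_acquisition(ph, prog, seed = 5, noise_sd = 0.01)
  k2 <- simulate_radial_acquisition(ph, prog, seed = 5, noise_sd = 0.01)
  expect_identical(k1$spokes, k2$spokes)
  k3 <- simulate_radial_acquisition(ph, prog, seed = 6, noise_sd = 0.01)
  expect_gt(max(Mod(k1$spokes - k3$spokes)), 0)
})

test_that("static tubes: zero instability reduces flow to a bright region", {
  ph <- make_flow_phantom(32, amplitude_pulsation = 0,
                          phase_pulsation = 0, phase_instability = 0)
  prog <- assemble_program(short_train(5))
  fps <- phantom_fingerprints(ph, prog)
  k1 <- simulate_radial_acquisition(ph, prog, seed = 1)
  k2 <- simulate_radial_acquisition(ph, prog, seed = 99)
  expect_equal(k1$spokes, k2$spokes)      # nothing stochastic remains
})

test_that("multicompartment phantom spans the stated composition", {
  ph <- make_multicompartment_phantom(64)
  expect_length(ph$regions, 13)
  pops <- vapply(ph$regions, function(r) r$spin$population, "")
  expect_equal(sum(pops == "fat"), 2)
  t2s <- vapply(ph$regions, function(r) r$spin$t2, numeric(1))[pops == "water"]
  t2s <- t2s[-1]                          # drop the saline background
  expect_equal(sum(t2s > 200), 2)
  expect_lt(min(t2s), 50)
  dfs <- vapply(ph$regions, function(r) r$spin$delta_f, numeric(1))
  expect_true(all(dfs[pops == "fat"] != 0))
  expect_true(all(dfs[pops == "water"] == 0))
})

test_that("spoke synthesis equals a direct DFT of the composite image", {
  ph <- make_flow_phantom(32, amplitude_pulsation = 0,
                          phase_pulsation = 0, phase_instability = 0)
  prog <- assemble_program(short_train(5))
  ks <- simulate_radial_acquisition(ph, prog, seed = 1)
  fps <- phantom_fingerprints(ph, prog)
  n <- 32
  # direct R oracle for one spoke and readout
  i <- 7
  img <- matrix(0 + 0i, n, n)
  for (r in seq_along(ph$regions)) img[ph$regions[[r]]$mask] <- fps[r, i]
  idx <- which(Mod(img) > 0, arr.ind = TRUE)
  xy <- cbind(idx[, 2] - 1 - n / 2, idx[, 1] - 1 - n / 2)
  for (j in c(1, 17, 30)) {
    kx <- ks$tvals[j] * cos(ks$angles[i])
    ky <- ks$tvals[j] * sin(ks$angles[i])
    want <- sum(img[idx] * exp(-1i * (kx * xy[, 1] + ky * xy[, 2])))
    expect_equal(ks$spokes[i, j], want, tolerance = 1e-10)
  }
  # zero-signal phantom gives all-zero spokes
  ph0 <- ph
  for (r in 1:3) ph0$regions[[r]]$spin$rho <- 0 + 0i
  k0 <- simulate_radial_acquisition(ph0, prog, seed = 1)
  expect_equal(max(Mod(k0$spokes)), 0)
})

test_that("adjoint reconstruction: rank-1 reduction, Parseval, fidelity", {
  n <- 64
  x <- ((0:(n - 1)) - n / 2)
  g <- function(cx, cy, s) outer(x, x, function(yy, xx)
    exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * s^2)))
  img <- g(5, -8, 7) + 0.6 * g(-10, 10, 5)
  nsp <- 128
  ang <- (0:(nsp - 1)) * pi / nsp
  tv <- ((0:(n - 1)) - n / 2) * 2 * pi / n
  idx <- which(img != 0, arr.ind = TRUE)
  xy <- cbind(idx[, 2] - 1 - n / 2, idx[, 1] - 1 - n / 2)
  G <- satmrf:::spoke_dft_cpp(xy, as.complex(img[idx]), ang, tv)
  ks <- structure(list(spokes = G, angles = ang, times = seq_len(nsp),
                       tvals = tv, matrix = n, fov_mm = 240,
                       pixel_mm = 240 / n), class = "radial_kspace")
  basis <- matrix(1 + 0i, nsp, 1)          # static series: flat basis
  rec <- Re(reconstruct_subspace_images(ks, basis)[, , 1])
  expect_gt(cor(as.vector(rec), as.vector(img)), 0.99)
  # energy bookkeeping: density-compensated k-space energy matches image
  w <- density_compensation(ks)
  ek <- sum(rep(w, each = nsp) * Mod(G)^2) / (2 * pi)^2
  expect_lt(abs(ek / sum(img^2) - 1), 0.1)
  # structural fidelity: on a complete Cartesian sampling the adjoint with
  # uniform cell weights is the exact inverse DFT of the same machinery
  kk <- ((0:(n - 1)) - n / 2) * 2 * pi / n
  kxc <- as.vector(outer(kk, rep(1, n)))
  kyc <- as.vector(outer(rep(1, n), kk))
  ph_k <- exp(-1i * (outer(kxc, xy[, 1]) + outer(kyc, xy[, 2])))
  Sc <- as.vector(ph_k %*% img[idx])
  cart <- satmrf:::spoke_adjoint_cpp(matrix(Sc * (2 * pi / n)^2, ncol = 1),
                                     kxc, kyc, n) / (2 * pi)^2
  cart <- Re(cart[, , 1])
  expect_gt(ssim_index(cart, img), 0.95)
  expect_lt(max(abs(cart - img)), 1e-10)
  expect_error(reconstruct_subspace_images(ks, matrix(1, 10, 1)), "basis")
})

test_that("matched-filter combination reduces to identity for one coil", {
  n <- 16
  imgs <- array(stats::rnorm(n * n * 2) + 1i * stats::rnorm(n * n * 2),
                c(n, n, 2))
  sens1 <- array(1 + 0i, c(n, n, 1))
  expect_equal(matched_filter_combine(list(imgs), sens1), imgs)
  # two coils with smooth sensitivities recover the underlying image
  s1 <- outer(seq(0.5, 1.5, length.out = n), rep(1, n))
  s2 <- outer(seq(1.5, 0.5, length.out = n), rep(1, n))
  sens2 <- array(c(s1, s2) + 0i, c(n, n, 2))
  coil_imgs <- list(array(rep(s1, 2), c(n, n, 2)) * imgs,
                    array(rep(s2, 2), c(n, n, 2)) * imgs)
  got <- matched_filter_combine(coil_imgs, sens2)
  expect_equal(got, imgs, tolerance = 1e-10)
})

test_that("matching identifies noiseless queries and flags empty voxels", {
  grid <- parameter_grid(build_geometric_grid(700, 6, 15),
                         build_geometric_grid(45, 6, 15), c(48, 72))
  prog <- assemble_program(short_train(20))
  dict <- compress_svd(simulate_dictionary(prog, grid), 6)
  ne <- nrow(dict$compressed)
  imgs <- array(0 + 0i, c(1, ne + 1, 6))
  imgs[1, seq_len(ne), ] <- dict$compressed * 2.5   # rho scale
  maps <- match_maps(imgs, dict)
  expect_equal(as.vector(maps$t1_map[1, seq_len(ne)]),
               dict$grid$entries$t1)
  expect_equal(as.vector(maps$t2_map[1, seq_len(ne)]),
               dict$grid$entries$t2)
  expect_equal(Mod(maps$rho_map[1, 1]), 2.5, tolerance = 1e-8)
  expect_true(all(abs(maps$correlation_map[1, seq_len(ne)] - 1) < 1e-10))
  # all-zero voxel
  expect_false(maps$matched[1, ne + 1])
  expect_equal(maps$correlation_map[1, ne + 1], 0)
  expect_true(is.na(maps$t1_map[1, ne + 1]))
  expect_error(match_maps(imgs[, , 1:3, drop = FALSE], dict), "rank")
})

test_that("ROI statistics and relative differences behave", {
  maps <- structure(list(t1_map = matrix(1000, 8, 8),
                         t2_map = matrix(50, 8, 8),
                         b1_map = matrix(60, 8, 8),
                         rho_map = matrix(1 + 0i, 8, 8),
                         correlation_map = matrix(1, 8, 8),
                         matched = matrix(TRUE, 8, 8)),
                    class = "parameter_maps")
  lab <- matrix(0L, 8, 8); lab[1:4, ] <- 1L; lab[5:8, ] <- 2L
  st <- roi_statistics(maps, lab)
  expect_true(all(st$sd == 0))
  expect_equal(st$mean[st$map == "t1"], c(1000, 1000))
  rd <- relative_difference(st, st)
  expect_true(all(rd$rel_diff == 0))
  expect_error(roi_statistics(maps, matrix(0L, 8, 8)), "no non-empty")
})

test_that("chemical saturation suppresses fat-region image intensity", {
  ph <- make_multicompartment_phantom(48)
  tc <- train_config(lengths = rep(50, 4))
  prog_mrf <- build_sequence("MRF", tc)
  prog_fat <- build_sequence("FatSatMRF_10", tc)
  ks_m <- simulate_radial_acquisition(ph, prog_mrf, seed = 3)
  ks_f <- simulate_radial_acquisition(ph, prog_fat, seed = 3)
  nro <- prog_mrf$n_readouts
  basis <- matrix(1 / sqrt(nro) + 0i, nro, 1)
  im_m <- Mod(reconstruct_subspace_images(ks_m, basis)[, , 1])
  im_f <- Mod(reconstruct_subspace_images(ks_f, basis)[, , 1])
  fat <- ph$regions[[12]]$mask | ph$regions[[13]]$mask
  water <- ph$regions[[2]]$mask
  expect_lt(mean(im_f[fat]), 0.7 * mean(im_m[fat]))
  # water compartments keep their signal
  expect_gt(mean(im_f[water]), 0.7 * mean(im_m[water]))
})
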