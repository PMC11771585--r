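# shared fixtures: short trains, toy programs, independent oracles

short_train <- function(per_segment = 25) {
  build_flip_angle_train(train_config(lengths = rep(per_segment, 4)))
}

event_row <- function(kind, time, flip = NA_real_, rf_phase = NA_real_,
                      duration = 0, m_slice = 0L, m_phase = 0L,
                      m_read = 0L, readout_angle = NA_real_,
                      segment = NA_character_, crush = FALSE,
                      band = NA_integer_) {
  data.frame(kind = kind, time = time, flip = flip, rf_phase = rf_phase,
             duration = duration, m_slice = m_slice, m_phase = m_phase,
             m_read = m_read, readout_angle = readout_angle,
             segment = segment, crush = crush, band = band,
             stringsAsFactors = FALSE)
}

# single excitation followed by readouts at the given times (free decay)
decay_program <- function(tes, flip = 90, tr = 10000) {
  rows <- rbind(
    event_row("excite", 0, flip = flip, rf_phase = 0),
    do.call(rbind, lapply(tes, function(t)
      event_row("readout", t, rf_phase = 0))))
  sequence_program(rows, tr = tr, te = tes[1], name = "decay",
                   validate = FALSE)
}

# inversion, then a ladder of small-flip excite/readout pairs
ir_program <- function(n, tr, te, flip = 4) {
  rows <- list(event_row("inversion", 0, flip = 180, rf_phase = 0))
  t <- tr
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- event_row("excite", t, flip = flip,
                                           rf_phase = 0)
    rows[[length(rows) + 1L]] <- event_row("readout", t + te, rf_phase = 0)
    rows[[length(rows) + 1L]] <- event_row("gradient", t + tr, m_slice = 1L)
    t <- t + tr
  }
  sequence_program(do.call(rbind, rows), tr = tr, te = te, name = "ir")
}

# random single-axis EPG state reached from equilibrium by random events
random_state <- function(max_order = 6, n_events = 12, seed = 1) {
  set.seed(seed)
  st <- equilibrium_state("slice", max_order)
  sp <- spin_system(800, 80, delta_f = 17)
  for (i in seq_len(n_events)) {
    op <- sample(3, 1)
    if (op == 1) st <- rf_rotation(st, runif(1, 0, 180), runif(1, 0, 360))
    else if (op == 2) st <- gradient_shift(st, "slice", sample(-2:2, 1))
    else st <- relax(st, sp, runif(1, 0, 15))
  }
  st
}

# independent oracle for the RF rotation: transform the configuration bank
# to an isochromat ensemble, rotate each isochromat with an explicit 3x3
# Bloch matrix, and transform back.
rf_oracle <- function(state, flip, phase) {
  K <- state$max_order[[1]]
  N <- 8L * K + 4L
  p <- (seq_len(N) - 1) / N
  ks <- -K:K
  ph <- exp(2i * pi * outer(p, ks))          # N x orders
  mplus <- ph %*% state$F
  mz <- ph %*% state$Z
  a <- flip * pi / 180
  pr <- phase * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  R <- rz(pr) %*% rx %*% rz(-pr)
  M <- rbind((t(mplus) + t(Conj(mplus))) / 2,        # complex Mx
             (t(mplus) - t(Conj(mplus))) / 2i,       # complex My
             t(mz))
  Mr <- R %*% M
  mplus2 <- t(Mr[1, ] + 1i * Mr[2, ])
  mz2 <- t(Mr[3, ])
  inv <- Conj(ph) / N
  out <- state
  out$F <- as.vector(t(inv) %*% t(mplus2))
  out$Z <- as.vector(t(inv) %*% t(mz2))
  out
}

# simple mean-covariance SSIM over sliding windows
ssim_index <- function(a, b, win = 7) {
  L <- max(abs(b))
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  n <- nrow(a)
  vals <- c()
  for (i in seq(1, n - win + 1, by = 3)) {
    for (j in seq(1, n - win + 1, by = 3)) {
      x <- a[i:(i + win - 1), j:(j + win - 1)]
      y <- b[i:(i + win - 1), j:(j + win - 1)]
      mx <- mean(x); my <- mean(y)
      vx <- stats::var(as.vector(x)); vy <- stats::var(as.vector(y))
      cxy <- stats::cov(as.vector(x), as.vector(y))
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                        ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# conjugate-mirror Conj(F(-k)) of the full state for invariant checks
state_norm2 <- function(st) sum(Mod(st$F)^2) + sum(Mod(st$Z)^2)
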