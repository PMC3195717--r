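test_that("delta_energy subtracts elementwise and checks alignment", {
  tr <- energy_trace(c(0, 10, 20), matrix(1:9, 3))
  expect_equal(delta_energy(tr, tr)$delta, matrix(0, 3, 3))
  tr2 <- energy_trace(c(0, 10, 20), matrix(1:9, 3) + 1)
  expect_equal(delta_energy(tr2, tr)$delta, matrix(1, 3, 3))
  tr3 <- energy_trace(c(0, 10, 30), matrix(1:9, 3))
  expect_error(delta_energy(tr3, tr), class = "enerdiss_alignment_error")
  tr4 <- energy_trace(c(0, 10, 20), matrix(1:12, 4))
  expect_error(delta_energy(tr4, tr), class = "enerdiss_alignment_error")
})

make_delta <- function(mat, times = (seq_len(ncol(mat)) - 1) * 10) {
  structure(list(times = times, delta = mat),
            class = "delta_energy_trace")
}

test_that("threshold-plus-sustain detection behaves per definition", {
  # all-zero delta: only the perturbed residue responds, at 0 fs
  d0 <- make_delta(matrix(0, 3, 20))
  p0 <- detect_response_times(d0, detection_policy(), perturbed_set = 2)
  expect_equal(as.numeric(p0), c(NA, 0, NA))
  # step to 1.0 at frame 11 (0-based frame 10), theta 0.5, m 3
  row <- c(rep(0, 10), rep(1, 10))
  d1 <- make_delta(rbind(row, 0))
  p1 <- detect_response_times(d1, detection_policy(0.5, 3),
                              perturbed_set = 2)
  expect_equal(as.numeric(p1)[1], 100)
  # single-frame spike never sustains m = 3
  spike <- rep(0, 20); spike[6] <- 5
  d2 <- make_delta(rbind(spike, 0))
  p2 <- detect_response_times(d2, detection_policy(0.5, 3),
                              perturbed_set = 2)
  expect_true(is.na(as.numeric(p2)[1]))
  # but does trigger with m = 1
  p3 <- detect_response_times(d2, detection_policy(0.5, 1),
                              perturbed_set = 2)
  expect_equal(as.numeric(p3)[1], 50)
})

test_that("relative mode scales thresholds by control noise", {
  set.seed(1)
  noise <- matrix(rnorm(2 * 50, sd = c(0.01, 1)), 2, 50)
  ctrl <- make_delta(noise)
  sig <- matrix(0, 2, 50)
  sig[, 26:50] <- 0.5   # same signal for both residues
  d <- make_delta(sig)
  pol <- detection_policy(mode = "relative", k_noise = 3)
  p <- detect_response_times(d, pol, perturbed_set = 1, control = ctrl)
  # residue 2's noise scale (~1) makes 0.5 sub-threshold; residue 1 fires
  expect_true(is.na(as.numeric(p)[2]))
  expect_error(detect_response_times(d, pol, perturbed_set = 1),
               class = "enerdiss_policy_error")
})

test_that("detector is monotone in theta and sustain", {
  set.seed(7)
  for (rep in 1:5) {
    mat <- matrix(abs(rnorm(6 * 40, sd = 0.5)), 6, 40)
    mat[, 1:5] <- 0
    d <- make_delta(mat)
    base <- as.numeric(detect_response_times(
      d, detection_policy(0.2, 2), perturbed_set = 1))
    for (pol in list(detection_policy(0.4, 2),
                     detection_policy(0.2, 4))) {
      harder <- as.numeric(detect_response_times(d, pol,
                                                 perturbed_set = 1))
      ok <- is.na(harder) | (!is.na(base) & harder >= base)
      expect_true(all(ok[-1]))
      # never converts nonresponsive -> responsive
      expect_true(all(is.na(harder[is.na(base)])))
    }
  }
})

test_that("dissipation_curve equals the brute-force count", {
  prof <- structure(c(0, 10, 20), perturbed = 1L,
                    times = seq(0, 30, 10), class = "response_profile")
  expect_equal(dissipation_curve(prof, seq(0, 30, 10))$NR,
               c(1, 2, 3, 3))
  # all nonresponsive except one perturbed
  prof2 <- structure(c(0, NA, NA), perturbed = 1L, times = c(0, 10),
                     class = "response_profile")
  expect_true(all(dissipation_curve(prof2)$NR == 1))
  # randomized property: matches direct enumeration, monotone, <= N
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    dt <- sample(c(NA, seq(0, 500, 10)), n, replace = TRUE)
    dt[1] <- 0
    prof <- structure(dt, perturbed = 1L, times = seq(0, 500, 10),
                      class = "response_profile")
    grid <- sort(sample(seq(0, 600, 5), 20))
    cv <- dissipation_curve(prof, grid)
    brute <- vapply(grid, function(tt) sum(!is.na(dt) & dt <= tt), 1)
    expect_equal(cv$NR, as.integer(brute))
    expect_true(all(diff(cv$NR) >= 0))
    expect_true(all(cv$NR <= n))
  }
})

test_that("profile built from the sigmoid model crosses midway at t0", {
  # construction oracle: response times drawn so counts follow the
  # two-state Boltzmann curve with t0 = 500, dt = 100
  grid <- seq(0, 1000, 5)
  target <- round(boltzmann_nr(grid, 1, 447, 500, 100))
  dt <- rep(NA_real_, 447)
  assigned <- 0
  for (k in seq_along(grid)) {
    add <- target[k] - assigned
    if (add > 0) dt[(assigned + 1):(assigned + add)] <- grid[k]
    assigned <- max(assigned, target[k])
  }
  prof <- structure(dt, perturbed = 1L, times = grid,
                    class = "response_profile")
  cv <- dissipation_curve(prof, grid)
  crossing <- grid[which(cv$NR >= 224)[1]]
  expect_lt(abs(crossing - 500), 10)
})

test_that("response times respect spring-graph causality on toys", {
  pr <- toy_pair(n = 15, residues = 1, factor = 5, n_steps = 800)
  delta <- delta_energy(pr$perturbed, pr$reference)
  prof <- detect_response_times(delta, detection_policy(),
                                perturbed_set = 1)
  dist <- bfs_distance(15, pr$network$springs, 1)
  dt <- as.numeric(prof)
  adj <- pr$network$springs
  for (i in which(!is.na(dt) & dist >= 1)) {
    nb <- c(adj$j[adj$i == i], adj$i[adj$j == i])
    closer <- nb[dist[nb] == dist[i] - 1]
    expect_true(any(dt[closer] <= dt[i], na.rm = TRUE))
  }
})

test_that("region means use responsive residues only (population SD)", {
  prof <- structure(c(100, 300, NA, 50), perturbed = integer(0),
                    times = seq(0, 300, 50), class = "response_profile")
  ann <- synth_annotation(4, c(0.5, 1), c("reg", "cat"))
  out <- region_mean_response(prof, ann)
  reg <- out[out$region == "reg", ]
  expect_equal(reg$mean, 200)
  expect_equal(reg$sd, 100)   # population SD of {100, 300}
  cat_row <- out[out$region == "cat", ]
  expect_equal(cat_row$mean, 50)
  expect_equal(cat_row$n_nonresponsive, 1)
  expect_equal(out[out$region == "All", ]$n_responsive, 3)
})

test_that("perturbing one end orders region means on a toy chain", {
  # simulation oracle for the qualitative regulatory < catalytic ordering
  pr <- toy_pair(n = 16, residues = 1, factor = 5, n_steps = 6000)
  delta <- delta_energy(pr$perturbed, pr$reference)
  prof <- detect_response_times(delta, detection_policy(),
                                perturbed_set = 1)
  ann <- synth_annotation(16, c(0.5, 1), c("regulatory", "catalytic"))
  out <- region_mean_response(prof, ann)
  expect_lt(out$mean[out$region == "regulatory"],
            out$mean[out$region == "catalytic"])
})
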