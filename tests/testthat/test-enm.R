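test_that("build_network applies the distance cutoff", {
  s <- protein_structure(1:3, rep("GLY", 3), rep("A", 3),
                         xyz = rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  expect_equal(nrow(build_network(s, cutoff = 6)$springs), 2)
  net <- build_network(s, cutoff = 11)
  expect_equal(nrow(net$springs), 3)
  expect_equal(net$springs$r0, c(5, 10, 5))
  # fully connected case: n(n-1)/2
  g <- synth_structure(8, "globule", seed = 1, packing = 0.05)
  expect_equal(nrow(build_network(g, cutoff = 1e4)$springs), 8 * 7 / 2)
})

test_that("isolated beads trigger a warning", {
  s <- protein_structure(1:3, rep("GLY", 3), rep("A", 3),
                         xyz = rbind(c(0, 0, 0), c(3.8, 0, 0),
                                     c(100, 0, 0)))
  expect_warning(build_network(s, cutoff = 6), "isolated")
})

test_that("init_state is deterministic and respects T = 0", {
  net <- build_network(synth_structure(10, "chain"))
  expect_equal(init_state(net, 0, seed = 1)$vel, matrix(0, 10, 3))
  s1 <- init_state(net, 310, seed = 5)
  s2 <- init_state(net, 310, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, init_state(net, 310, seed = 6)))
  # net momentum removed
  expect_equal(colSums(s1$vel * net$mass), rep(0, 3), tolerance = 1e-12)
})

test_that("mean initial kinetic energy matches equipartition", {
  # oracle: <KE> = (3/2) (N-1) kB T after momentum removal (3 dof gone)
  n <- 40; temp <- 310
  net <- build_network(synth_structure(n, "helix"))
  kb <- 1.987204259e-3
  ke <- vapply(1:200, function(seed) {
    st <- init_state(net, temp, seed)
    sum(0.5 * net$mass * st$vel^2) / 4.184e-4
  }, numeric(1))
  expected <- 1.5 * (n - 1) * kb * temp
  expect_equal(mean(ke), expected, tolerance = 0.03)
})

test_that("apply_perturbation scales velocity, KE by exactly f^2", {
  net <- build_network(synth_structure(12, "chain"))
  st <- init_state(net, 310, seed = 2)
  expect_identical(apply_perturbation(st, 3, 1), st)
  p <- apply_perturbation(st, 3, 4)
  expect_equal(p$vel[3, ], st$vel[3, ] * 4)
  expect_identical(p$vel[-3, ], st$vel[-3, ])
  ke <- function(s, i) 0.5 * net$mass[i] * sum(s$vel[i, ]^2)
  expect_equal(ke(p, 3), 16 * ke(st, 3))
  # multi-residue bookkeeping: total energy up by (f^2-1) * sum KE
  p2 <- apply_perturbation(st, c(2, 5), 2)
  expect_equal(total_energy(net, p2) - total_energy(net, st),
               3 * (ke(st, 2) + ke(st, 5)) / 4.184e-4)
  expect_error(apply_perturbation(st, 99, 2),
               class = "enerdiss_index_error")
})

test_that("a resting state at mechanical equilibrium is a fixed point", {
  net <- build_network(synth_structure(6, "chain"))
  st <- init_state(net, 0, seed = 0)
  frames <- integrate_nve(net, st, simulation_config(n_steps = 50,
                                                     save_interval = 10))
  for (fr in frames) expect_equal(fr$pos, st$pos)
})

test_that("two-bead oscillator matches the analytic frequency", {
  m1 <- 110; m2 <- 80; k <- 1; d <- 0.5
  net <- two_bead_network(m1, m2, k = k, stretch = d)
  omega <- sqrt(k * 4.184e-4 * (1 / m1 + 1 / m2))   # rad/fs
  period <- 2 * pi / omega
  st <- structure(list(pos = net$xyz0, vel = matrix(0, 2, 3), time = 0),
                  class = "system_state")
  cfg <- simulation_config(n_steps = ceiling(period * 3),
                           save_interval = 1)
  frames <- integrate_nve(net, st, cfg)
  sep <- vapply(frames, function(f) f$pos[2, 1] - f$pos[1, 1], 1)
  # measured period from the separation maxima (first return to ~max)
  above <- which(sep > net$springs$r0 + d * 0.999)
  gaps <- split(above, cumsum(c(1, diff(above) > 1)))
  expect_gte(length(gaps), 3)
  centers <- vapply(gaps, mean, 1) - 1   # frame index -> time in fs
  measured <- mean(diff(centers))
  expect_equal(measured, period, tolerance = 0.01)
})

test_that("NVE conserves energy and the residue partition is complete", {
  net <- build_network(synth_structure(30, "globule", seed = 11))
  cfg <- simulation_config(n_steps = 2000, equilibration_steps = 100,
                           seed = 4)
  st <- equilibrate(net, init_state(net, 310, 4), cfg)
  e0 <- total_energy(net, st)
  frames <- integrate_nve(net, st, cfg)
  for (fr in frames[c(1, 100, length(frames))]) {
    s <- structure(list(pos = fr$pos, vel = fr$vel),
                   class = "system_state")
    expect_lt(abs(total_energy(net, s) - e0) / e0, 1e-4)
    expect_lt(abs(sum(per_residue_energy(net, s)) -
                    total_energy(net, s)) / abs(total_energy(net, s)),
              1e-9)
  }
})

test_that("per-residue energy follows the half-spring split", {
  d <- 0.6; k <- 1
  net <- two_bead_network(k = k, stretch = d)
  st <- structure(list(pos = net$xyz0, vel = matrix(0, 2, 3), time = 0),
                  class = "system_state")
  e <- per_residue_energy(net, st)
  expect_equal(e, rep(0.25 * k * d^2, 2))
  # all at rest length, zero velocity -> all exactly zero
  net0 <- build_network(synth_structure(5, "chain"))
  st0 <- init_state(net0, 0, 0)
  expect_equal(per_residue_energy(net0, st0), rep(0, 5))
})

test_that("package integrator agrees with a naive brute-force oracle", {
  net <- build_network(synth_structure(8, "globule", seed = 3,
                                       packing = 0.2))
  st <- init_state(net, 310, seed = 9)
  cfg <- simulation_config(n_steps = 200, save_interval = 200)
  got <- integrate_nve(net, st, cfg)[[2]]
  oracle <- naive_vv(net$mass, st$pos, st$vel, net$springs,
                     cfg$timestep, 200)
  expect_equal(got$pos, oracle$pos, tolerance = 1e-10)
  expect_equal(got$vel, oracle$vel, tolerance = 1e-10)
})

test_that("run_pair shares grid, differs only by the perturbation", {
  pr <- toy_pair(n = 20, residues = 1, factor = 4, n_steps = 400)
  expect_identical(pr$perturbed$times, pr$reference$times)
  d0 <- pr$perturbed$energies[, 1] - pr$reference$energies[, 1]
  # frame-0 difference localized at the perturbed residue, = (f^2-1) KE
  expect_true(all(d0[-1] == 0))
  ke1 <- 0.5 * pr$network$mass[1] * sum(pr$state$vel[1, ]^2) / 4.184e-4
  expect_equal(d0[1], 15 * ke1, tolerance = 1e-12)
  # residues farther along the chain diverge at later frames
  first_dev <- apply(abs(pr$perturbed$energies - pr$reference$energies)
                     > 1e-8, 1, function(r) {
                       w <- which(r); if (length(w)) w[1] else Inf
                     })
  expect_true(first_dev[20] > first_dev[2])
  # f = 1 null pair is bit-identical
  nul <- run_pair(pr$network, pr$state, 1, 1, pr$config)
  expect_identical(nul$perturbed$energies, nul$reference$energies)
})

test_that("identical inputs give bit-identical traces (determinism)", {
  a <- toy_pair(n = 12, n_steps = 200, seed = 8)
  b <- toy_pair(n = 12, n_steps = 200, seed = 8)
  expect_identical(a$perturbed$energies, b$perturbed$energies)
  expect_identical(a$reference$energies, b$reference$energies)
})

test_that("disconnected components never respond (causality)", {
  # two 5-bead chains 500 A apart: no spring path between them
  xyz <- rbind(cbind(seq(0, by = 3.8, length.out = 5), 0, 0),
               cbind(seq(500, by = 3.8, length.out = 5), 0, 0))
  s <- protein_structure(1:10, rep("GLY", 10), rep("A", 10), xyz = xyz)
  net <- build_network(s, cutoff = 10)
  cfg <- simulation_config(n_steps = 500, equilibration_steps = 100,
                           seed = 1)
  st <- equilibrate(net, init_state(net, 310, 1), cfg)
  pair <- run_pair(net, st, residues = 1, factor = 4, cfg)
  delta <- delta_energy(pair$perturbed, pair$reference)
  expect_true(all(delta$delta[6:10, ] == 0))
})

test_that("soften_network rescales only incident springs", {
  net <- build_network(synth_structure(10, "chain"))
  soft <- soften_network(net, 5, factor = 0.5)
  hit <- net$springs$i == 5 | net$springs$j == 5
  expect_equal(soft$springs$k[hit], net$springs$k[hit] * 0.5)
  expect_equal(soft$springs$k[!hit], net$springs$k[!hit])
})
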