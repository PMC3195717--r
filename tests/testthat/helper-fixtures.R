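# Shared fixture builders and independent oracles.

# minimal PDB text for a handful of CA records
make_pdb_lines <- function(xyz, resnames = NULL, chain = "A",
                           atom = "CA") {
  n <- nrow(xyz)
  if (is.null(resnames)) resnames <- rep("GLY", n)
  sprintf(
    "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), atom, resnames, chain, seq_len(n),
    xyz[, 1], xyz[, 2], xyz[, 3])
}

# hand-built two-bead network with one spring (bypasses build_network)
two_bead_network <- function(m1 = 110, m2 = 110, k = 1, r0 = 3.8,
                             stretch = 0) {
  s <- protein_structure(index = 1:2, name = c("GLY", "GLY"),
                         chain_id = c("A", "A"),
                         mass = c(m1, m2),
                         xyz = rbind(c(0, 0, 0), c(r0 + stretch, 0, 0)))
  net <- build_network(s, cutoff = r0 + abs(stretch) + 1, stiffness = k)
  net$springs$r0 <- r0   # impose the rest length, leaving the stretch
  net
}

# independent naive velocity-Verlet oracle: plain loops over springs,
# no shared code with the package integrator
naive_vv <- function(mass, pos, vel, springs, dt, n_steps) {
  kcal <- 4.184e-4
  n <- nrow(pos)
  force <- function(p) {
    f <- matrix(0, n, 3)
    for (s in seq_len(nrow(springs))) {
      i <- springs$i[s]; j <- springs$j[s]
      d <- p[i, ] - p[j, ]
      r <- sqrt(sum(d^2))
      fmag <- -springs$k[s] * kcal * (r - springs$r0[s])
      f[i, ] <- f[i, ] + fmag * d / r
      f[j, ] <- f[j, ] - fmag * d / r
    }
    f
  }
  acc <- force(pos) / mass
  for (step in seq_len(n_steps)) {
    vel <- vel + 0.5 * dt * acc
    pos <- pos + dt * vel
    acc <- force(pos) / mass
    vel <- vel + 0.5 * dt * acc
  }
  list(pos = pos, vel = vel)
}

# BFS graph distances from a source set over the spring graph
bfs_distance <- function(n, springs, sources) {
  adj <- vector("list", n)
  for (s in seq_len(nrow(springs))) {
    i <- springs$i[s]; j <- springs$j[s]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  dist <- rep(Inf, n)
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# small equilibrated pair-run helper used by several test files
toy_pair <- function(n = 20, kind = "chain", residues = 1, factor = 4,
                     n_steps = 600, seed = 3, struct_seed = 42,
                     temperature = 310) {
  s <- synth_structure(n, kind, seed = struct_seed)
  net <- build_network(s)
  cfg <- simulation_config(n_steps = n_steps, equilibration_steps = 200,
                           seed = seed, temperature = temperature)
  st <- equilibrate(net, init_state(net, temperature, seed), cfg)
  c(run_pair(net, st, residues, factor, cfg),
    list(network = net, state = st, config = cfg))
}
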