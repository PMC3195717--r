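#' Generate a synthetic toy structure
#'
#' Deterministic generators for the three fixture geometries used
#' throughout the test-suite:
#' \describe{
#'   \item{chain}{collinear beads along x at fixed spacing (default
#'     3.8 A, the canonical C-alpha virtual bond length);}
#'   \item{helix}{an ideal alpha-helical C-alpha trace (rise 1.5 A per
#'     residue, 100 degree twist, radius 2.3 A);}
#'   \item{globule}{self-avoiding random placement with a minimum
#'     separation (default 3.5 A) inside a sphere sized for the target
#'     packing fraction.  Random sequential placement jams near packing
#'     0.38, so the default target is 0.30.}
#' }
#' All beads are glycine-named with uniform 110 amu mass; geometry, not
#' chemistry, is what these fixtures exercise.
#'
#' @param n number of residues (>= 2).
#' @param kind "chain", "helix" or "globule".
#' @param spacing chain spacing, A.
#' @param min_sep globule minimum bead separation, A.
#' @param packing globule target packing fraction (0 < packing <= 0.35).
#' @param seed RNG seed (globule only); same seed, same structure.
#' @param max_tries placement attempts per bead before giving up.
#' @return a [protein_structure()] with `source_id` "synthetic-<kind>".
#' @export
synth_structure <- function(n, kind = c("chain", "helix", "globule"),
                            spacing = 3.8, min_sep = 3.5, packing = 0.30,
                            seed = 0, max_tries = 2000) {
  kind <- match.arg(kind)
  ed_assert(n >= 2, "enerdiss_input_error", "need n >= 2")
  xyz <- switch(kind,
    chain = cbind((seq_len(n) - 1) * spacing, 0, 0),
    helix = {
      phi <- (seq_len(n) - 1) * 100 * pi / 180
      cbind(2.3 * cos(phi), 2.3 * sin(phi), (seq_len(n) - 1) * 1.5)
    },
    globule = {
      ed_assert(packing > 0 && packing <= 0.35, "enerdiss_input_error",
                "globule packing fraction must be in (0, 0.35]")
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(seed)
      radius <- (min_sep / 2) * (n / packing)^(1 / 3)
      pos <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          # uniform point in the sphere
          p <- stats::runif(3, -1, 1) * radius
          if (sum(p^2) > radius^2) next
          if (i == 1 ||
              min(sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                     2, p)^2))) >= min_sep) {
            pos[i, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed) {
          ed_stop("enerdiss_generation_error",
                  "could not place bead %d after %d tries (packing too dense)",
                  i, max_tries)
        }
      }
      pos
    })
  protein_structure(index = seq_len(n), name = rep("GLY", n),
                    chain_id = rep("A", n), mass = rep(.DEFAULT_MASS, n),
                    xyz = xyz, source_id = paste0("synthetic-", kind))
}

#' Synthetic sigmoid dissipation curve with known truth
#'
#' Samples the two-state Boltzmann model on a uniform grid, adds Gaussian
#' noise, and optionally turns the result into a legal count curve
#' (rounded to integers, clamped to [NR1, NR2], monotonized by cumulative
#' max).  The generating parameters are stored in the `truth` attribute
#' for fit-recovery tests.
#'
#' @param NR1,NR2,t0,dt model parameters (see [boltzmann_nr()]).
#' @param n_points grid size (>= 5).
#' @param t_range length-2 time window, fs.
#' @param noise_sd additive Gaussian noise SD, residues.
#' @param integerize logical; make the curve a valid count curve.
#' @param seed RNG seed.
#' @return a `dissipation_curve` with attributes `NR1` and `truth`.
#' @export
synth_boltzmann_curve <- function(NR1 = 1, NR2 = 447, t0 = 500, dt = 100,
                                  n_points = 200,
                                  t_range = c(0, 1000), noise_sd = 0,
                                  integerize = FALSE, seed = 0) {
  ed_assert(n_points >= 5, "enerdiss_input_error", "need n_points >= 5")
  t <- seq(t_range[1], t_range[2], length.out = n_points)
  y <- boltzmann_nr(t, NR1, NR2, t0, dt)
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    y <- y + stats::rnorm(n_points, sd = noise_sd)
  }
  if (integerize) {
    y <- pmin(pmax(round(y), NR1), NR2)
    y <- cummax(y)
  }
  structure(data.frame(t = t, NR = y),
            NR1 = NR1,
            truth = list(NR1 = NR1, NR2 = NR2, t0 = t0, dt = dt,
                         noise_sd = noise_sd, seed = seed),
            class = c("dissipation_curve", "data.frame"))
}

#' Synthetic Lorentzian difference curve with known truth
#'
#' @param NR0,tc,w,A model parameters (see [lorentz_delta()]).
#' @param n_points grid size (>= 6).
#' @param t_range length-2 time window, fs.
#' @param noise_sd additive Gaussian noise SD, residues.
#' @param seed RNG seed.
#' @return a `difference_curve` (t, dNR) with attribute `truth`.
#' @export
synth_lorentz_curve <- function(NR0 = -5, tc = 480, w = 400, A = 20000,
                                n_points = 200, t_range = c(0, 1000),
                                noise_sd = 0, seed = 0) {
  ed_assert(n_points >= 6, "enerdiss_input_error", "need n_points >= 6")
  t <- seq(t_range[1], t_range[2], length.out = n_points)
  y <- lorentz_delta(t, NR0, tc, w, A)
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    y <- y + stats::rnorm(n_points, sd = noise_sd)
  }
  structure(data.frame(t = t, dNR = y),
            truth = list(NR0 = NR0, tc = tc, w = w, A = A,
                         noise_sd = noise_sd, seed = seed),
            class = c("difference_curve", "data.frame"))
}

#' Synthetic contiguous region annotation
#'
#' Splits 1..n into contiguous blocks at the given cumulative fractions,
#' mimicking a domain segmentation (e.g. N-lobe / C-lobe / ACT1 / ACT2).
#'
#' @param n residue count.
#' @param boundaries increasing fractions in (0, 1], one per label; the
#'   k-th block ends at residue floor(boundaries[k] * n).
#' @param labels one label per boundary.
#' @return a `region_annotation`.
#' @export
synth_annotation <- function(n, boundaries, labels) {
  ed_assert(length(boundaries) == length(labels), "enerdiss_spec_error",
            "boundaries and labels must have equal length")
  ed_assert(all(diff(boundaries) > 0) && all(boundaries > 0) &&
              all(boundaries <= 1),
            "enerdiss_spec_error",
            "boundaries must be increasing fractions in (0, 1]")
  ends <- floor(boundaries * n)
  ends[length(ends)] <- n
  starts <- c(1, utils::head(ends, -1) + 1)
  spec <- data.frame(start = starts, end = ends, label = labels)
  spec <- spec[spec$start <= spec$end, , drop = FALSE]
  dummy <- structure(list(residues = data.frame(index = seq_len(n))),
                     class = "protein_structure")
  annotate_regions(dummy, spec)
}
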