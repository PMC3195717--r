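#' Perturbed-minus-reference energy difference
#'
#' @param perturbed,reference `energy_trace`s on the identical time grid
#'   with the same residue count.
#' @return a `delta_energy_trace`: times plus the residues x frames
#'   difference matrix (kcal/mol).
#' @export
delta_energy <- function(perturbed, reference) {
  ed_assert(identical(dim(perturbed$energies), dim(reference$energies)),
            "enerdiss_alignment_error", "residue/frame counts differ")
  ed_assert(isTRUE(all.equal(perturbed$times, reference$times,
                             tolerance = 0)),
            "enerdiss_alignment_error", "time grids differ")
  structure(list(times = perturbed$times,
                 delta = perturbed$energies - reference$energies,
                 metadata = perturbed$metadata),
            class = "delta_energy_trace")
}

#' Response-detection policy
#'
#' The response criterion is this package's own definition (none is given
#' with the model itself): residue i responds at the earliest frame t such
#' that |delta| stays at or above an effective threshold for `sustain`
#' consecutive frames starting at t.  In "absolute" mode the threshold is
#' `threshold` kcal/mol for every residue; in "relative" mode it is
#' `k_noise` times a per-residue null-noise scale (standard deviation of
#' an f = 1 control difference trace).
#'
#' @param threshold absolute threshold theta, kcal/mol (> 0).
#' @param sustain required consecutive frames m (>= 1).
#' @param mode "absolute" or "relative".
#' @param k_noise noise multiplier for relative mode (> 0).
#' @return a `detection_policy`.
#' @export
detection_policy <- function(threshold = 0.1, sustain = 3,
                             mode = c("absolute", "relative"),
                             k_noise = 3) {
  mode <- match.arg(mode)
  ed_assert(sustain >= 1, "enerdiss_policy_error", "sustain must be >= 1")
  if (mode == "absolute") {
    ed_assert(threshold > 0, "enerdiss_policy_error",
              "threshold must be > 0")
  } else {
    ed_assert(k_noise > 0, "enerdiss_policy_error", "k_noise must be > 0")
  }
  structure(list(threshold = threshold, sustain = as.integer(sustain),
                 mode = mode, k_noise = k_noise),
            class = "detection_policy")
}

# earliest start index of a run of >= m TRUEs per row; NA if none
.first_sustained <- function(hit, m) {
  nf <- ncol(hit)
  if (m > nf) return(rep(NA_integer_, nrow(hit)))
  cs <- t(apply(hit, 1, cumsum))
  if (m == 1) {
    win <- hit
  } else {
    win <- cs[, m:nf, drop = FALSE] -
      cbind(0, cs[, 1:(nf - m), drop = FALSE])
    win <- win == m
  }
  apply(win, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
}

#' Detect per-residue response times
#'
#' Applies a [detection_policy()] to a difference trace.  Perturbed
#' residues are assigned response time 0 by definition; residues never
#' meeting the criterion are "nonresponsive" (NA).
#'
#' @param delta a `delta_energy_trace`.
#' @param policy a `detection_policy`.
#' @param perturbed_set indices of the perturbed residues.
#' @param control optional `delta_energy_trace` from a null (f = 1 or
#'   noise-only) pair; required for relative mode.
#' @return a `response_profile`: numeric vector of response times in fs
#'   (NA = nonresponsive) with attributes `perturbed` (the perturbed set),
#'   `times` (the frame grid) and `policy`.
#' @export
detect_response_times <- function(delta, policy = detection_policy(),
                                  perturbed_set, control = NULL) {
  n <- nrow(delta$delta)
  ed_assert(length(perturbed_set) >= 1 &&
              all(perturbed_set >= 1 & perturbed_set <= n),
            "enerdiss_index_error", "invalid perturbed set")
  if (policy$mode == "relative") {
    ed_assert(!is.null(control), "enerdiss_policy_error",
              "relative mode requires a null-control difference trace")
    noise <- apply(control$delta, 1, stats::sd)
    theta <- policy$k_noise * pmax(noise, .Machine$double.eps)
  } else {
    theta <- rep(policy$threshold, n)
  }
  hit <- abs(delta$delta) >= theta
  idx <- .first_sustained(hit, policy$sustain)
  dt <- delta$times[idx]
  dt[perturbed_set] <- 0
  structure(dt, perturbed = as.integer(perturbed_set),
            times = delta$times, policy = policy,
            class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf(
    "response_profile: %d residues, %d responsive, %d nonresponsive\n",
    length(x), sum(!is.na(x)), sum(is.na(x))))
  invisible(x)
}

#' Cumulative energy-dissipation curve NR(t)
#'
#' NR(t) counts the residues whose response time is at or before t.
#' Nonresponsive residues are never counted (no fabricated plateau).
#'
#' @param profile a `response_profile` (or plain numeric vector of
#'   response times with NA = nonresponsive).
#' @param grid evaluation times in fs, increasing; defaults to the
#'   profile's own frame grid.
#' @return a `dissipation_curve`: data.frame (t, NR) with attribute
#'   `NR1` = number of perturbed residues.
#' @export
dissipation_curve <- function(profile, grid = NULL) {
  if (is.null(grid)) grid <- attr(profile, "times")
  ed_assert(!is.null(grid) && all(diff(grid) > 0),
            "enerdiss_input_error", "grid must be increasing")
  dt <- as.numeric(profile)
  dt <- dt[!is.na(dt)]
  nr <- vapply(grid, function(t) sum(dt <= t), numeric(1))
  structure(data.frame(t = as.numeric(grid), NR = as.integer(nr)),
            NR1 = length(attr(profile, "perturbed")),
            class = c("dissipation_curve", "data.frame"))
}

#' Per-region mean and standard deviation of response times
#'
#' Arithmetic mean and population standard deviation of the response time
#' over responsive residues in each region, plus an "All" row;
#' nonresponsive residues are excluded and counted separately.
#'
#' @param profile a `response_profile`.
#' @param annotation a `region_annotation` covering the same residues.
#' @return data.frame: region, n_responsive, n_nonresponsive, mean, sd
#'   (fs).  Regions with no responsive residue get NA mean/sd.
#' @export
region_mean_response <- function(profile, annotation) {
  ed_assert(length(profile) == length(annotation),
            "enerdiss_input_error",
            "annotation does not cover the profile's residues")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  regions <- unique(c("All", as.character(unique(annotation))))
  rows <- lapply(regions, function(rg) {
    sel <- if (rg == "All") rep(TRUE, length(profile))
           else annotation == rg
    dt <- as.numeric(profile)[sel]
    resp <- dt[!is.na(dt)]
    data.frame(region = rg,
               n_responsive = length(resp),
               n_nonresponsive = sum(is.na(dt)),
               mean = if (length(resp)) mean(resp) else NA_real_,
               sd = if (length(resp)) pop_sd(resp) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
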