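#' Dual-echo volume pair
#'
#' Container for two co-registered 3D intensity volumes acquired at
#' different echo times, the unit of relaxometry input.
#'
#' @param echo1,echo2 3D numeric arrays of identical dimensions with
#'   finite, non-negative intensities.
#' @param te1,te2 Echo times in ms, `0 < te1 < te2`.
#' @param voxdim Voxel dimensions `c(dx, dy, dz)` in mm.
#' @return A list of class `"echo_pair"`.
#' @export
echo_pair <- function(echo1, echo2, te1, te2, voxdim) {
  if (!identical(dim(echo1), dim(echo2)) || length(dim(echo1)) != 3) {
    abort("`echo1` and `echo2` must be 3D arrays of identical dimensions.")
  }
  if (te1 <= 0 || te2 <= te1) abort("Echo times must satisfy 0 < te1 < te2.")
  if (anyNA(echo1) || anyNA(echo2) || min(echo1) < 0 || min(echo2) < 0) {
    abort("Echo intensities must be finite and non-negative.")
  }
  if (length(voxdim) != 3 || any(voxdim <= 0)) abort("`voxdim` must be 3 positive values (mm).")
  structure(list(echo1 = echo1, echo2 = echo2, te1 = te1, te2 = te2,
                 voxdim = as.numeric(voxdim)),
            class = "echo_pair")
}

#' Nerve label map
#'
#' Integer label volume distinguishing the nerve sub-structures:
#' 0 = background/muscle, 1 = inner epineurium, 2 = fascicles. The whole
#' nerve is the union of labels 1 and 2.
#'
#' @param labels 3D integer array with values in `{0, 1, 2}`.
#' @param voxdim Voxel dimensions `c(dx, dy, dz)` in mm.
#' @return A list of class `"nerve_label_map"`.
#' @export
nerve_label_map <- function(labels, voxdim) {
  if (length(dim(labels)) != 3) abort("`labels` must be a 3D array.")
  if (!all(labels %in% 0:2)) abort("Labels must be 0 (background), 1 (epineurium) or 2 (fascicle).")
  if (length(voxdim) != 3 || any(voxdim <= 0)) abort("`voxdim` must be 3 positive values (mm).")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxdim = as.numeric(voxdim)),
            class = "nerve_label_map")
}

## Labels a structure name resolves to.
structure_labels <- function(structure) {
  if (is.numeric(structure)) {
    if (!all(structure %in% 1:2)) abort("Numeric structure labels must be in {1, 2}.")
    return(as.integer(structure))
  }
  switch(match.arg(structure, c("fascicle", "epineurium", "nerve")),
         fascicle = 2L, epineurium = 1L, nerve = c(1L, 2L))
}

## Select the n voxels with the smallest metric value, ties broken by
## voxel index so renders are deterministic.
smallest_n <- function(metric, n) {
  order(metric, seq_along(metric))[seq_len(n)]
}

## Render one 2D nerve cross-section. Returns an nx x ny integer matrix.
render_cross_section <- function(csa_mm2, fasc_fraction, geom) {
  n_target <- max(round(csa_mm2 / (geom$dx * geom$dy)), 8L)
  ## ellipse with the target area; check it fits with margin for jitter
  q <- runif(1, geom$axis_ratio_range[1], geom$axis_ratio_range[2])
  a <- sqrt(q * n_target * geom$dx * geom$dy / pi)  # semi-major, mm
  b <- a / q
  margin <- 3 * geom$center_jitter_mm + 2 * max(geom$dx, geom$dy)
  if (2 * a + 2 * margin > min(geom$nx * geom$dx, geom$ny * geom$dy)) {
    abort(sprintf("Requested CSA %.1f mm^2 does not fit in the %d x %d grid.",
                  csa_mm2, geom$nx, geom$ny))
  }
  theta <- runif(1, 0, pi)
  x <- (seq_len(geom$nx) - (geom$nx + 1) / 2) * geom$dx
  y <- (seq_len(geom$ny) - (geom$ny + 1) / 2) * geom$dy
  X <- matrix(x, geom$nx, geom$ny)
  Y <- matrix(y, geom$nx, geom$ny, byrow = TRUE)
  U <- cos(theta) * X + sin(theta) * Y
  V <- -sin(theta) * X + cos(theta) * Y
  ellipse_metric <- (U / a)^2 + (V / b)^2
  nerve_idx <- smallest_n(as.vector(ellipse_metric), n_target)

  ## fascicle centres: spaced rejection sampling inside the ellipse core,
  ## with deterministic relaxation of the separation if packing stalls
  k <- if (geom$n_fascicles_range[1] == geom$n_fascicles_range[2]) {
    geom$n_fascicles_range[1]
  } else {
    sample(seq(geom$n_fascicles_range[1], geom$n_fascicles_range[2]), 1)
  }
  sep <- max(2 * geom$fascicle_radius_range[1],
             2 * sqrt(fasc_fraction * n_target * geom$dx * geom$dy / (pi * k)) * 0.8)
  centres <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centres) < k) {
    tries <- tries + 1L
    if (tries > 400L) {  # relax spacing rather than fail on dense nerves
      sep <- sep * 0.8
      tries <- 0L
      if (sep < min(geom$dx, geom$dy) / 4) {
        abort("Fascicle packing failed: could not place fascicle centres.")
      }
    }
    cu <- runif(1, -a, a); cv <- runif(1, -b, b)
    if ((cu / a)^2 + (cv / b)^2 > 0.7^2) next
    if (nrow(centres) > 0 &&
        min(sqrt((centres[, 1] - cu)^2 + (centres[, 2] - cv)^2)) < sep) next
    centres <- rbind(centres, c(cu, cv))
  }

  ## fascicles: the fraction of nerve voxels nearest to any centre,
  ## partitioned implicitly by nearest centre (disc-like disjoint regions
  ## separated by the epineurial web and rim)
  n_fasc <- round(fasc_fraction * n_target)
  Uv <- as.vector(U)[nerve_idx]
  Vv <- as.vector(V)[nerve_idx]
  d2min <- rep(Inf, length(nerve_idx))
  for (i in seq_len(nrow(centres))) {
    d2 <- (Uv - centres[i, 1])^2 + (Vv - centres[i, 2])^2
    d2min <- pmin(d2min, d2)
  }
  fasc_idx <- nerve_idx[smallest_n(d2min, n_fasc)]

  section <- matrix(0L, geom$nx, geom$ny)
  section[nerve_idx] <- 1L
  section[fasc_idx] <- 2L
  section
}

## Shift a matrix by whole voxels, filling with background.
shift_matrix <- function(m, ox, oy) {
  if (ox == 0 && oy == 0) return(m)
  out <- matrix(0L, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - ox
  src_c <- seq_len(ncol(m)) - oy
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

apply_noise <- function(signal, sigma, model) {
  if (!is.finite(sigma) || sigma <= 0) return(signal)
  n <- length(signal)
  if (model == "rician") {
    sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  } else {
    pmax(signal + rnorm(n, 0, sigma), 0)
  }
}

#' Build a dual-echo phantom and its ground-truth label map
#'
#' Renders a synthetic sciatic nerve cross-section (elliptical whole
#' nerve partitioned into disjoint fascicle regions and surrounding
#' epineurium) replicated across slices with per-slice whole-voxel
#' centre jitter, then simulates the two vTE echoes with mono-exponential
#' decay per compartment: `S(t) = amplitude(label) * exp(-t / T2*(label))`,
#' plus Rician or Gaussian noise at the configured SNR. The rendered
#' whole-nerve area matches the subject's true CSA to within half a
#' voxel per slice, and the fascicle-to-nerve area ratio matches the
#' true fraction to within one voxel.
#'
#' Uses the current RNG state; seed with `set.seed()` for
#' reproducibility.
#'
#' @param subject One-row tibble from [draw_subject()] (needs
#'   `true_csa_mm2`, `true_fasc_fraction`, `true_fascicle_t2star_ms`,
#'   `true_epineurium_t2star_ms`).
#' @param geom A [geometry_config()].
#' @param acq An [acquisition_spec()]. The noise sigma is the noiseless
#'   fascicle TE1 signal divided by `acq$snr`.
#' @param compartments A [default_compartments()].
#' @return List with `echoes` (an [echo_pair()]) and `labels`
#'   (a [nerve_label_map()]).
#' @examples
#' set.seed(7)
#' subj <- draw_subject("HC")
#' ph <- build_phantom(subj, acq = acquisition_spec(snr = Inf))
#' table(ph$labels$labels)
#' @export
build_phantom <- function(subject, geom = geometry_config(),
                          acq = acquisition_spec(),
                          compartments = default_compartments()) {
  section <- render_cross_section(subject$true_csa_mm2,
                                  subject$true_fasc_fraction, geom)

  ## per-slice jitter in whole voxels (area-preserving)
  jit <- matrix(round(rnorm(2 * geom$nslices, 0, geom$center_jitter_mm) /
                        c(geom$dx, geom$dy)),
                ncol = 2, byrow = TRUE)
  labels <- array(0L, dim = c(geom$nx, geom$ny, geom$nslices))
  for (s in seq_len(geom$nslices)) {
    labels[, , s] <- shift_matrix(section, jit[s, 1], jit[s, 2])
  }

  t2 <- c(compartments$muscle_t2star_ms,
          subject$true_epineurium_t2star_ms,
          subject$true_fascicle_t2star_ms)
  amp <- c(compartments$muscle_amplitude,
           compartments$epineurium_amplitude,
           compartments$fascicle_amplitude)
  idx <- as.vector(labels) + 1L
  sigma <- compartments$fascicle_amplitude *
    exp(-acq$te1 / subject$true_fascicle_t2star_ms) / acq$snr

  make_echo <- function(te) {
    s <- amp[idx] * exp(-te / t2[idx])
    array(apply_noise(s, sigma, acq$noise), dim = dim(labels))
  }
  e1 <- make_echo(acq$te1)
  e2 <- make_echo(acq$te2)
  voxdim <- c(geom$dx, geom$dy, geom$dz)
  list(echoes = echo_pair(e1, e2, acq$te1, acq$te2, voxdim),
       labels = nerve_label_map(labels, voxdim))
}

#' Simulate a second rater by perturbing structure boundaries
#'
#' Flips labels of boundary voxels (voxels with an in-plane 4-neighbour
#' of a different label) at the given rate, assigning each flipped voxel
#' the label of one of its differing neighbours. The output is always a
#' valid label map, so the whole nerve remains the union of epineurium
#' and fascicles.
#'
#' @param mask A [nerve_label_map()].
#' @param rate Flip probability for boundary voxels, in `[0, 0.5]`.
#' @return A perturbed [nerve_label_map()].
#' @examples
#' set.seed(1)
#' ph <- build_phantom(draw_subject("HC"))
#' rater2 <- perturb_mask(ph$labels, 0.2)
#' @export
perturb_mask <- function(mask, rate) {
  stopifnot(inherits(mask, "nerve_label_map"))
  if (rate < 0 || rate > 0.5) abort("`rate` must be in [0, 0.5].")
  if (rate == 0) return(mask)
  lab <- mask$labels
  out <- lab
  nx <- dim(lab)[1]; ny <- dim(lab)[2]
  for (s in seq_len(dim(lab)[3])) {
    m <- lab[, , s]
    up    <- rbind(m[-1, , drop = FALSE], m[nx, , drop = FALSE])
    down  <- rbind(m[1, , drop = FALSE], m[-nx, , drop = FALSE])
    left  <- cbind(m[, -1, drop = FALSE], m[, ny, drop = FALSE])
    right <- cbind(m[, 1, drop = FALSE], m[, -ny, drop = FALSE])
    boundary <- which(m != up | m != down | m != left | m != right)
    if (!length(boundary)) next
    flip <- boundary[runif(length(boundary)) < rate]
    if (!length(flip)) next
    nb <- cbind(up[flip], down[flip], left[flip], right[flip])
    new <- m[flip]
    for (j in seq_along(flip)) {
      diff_nb <- nb[j, nb[j, ] != m[flip[j]]]
      new[j] <- diff_nb[sample.int(length(diff_nb), 1)]
    }
    m[flip] <- new
    out[, , s] <- m
  }
  nerve_label_map(out, mask$voxdim)
}
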