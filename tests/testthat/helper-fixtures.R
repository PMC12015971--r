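# Small fixtures shared across tests. The tiny grid keeps phantom tests
# fast; the nerve physics is unchanged.

tiny_geometry <- function(nslices = 4L) {
  geometry_config(nx = 48L, ny = 48L, nslices = nslices,
                  center_jitter_mm = 0.3)
}

tiny_config <- function(seed = NULL, snr = 50, noise = "rician") {
  run_config(seed = seed,
             geometry = tiny_geometry(),
             acquisition = acquisition_spec(snr = snr, noise = noise))
}

noiseless_acq <- function() acquisition_spec(snr = Inf)

# Uniform one-compartment echo pair: every voxel decays with time
# constant `t2star` from amplitude `amp`.
uniform_echo_pair <- function(t2star, amp = 100, dims = c(4, 4, 3),
                              te1 = 1.05, te2 = 5.37) {
  e1 <- array(amp * exp(-te1 / t2star), dim = dims)
  e2 <- array(amp * exp(-te2 / t2star), dim = dims)
  echo_pair(e1, e2, te1, te2, c(0.6, 0.6, 5))
}

# Label map with a centred square nerve whose inner part is fascicle.
block_label_map <- function(nx = 12, ny = 12, nslices = 3,
                            voxdim = c(0.6, 0.6, 5)) {
  lab <- array(0L, dim = c(nx, ny, nslices))
  lab[3:(nx - 2), 3:(ny - 2), ] <- 1L
  lab[5:(nx - 4), 5:(ny - 4), ] <- 2L
  nerve_label_map(lab, voxdim)
}
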