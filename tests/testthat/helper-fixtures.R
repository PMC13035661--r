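# Shared phantom fixtures, built once per test run and memoised: the
# 0.5 mm phantoms are the reference pair used for oracle-equivalence
# checks, coarser variants keep the remaining tests fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build_fixture(name), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

build_fixture <- function(name) {
  switch(name,
    # straight half-dissected tube, fine grid
    tube05 = {
      ph <- voxelize_phantom(phantom_spec("straight", length = 100, r0 = 15,
                                          fl_fraction = 0.5, spacing = 0.5))
      cl <- extract_centerline(ph$volume)
      prof <- diameter_profile(ph$volume, cl)
      list(ph = ph, cl = cl, prof = prof,
           meas = global_measures(ph$volume, cl, prof))
    },
    # Gaussian bulge phantom, fine grid
    bulge05 = {
      ph <- voxelize_phantom(phantom_spec(
        "straight", length = 100, r0 = 15,
        bulge = list(amplitude = 5, center = 50, width = 10),
        fl_fraction = 0.5, spacing = 0.5))
      cl <- extract_centerline(ph$volume)
      prof <- diameter_profile(ph$volume, cl)
      list(ph = ph, cl = cl, prof = prof,
           meas = global_measures(ph$volume, cl, prof))
    },
    # curved phantom with thrombus, coarse grid
    cane1 = {
      ph <- voxelize_phantom(phantom_spec("candy_cane", arch_radius = 40,
                                          descending_length = 120, r0 = 12,
                                          fl_fraction = 0.4, th_fraction = 0.25,
                                          spacing = 1.0))
      cl <- extract_centerline(ph$volume)
      prof <- diameter_profile(ph$volume, cl)
      list(ph = ph, cl = cl, prof = prof,
           meas = global_measures(ph$volume, cl, prof))
    },
    # straight tube, coarse grid (for refinement / rotation checks)
    tube10 = {
      ph <- voxelize_phantom(phantom_spec("straight", length = 100, r0 = 15,
                                          fl_fraction = 0.5, spacing = 1.0))
      cl <- extract_centerline(ph$volume)
      list(ph = ph, cl = cl)
    },
    stop("unknown fixture: ", name)
  )
}

# a small, quick phantom volume for plumbing tests
quick_phantom <- function(fl_fraction = 0.5, th_fraction = 0, length = 50,
                          r0 = 8) {
  voxelize_phantom(phantom_spec("straight", length = length, r0 = r0,
                                fl_fraction = fl_fraction,
                                th_fraction = th_fraction, spacing = 1.0))
}

# brute-force AUC oracle: explicit pair counting with ties scored 0.5
bruteforce_auc <- function(values, outcomes) {
  xs <- values[outcomes == 1]
  xn <- values[outcomes == 0]
  total <- 0
  for (s in xs) for (n in xn) {
    total <- total + (s > n) + 0.5 * (s == n)
  }
  total / (length(xs) * length(xn))
}

# brute-force two-sample KS oracle: scan the pooled points directly
bruteforce_ks <- function(a, b) {
  best <- 0
  for (t in c(a, b)) {
    best <- max(best, abs(mean(a <= t) - mean(b <= t)))
  }
  best
}
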