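## small slab fixture shared across the Fourier tests
fourier_slab <- function() {
  generate_slab_in_bath_mesh(
    4e-3, 3e-3, c(2e-3, 2e-3, 1e-3),
    electrode_patches = list(list(shape = "rect", dims = c(1e-3, 1e-3),
                                  center = c(0, 0))),
    max_cell = 1e-3)
}

test_that("pulse synthesis", {
  w <- make_pulse("square", 1, 200e-6, 10e-6, 4e-3)
  expect_identical(sum(w$samples == 1), 20L)
  expect_identical(sum(w$samples != 0), 20L)
  z <- make_pulse("alpha", 0, 300e-6, 10e-6, 2e-3)
  expect_identical(unique(z$samples), 0)
  s <- make_pulse("sine", 2, 400e-6, 10e-6, 4e-3)
  expect_lt(abs(sum(s$samples)), 1e-12)
  expect_error(make_pulse("square", 1, 5e-3, 10e-6, 2e-3),
               "record_length")
})

test_that("FFT decomposition and round trip", {
  ## the canonical record: 1 s at dt = 10 us -> 50,001 frequencies up to
  ## 50 kHz
  w <- make_pulse("square", 1, 200e-6, 10e-6, 1)
  dec <- decompose(w)
  expect_identical(length(dec$frequencies), 50001L)
  expect_equal(max(dec$frequencies), 5e4, tolerance = 1e-12)
  expect_lt(max(abs(femvc:::.recompose(dec$coefficients, dec$n) -
                    w$samples)), 1e-12)
  ## delta input has a flat magnitude spectrum
  d <- waveform(c(1, rep(0, 63)), 1e-5)
  dd <- decompose(d)
  expect_lt(diff(range(Mod(dd$coefficients))), 1e-12)
  ## odd-length record round trip
  o <- waveform(rnorm(101), 1e-5)
  doo <- decompose(o)
  expect_lt(max(abs(femvc:::.recompose(doo$coefficients, doo$n) -
                    o$samples)), 1e-12)
})

test_that("frequency pruning bounds the reconstruction error", {
  w <- make_pulse("square", 1, 200e-6, 10e-6, 4e-3)
  dec <- decompose(w)
  all_in <- prune_frequencies(dec$coefficients, 0)
  expect_identical(all_in$index, seq_along(dec$coefficients))
  expect_identical(all_in$dropped_energy, 0)
  top <- prune_frequencies(dec$coefficients, 1)
  expect_true(1L %in% top$index)
  expect_lte(length(top$index), 2L)
  ## threshold 1e-3: reconstruction from retained coefficients within 1%
  pr <- prune_frequencies(dec$coefficients, 1e-3)
  kept <- dec$coefficients
  kept[-pr$index] <- 0
  rec <- femvc:::.recompose(kept, dec$n)
  expect_lt(max(abs(rec - w$samples)) / max(w$samples), 0.01)
})

test_that("dispersionless medium with faradaic interface preserves pulse shape", {
  mesh <- fourier_slab()
  ## frequency-independent conductivity: no dispersion terms at all
  db <- tissue_table()
  db$flat <- list(sigma_static = 1,
                  cole_cole = cole_cole_params(0, numeric(0), numeric(0),
                                               numeric(0), 1))
  pulse <- make_pulse("square", 1, 200e-6, 10e-6, 2e-3)
  job <- fourier_job(mesh, list("1" = "flat", "2" = "flat"),
                     "dispersive", "faradaic",
                     stim_marker = 111L, ground_marker = 102L,
                     pulse = pulse, probes = rbind(c(0, 0, 0.5e-3)),
                     prune_threshold = 0, tissue_db = db)
  res <- run_fourier_job(job, tol = 1e-10)
  out <- res$probes[, 1]
  scale <- max(abs(out)) / max(abs(pulse$samples))
  expect_gt(scale, 0)
  expect_lt(max(abs(out / scale - pulse$samples)) / max(pulse$samples),
            1e-6)
})

test_that("pipeline is linear in the stimulus amplitude", {
  mesh <- fourier_slab()
  mk <- list("1" = "ringer", "2" = "grey")
  run_amp <- function(a) {
    pulse <- make_pulse("square", a, 200e-6, 20e-6, 1e-3)
    job <- fourier_job(mesh, mk, "dispersive", "cpa", 111L, 102L,
                       pulse, rbind(c(0, 0, 0.5e-3)),
                       prune_threshold = 5e-3)
    run_fourier_job(job)$probes[, 1]
  }
  w1 <- run_amp(1); w2 <- run_amp(2)
  expect_lt(max(abs(w2 - 2 * w1)) / max(abs(w2)), 1e-8)
})

test_that("interface mode dominates; tissue dispersion mode barely matters", {
  mesh <- fourier_slab()
  mk <- list("1" = "ringer", "2" = "grey")
  pulse <- make_pulse("square", 1, 200e-6, 20e-6, 2e-3)
  probe <- rbind(c(0, 0, 0.25e-3))
  runjob <- function(mat, ifc) {
    job <- fourier_job(mesh, mk, mat, ifc, 111L, 102L, pulse, probe,
                       prune_threshold = 2e-3)
    run_fourier_job(job)$probes[, 1]
  }
  w_cpa_disp <- runjob("dispersive", "cpa")
  w_cpa_cap <- runjob("capacitive", "cpa")
  w_rc_disp <- runjob("dispersive", "rc")
  nrm <- max(abs(w_cpa_disp))
  ## capacitive vs dispersive tissue with the same interface: near-overlap
  expect_lt(max(abs(w_cpa_disp - w_cpa_cap)) / nrm, 0.05)
  ## cpa vs rc interface with the same tissue: clearly distinct waveforms
  expect_gt(max(abs(w_cpa_disp - w_rc_disp)) / nrm,
            2 * max(abs(w_cpa_disp - w_cpa_cap)) / nrm)
})

test_that("padding and sampling mitigate Gibbs ringing before the pulse", {
  mesh <- fourier_slab()
  mk <- list("1" = "ringer", "2" = "grey")
  ring_amp <- function(dt, record) {
    pulse <- make_pulse("square", 1, 200e-6, dt, record)
    job <- fourier_job(mesh, mk, "capacitive", "cpa", 111L, 102L, pulse,
                       rbind(c(0, 0, 0.25e-3)), prune_threshold = 1e-3)
    res <- run_fourier_job(job)
    n <- length(pulse$samples)
    i0 <- floor((n - round(200e-6 / dt)) / 2)  # pulse start sample
    pre <- res$probes[seq_len(max(1L, i0 - 5L)), 1]
    max(abs(pre)) / max(abs(res$probes[, 1]))
  }
  coarse <- ring_amp(20e-6, 1e-3)
  fine <- ring_amp(10e-6, 2e-3)
  expect_lt(fine, coarse + 1e-12)
})
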