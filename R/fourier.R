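## FEM-Fourier transient stimulation: a stimulating voltage waveform is
## decomposed with a real FFT, the frequency-domain FEM is solved once
## per retained frequency (per unit metal potential, exploiting
## linearity), and probe-point time courses are reconstituted with the
## inverse FFT. Material admittivities follow either the dispersive
## (Cole-Cole per frequency) or capacitive (Cole-Cole frozen at the
## record's average frequency) convention; the electrode interface is
## either the full CPA/charge-transfer parallel network per frequency or
## its equivalent RC reduced at the average frequency.

#' Sampled waveform
#'
#' @param samples numeric samples (V or A).
#' @param dt sample interval (s).
#' @param t0 time of the first sample (s).
#' @return object of class `waveform`.
#' @export
waveform <- function(samples, dt, t0 = 0) {
  stopifnot(dt > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), dt = dt, t0 = t0),
            class = "waveform")
}

#' Synthesize a stimulation pulse
#'
#' The pulse is centered in a zero-padded record (padding controls Gibbs
#' ringing in the reconstruction).
#'
#' @param shape `"square"`, `"alpha"` (t/tau exp(1 - t/tau) with
#'   tau = duration/4, clipped to the duration window) or `"sine"` (one
#'   full period over the duration).
#' @param amplitude peak amplitude.
#' @param duration pulse duration (s).
#' @param dt sample interval (s).
#' @param record_length total record length (s), at least `duration`.
#' @return a [waveform()].
#' @export
make_pulse <- function(shape = c("square", "alpha", "sine"), amplitude,
                       duration, dt, record_length) {
  shape <- match.arg(shape)
  if (duration > record_length)
    stop("duration exceeds record_length")
  n <- round(record_length / dt)
  nd <- round(duration / dt)
  if (nd < 1) stop("duration shorter than one sample")
  x <- numeric(n)
  i0 <- floor((n - nd) / 2)
  tt <- (seq_len(nd) - 0.5) * dt
  pulse <- switch(shape,
    square = rep(amplitude, nd),
    alpha = {
      tau <- duration / 4
      amplitude * (tt / tau) * exp(1 - tt / tau)
    },
    sine = amplitude * sin(2 * pi * tt / duration))
  x[i0 + seq_len(nd)] <- pulse
  waveform(x, dt)
}

#' One-sided FFT decomposition of a waveform
#'
#' `N` samples at spacing `dt` give `floor(N/2) + 1` frequencies from 0 to
#' `1/(2 dt)`.
#'
#' @param w a [waveform()].
#' @return list: `frequencies` (Hz), `coefficients` (complex, one-sided
#'   unnormalized FFT), `n` (record length), `dt`.
#' @export
decompose <- function(w) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  X <- fft(w$samples)
  nh <- floor(n / 2) + 1L
  list(frequencies = (seq_len(nh) - 1L) / (n * w$dt),
       coefficients = X[seq_len(nh)], n = n, dt = w$dt)
}

## rebuild the full conjugate-symmetric spectrum from one-sided
## coefficients and invert
.recompose <- function(coef_onesided, n) {
  nh <- length(coef_onesided)
  X <- complex(n)
  X[seq_len(nh)] <- coef_onesided
  if (n > 1L) {
    hi <- seq(2L, n - nh + 1L)
    X[n + 2L - hi] <- Conj(coef_onesided[hi])
  }
  Re(fft(X, inverse = TRUE)) / n
}

#' Prune negligible spectral components
#'
#' Retains the DC component plus every coefficient with
#' `|c| >= threshold * max |c|`, and reports the relative L2 energy of the
#' dropped part (an upper bound on the relative reconstruction error).
#'
#' @param coefficients complex one-sided FFT coefficients.
#' @param threshold relative magnitude threshold in `[0, 1]`.
#' @return list: `index` (retained positions), `dropped_energy` (relative
#'   L2 norm of dropped coefficients).
#' @export
prune_frequencies <- function(coefficients, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  a <- Mod(coefficients)
  keep <- a >= threshold * max(a)
  keep[1] <- TRUE
  tot <- sqrt(sum(a^2))
  list(index = which(keep),
       dropped_energy = if (tot > 0) sqrt(sum(a[!keep]^2)) / tot else 0)
}

#' FEM-Fourier job description
#'
#' @param mesh a [tet_mesh()].
#' @param tissues named list: cell marker (character) to tissue name (see
#'   [tissue_table()]).
#' @param material_mode `"dispersive"` (Cole-Cole per frequency) or
#'   `"capacitive"` (Cole-Cole at the record's average frequency; the
#'   displacement term still scales with the actual frequency).
#' @param interface_mode `"cpa"` (parallel CPA/charge-transfer network per
#'   frequency), `"rc"` (equivalent RC of that network at the average
#'   frequency; its reactance still varies with frequency) or
#'   `"faradaic"` (charge-transfer conductance alone, purely resistive).
#' @param stim_marker facet marker of the stimulating electrode.
#' @param ground_marker facet marker of the ground electrode.
#' @param pulse the stimulating metal-potential [waveform()].
#' @param probes `n` x 3 matrix of observation points.
#' @param cpa,ct interface network parameters ([cpa_params()],
#'   [charge_transfer_params()]).
#' @param prune_threshold relative spectral threshold (default 1e-4; 0
#'   solves every frequency).
#' @param tissue_db tissue parameter table (default [tissue_table()]);
#'   pass a table with override entries for custom media.
#' @return object of class `fourier_job`.
#' @export
fourier_job <- function(mesh, tissues,
                        material_mode = c("dispersive", "capacitive"),
                        interface_mode = c("cpa", "rc", "faradaic"),
                        stim_marker, ground_marker, pulse, probes,
                        cpa = cpa_params(), ct = charge_transfer_params(),
                        prune_threshold = 1e-4,
                        tissue_db = tissue_table()) {
  material_mode <- match.arg(material_mode)
  interface_mode <- match.arg(interface_mode)
  stopifnot(inherits(pulse, "waveform"))
  mk <- unique(mesh$cell_markers)
  miss <- setdiff(as.character(mk), names(tissues))
  if (length(miss))
    stop("tissues missing for marker(s): ", paste(miss, collapse = ", "))
  structure(list(mesh = mesh, tissues = tissues,
                 material_mode = material_mode,
                 interface_mode = interface_mode,
                 stim_marker = as.integer(stim_marker),
                 ground_marker = as.integer(ground_marker),
                 pulse = pulse, probes = matrix(as.numeric(probes),
                                                ncol = 3L),
                 cpa = cpa, ct = ct, prune_threshold = prune_threshold,
                 tissue_db = tissue_db),
            class = "fourier_job")
}

#' Amplitude-weighted average frequency of a spectrum
#'
#' `sum(f |c|) / sum(|c|)` over positive frequencies: the reference
#' frequency at which "capacitive" material and "rc" interface modes
#' freeze their parameters.
#'
#' @param dec a [decompose()] result.
#' @return frequency (Hz).
#' @export
average_frequency <- function(dec) {
  a <- Mod(dec$coefficients[-1])
  f <- dec$frequencies[-1]
  if (sum(a) == 0) return(0)
  sum(f * a) / sum(a)
}

#' Run a FEM-Fourier transient simulation
#'
#' @param job a [fourier_job()].
#' @param tol,max_iter,preconditioner solver controls per frequency.
#' @param verbose print per-frequency progress.
#' @return list: `time` (s), `input` (the pulse samples), `probes`
#'   (matrix, one column per probe point: reconstructed potential time
#'   series, V), `f_avg`, `n_solved`, `dropped_energy`, `frequencies`
#'   (solved set).
#' @export
run_fourier_job <- function(job, tol = 1e-8, max_iter = 600L,
                            preconditioner = "chol", verbose = FALSE) {
  stopifnot(inherits(job, "fourier_job"))
  dec <- decompose(job$pulse)
  favg <- average_frequency(dec)
  pr <- prune_frequencies(dec$coefficients, job$prune_threshold)
  mesh <- job$mesh
  locator <- mesh_locator(mesh)
  tt <- job$tissue_db
  ## material admittivity per marker at frequency f
  mat_at <- function(f) {
    fm <- if (job$material_mode == "dispersive") f else favg
    out <- list()
    for (mk in names(job$tissues)) {
      ce <- cole_cole_eval(tt[[job$tissues[[mk]]]]$cole_cole, fm)
      out[[mk]] <- if (f == 0) complex(real = ce$sigma)
                   else admittivity_of(ce$sigma, ce$eps_r, f)$value
    }
    out
  }
  iface_at <- function(f) {
    base <- switch(job$interface_mode,
      cpa = interface_model("parallel", job$cpa, job$ct),
      rc = interface_model("parallel", job$cpa, job$ct,
                           fixed_frequency = favg),
      faradaic = interface_model("faradaic", job$cpa, job$ct))
    if (f == 0) {
      ## DC: faradaic path only (CPA diverges); the rc network keeps its
      ## conductive branch
      complex(real = Re(surface_admittance(base, 0)))
    } else surface_admittance(base, f)
  }
  np <- nrow(job$probes)
  H <- matrix(0i, length(dec$coefficients), np)
  solved <- integer(0)
  iters <- integer(0)
  fail <- numeric(0)
  for (k in pr$index) {
    f <- dec$frequencies[k]
    if (Mod(dec$coefficients[k]) == 0 && k != 1L) next
    y_iface <- iface_at(f)
    estim <- electrode_spec(job$stim_marker, "stimulating",
                            interface = y_iface, phi_metal = 1)
    egnd <- electrode_spec(job$ground_marker, "ground",
                           interface = y_iface)
    ok <- tryCatch({
      if (f == 0) {
        sys <- assemble_stiffness(mesh,
                                  lapply(mat_at(0), Re), order = 1L)
        sys <- add_robin_interface(sys, estim, 0)
        sys <- add_robin_interface(sys, egnd, 0)
        fld <- solve_fem(sys, "cg", tol = tol, max_iter = max_iter,
                         preconditioner = preconditioner)
      } else {
        sys <- assemble_complex_block(mesh, mat_at(f), order = 1L)
        sys <- add_robin_interface(sys, estim, f)
        sys <- add_robin_interface(sys, egnd, f)
        fld <- solve_fem(sys, "gmres", tol = tol, max_iter = max_iter,
                         preconditioner = preconditioner)
      }
      H[k, ] <- evaluate_field(fld, job$probes, locator = locator)
      solved <- c(solved, k)
      iters <- c(iters, fld$info$iterations)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) fail <- c(fail, f)
    if (verbose && length(solved) %% 10L == 0L)
      message(sprintf("solved %d/%d frequencies", length(solved),
                      length(pr$index)))
  }
  if (length(fail))
    stop("non-convergent frequency solves at f = ",
         paste(format(fail), collapse = ", "), " Hz")
  probes_t <- vapply(seq_len(np), function(p)
    .recompose(H[, p] * dec$coefficients, dec$n), numeric(dec$n))
  list(time = (seq_len(dec$n) - 1L) * dec$dt,
       input = job$pulse$samples,
       probes = probes_t,
       f_avg = favg, n_solved = length(solved),
       dropped_energy = pr$dropped_energy,
       frequencies = dec$frequencies[solved],
       iterations = iters)
}
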