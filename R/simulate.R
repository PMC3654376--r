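#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with physiologically
#' motivated defaults sized for desk-scale experiments: a 64-sensor montage,
#' an icosphere "cortex" tessellated into about 200 patches, a 20-spike
#' cluster, pink (1/f) background sources, and one planted coherent pair in
#' the alpha band at coupling 0.9.
#'
#' @param n_sensors number of scalp sensors (Fibonacci-distributed on an
#'   outer sphere).
#' @param subdivisions icosphere subdivision level (s gives `20 * 4^s`
#'   triangles).
#' @param radius_cm cortical sphere radius in cm.
#' @param sensor_radius_cm sensor sphere radius in cm (must exceed
#'   `radius_cm`).
#' @param n_patches target number of equivalent-dipole patches.
#' @param parcels_per_hemisphere number of parcels per hemisphere.
#' @param fs sampling rate in Hz (>= 140 so the 70 Hz analysis band is below
#'   Nyquist).
#' @param n_spikes number of interictal spikes in the recording.
#' @param spike_amplitude spike transient amplitude in source units.
#' @param spike_width_ms biphasic spike transient width (default 70 ms, a
#'   typical interictal spike duration).
#' @param noise_exponent spectral exponent of the 1/f^e background (default
#'   1, pink noise).
#' @param source_sd background source standard deviation (unit dipole
#'   moments).
#' @param planted_amp standard deviation of the planted narrow-band
#'   component (default 2 x `source_sd`: a strong pathological oscillation).
#' @param planted data.frame of planted coherent pairs with columns
#'   `patch_a`, `patch_b` (patch ids, or NA to auto-select two distant
#'   inter-hemispheric patches), `band` (band name), `strength` (coupling in
#'   `[0, 1]`); default one alpha-band pair at 0.9.
#' @param noise_sd sensor noise standard deviation in microvolt.
#' @param sigma volume conductivity in S/m (default 0.33, brain tissue).
#' @param seed RNG seed; identical configurations give identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sensors = 64L, subdivisions = 3L, radius_cm = 9,
                       sensor_radius_cm = 10, n_patches = 200L,
                       parcels_per_hemisphere = 10L, fs = 250,
                       n_spikes = 20L, spike_amplitude = 10,
                       spike_width_ms = 70, noise_exponent = 1,
                       source_sd = 1, planted_amp = 2 * source_sd,
                       planted = data.frame(patch_a = NA_integer_,
                                            patch_b = NA_integer_,
                                            band = "alpha", strength = 0.9),
                       noise_sd = 1, sigma = 0.33, seed = 1L) {
  stopifnot(fs >= 140, sensor_radius_cm > radius_cm, subdivisions >= 0)
  if (nrow(planted) && any(planted$strength < 0 | planted$strength > 1)) {
    stop("coupling strengths must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Icosphere cortical mesh
#'
#' Builds a geodesic sphere by recursive midpoint subdivision of an
#' icosahedron (`20 * 4^s` triangles, outward-consistent winding), labelled
#' into left/right hemispheres by the sign of x.
#'
#' @param subdivisions subdivision level `s >= 0`.
#' @param radius_cm sphere radius in cm (vertices are stored in mm).
#' @return A [cortical_mesh()].
#' @export
make_sphere_mesh <- function(subdivisions = 3L, radius_cm = 8) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  norm_rows <- function(m) m / sqrt(rowSums(m^2))
  v <- norm_rows(v)
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c0 <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c0); ca <- midpoint(c0, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c0, ca, bc), c(ab, bc, ca)
      )
    }
    v <- verts
    f <- nf
  }
  v <- v * radius_cm * 10  # cm -> mm
  mesh <- cortical_mesh(v, f)
  # enforce outward winding
  n <- triangle_normals(mesh)
  cen <- triangle_centroids(mesh)
  flip <- rowSums(n * cen) < 0
  if (any(flip)) {
    f2 <- mesh$triangles
    f2[flip, c(2L, 3L)] <- f2[flip, c(3L, 2L)]
    mesh <- cortical_mesh(mesh$vertices, f2, hemisphere = mesh$hemisphere)
  }
  mesh
}

#' Near-uniform sensor positions on a sphere (Fibonacci lattice)
#'
#' @param n number of sensors.
#' @param radius_cm sphere radius in cm.
#' @return n x 3 matrix of positions in mm.
#' @export
fibonacci_sensors <- function(n, radius_cm = 10) {
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * (seq_len(n) - 1L)
  radius_cm * 10 * cbind(r * cos(th), r * sin(th), z)
}

#' Analytic lead field for oriented patch dipoles
#'
#' Infinite-homogeneous-medium dipole potential
#' `V = p . (r - r0) / (4 pi sigma |r - r0|^3)` evaluated for each patch's
#' oriented unit dipole (at its centroid) and each sensor, then
#' average-referenced per column. Geometry is converted to metres; with unit
#' dipole moments of 10 nA m the entries come out in microvolt at realistic
#' scalp magnitudes. A homogeneous medium ignores the skull, so this is a
#' deliberately idealised forward model used to exercise the inverse and
#' coherence mathematics, not a physiological head model.
#'
#' @param tess a [tessellate_patches()] result (uses centroids and
#'   orientations).
#' @param sensors n_sensors x 3 positions in mm, strictly outside the source
#'   radius.
#' @param sigma conductivity in S/m (default 0.33).
#' @param reference average-reference the columns (default `TRUE`).
#' @return Lead field matrix, sensors x patches (microvolt per unit moment).
#' @export
make_leadfield <- function(tess, sensors, sigma = 0.33, reference = TRUE) {
  sensors <- as.matrix(sensors)
  src <- tess$centroid
  ori <- tess$orientation
  ns <- nrow(sensors)
  np <- nrow(src)
  K <- matrix(0, ns, np)
  sens_m <- sensors / 1000
  src_m <- src / 1000
  moment <- 1e-8  # 10 nA m per unit dipole moment
  for (p in seq_len(np)) {
    d <- sweep(sens_m, 2L, src_m[p, ], "-")
    r3 <- rowSums(d^2)^1.5
    if (any(r3 == 0)) stop("sensor coincident with source patch ", p)
    K[, p] <- moment * (d %*% ori[p, ]) / (4 * pi * sigma * r3) * 1e6  # V->uV
  }
  if (reference) K <- average_reference(K)
  K
}

# Gaussian noise with a 1/f^exponent amplitude spectrum, unit variance.
colored_noise <- function(n, fs, exponent = 1) {
  if (exponent == 0) return(rnorm(n))
  w <- rnorm(n)
  W <- fft(w)
  k <- 0:(n - 1)
  fold <- pmin(k, n - k)           # two-sided frequency index
  f <- fold * fs / n
  g <- c(0, f[-1L]^(-exponent / 2))
  x <- Re(fft(W * g, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(rep(0, n))
  x / s
}

# Gaussian noise band-limited to [f1, f2] Hz, unit variance.
band_noise <- function(n, fs, f1, f2) {
  w <- rnorm(n)
  W <- fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  mask <- as.numeric(f >= f1 & f <= f2)
  x <- Re(fft(W * mask, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(rep(0, n))
  x / s
}

# Remove the [f1, f2] Hz content of a signal (used so a planted pair's band
# content is exactly the mixed component).
band_stop <- function(x, fs, f1, f2) {
  n <- length(x)
  X <- fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  X[f >= f1 & f <= f2] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Biphasic spike transient
#'
#' A derivative-of-Gaussian waveform (one sharp positive and one negative
#' deflection) of the given total width, normalised to peak amplitude 1.
#'
#' @param fs sampling rate in Hz.
#' @param width_ms total transient width in ms (default 70).
#' @return Numeric vector of `round(fs * width_ms / 1000)` samples.
#' @export
spike_waveform <- function(fs, width_ms = 70) {
  n <- max(3L, as.integer(round(fs * width_ms / 1000)))
  t <- seq(-1, 1, length.out = n)
  s <- 1 / 3
  w <- -t / s^2 * exp(-t^2 / (2 * s^2))
  w / max(abs(w))
}

#' Simulate patch source waveforms with known structure
#'
#' Generates per-patch source time series consisting of (i) 1/f^e Gaussian
#' background noise, (ii) planted coherent pairs sharing a band-limited
#' component mixed at the configured coupling strength (the pair members'
#' own band content is replaced, so at strength 1 their band content is
#' identical and the asymptotic band coherence is 1), and (iii) a biphasic
#' spike transient at `n_spikes` known times on a designated focus patch.
#' Spike times closer than 3 s are respaced with a warning.
#'
#' @param config a [sim_config()].
#' @param tess a [tessellate_patches()] of the simulated mesh.
#' @param duration_s recording length; default spaces the spikes 3.5 s apart
#'   with 2 s margins.
#' @param spike_times optional explicit spike peak times in seconds.
#' @param focus_patch patch receiving the spike transient; default the patch
#'   with the most superior centroid.
#' @return List with `J` (patches x samples), `fs`, and `truth` (a list with
#'   `spike_times`, `focus_patch`, `pairs` -- the planted pairs with resolved
#'   patch ids and band edges -- and the generator parameters).
#' @export
simulate_sources <- function(config, tess, duration_s = NULL,
                             spike_times = NULL, focus_patch = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  if (is.null(spike_times)) {
    spike_times <- 2 + 3.5 * (seq_len(config$n_spikes) - 1L)
  }
  if (length(spike_times) > 1L && any(diff(sort(spike_times)) < 3)) {
    warning("spike times closer than 3 s; respacing at 3.5 s")
    spike_times <- 2 + 3.5 * (seq_along(spike_times) - 1L)
  }
  if (is.null(duration_s)) duration_s <- max(spike_times) + 2
  n <- as.integer(round(duration_s * fs))
  np <- tess$n_patches
  if (is.null(focus_patch)) focus_patch <- which.max(tess$centroid[, 3L])

  J <- matrix(0, np, n)
  for (p in seq_len(np)) {
    J[p, ] <- config$source_sd * colored_noise(n, fs, config$noise_exponent)
  }

  pairs <- config$planted
  bands <- band_table()
  if (nrow(pairs)) {
    pairs$patch_a <- as.integer(pairs$patch_a)
    pairs$patch_b <- as.integer(pairs$patch_b)
    for (i in seq_len(nrow(pairs))) {
      if (is.na(pairs$patch_a[i]) || is.na(pairs$patch_b[i])) {
        # two distant inter-hemispheric patches near the lateral poles
        right <- which(tess$hemisphere == "right")
        left <- which(tess$hemisphere == "left")
        pairs$patch_a[i] <- right[which.max(tess$centroid[right, 1L])]
        pairs$patch_b[i] <- left[which.min(tess$centroid[left, 1L])]
      }
      brow <- bands[bands$band == pairs$band[i], ]
      if (!nrow(brow)) stop("unknown band in planted pair: ", pairs$band[i])
      f1 <- brow$fmin
      f2 <- brow$fmax
      c0 <- pairs$strength[i]
      shared <- band_noise(n, fs, f1, f2)
      for (pp in c(pairs$patch_a[i], pairs$patch_b[i])) {
        own <- band_noise(n, fs, f1, f2)
        J[pp, ] <- band_stop(J[pp, ], fs, f1, f2) +
          config$planted_amp * (sqrt(c0) * shared + sqrt(1 - c0) * own)
      }
      pairs$fmin[i] <- f1
      pairs$fmax[i] <- f2
    }
  }

  spk <- config$spike_amplitude * spike_waveform(fs, config$spike_width_ms)
  half <- (length(spk) - 1L) %/% 2L
  peak_i <- which.max(abs(spk))
  for (t0 in spike_times) {
    centre <- as.integer(round(t0 * fs)) + 1L
    idx <- (centre - peak_i + 1L):(centre - peak_i + length(spk))
    ok <- idx >= 1L & idx <= n
    J[focus_patch, idx[ok]] <- J[focus_patch, idx[ok]] + spk[ok]
  }

  list(
    J = J, fs = fs,
    truth = list(
      spike_times = spike_times, focus_patch = focus_patch, pairs = pairs,
      fs = fs, duration_s = duration_s,
      source_sd = config$source_sd, planted_amp = config$planted_amp,
      spike_amplitude = config$spike_amplitude,
      spike_width_ms = config$spike_width_ms,
      noise_exponent = config$noise_exponent,
      units = list(J = "unit dipole moment (10 nA m)", time = "s")
    )
  )
}

#' Angular-sector parcellation of a tessellation
#'
#' Groups patches into named parcels per hemisphere by binning patch
#' centroids into polar bands and azimuthal sectors -- a deterministic,
#' contiguous stand-in for an anatomical (Brodmann-area) parcel table.
#' Labels are `P<k>_R` / `P<k>_L`.
#'
#' @param tess a [tessellate_patches()] result.
#' @param per_hemisphere target parcel count per hemisphere.
#' @return A data.frame `(patch_id, parcel, hemisphere)` covering every
#'   patch, suitable for [average_by_parcel()].
#' @export
make_parcel_map <- function(tess, per_hemisphere = 10L) {
  out <- data.frame(patch_id = seq_len(tess$n_patches),
                    parcel = NA_character_,
                    hemisphere = tess$hemisphere)
  for (h in c("right", "left")) {
    idx <- which(tess$hemisphere == h)
    if (!length(idx)) next
    npar <- min(per_hemisphere, length(idx))
    cen <- tess$centroid[idx, , drop = FALSE]
    nz <- max(1L, as.integer(round(sqrt(npar))))
    zq <- cut(rank(cen[, 3L], ties.method = "first"),
              breaks = nz, labels = FALSE)
    per_band <- diff(round(seq(0, npar, length.out = nz + 1L)))
    per_band[per_band < 1L] <- 1L
    lab <- integer(length(idx))
    off <- 0L
    for (b in seq_len(nz)) {
      sel <- which(zq == b)
      if (!length(sel)) next
      nsec <- per_band[b]
      az <- atan2(cen[sel, 2L], cen[sel, 1L])
      sec <- cut(rank(az, ties.method = "first"), breaks = nsec,
                 labels = FALSE)
      lab[sel] <- off + sec
      off <- off + nsec
    }
    suff <- if (h == "right") "R" else "L"
    out$parcel[idx] <- sprintf("P%02d_%s", lab, suff)
  }
  out
}

#' Simulate a complete synthetic recording with ground truth
#'
#' Composes the generator chain: icosphere mesh, tessellation, parcel map,
#' analytic lead field, structured sources, and noisy forward projection to
#' the sensors. Optionally writes every pipeline input to `out_dir` (EDF
#' recording, events TSV, PLY mesh, lead-field TSV, parcel TSV, truth JSON).
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory for the file bundle.
#' @return List with `recording` ([sensor_recording()]), `mesh`, `tess`,
#'   `K` (lead field), `W` (surface Laplacian), `parcel_map`, `sources`
#'   (true `J`), `truth`, and `files` (paths, when written).
#' @export
simulate_recording <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  restore <- local_rng(config$seed)
  on.exit(restore(), add = TRUE)

  mesh <- make_sphere_mesh(config$subdivisions, config$radius_cm)
  target <- mesh_area(mesh) / config$n_patches
  tess <- tessellate_patches(mesh, target_area = target, seed = 0L)
  parcel_map <- make_parcel_map(tess, config$parcels_per_hemisphere)
  sensors <- fibonacci_sensors(config$n_sensors, config$sensor_radius_cm)
  K <- make_leadfield(tess, sensors, sigma = config$sigma)
  W <- build_laplacian(tess$neighbors)
  sim <- simulate_sources(config, tess)
  Phi <- forward_project(K, sim$J, noise_sd = config$noise_sd)
  rec <- sensor_recording(Phi, config$fs,
                          spike_times = sim$truth$spike_times)
  out <- list(recording = rec, mesh = mesh, tess = tess, K = K, W = W,
              parcel_map = parcel_map, sources = sim$J, truth = sim$truth,
              sensors = sensors, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      edf = file.path(out_dir, "recording.edf"),
      events = file.path(out_dir, "events.tsv"),
      mesh = file.path(out_dir, "mesh.ply"),
      leadfield = file.path(out_dir, "leadfield.tsv"),
      parcels = file.path(out_dir, "parcels.tsv"),
      truth = file.path(out_dir, "truth.json")
    )
    write_edf(rec, files[["edf"]])
    write_events(sim$truth$spike_times, "spike", files[["events"]])
    write_mesh(mesh, files[["mesh"]])
    write_leadfield(K, files[["leadfield"]])
    write.table(parcel_map, files[["parcels"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(sim$truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$files <- files
  }
  out
}

#' Read and write lead-field matrices as TSV
#'
#' Sensors in rows, patches in columns, tab-separated with a header row of
#' patch ids and a leading `sensor` column.
#'
#' @param K lead field matrix.
#' @param path file path.
#' @return `read_leadfield()` returns the numeric matrix.
#' @export
write_leadfield <- function(K, path) {
  df <- data.frame(sensor = seq_len(nrow(K)), K)
  names(df) <- c("sensor", sprintf("patch_%d", seq_len(ncol(K))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  df <- read.delim(path)
  as.matrix(df[, -1L, drop = FALSE])
}

#' Read a parcel table
#'
#' TSV with columns `patch_id`, `parcel`, `hemisphere`.
#' @param path file path.
#' @return A validated parcel-map data.frame.
#' @export
read_parcel_map <- function(path) {
  normalize_parcel_map(read.delim(path, stringsAsFactors = FALSE))
}
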