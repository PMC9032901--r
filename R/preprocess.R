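#' Preprocessing configuration
#'
#' Bundles every tunable of the raw-spectrum-to-fingerprint chain. Defaults
#' follow standard MALDI-ToF biotyping practice: trim to the informative
#' mass window, square-root variance stabilisation, Savitzky-Golay
#' smoothing with half-window 15 points, SNIP baseline estimation with 30
#' clipping iterations, and retention of peaks with signal-to-noise >= 6.
#'
#' @param mode `"protein"` or `"lipid"`; sets mode-dependent defaults
#'   (trim window 3500--20000 Da vs 400--2000 Da, peak merge tolerance
#'   2.0 Da vs 0.5 Da).
#' @param mass_range_lo,mass_range_hi Analysis window in Da.
#' @param sg_half_window Savitzky-Golay half-window in points (window is
#'   `2*sg_half_window + 1` points wide).
#' @param sg_poly_order Degree of the local polynomial fit.
#' @param snip_iterations Number of SNIP clipping iterations (equals the
#'   widest clipping half-window in points).
#' @param snip_decreasing Use the decreasing window schedule (default);
#'   `FALSE` runs windows from 1 up to `snip_iterations`.
#' @param snr_threshold Minimum peak signal-to-noise ratio.
#' @param peak_half_window Local-maximum half-window in points for peak
#'   picking.
#' @param merge_tolerance Peaks closer than this (Da) are merged, keeping
#'   the more intense member.
#' @param step_order Stage order for the profile stages; any permutation of
#'   `c("trim", "sqrt", "smooth", "baseline", "detect")` containing
#'   `"detect"`. TIC normalisation and peak merging always run last.
#'
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(mode = "protein",
                              mass_range_lo = NULL, mass_range_hi = NULL,
                              sg_half_window = 15L, sg_poly_order = 3L,
                              snip_iterations = 30L, snip_decreasing = TRUE,
                              snr_threshold = 6, peak_half_window = 20L,
                              merge_tolerance = NULL,
                              step_order = c("trim", "sqrt", "smooth",
                                             "baseline", "detect")) {
  assert_mode(mode)
  trim <- TRIM_RANGES[[mode]]
  mass_range_lo <- mass_range_lo %||% trim[1L]
  mass_range_hi <- mass_range_hi %||% trim[2L]
  merge_tolerance <- merge_tolerance %||% unname(MERGE_TOL[[mode]])
  if (mass_range_lo >= mass_range_hi) {
    abort("`mass_range_lo` must be < `mass_range_hi`.",
          class = "fingernet_bad_param")
  }
  if (sg_half_window < sg_poly_order) {
    abort("`sg_half_window` must be >= `sg_poly_order`.",
          class = "fingernet_bad_param")
  }
  if (snip_iterations < 1L) {
    abort("`snip_iterations` must be >= 1.", class = "fingernet_bad_param")
  }
  if (snr_threshold <= 0) {
    abort("`snr_threshold` must be > 0.", class = "fingernet_bad_param")
  }
  bad <- setdiff(step_order, c("trim", "sqrt", "smooth", "baseline", "detect"))
  if (length(bad) || !"detect" %in% step_order) {
    abort("`step_order` must be stages from trim/sqrt/smooth/baseline/detect and include 'detect'.",
          class = "fingernet_bad_param")
  }
  structure(
    list(mode = mode, mass_range_lo = mass_range_lo,
         mass_range_hi = mass_range_hi,
         sg_half_window = as.integer(sg_half_window),
         sg_poly_order = as.integer(sg_poly_order),
         snip_iterations = as.integer(snip_iterations),
         snip_decreasing = isTRUE(snip_decreasing),
         snr_threshold = snr_threshold,
         peak_half_window = as.integer(peak_half_window),
         merge_tolerance = merge_tolerance,
         step_order = step_order),
    class = "preprocess_config"
  )
}

replace_intensity <- function(spectrum, intensity) {
  out <- spectrum
  out$intensity <- intensity
  out
}

#' Trim a spectrum to a mass window
#'
#' Retains exactly the points with `lo <= mz <= hi` (closed interval).
#'
#' @param spectrum A [raw_spectrum()].
#' @param lo,hi Window bounds in Da, `lo < hi`.
#' @return The trimmed [raw_spectrum()].
#' @export
trim_mass_range <- function(spectrum, lo, hi) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (lo >= hi) abort("`lo` must be < `hi`.", class = "fingernet_bad_param")
  keep <- spectrum$mz >= lo & spectrum$mz <= hi
  if (!any(keep)) {
    abort(sprintf("Spectrum %s is unusable: no points in [%g, %g] Da.",
                  node_id(spectrum), lo, hi),
          class = "fingernet_unusable_spectrum")
  }
  out <- spectrum
  out$mz <- spectrum$mz[keep]
  out$intensity <- spectrum$intensity[keep]
  out
}

#' Square-root intensity transform
#'
#' Variance stabilisation for ion-counting detectors: each intensity is
#' replaced by its square root; the m/z axis is unchanged.
#'
#' @param spectrum A [raw_spectrum()].
#' @return The transformed [raw_spectrum()].
#' @export
sqrt_transform <- function(spectrum) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (any(spectrum$intensity < 0)) {
    abort("Negative intensity; cannot square-root transform.",
          class = "fingernet_bad_spectrum")
  }
  replace_intensity(spectrum, sqrt(spectrum$intensity))
}

# Savitzky-Golay convolution coefficients for the window centre:
# first row of (A'A)^{-1} A' with A the Vandermonde matrix on -h..h.
sg_coefficients <- function(half_window, poly_order) {
  x <- seq.int(-half_window, half_window)
  A <- outer(x, 0:poly_order, `^`)
  # value at the centre = e1' (A'A)^{-1} A' y
  drop(solve(crossprod(A), t(A))[1L, ])
}

# Least-squares polynomial fit over an index window, evaluated at `at`
# (index offsets relative to the window's first point).
poly_fit_at <- function(y, offsets, poly_order, at) {
  A <- outer(offsets, 0:min(poly_order, length(offsets) - 1L), `^`)
  beta <- qr.coef(qr(A), y)
  beta[is.na(beta)] <- 0
  drop(outer(at, 0:(length(beta) - 1L), `^`) %*% beta)
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the centre value of a least-squares polynomial of
#' degree `poly_order` fitted over the `2*half_window + 1` surrounding
#' points (index-based windows). Points within `half_window` of either end
#' are smoothed with the truncated window actually available.
#'
#' @param spectrum A [raw_spectrum()].
#' @param half_window Half-window size in points.
#' @param poly_order Polynomial degree, `< 2*half_window + 1`.
#' @return The smoothed [raw_spectrum()].
#' @export
savitzky_golay_smooth <- function(spectrum, half_window = 15L,
                                  poly_order = 3L) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  n <- length(spectrum$intensity)
  w <- 2L * half_window + 1L
  if (w > n) {
    abort(sprintf("Spectrum has %d points but the smoothing window needs %d; use a smaller half_window.",
                  n, w), class = "fingernet_bad_param")
  }
  if (poly_order >= w) {
    abort("`poly_order` must be < 2*half_window + 1.",
          class = "fingernet_bad_param")
  }
  y <- spectrum$intensity
  coef <- sg_coefficients(half_window, poly_order)
  smoothed <- stats::filter(y, coef, sides = 2)
  smoothed <- as.numeric(smoothed)
  # truncated-window fits at the edges
  for (i in seq_len(half_window)) {
    lo <- 1L
    hi <- i + half_window
    smoothed[i] <- poly_fit_at(y[lo:hi], seq.int(lo, hi) - lo, poly_order,
                               i - lo)
    j <- n - i + 1L
    lo2 <- j - half_window
    smoothed[j] <- poly_fit_at(y[lo2:n], seq.int(lo2, n) - lo2, poly_order,
                               j - lo2)
  }
  replace_intensity(spectrum, smoothed)
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak clipping: the baseline
#' starts as the intensity profile and, for clipping half-windows `k`
#' running from `iterations` down to 1 (decreasing schedule, the default),
#' every point is replaced by
#' `min(b[i], (b[i-k] + b[i+k]) / 2)` with indices clamped at the spectrum
#' edges. The result never exceeds the input pointwise. No log-log-sqrt
#' pre-compression is applied: the chain square-root transforms intensities
#' upstream.
#'
#' @param spectrum A [raw_spectrum()] (typically smoothed).
#' @param iterations Number of clipping passes (>= 1); also the widest
#'   clipping half-window in points.
#' @param decreasing Use the decreasing window schedule (default `TRUE`).
#' @return Numeric baseline vector, same length as the spectrum.
#' @export
snip_baseline <- function(spectrum, iterations = 30L, decreasing = TRUE) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (iterations < 1L) {
    abort("`iterations` must be >= 1.", class = "fingernet_bad_param")
  }
  y <- spectrum$intensity
  n <- length(y)
  ks <- if (isTRUE(decreasing)) seq.int(iterations, 1L) else seq_len(iterations)
  b <- y
  idx <- seq_len(n)
  for (k in ks) {
    left <- pmax(idx - k, 1L)
    right <- pmin(idx + k, n)
    b <- pmin(b, (b[left] + b[right]) / 2)
  }
  b
}

#' Subtract a baseline
#'
#' Subtracts the baseline pointwise and clamps at zero, so the corrected
#' spectrum never has negative intensities.
#'
#' @param spectrum A [raw_spectrum()].
#' @param baseline Numeric vector of the same length (e.g. from
#'   [snip_baseline()]).
#' @return The corrected [raw_spectrum()].
#' @export
remove_baseline <- function(spectrum, baseline) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (length(baseline) != length(spectrum$intensity)) {
    abort("Baseline length does not match the spectrum.",
          class = "fingernet_bad_param")
  }
  replace_intensity(spectrum, pmax(spectrum$intensity - baseline, 0))
}

#' Robust noise level of a spectrum
#'
#' Estimates the noise standard deviation as 1.4826 times the median
#' absolute deviation of the intensities about their median, over the whole
#' (baseline-corrected) spectrum. For a flat spectrum the estimate is 0 and
#' downstream signal-to-noise ratios are undefined.
#'
#' @param spectrum A [raw_spectrum()], baseline already removed.
#' @return Noise level in intensity units (>= 0).
#' @export
estimate_noise <- function(spectrum) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (length(spectrum$intensity) < 10L) {
    abort("Need at least 10 points to estimate noise.",
          class = "fingernet_bad_param")
  }
  stats::mad(spectrum$intensity)  # 1.4826 * MAD about the median
}

#' Pick peaks by local maximum and signal-to-noise
#'
#' A point is a peak iff it is the strict maximum of its index window of
#' `2*peak_half_window + 1` points (ties broken to the lowest index) and
#' its intensity divided by `noise` is at least `snr_threshold`. Because
#' the criterion is a ratio, the picked peaks are invariant under uniform
#' intensity scaling.
#'
#' @param spectrum A baseline-corrected [raw_spectrum()].
#' @param snr_threshold Minimum signal-to-noise ratio (default 6).
#' @param peak_half_window Half-window in points for the local-maximum test.
#' @param noise Noise level; defaults to [estimate_noise()] of the spectrum.
#' @return A [peaklist()] (not yet normalised), peaks in ascending m/z.
#' @export
detect_peaks <- function(spectrum, snr_threshold = 6, peak_half_window = 20L,
                         noise = NULL) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  noise <- noise %||% estimate_noise(spectrum)
  if (noise <= 0) {
    abort(sprintf("Noise level is 0 for %s; S/N is undefined - inspect the spectrum.",
                  node_id(spectrum)), class = "fingernet_zero_noise")
  }
  y <- spectrum$intensity
  n <- length(y)
  is_peak <- y >= snr_threshold * noise
  for (d in seq_len(peak_half_window)) {
    if (!any(is_peak)) break
    lead <- c(y[-seq_len(d)], rep(-Inf, d))   # y[i + d]
    lag  <- c(rep(-Inf, d), y[seq_len(n - d)]) # y[i - d]
    # strict max over the window; equal values concede to the lower index
    is_peak <- is_peak & (y >= lead) & (y > lag)
  }
  peaklist(spectrum$mz[is_peak], y[is_peak],
           sample_id = spectrum$sample_id,
           replicate_id = spectrum$replicate_id,
           mode = spectrum$mode, normalized = FALSE)
}

#' Merge peaks closer than a tolerance
#'
#' Greedy non-maximum suppression: peaks are visited in decreasing
#' intensity (ties by lower m/z) and kept unless a stronger peak within
#' `tolerance` Da has already been kept, so of any close group the most
#' intense member survives.
#'
#' @param peaks A [peaklist()].
#' @param tolerance Merge tolerance in Da.
#' @return The merged [peaklist()].
#' @export
merge_close_peaks <- function(peaks, tolerance) {
  stopifnot(inherits(peaks, "peaklist"))
  n <- length(peaks$mz)
  if (n <= 1L) return(peaks)
  ord <- order(-peaks$intensity, peaks$mz)
  kept_mz <- numeric(0)
  keep <- logical(n)
  for (i in ord) {
    if (!length(kept_mz) || min(abs(kept_mz - peaks$mz[i])) > tolerance) {
      keep[i] <- TRUE
      kept_mz <- c(kept_mz, peaks$mz[i])
    }
  }
  out <- peaks
  out$mz <- peaks$mz[keep]
  out$intensity <- peaks$intensity[keep]
  out
}

#' Total-ion-current normalisation
#'
#' Divides peak intensities by their sum, so the fingerprint's intensities
#' sum to one (within 1e-9). Idempotent.
#'
#' @param peaks A non-empty [peaklist()].
#' @return The normalised [peaklist()] with `normalized = TRUE`.
#' @export
tic_normalize <- function(peaks) {
  stopifnot(inherits(peaks, "peaklist"))
  if (length(peaks$mz) == 0L) {
    abort(sprintf("Peak list %s is empty; cannot TIC-normalise.",
                  node_id(peaks)), class = "fingernet_bad_peaklist")
  }
  total <- sum(peaks$intensity)
  if (total <= 0) {
    abort("Total intensity is zero; cannot TIC-normalise.",
          class = "fingernet_bad_peaklist")
  }
  out <- peaks
  out$intensity <- peaks$intensity / total
  out$normalized <- TRUE
  out
}

#' Full preprocessing chain: raw spectrum to normalised fingerprint
#'
#' Applies, in the default stage order, mass-window trim, square-root
#' transform, Savitzky-Golay smoothing, SNIP baseline subtraction, robust
#' noise estimation with S/N peak picking, close-peak merging, and TIC
#' normalisation. `config$step_order` can reorder the profile stages for
#' method comparison; peak merging and TIC normalisation always run last.
#'
#' @param raw A [raw_spectrum()].
#' @param config A [preprocess_config()]; defaults to the configuration for
#'   the spectrum's mode.
#' @param verbose Emit a one-line log per spectrum.
#' @return A normalised [peaklist()], or `NULL` (with a warning of class
#'   `fingernet_unusable`) when no peak clears the S/N threshold.
#' @export
preprocess_pipeline <- function(raw, config = NULL, verbose = FALSE) {
  stopifnot(inherits(raw, "raw_spectrum"))
  config <- config %||% preprocess_config(mode = raw$mode)
  n_in <- length(raw$mz)
  state <- raw
  centroided <- FALSE
  noise <- NA_real_
  run_stage <- function(state, stage) {
    switch(stage,
      trim = trim_mass_range(state, config$mass_range_lo, config$mass_range_hi),
      sqrt = sqrt_transform(state),
      smooth = savitzky_golay_smooth(state, config$sg_half_window,
                                     config$sg_poly_order),
      baseline = remove_baseline(state,
                                 snip_baseline(state, config$snip_iterations,
                                               config$snip_decreasing)),
      abort(sprintf("Unknown stage '%s'.", stage),
            class = "fingernet_bad_param")
    )
  }
  for (stage in config$step_order) {
    if (stage == "detect") {
      noise <- estimate_noise(state)
      state <- tryCatch(
        detect_peaks(state, config$snr_threshold, config$peak_half_window,
                     noise = noise),
        fingernet_zero_noise = function(e) stop(e),
        error = function(e) {
          abort(sprintf("Stage 'detect' failed for %s: %s",
                        node_id(raw), conditionMessage(e)),
                class = "fingernet_stage_error")
        }
      )
      centroided <- TRUE
    } else if (centroided) {
      # non-canonical orders apply the remaining profile transforms to the
      # centroided intensity vector (comparison runs only)
      state <- switch(stage,
        trim = {
          keep <- state$mz >= config$mass_range_lo &
            state$mz <= config$mass_range_hi
          out <- state; out$mz <- state$mz[keep]
          out$intensity <- state$intensity[keep]; out
        },
        sqrt = { out <- state; out$intensity <- sqrt(state$intensity); out },
        smooth = state,
        baseline = state
      )
    } else {
      state <- tryCatch(
        run_stage(state, stage),
        fingernet_unusable_spectrum = function(e) stop(e),
        error = function(e) {
          abort(sprintf("Stage '%s' failed for %s: %s",
                        stage, node_id(raw), conditionMessage(e)),
                class = "fingernet_stage_error")
        }
      )
    }
  }
  if (length(state$mz) == 0L) {
    warn(sprintf("Spectrum %s is unusable: no peak reaches S/N >= %g.",
                 node_id(raw), config$snr_threshold),
         class = "fingernet_unusable")
    return(NULL)
  }
  out <- merge_close_peaks(state, config$merge_tolerance)
  out <- tic_normalize(out)
  if (verbose) {
    message(sprintf(
      "preprocess id=%s points_in=%d peaks_out=%d noise=%.4g stages=%s",
      node_id(raw), n_in, length(out$mz), noise,
      paste(config$step_order, collapse = ">")))
  }
  out
}
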