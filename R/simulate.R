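#' Simulation configuration
#'
#' Parameters of the hierarchical fingerprint simulator. Strains inherit a
#' three-level peak hierarchy — peaks shared by the whole taxonomic order,
#' peaks shared by the genus, and strain-specific peaks — which is the
#' minimal structure able to reproduce order-level clusters with genus
#' substructure. Replicate noise consists of m/z jitter, lognormal
#' intensity noise, random peak dropout and spurious noise peaks; lipid
#' fingerprints can additionally be spiked with a PEG ladder.
#'
#' @param mode `"protein"` or `"lipid"`.
#' @param n_orders,genera_per_order,strains_per_genus,replicates_per_strain
#'   Panel layout (fully crossed).
#' @param peaks_order,peaks_genus,peaks_strain Template peaks per hierarchy
#'   level (defaults 30/10/10).
#' @param mz_jitter_sd Replicate m/z jitter SD in Da (default 1.5 protein,
#'   0.05 lipid, reflecting linear vs reflectron mass accuracy).
#' @param intensity_sdlog Lognormal SD of multiplicative intensity noise.
#' @param dropout Probability that a template peak is missing from a
#'   replicate.
#' @param noise_peaks Mean number (Poisson) of spurious peaks per replicate.
#' @param peg_prob Probability of spiking a lipid replicate with a PEG
#'   ladder.
#' @param reference_fraction Fraction of strains labelled `reference` in
#'   the manifest (the rest are `query`).
#' @param raw Raw-profile parameters: `grid_step` (Da), `peak_sd` (Gaussian
#'   peak width, Da), `baseline_amp` and `baseline_decay` (exponential
#'   baseline), `noise_sd` (half-normal additive noise),
#'   `intensity_scale` (counts per unit template intensity). `NULL` entries
#'   take mode defaults.
#' @param seed Root seed (mandatory); every derived random draw flows from
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(mode = "protein", n_orders = 4L, genera_per_order = 3L,
                       strains_per_genus = 2L, replicates_per_strain = 2L,
                       peaks_order = 30L, peaks_genus = 10L, peaks_strain = 10L,
                       mz_jitter_sd = NULL, intensity_sdlog = 0.3,
                       dropout = 0.1, noise_peaks = 5, peg_prob = 0,
                       reference_fraction = 0, raw = list(), seed) {
  assert_mode(mode)
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory.", class = "fingernet_bad_param")
  }
  counts <- c(n_orders, genera_per_order, strains_per_genus,
              replicates_per_strain)
  if (any(counts < 1L)) {
    abort("Panel layout counts must all be >= 1.",
          class = "fingernet_bad_param")
  }
  probs <- c(dropout, peg_prob, reference_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must be in [0, 1].", class = "fingernet_bad_param")
  }
  mz_jitter_sd <- mz_jitter_sd %||% if (mode == "protein") 1.5 else 0.05
  if (mz_jitter_sd < 0 || intensity_sdlog < 0) {
    abort("Noise magnitudes must be >= 0.", class = "fingernet_bad_param")
  }
  raw_defaults <- if (mode == "protein") {
    list(grid_step = 1.0, peak_sd = 3.0, baseline_amp = 100,
         baseline_decay = 20000, noise_sd = 1.0, intensity_scale = 1e4)
  } else {
    list(grid_step = 0.05, peak_sd = 0.12, baseline_amp = 100,
         baseline_decay = 2000, noise_sd = 1.0, intensity_scale = 1e4)
  }
  raw <- utils::modifyList(raw_defaults, raw)
  if (raw$grid_step <= 0) {
    abort("`raw$grid_step` must be > 0.", class = "fingernet_bad_param")
  }
  structure(
    list(mode = mode, n_orders = as.integer(n_orders),
         genera_per_order = as.integer(genera_per_order),
         strains_per_genus = as.integer(strains_per_genus),
         replicates_per_strain = as.integer(replicates_per_strain),
         peaks_order = as.integer(peaks_order),
         peaks_genus = as.integer(peaks_genus),
         peaks_strain = as.integer(peaks_strain),
         mz_jitter_sd = mz_jitter_sd, intensity_sdlog = intensity_sdlog,
         dropout = dropout, noise_peaks = noise_peaks, peg_prob = peg_prob,
         reference_fraction = reference_fraction, raw = raw,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Derived sub-seeds keep template and replicate randomness in separate,
# reproducible streams.
derive_seed <- function(root, k) {
  as.integer((as.double(root) + k * 7919) %% (2^31 - 1))
}

#' Simulated panel manifest
#'
#' Builds the fully crossed order x genus x strain x replicate manifest
#' with deterministic identifiers (`o01g02s01` etc.).
#'
#' @param config A [sim_config()].
#' @return A manifest tibble (see [read_taxonomy()]).
#' @export
make_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(
    replicate_id = seq_len(config$replicates_per_strain),
    strain = seq_len(config$strains_per_genus),
    genus_i = seq_len(config$genera_per_order),
    order_i = seq_len(config$n_orders)
  )[, 4:1]
  n_strains <- config$n_orders * config$genera_per_order *
    config$strains_per_genus
  n_ref_strains <- round(config$reference_fraction * n_strains)
  strain_key <- with(grid, paste(order_i, genus_i, strain))
  strain_rank <- match(strain_key, unique(strain_key))
  tibble::tibble(
    sample_id = sprintf("o%02dg%02ds%02d", grid$order_i, grid$genus_i,
                        grid$strain),
    replicate_id = as.integer(grid$replicate_id),
    order = sprintf("order%02d", grid$order_i),
    genus = sprintf("genus%02d_%02d", grid$order_i, grid$genus_i),
    species = sprintf("genus%02d_%02d sp. %d", grid$order_i, grid$genus_i,
                      grid$strain),
    source = ifelse(strain_rank <= n_ref_strains, "reference", "query"),
    mode = config$mode
  )
}

# Draw n positions uniformly in [lo, hi] with a minimum mutual gap, also
# keeping clear of `avoid` positions.
draw_positions <- function(n, lo, hi, min_gap, avoid = numeric()) {
  if (n * min_gap > (hi - lo)) {
    abort("Mass range too small for the requested peak count at the required spacing.",
          class = "fingernet_bad_param")
  }
  pos <- numeric(0)
  tries <- 0L
  while (length(pos) < n) {
    cand <- runif(1, lo, hi)
    if (!length(c(pos, avoid)) ||
        min(abs(c(pos, avoid) - cand)) >= min_gap) {
      pos <- c(pos, cand)
    }
    tries <- tries + 1L
    if (tries > 1000L * n) {
      abort("Could not place template peaks at the required spacing.",
            class = "fingernet_bad_param")
    }
  }
  sort(pos)
}

#' Hierarchical peak templates for a panel
#'
#' Draws order-shared peaks once per order, genus-shared peaks once per
#' genus and strain-specific peaks once per strain, uniformly in the mode's
#' trimmed mass range with a minimum spacing of twice the merge tolerance,
#' with lognormal base intensities normalised per strain template.
#'
#' @param manifest Manifest from [make_taxonomy()].
#' @param config The matching [sim_config()].
#' @return Named list (by `sample_id`) of `taxon_template` objects with
#'   fields `mz`, `intensity`, `level` (`order`/`genus`/`strain`), `order`,
#'   `genus`, `sample_id`, `mode`.
#' @export
make_templates <- function(manifest, config) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- validate_manifest(manifest)
  trim <- TRIM_RANGES[[config$mode]]
  min_gap <- 2 * unname(MERGE_TOL[[config$mode]])
  strains <- dplyr::distinct(manifest, .data$sample_id, .data$order,
                             .data$genus)
  withr::with_seed(derive_seed(config$seed, 1L), {
    order_peaks <- lapply(
      setNames(nm = sort(unique(strains$order))),
      function(o) list(mz = draw_positions(config$peaks_order, trim[1L],
                                           trim[2L], min_gap),
                       int = rlnorm(config$peaks_order, 0, 0.5))
    )
    genus_tbl <- dplyr::distinct(strains, .data$order, .data$genus)
    genus_peaks <- list()
    for (k in order(genus_tbl$genus)) {
      o <- genus_tbl$order[k]; g <- genus_tbl$genus[k]
      genus_peaks[[g]] <- list(
        mz = draw_positions(config$peaks_genus, trim[1L], trim[2L], min_gap,
                            avoid = order_peaks[[o]]$mz),
        int = rlnorm(config$peaks_genus, 0, 0.5)
      )
    }
    templates <- list()
    for (k in order(strains$sample_id)) {
      s <- strains[k, ]
      op <- order_peaks[[s$order]]
      gp <- genus_peaks[[s$genus]]
      sp <- list(
        mz = draw_positions(config$peaks_strain, trim[1L], trim[2L], min_gap,
                            avoid = c(op$mz, gp$mz)),
        int = rlnorm(config$peaks_strain, 0, 0.5)
      )
      mz <- c(op$mz, gp$mz, sp$mz)
      int <- c(op$int, gp$int, sp$int)
      level <- rep(c("order", "genus", "strain"),
                   c(length(op$mz), length(gp$mz), length(sp$mz)))
      ord <- order(mz)
      templates[[s$sample_id]] <- structure(
        list(sample_id = s$sample_id, order = s$order, genus = s$genus,
             mode = config$mode, mz = mz[ord],
             intensity = int[ord] / sum(int), level = level[ord]),
        class = "taxon_template"
      )
    }
    templates[order(names(templates))]
  })
}

#' @export
print.taxon_template <- function(x, ...) {
  cat(sprintf("<taxon_template> %s (%s / %s), %d peaks [%s]\n",
              x$sample_id, x$order, x$genus, length(x$mz), x$mode))
  invisible(x)
}

# Non-maximum-suppression merge on bare vectors; returns kept indices in
# ascending-mz order.
nms_keep <- function(mz, intensity, tol) {
  n <- length(mz)
  if (n <= 1L) return(seq_len(n))
  ord <- order(-intensity, mz)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || min(abs(mz[kept] - mz[i])) > tol) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Simulate a replicate fingerprint from a template
#'
#' Each template peak survives with probability `1 - dropout`, its m/z is
#' jittered by centred Gaussian noise and its intensity multiplied by
#' lognormal noise; Poisson-many spurious noise peaks are added at uniform
#' positions; lipid replicates are optionally spiked with a PEG ladder
#' (spacing 44.026 Da). Peaks closer than the mode's merge tolerance are
#' merged keeping the stronger member, and the result is TIC-normalised.
#'
#' @param template A `taxon_template` from [make_templates()].
#' @param config The matching [sim_config()].
#' @param replicate_id Replicate number for the returned fingerprint.
#' @param replicate_seed Seed for this replicate's random draws.
#' @return A normalised [peaklist()]; if a PEG ladder was injected the
#'   attribute `peg_spiked` is `TRUE`.
#' @export
simulate_peaklist <- function(template, config, replicate_id = 1L,
                              replicate_seed) {
  stopifnot(inherits(template, "taxon_template"),
            inherits(config, "sim_config"))
  trim <- TRIM_RANGES[[config$mode]]
  tol <- unname(MERGE_TOL[[config$mode]])
  withr::with_seed(as.integer(replicate_seed), {
    keep <- runif(length(template$mz)) >= config$dropout
    if (!any(keep)) keep[which.max(template$intensity)] <- TRUE
    mz <- template$mz[keep] + rnorm(sum(keep), 0, config$mz_jitter_sd)
    int <- template$intensity[keep] * rlnorm(sum(keep), 0,
                                             config$intensity_sdlog)
    n_noise <- rpois(1L, config$noise_peaks)
    if (n_noise > 0L) {
      mz <- c(mz, runif(n_noise, trim[1L], trim[2L]))
      int <- c(int, rlnorm(n_noise, log(0.3 * median(template$intensity)),
                           0.5))
    }
    peg <- FALSE
    if (config$mode == "lipid" && config$peg_prob > 0 &&
        runif(1) < config$peg_prob) {
      peg <- TRUE
      start <- runif(1, 420, 700)
      len <- sample(8:15, 1L)
      peg_mz <- start + 44.026 * seq.int(0L, len - 1L)
      peg_mz <- peg_mz[peg_mz <= trim[2L]]
      mz <- c(mz, peg_mz)
      int <- c(int, rlnorm(length(peg_mz), log(median(template$intensity)),
                           0.3))
    }
    inside <- mz >= trim[1L] & mz <= trim[2L]
    mz <- mz[inside]; int <- int[inside]
    ord <- order(mz)
    mz <- mz[ord]; int <- int[ord]
    kept <- nms_keep(mz, int, tol)
    pl <- peaklist(mz[kept], int[kept], sample_id = template$sample_id,
                   replicate_id = replicate_id, mode = config$mode)
    pl <- tic_normalize(pl)
    attr(pl, "peg_spiked") <- peg
    pl
  })
}

#' Simulate a raw profile spectrum from a template
#'
#' Builds a continuous spectrum on a uniform m/z grid over the mode's
#' acquisition range: a sum of Gaussian peaks of width `raw$peak_sd` at
#' jittered template positions with heights proportional to the template
#' intensities, plus an exponentially decaying baseline and non-negative
#' (half-normal) additive noise.
#'
#' @inheritParams simulate_peaklist
#' @return A [raw_spectrum()].
#' @export
simulate_raw_spectrum <- function(template, config, replicate_id = 1L,
                                  replicate_seed) {
  stopifnot(inherits(template, "taxon_template"),
            inherits(config, "sim_config"))
  rng <- MODE_RANGES[[config$mode]]
  rp <- config$raw
  withr::with_seed(as.integer(replicate_seed), {
    grid <- seq(rng[1L], rng[2L], by = rp$grid_step)
    pos <- template$mz + rnorm(length(template$mz), 0, config$mz_jitter_sd)
    height <- template$intensity * rp$intensity_scale *
      rlnorm(length(template$mz), 0, config$intensity_sdlog)
    signal <- numeric(length(grid))
    half_span <- 6 * rp$peak_sd
    for (p in seq_along(pos)) {
      i1 <- max(1L, ceiling((pos[p] - half_span - rng[1L]) / rp$grid_step) + 1L)
      i2 <- min(length(grid),
                floor((pos[p] + half_span - rng[1L]) / rp$grid_step) + 1L)
      if (i1 > i2) next
      idx <- i1:i2
      signal[idx] <- signal[idx] +
        height[p] * exp(-(grid[idx] - pos[p])^2 / (2 * rp$peak_sd^2))
    }
    baseline <- rp$baseline_amp * exp(-(grid - rng[1L]) / rp$baseline_decay)
    # shot-noise scaling: detector noise grows with the local ion flux, the
    # regime the chain's square-root transform is designed to stabilise
    level <- signal + baseline
    noise <- abs(rnorm(length(grid), 0, rp$noise_sd)) *
      sqrt(pmax(level, 1) / max(rp$baseline_amp, 1))
    raw_spectrum(grid, level + noise,
                 sample_id = template$sample_id,
                 replicate_id = replicate_id, mode = config$mode)
  })
}

#' Simulate a complete panel
#'
#' Convenience wrapper: builds the manifest, the templates and one
#' fingerprint (or raw spectrum) per replicate, with per-replicate seeds
#' derived deterministically from the root seed.
#'
#' @param config A [sim_config()].
#' @param raw If `TRUE`, return raw profile spectra instead of peak lists.
#' @return List with `manifest`, `templates`, `peaklists` (or `spectra`),
#'   and `replicate_seeds`.
#' @export
simulate_panel <- function(config, raw = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- make_taxonomy(config)
  templates <- make_templates(manifest, config)
  rep_seeds <- withr::with_seed(derive_seed(config$seed, 2L),
                                sample.int(2^31 - 2, nrow(manifest)))
  objs <- purrr::map(seq_len(nrow(manifest)), function(k) {
    tpl <- templates[[manifest$sample_id[k]]]
    if (raw) {
      simulate_raw_spectrum(tpl, config, manifest$replicate_id[k],
                            rep_seeds[k])
    } else {
      simulate_peaklist(tpl, config, manifest$replicate_id[k], rep_seeds[k])
    }
  })
  out <- list(manifest = manifest, templates = templates,
              replicate_seeds = rep_seeds)
  if (raw) out$spectra <- objs else out$peaklists <- objs
  out
}
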