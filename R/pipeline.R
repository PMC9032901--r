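#' Run the full chemotaxonomic pipeline
#'
#' One-shot orchestration: (optionally) preprocess raw spectra into
#' fingerprints, flag polymer contamination, compute the all-pairs cosine
#' matrix, build the thresholded mutual top-k network and the t-SNE
#' embedding, cluster by connected components, and summarise cluster/order
#' composition and query concordance against the taxonomy manifest.
#'
#' @param inputs List of [peaklist()] or [raw_spectrum()] objects (all the
#'   same mode), or a character vector of MGF / mzXML file paths.
#' @param taxonomy Manifest tibble (see [read_taxonomy()]) or path to a
#'   manifest TSV.
#' @param preprocess A [preprocess_config()] used when `inputs` contains
#'   raw spectra; defaults per mode.
#' @param mz_tolerance Cosine matching tolerance in Da (mode default when
#'   `NULL`).
#' @param threshold,top_k Network construction parameters
#'   (see [build_network()]).
#' @param perplexity t-SNE perplexity (see [tsne_embed()]).
#' @param seed Seed recorded for the embedding and run manifest.
#' @param drop_polymer Drop polymer-flagged fingerprints before the
#'   similarity stage (default `FALSE`: they are flagged but kept).
#' @param outdir Optional output directory; when given, writes `peaks.mgf`,
#'   `edges.tsv`, `coords.tsv`, `composition.tsv`, `concordance.tsv` and
#'   `run_manifest.json`.
#' @param verbose Log one line per stage.
#' @return A `fingernet_run` object: list with `peaklists`, `similarity`,
#'   `network`, `embedding`, `assignment`, `composition`, `concordance`
#'   (NULL when the manifest has no queries), and `run_manifest`.
#' @export
run_pipeline <- function(inputs, taxonomy, preprocess = NULL,
                         mz_tolerance = NULL, threshold = 0.7, top_k = 10L,
                         perplexity = 15, seed = 42L, drop_polymer = FALSE,
                         outdir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  taxonomy <- validate_manifest(taxonomy)

  if (is.character(inputs)) {
    paths <- inputs
    inputs <- list()
    for (p in paths) {
      if (grepl("\\.mgf$", p, ignore.case = TRUE)) {
        inputs <- c(inputs, read_mgf(p))
      } else if (grepl("\\.mzxml$", p, ignore.case = TRUE)) {
        inputs <- c(inputs, read_mzxml(p))
      } else {
        abort(sprintf("Unrecognised input file type: %s", p),
              class = "fingernet_io_error")
      }
    }
  }
  stopifnot(is.list(inputs), length(inputs) >= 2L)
  modes <- unique(purrr::map_chr(inputs, "mode"))
  if (length(modes) != 1L) {
    abort("Inputs mix protein and lipid spectra; run the modes separately.",
          class = "fingernet_mode_mismatch")
  }

  is_raw <- purrr::map_lgl(inputs, inherits, "raw_spectrum")
  if (any(is_raw)) {
    preprocess <- preprocess %||% preprocess_config(mode = modes)
    say("stage=preprocess n=%d", sum(is_raw))
    inputs <- purrr::map(inputs, function(x) {
      if (inherits(x, "raw_spectrum")) {
        preprocess_pipeline(x, preprocess, verbose = verbose)
      } else x
    })
    dropped <- purrr::map_lgl(inputs, is.null)
    if (any(dropped)) say("stage=preprocess unusable=%d", sum(dropped))
    inputs <- inputs[!dropped]
  }

  inputs <- flag_polymer_series(inputs)
  flagged <- purrr::map_lgl(inputs,
                            ~ "polymer_contaminated" %in% .x$flags)
  if (any(flagged)) {
    say("stage=flag-polymers flagged=%d", sum(flagged))
  }
  if (drop_polymer && any(flagged)) inputs <- inputs[!flagged]
  if (length(inputs) < 2L) {
    abort("Fewer than two usable fingerprints remain.",
          class = "fingernet_bad_param")
  }

  say("stage=similarity n=%d", length(inputs))
  sim <- similarity_matrix(inputs, mz_tolerance = mz_tolerance)
  say("stage=network threshold=%g top_k=%d", threshold, top_k)
  net <- build_network(sim, threshold = threshold, top_k = top_k)
  say("stage=embed perplexity=%g seed=%d", perplexity, seed)
  emb <- tsne_embed(sim, perplexity = perplexity, seed = seed)
  assignment <- cluster_components(net)
  composition <- summarize_clusters(assignment, taxonomy)
  concordance <- if (any(taxonomy$source == "query")) {
    summarize_query_concordance(assignment, taxonomy)
  } else NULL

  run_manifest <- list(
    tool = "fingernet",
    version = as.character(utils::packageVersion("fingernet")),
    subcommand = "run",
    parameters = list(
      mode = modes,
      mz_tolerance = sim$mz_tolerance,
      threshold = threshold, top_k = as.integer(top_k),
      perplexity = emb$params$perplexity,
      learning_rate = emb$params$learning_rate,
      iterations = emb$params$iterations,
      early_exaggeration = emb$params$early_exaggeration,
      drop_polymer = drop_polymer
    ),
    n_fingerprints = length(inputs),
    n_flagged_polymer = sum(flagged),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- structure(
    list(peaklists = inputs, similarity = sim, network = net,
         embedding = emb, assignment = assignment,
         composition = composition, concordance = concordance,
         run_manifest = run_manifest),
    class = "fingernet_run"
  )
  if (!is.null(outdir)) write_run(result, outdir)
  result
}

# Write every pipeline artifact; all files except run_manifest.json are
# byte-deterministic given identical inputs and parameters.
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- run$run_manifest$parameters
  hdr <- sprintf("# %s=%s", names(params),
                 vapply(params, function(p) paste(format(p), collapse = ","),
                        character(1)))
  hdr <- c(hdr, sprintf("# seed=%d", run$run_manifest$seed))
  write_mgf(run$peaklists, file.path(outdir, "peaks.mgf"))
  write_edges_tsv(run$network$edges, file.path(outdir, "edges.tsv"), hdr)
  coords <- tidy(run$embedding)
  coords$cluster_id <- run$assignment$cluster_id[
    match(node_id(coords), run$assignment$id)]
  write_coords_tsv(coords, file.path(outdir, "coords.tsv"), hdr)
  write_tsv_lf(run$composition, file.path(outdir, "composition.tsv"), hdr)
  if (!is.null(run$concordance)) {
    write_tsv_lf(run$concordance, file.path(outdir, "concordance.tsv"), hdr)
  }
  jsonlite::write_json(run$run_manifest,
                       file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.fingernet_run <- function(x, ...) {
  cat(sprintf("<fingernet_run> %d fingerprints, %d edges, %d clusters\n",
              length(x$peaklists), nrow(x$network$edges),
              dplyr::n_distinct(x$assignment$cluster_id)))
  if (!is.null(x$concordance)) {
    with(x$concordance, cat(sprintf(
      "queries: %d | matched %.1f%% | isolated %.1f%% | misassigned %.1f%%\n",
      n_queries, pct_matched, pct_isolated, pct_misassigned)))
  }
  invisible(x)
}

#' @describeIn run_pipeline Per-fingerprint tibble: embedding coordinates
#'   plus cluster assignment.
#' @param x A `fingernet_run`.
#' @param ... Unused.
#' @export
tidy.fingernet_run <- function(x, ...) {
  coords <- tidy(x$embedding)
  coords$id <- node_id(coords)
  dplyr::left_join(coords, x$assignment, by = "id")
}

#' @describeIn run_pipeline One-row run summary (fingerprint, edge and
#'   cluster counts plus the concordance percentages when queries exist).
#' @export
glance.fingernet_run <- function(x, ...) {
  base <- tibble::tibble(
    n_fingerprints = length(x$peaklists),
    n_edges = nrow(x$network$edges),
    n_clusters = dplyr::n_distinct(x$assignment$cluster_id),
    n_singletons = sum(x$assignment$singleton)
  )
  if (!is.null(x$concordance)) base <- dplyr::bind_cols(base, x$concordance)
  base
}
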