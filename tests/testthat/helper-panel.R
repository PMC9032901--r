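# The default simulated panel (4 orders x 3 genera x 2 strains x 2
# replicates) plus its similarity matrix is used by several test files;
# cache it per session.
panel_cache <- new.env(parent = emptyenv())

default_panel <- function(seed = 42L) {
  key <- paste0("panel_", seed)
  if (is.null(panel_cache[[key]])) {
    cfg <- sim_config(seed = seed)
    panel <- simulate_panel(cfg)
    panel$similarity <- similarity_matrix(panel$peaklists)
    panel_cache[[key]] <- panel
  }
  panel_cache[[key]]
}
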