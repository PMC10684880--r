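# Shared synthetic world, built once per test run.
.world_cache <- new.env(parent = emptyenv())

test_world <- function(seed = 20231128) {
  key <- as.character(seed)
  if (is.null(.world_cache[[key]])) {
    cfg <- synth_config(seed = seed)
    w <- generate_foods(cfg)
    w$anchors <- generate_anchors(cfg)
    w$cfg <- cfg
    .world_cache[[key]] <- w
  }
  .world_cache[[key]]
}

# composition concentrated on a few groups (named percent vector filled up
# with refined grains to sum to 100)
quick_comp <- function(..., total_mass_g = 1800) {
  shares <- c(...)
  filler <- 100 - sum(shares)
  stopifnot(filler >= 0)
  if ("refined grains" %in% names(shares)) {
    shares[["refined grains"]] <- shares[["refined grains"]] + filler
  } else {
    shares <- c(shares, "refined grains" = filler)
  }
  diet_composition(shares, total_mass_g = total_mass_g, percent = TRUE)
}
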