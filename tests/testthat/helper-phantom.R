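# One shared phantom realization, built once per test run.
phantom_cache <- new.env(parent = emptyenv())

shared_phantom <- function() {
  if (is.null(phantom_cache$ph)) {
    phantom_cache$spec <- default_phantom_spec()
    phantom_cache$ph <- build_phantom(phantom_cache$spec, seed = 42)
  }
  list(spec = phantom_cache$spec, maps = phantom_cache$ph$maps,
       labels = phantom_cache$ph$labels)
}

default_structure_ids <- function() {
  stats::setNames(1:4, default_structures()$name)
}

# single-voxel quantitative maps for signal-equation checks
voxel_maps <- function(t1 = 1000, t2 = 100, pd = 1) {
  suppressWarnings(quantitative_maps(array(t1, c(1, 1, 1)),
                                     array(t2, c(1, 1, 1)),
                                     array(pd, c(1, 1, 1)),
                                     spacing = c(1, 1, 1)))
}
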