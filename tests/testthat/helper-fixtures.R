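# Shared small fixtures, built once per test run. 48^3 grid at 2.5 mm with
# 642-vertex hemispheres keeps unit tests fast; the acceptance tests use the
# full desk-scale configuration.

small_phantom_config <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(48L, 48L, 48L), voxel_size_mm = 2.5),
                            list(...))
  do.call(phantom_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

small_phantom <- function() fixture("ph48", function() make_phantom(small_phantom_config()))
small_fields <- function() fixture("f48", function() make_fields(field_config(), small_phantom()))
small_surface <- function() fixture("s642", function()
  make_surface_model(surface_config(n_vertices = 642L), small_phantom()))
default_lookup <- function() fixture("lookup", function() build_lookup(mp2rage_protocol()))
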