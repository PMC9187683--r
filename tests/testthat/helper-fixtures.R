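# Shared fixtures: model-generated polarizer stacks and cached Monte Carlo
# runs (the MC fixtures are simulated once per test session).

# four-angle stack generated exactly from the Malus model
model_stack <- function(I_pol, I_unpol, alpha, dims = c(4, 4),
                        angles = c(0, 45, 90, 135), pixel_scale = 0.26) {
  as_field <- function(x) if (is.matrix(x)) x else matrix(x, dims[1], dims[2])
  Ip <- as_field(I_pol); Iu <- as_field(I_unpol); al <- as_field(alpha)
  frames <- lapply(angles, function(a0)
    Ip * cos((a0 - al) * pi / 180)^2 + Iu)
  names(frames) <- as.character(angles)
  polarized_stack(frames, pixel_scale = pixel_scale)
}

# random smooth parameter fields under a fixed seed
random_fields <- function(dims = c(6, 5), seed = 1) {
  set.seed(seed)
  list(I_pol = matrix(runif(prod(dims), 0.5, 5), dims[1], dims[2]),
       I_unpol = matrix(runif(prod(dims), 0, 3), dims[1], dims[2]),
       alpha = matrix(runif(prod(dims), -89, 89), dims[1], dims[2]))
}

# cached beam simulations shared across test files
mc_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    cache[[name]] <- switch(name,
      e6 = simulate_beam("6MeV", 1000, seed = 101),
      e18_shallow = {
        set.seed(202)
        res <- lapply(1:150, function(k) transport_electron(18000))
        cherenkovpol:::bind_photons(res)
      },
      p6 = simulate_beam("6MV", 2500, seed = 303),
      stop("unknown fixture"))
    cache[[name]]
  }
})

# flat (uniform-density) angular distribution: the identity correction
flat_distribution <- function(depth = 10, off_axis = 0) {
  angular_distribution(rep(100, 180), rep(100, 72),
                       region = list(depth = depth, off_axis = off_axis,
                                     voxel = 1))
}
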