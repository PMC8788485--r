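# Small shared fixtures, built once per test session.

tiny_geom <- function(n = 32L) pet_geometry(n, n, pi, n)

fixture_env <- new.env()

# cached small system matrices / simulations so repeated tests stay fast
get_fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

toy_system32 <- function() {
  get_fixture("sys32", function() {
    geom <- tiny_geom(32L)
    sm <- system_matrix(geom, 32L)
    truth <- rasterize(phantom_spec(list(
      shape_disk(0.5, 0.5, 0.32, 1),
      shape_disk(0.38, 0.42, 0.08, 3),
      shape_disk(0.62, 0.6, 0.1, 2)), 32L, "toy"), 32L)
    sim <- simulate_sinogram(truth, sm, 4e4, seed = 7)
    list(geom = geom, sm = sm, truth = sim$truth, sino = sim$sino,
         gbar = sim$gbar)
  })
}

toy_system64 <- function() {
  get_fixture("sys64", function() {
    geom <- tiny_geom(64L)
    sm <- system_matrix(geom, 64L)
    truth <- rasterize(circles_phantom(), 64L)
    sim <- simulate_sinogram(truth, sm, 1e5, seed = 11)
    list(geom = geom, sm = sm, truth = sim$truth, sino = sim$sino,
         gbar = sim$gbar)
  })
}

# classical MLEM reference loop (independent of the package optimizer:
# plain Matrix algebra on the full system)
mlem_reference <- function(sino, sm, n_iter, f0 = NULL) {
  g <- as.numeric(sino$counts)
  sens <- sm$sens
  f <- if (is.null(f0)) {
    v <- numeric(ncol(sm$H)); v[sens > 0] <- sum(g) / sum(sens); v
  } else as.numeric(f0)
  for (it in seq_len(n_iter)) {
    gbar <- as.numeric(sm$H %*% f) + sino$r
    y <- ifelse(g > 0, g / pmax(gbar, 1e-15), 0)
    bp <- as.numeric(Matrix::crossprod(sm$H, y))
    f <- ifelse(sens > 0, f * bp / pmax(sens, 1e-300), 0)
  }
  f
}
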