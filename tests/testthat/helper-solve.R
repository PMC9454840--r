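# Lazily computed, cached FEM solutions shared across test files so the
# chamber is meshed and solved only once per resolution.
solve_cache <- new.env(parent = emptyenv())

cached_field <- function(h = 3e-4, voltage = 1) {
  key <- sprintf("f_%g_%g", h, voltage)
  if (is.null(solve_cache[[key]])) {
    mesh <- generate_mesh(default_chamber(), h)
    solve_cache[[key]] <- solve_potential(mesh, voltage)
  }
  solve_cache[[key]]
}

# trapezoidal integral, used as an independent numerical oracle
trapz_oracle <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
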