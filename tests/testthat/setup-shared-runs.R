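# Pipeline runs shared across test files (built once; L = 10 keeps the
# end-to-end problem size small enough for routine testing).
shared <- new.env()

shared_two_cell <- function() {
  if (is.null(shared$two_cell)) {
    shared$two_cell <- suppressWarnings(
      run_two_cell(L = 10, pressure_ratio = 0.8, verbose = FALSE))
  }
  shared$two_cell
}

shared_sphere <- function() {
  if (is.null(shared$sphere)) {
    vol <- render_sphere(R = 20)
    shared$sphere <- suppressWarnings(run_pipeline(vol))
    attr(shared$sphere, "center") <- attr(vol, "center")
    attr(shared$sphere, "radius") <- 20
  }
  shared$sphere
}
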