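# Shared fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small single-shot desk design (matrix 48, full-strength gradients)
fx_seq48 <- function() fx("seq48", function()
  desk_sequence(48, 7e-4, etl = 9, n_shots = 1, readout_dur = 0.016))

fx_seq48_comp <- function() fx("seq48c", function()
  compensate_sequence(fx_seq48())$seq)

# 0.55T protocol-scale design (Table-1 parameters, even ETL)
fx_seq055 <- function() fx("seq055", function() {
  p <- protocol_defaults("0.55T")
  design_ring_set(fov = p$fov, resolution = p$resolution, etl = p$etl,
                  n_shots = p$n_shots, gmax = p$gmax, smax = p$smax,
                  readout_dur = p$readout, even_central = "floor")
})

fx_seq055_comp <- function() fx("seq055c", function()
  compensate_sequence(fx_seq055())$seq)

# 48-matrix phantom with relaxation disabled (pure proton-density k-space)
fx_phantom48_norelax <- function() fx("ph48", function() {
  ph <- make_phantom("shepp-logan", 48, 7e-4)
  ph$T1[] <- 1e9; ph$T2[] <- 1e9
  ph
})

grid_radius2 <- function(n) {
  u <- seq_len(n) - (n + 1) / 2
  outer(u^2, u^2, `+`)
}
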