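# Desk-scale simulator configuration for fast unit tests: a 256 x 256 panel
# (64 mm square at isocenter scale) with a 40 mm field. Physics parameters
# (pitch, noise, blur, contrast) match the full-scale defaults.

small_geometry <- function() {
  beam_geometry(sad_mm = 1000, sid_mm = 1600, pixel_pitch_mm = 0.4,
                panel_rows = 256L, panel_cols = 256L)
}

small_linac <- function(bb = room_vector(), axis = c(0, 0),
                        noise = 0, seed = 1L, ...) {
  virtual_linac(bb_position = bb, axis_offset = axis,
                geometry = small_geometry(), field_size_mm = 40,
                noise_sigma_frac = noise, seed = seed, ...)
}

norm2 <- function(x) sqrt(sum(x^2))
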