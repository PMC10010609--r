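# small fixtures shared across test files; everything is built in code

# unbranched primary of given length
line_rs <- function(length = 0.1, diameter = 1.05e-3) {
  root_system(data.frame(
    axis_id = "P", parent_axis = NA_character_, insertion_position = 0,
    length = length, order = 0L, diameter = diameter))
}

# primary + explicitly placed laterals (insertion = distance to primary tip)
branched_rs <- function(primary = 0.3, insertions = c(0.1, 0.2),
                        lengths = 0.05, diameters = 0.36e-3) {
  n <- length(insertions)
  lengths <- rep_len(lengths, n)
  diameters <- rep_len(diameters, n)
  root_system(data.frame(
    axis_id = c("P", paste0("L", seq_len(n))),
    parent_axis = c(NA_character_, rep("P", n)),
    insertion_position = c(0, insertions),
    length = c(primary, lengths),
    order = c(0L, rep(1L, n)),
    diameter = c(1.05e-3, diameters)))
}

# CTR-like defaults with a flat or ramped axial conductance profile
ctr_params <- function(K = 1e-10, ...) {
  transport_params(K_knots = data.frame(dist = 0.05, K = K), ...)
}

# hydrostatic-only parameter set (no solutes, no osmosis)
hydro_params <- function(k = 1e-7, K = 1e-10) {
  transport_params(k = k, K_knots = data.frame(dist = 0.05, K = K),
                   sigma = 0, Js_star = 0, Ps = 0)
}

# virtual cutting of a known root system into digitized cut sets, used to
# test reconstruction; blades are distances to the primary tip, increasing
virtual_cut_sets <- function(rs, blades) {
  a <- rs$axes
  lat <- a[a$order == 1L, , drop = FALSE]
  L0 <- a$length[a$order == 0L]
  bounds <- c(0, blades)
  sets <- lapply(seq_along(blades), function(i) {
    sel <- lat$insertion_position > bounds[i] &
      lat$insertion_position <= bounds[i + 1]
    list(primary_length = bounds[i + 1] - bounds[i],
         laterals = data.frame(
           insertion_position = lat$insertion_position[sel] - bounds[i],
           length = lat$length[sel],
           diameter = lat$diameter[sel]))
  })
  sel <- lat$insertion_position > bounds[length(bounds)]
  remainder <- root_system(data.frame(
    axis_id = c("P", if (sum(sel)) paste0("L", seq_len(sum(sel)))),
    parent_axis = c(NA_character_, rep("P", sum(sel))),
    insertion_position = c(0, lat$insertion_position[sel] - max(blades)),
    length = c(L0 - max(blades), lat$length[sel]),
    order = c(0L, rep(1L, sum(sel))),
    diameter = c(a$diameter[a$order == 0L], lat$diameter[sel])))
  list(cut_sets = sets, basal_remainder = remainder)
}
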