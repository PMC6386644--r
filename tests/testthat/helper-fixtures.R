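# Shared fixtures built in code.

trapz <- archflow:::trapz

# a physiologic aortic inflow: 5 L/min mean, 20 L/min peak, 1 s cycle
demo_inflow <- function(seed = 1, n = 256) {
  gen_inflow_waveform(5, 20, 1, n, seed = seed)
}

# constant (flat) waveform at `lpm` L/min
flat_inflow <- function(lpm, period = 1, n = 128) {
  gen_inflow_waveform(lpm, lpm, period, n, seed = 1)
}

# sinusoidal waveform q = mean + amp * sin(2 pi t / period), mL/s units in
sine_inflow <- function(mean_mls, amp_mls, period = 1, n = 512) {
  t <- seq(0, period, length.out = n + 1)
  q <- mean_mls + amp_mls * sin(2 * pi * t / period)
  q[n + 1] <- q[1]
  flow_waveform(t, mls_to_m3s(q))
}

# four identical outlets; the node then behaves as one Windkessel fed by
# inflow/4 per outlet (cross-module equivalence oracle)
identical_outlet_model <- function(inflow, wk) {
  outs <- lapply(c("BCT", "LCCA", "LSA", "DAo"), function(nm) {
    outlet_branch(nm, 1.0, wk)
  })
  arch_model(inflow, outs, topology = "pre_tevar")
}

# attach explicit fields to a mesh
within_fields <- function(mesh, p, s) {
  mesh$face_pressure <- p
  mesh$face_shear <- s
  mesh
}

# scale a waveform's flows by a factor
scale_waveform <- function(w, fac) {
  flow_waveform(w$times, w$flows * fac)
}
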