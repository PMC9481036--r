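# Shared fixtures: the reference 1 MHz coil and series circuits with a
# prescribed Q at 1 MHz (L fixed at 10 uH, R and C derived).

ref_coil <- function(Q = 49.83, f_r = 1e6) coil_params(f_r, Q)

circuit_with_q <- function(Q, f_r = 1e6, L = 10e-6) {
  omega <- 2 * pi * f_r
  circuit_params(L = L, R = omega * L / Q, C = 1 / (omega^2 * L))
}

# ring-down record long enough for ~3.3 halvings (decimal-fit floor) but
# never shorter than 20 carrier cycles
ringdown_duration <- function(Q, f = 1e6) {
  max(20, ceiling(3.3 * cycles_to_halve(Q))) / f
}

# random sampled targets for property loops
random_target <- function(n, dt = 2e-6, scale = 1) {
  sampled_target(dt, scale * stats::runif(n, -1, 1))
}
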