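# Independent oracles used across the suite.

# Brute-force 3-D geometry oracle: for a field dipping at inclination I
# (degrees, positive into the ground), find the angle theta to the field
# vector whose cone of movement directions contains the most-upward
# direction. Maximizes the vertical component over all unit vectors at
# angle theta from the field, over a fine theta grid.
brute_max_up <- function(incl_deg, theta_deg) {
  I <- incl_deg * pi / 180
  f_z <- -sin(I)                    # z-up frame; I > 0 dips below horizon
  e1_z <- cos(I)                    # vertical-plane direction orthogonal to f
  theta <- theta_deg * pi / 180
  # max over the cone azimuth phi of u_z = cos(theta) f_z + sin(theta) *
  #   (cos(phi) e1_z + sin(phi) e2_z); the phi-max is sqrt(e1_z^2 + e2_z^2)
  cos(theta) * f_z + abs(sin(theta)) * abs(e1_z)
}

brute_best_up_angle <- function(incl_deg, step = 0.05) {
  theta <- seq(0, 360 - step, by = step)
  theta[which.max(brute_max_up(incl_deg, theta))]
}

# reflection of a direction about the 0-180 degree axis
reflect_axis0 <- function(x) (360 - x) %% 360

# circular mean / resultant by direct unit-vector summation
direct_circ_mean <- function(deg) {
  a <- deg * pi / 180
  m <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  m %% 360
}
direct_R <- function(deg) {
  a <- deg * pi / 180
  sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

# theoretical mean resultant length of a von Mises distribution,
# A(kappa) = I1(kappa) / I0(kappa), via base Bessel functions
vm_mean_resultant <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# large-sample standard error (degrees) of a circular mean with resultant R
circ_mean_se_deg <- function(R, n) sqrt(-2 * log(R) / n) * 180 / pi
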