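# shared fixtures, built once per test run and memoized

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# hexagonal benzene-like geometry (C ring 1.39 A, H at 2.48 A)
benzene_conformer <- function() {
  th <- (0:5) * pi / 3
  conformer(c(rep("C", 6), rep("H", 6)),
            rbind(cbind(1.39 * cos(th), 1.39 * sin(th), 0),
                  cbind(2.48 * cos(th), 2.48 * sin(th), 0)),
            label = "hexagonal-ring")
}

# small symmetric water built directly in Cartesian space: O at the
# origin, hydrogens mirror-symmetric about the yz plane, so x -> -x is
# the exact molecular mirror
water_xy <- function(r = 0.9572, theta = 104.52 * pi / 180) {
  x <- r * sin(theta / 2)
  y <- r * cos(theta / 2)
  conformer(c("O", "H", "H"),
            rbind(c(0, 0, 0), c(x, y, 0), c(-x, y, 0)),
            label = "water-sym")
}

# the standard toy-water dataset used across map tests (102 records,
# the small-molecule benchmark protocol size)
water_dataset <- function() {
  memo("water_dataset", make_dataset(toy_water(), 102, seed = 11))
}

water_system <- function() memo("water_system", toy_water())
ethanol_system <- function() memo("ethanol_system", toy_ethanol())

# the fivefold-CV fitting protocol used in evaluation tests
cv_fit <- function(u, y, kind, basis, seed = 1) {
  fit_energy_map_cv(u, y, kind, basis, seed = seed)
}

test_mae <- function(map, u, y) {
  mean(abs(predict_energy(map, u) - y))
}
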