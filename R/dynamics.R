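#' Finite-difference atomic forces
#'
#' Central differences per Cartesian component,
#' \eqn{F_{a\mu} = -[E(x + \epsilon e_{a\mu}) - E(x - \epsilon e_{a\mu})]/(2\epsilon)},
#' costing 6N energy evaluations for N atoms.  Central differences are
#' exact for quadratic surfaces and second-order accurate otherwise;
#' this is the default force route on learned energy surfaces, where a
#' cheap energy evaluation is available but analytic gradients may not
#' be.
#'
#' @param energy_fn function taking an N x 3 coordinate matrix
#'   (Angstrom) and returning an energy (kcal/mol)
#' @param coords N x 3 coordinate matrix
#' @param fd_epsilon displacement in Angstrom (default 0.001)
#' @return N x 3 matrix of forces in kcal/mol/Angstrom
#' @export
finite_difference_forces <- function(energy_fn, coords,
                                     fd_epsilon = 0.001) {
  if (fd_epsilon <= 0) stop("fd_epsilon must be positive")
  coords <- as.matrix(coords)
  FF <- matrix(0, nrow(coords), 3L)
  for (a in seq_len(nrow(coords))) {
    for (mu in 1:3) {
      xp <- coords; xp[a, mu] <- xp[a, mu] + fd_epsilon
      xm <- coords; xm[a, mu] <- xm[a, mu] - fd_epsilon
      ep <- energy_fn(xp); em <- energy_fn(xm)
      if (!is.finite(ep) || !is.finite(em)) {
        stop("non-finite energy in finite-difference stencil at atom ",
             a, ", component ", mu)
      }
      FF[a, mu] <- -(ep - em) / (2 * fd_epsilon)
    }
  }
  FF
}

#' Integrator parameters
#'
#' Defaults follow common practice for learned-surface gas-phase MD:
#' 0.5 fs timestep, 350 K thermostat target, friction 0.413 fs^-1
#' (0.01 atomic units), finite-difference displacement 0.001 Angstrom,
#' and 3 inner steps per outer force correction in the multiple
#' time-step integrator.
#'
#' @param dt timestep in fs
#' @param temperature thermostat target in K
#' @param friction Langevin friction in fs^-1
#' @param fd_epsilon finite-difference displacement in Angstrom
#' @param n_inner inner steps per outer RESPA correction
#' @param seed integer seed for stochastic integrators
#' @param energy_bound abort threshold on |potential energy| (kcal/mol)
#' @return a list of validated parameters
#' @export
integrator_params <- function(dt = 0.5, temperature = 350,
                              friction = friction_au_to_fs(0.01),
                              fd_epsilon = 0.001, n_inner = 3L,
                              seed = 1L, energy_bound = 1e6) {
  if (dt <= 0) stop("dt must be positive")
  if (friction < 0) stop("friction must be non-negative")
  if (fd_epsilon <= 0) stop("fd_epsilon must be positive")
  if (n_inner < 1L) stop("n_inner must be at least 1")
  list(dt = dt, temperature = temperature, friction = friction,
       fd_epsilon = fd_epsilon, n_inner = as.integer(n_inner),
       seed = as.integer(seed), energy_bound = energy_bound)
}

#' Molecular dynamics state
#'
#' @param positions N x 3 matrix (Angstrom)
#' @param velocities N x 3 matrix (Angstrom/fs); defaults to rest
#' @param masses per-atom masses in amu
#' @param time current time in fs
#' @return an object of class \code{md_state}
#' @export
md_state <- function(positions, velocities = NULL, masses, time = 0) {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3L)
  velocities <- as.matrix(velocities)
  if (!all(dim(positions) == dim(velocities))) {
    stop("positions and velocities differ in shape")
  }
  if (length(masses) != nrow(positions)) {
    stop("masses length does not match atom count")
  }
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(positions = positions, velocities = velocities,
                 masses = as.numeric(masses), time = time),
            class = "md_state")
}

#' Initial state for a conformer
#' @param conf a \code{conformer}
#' @param velocities optional N x 3 velocity matrix (Angstrom/fs)
#' @return an \code{md_state} with standard atomic masses
#' @export
md_state_from_conformer <- function(conf, velocities = NULL) {
  md_state(conf$coords, velocities, atomic_masses(conf$species))
}

# kinetic energy in kcal/mol from velocities in A/fs and masses in amu
.kinetic_energy <- function(vel, masses) {
  0.5 * sum(masses * rowSums(vel^2)) / densfunc_units$acc_conv
}

# assemble an md_trajectory from frame storage.  Integrators keep the
# frame lists as plain local variables and assign into them directly,
# which R updates in place; routing the stores through a helper would
# bump reference counts and make long runs quadratic in step count.
.traj_finish <- function(positions, velocities, time, E_pot, E_kin,
                         masses) {
  structure(list(positions = positions,
                 velocities = velocities,
                 masses = masses,
                 table = data.frame(step = seq_along(time) - 1L,
                                    time = time,
                                    E_pot = E_pot,
                                    E_kin = E_kin,
                                    E_tot = E_pot + E_kin)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  n <- nrow(x$table)
  cat("md_trajectory:", n, "frames,", x$table$time[n], "fs; E_tot drift",
      signif(x$table$E_tot[n] - x$table$E_tot[1], 4), "kcal/mol\n")
  invisible(x)
}

#' Constant-energy (NVE) trajectory by velocity Verlet
#'
#' @param energy_fn potential energy function of an N x 3 coordinate
#'   matrix (kcal/mol)
#' @param state initial \code{md_state}
#' @param params \code{integrator_params()}
#' @param n_steps number of timesteps
#' @return an \code{md_trajectory} with per-frame positions,
#'   velocities and an energy table (step, time, E_pot, E_kin, E_tot)
#' @export
nve_trajectory <- function(energy_fn, state, params = integrator_params(),
                           n_steps) {
  dt <- params$dt
  conv <- densfunc_units$acc_conv
  nf <- n_steps + 1L
  pos_l <- vector("list", nf); vel_l <- vector("list", nf)
  time_v <- numeric(nf); epot_v <- numeric(nf); ekin_v <- numeric(nf)
  pos_l[[1L]] <- state$positions; vel_l[[1L]] <- state$velocities
  time_v[1L] <- state$time
  epot_v[1L] <- energy_fn(state$positions)
  ekin_v[1L] <- .kinetic_energy(state$velocities, state$masses)
  FF <- finite_difference_forces(energy_fn, state$positions,
                                 params$fd_epsilon)
  for (s in seq_len(n_steps)) {
    acc <- conv * FF / state$masses
    state$velocities <- state$velocities + 0.5 * dt * acc
    state$positions <- state$positions + dt * state$velocities
    FF <- finite_difference_forces(energy_fn, state$positions,
                                   params$fd_epsilon)
    state$velocities <- state$velocities + 0.5 * dt * conv * FF / state$masses
    state$time <- state$time + dt
    epot <- energy_fn(state$positions)
    if (!is.finite(epot) || abs(epot) > params$energy_bound) {
      stop("energy diverged at step ", s, " (E_pot = ", epot,
           " kcal/mol); reduce dt or check the surface")
    }
    pos_l[[s + 1L]] <- state$positions; vel_l[[s + 1L]] <- state$velocities
    time_v[s + 1L] <- state$time; epot_v[s + 1L] <- epot
    ekin_v[s + 1L] <- .kinetic_energy(state$velocities, state$masses)
  }
  .traj_finish(pos_l, vel_l, time_v, epot_v, ekin_v, state$masses)
}

#' Langevin (constant-temperature) trajectory
#'
#' BAOAB splitting: half kick, half drift, exact
#' Ornstein-Uhlenbeck velocity update, half drift, half kick.  With
#' zero friction the OU step is the identity and the scheme reduces
#' exactly to velocity Verlet.  Deterministic given \code{params$seed};
#' the global RNG state is left untouched.
#'
#' @inheritParams nve_trajectory
#' @return an \code{md_trajectory}
#' @export
langevin_trajectory <- function(energy_fn, state,
                                params = integrator_params(), n_steps) {
  dt <- params$dt
  conv <- densfunc_units$acc_conv
  gam <- params$friction
  kT <- densfunc_units$kB * params$temperature
  c1 <- exp(-gam * dt)
  c2 <- sqrt((1 - c1^2) * kT * conv / state$masses)  # per-atom, A/fs
  n_at <- nrow(state$positions)
  nf <- n_steps + 1L
  pos_l <- vector("list", nf); vel_l <- vector("list", nf)
  time_v <- numeric(nf); epot_v <- numeric(nf); ekin_v <- numeric(nf)
  pos_l[[1L]] <- state$positions; vel_l[[1L]] <- state$velocities
  time_v[1L] <- state$time
  epot_v[1L] <- energy_fn(state$positions)
  ekin_v[1L] <- .kinetic_energy(state$velocities, state$masses)
  FF <- finite_difference_forces(energy_fn, state$positions,
                                 params$fd_epsilon)
  .with_seed(params$seed, {
    for (s in seq_len(n_steps)) {
      state$velocities <- state$velocities +
        0.5 * dt * conv * FF / state$masses
      state$positions <- state$positions + 0.5 * dt * state$velocities
      if (gam > 0) {
        noise <- matrix(stats::rnorm(3L * n_at), n_at, 3L)
        state$velocities <- c1 * state$velocities + c2 * noise
      }
      state$positions <- state$positions + 0.5 * dt * state$velocities
      FF <- finite_difference_forces(energy_fn, state$positions,
                                     params$fd_epsilon)
      state$velocities <- state$velocities +
        0.5 * dt * conv * FF / state$masses
      state$time <- state$time + dt
      epot <- energy_fn(state$positions)
      if (!is.finite(epot) || abs(epot) > params$energy_bound) {
        stop("energy diverged at step ", s)
      }
      pos_l[[s + 1L]] <- state$positions
      vel_l[[s + 1L]] <- state$velocities
      time_v[s + 1L] <- state$time; epot_v[s + 1L] <- epot
      ekin_v[s + 1L] <- .kinetic_energy(state$velocities, state$masses)
    }
  })
  .traj_finish(pos_l, vel_l, time_v, epot_v, ekin_v, state$masses)
}

#' Multiple time-step (RESPA) trajectory with periodic force corrections
#'
#' Reversible reference-system propagator: inner velocity-Verlet steps
#' use the cheap reference surface; at outer boundaries (every
#' \code{params$n_inner} steps) the force difference between the
#' accurate and the reference surface is applied as a symmetric
#' impulse scaled to the outer timestep.  Time-reversible by
#' construction.  With \code{accurate == reference} the correction
#' vanishes and the trajectory equals plain NVE on the reference
#' surface; with \code{n_inner = 1} it equals NVE on the accurate
#' surface up to integrator accuracy.
#'
#' @param reference_energy_fn cheap reference potential (kcal/mol)
#' @param accurate_energy_fn accurate potential used for the periodic
#'   corrections
#' @param state initial \code{md_state}
#' @param params \code{integrator_params()}; \code{n_inner} sets the
#'   correction interval
#' @param n_steps total number of inner timesteps (rounded down to a
#'   whole number of outer cycles)
#' @return an \code{md_trajectory}; \code{E_pot} is recorded on the
#'   accurate surface
#' @export
respa_trajectory <- function(reference_energy_fn, accurate_energy_fn,
                             state, params = integrator_params(),
                             n_steps) {
  dt <- params$dt
  n_in <- params$n_inner
  conv <- densfunc_units$acc_conv
  n_outer <- n_steps %/% n_in
  nf <- n_outer * n_in + 1L
  pos_l <- vector("list", nf); vel_l <- vector("list", nf)
  time_v <- numeric(nf); epot_v <- numeric(nf); ekin_v <- numeric(nf)
  pos_l[[1L]] <- state$positions; vel_l[[1L]] <- state$velocities
  time_v[1L] <- state$time
  epot_v[1L] <- accurate_energy_fn(state$positions)
  ekin_v[1L] <- .kinetic_energy(state$velocities, state$masses)
  fd <- params$fd_epsilon
  frame <- 1L
  F_ref <- finite_difference_forces(reference_energy_fn, state$positions, fd)
  F_acc <- finite_difference_forces(accurate_energy_fn, state$positions, fd)
  for (o in seq_len(n_outer)) {
    # outer half-kick with the force correction
    state$velocities <- state$velocities +
      0.5 * (n_in * dt) * conv * (F_acc - F_ref) / state$masses
    for (s in seq_len(n_in)) {
      state$velocities <- state$velocities +
        0.5 * dt * conv * F_ref / state$masses
      state$positions <- state$positions + dt * state$velocities
      F_ref <- finite_difference_forces(reference_energy_fn,
                                        state$positions, fd)
      state$velocities <- state$velocities +
        0.5 * dt * conv * F_ref / state$masses
      state$time <- state$time + dt
      frame <- frame + 1L
      epot <- accurate_energy_fn(state$positions)
      if (!is.finite(epot) || abs(epot) > params$energy_bound) {
        stop("energy diverged at outer cycle ", o, ", inner step ", s)
      }
      pos_l[[frame]] <- state$positions; vel_l[[frame]] <- state$velocities
      time_v[frame] <- state$time; epot_v[frame] <- epot
      ekin_v[frame] <- .kinetic_energy(state$velocities, state$masses)
    }
    F_acc <- finite_difference_forces(accurate_energy_fn,
                                      state$positions, fd)
    state$velocities <- state$velocities +
      0.5 * (n_in * dt) * conv * (F_acc - F_ref) / state$masses
    # the stored closing frame of this cycle gains the outer half-kick
    vel_l[[frame]] <- state$velocities
    ekin_v[frame] <- .kinetic_energy(state$velocities, state$masses)
  }
  .traj_finish(pos_l, vel_l, time_v, epot_v, ekin_v, state$masses)
}

#' Geometry optimization on an energy surface
#'
#' Quasi-Newton (BFGS) descent driven by finite-difference gradients,
#' declared converged when the largest force component drops below
#' \code{force_tol}.  Callers are responsible for starting within the
#' validity region of a learned surface; for learned surfaces a
#' \code{displacement_bound} (box constraint around the start, via
#' L-BFGS-B) is strongly recommended, since an unconstrained descent
#' can wander out of the training manifold into regions where a kernel
#' model extrapolates arbitrarily.
#'
#' @param energy_fn potential energy function of an N x 3 matrix
#' @param start starting \code{conformer} or coordinate matrix
#' @param force_tol convergence threshold on max |F| in
#'   kcal/mol/Angstrom (default 1e-3)
#' @param max_iter maximum BFGS iterations
#' @param fd_epsilon finite-difference displacement
#' @param displacement_bound optional per-component box half-width
#'   (Angstrom) about the start
#' @return a list with \code{coords}, \code{energy}, \code{converged},
#'   \code{max_force}, and (when \code{start} was a conformer)
#'   \code{conformer}
#' @export
optimize_geometry <- function(energy_fn, start, force_tol = 1e-3,
                              max_iter = 500L, fd_epsilon = 0.001,
                              displacement_bound = NULL) {
  conf <- NULL
  if (inherits(start, "conformer")) {
    conf <- start
    coords <- start$coords
  } else {
    coords <- as.matrix(start)
  }
  shape <- dim(coords)
  fn <- function(x) energy_fn(matrix(x, shape[1], shape[2]))
  gr <- function(x) {
    -as.vector(finite_difference_forces(energy_fn,
                                        matrix(x, shape[1], shape[2]),
                                        fd_epsilon))
  }
  x <- as.vector(coords)
  maxF <- max(abs(gr(x)))
  converged <- maxF < force_tol
  it_used <- 0L
  while (!converged && it_used < max_iter) {
    res <- if (is.null(displacement_bound)) {
      stats::optim(x, fn, gr, method = "BFGS",
                   control = list(maxit = max_iter - it_used,
                                  reltol = 1e-14))
    } else {
      x0 <- as.vector(coords)
      stats::optim(x, fn, gr, method = "L-BFGS-B",
                   lower = x0 - displacement_bound,
                   upper = x0 + displacement_bound,
                   control = list(maxit = max_iter - it_used,
                                  factr = 10))
    }
    x <- res$par
    it_used <- it_used + res$counts[["function"]]
    maxF <- max(abs(gr(x)))
    converged <- maxF < force_tol
    if (res$convergence == 0 && !converged) break  # stalled
  }
  coords <- matrix(x, shape[1], shape[2])
  out <- list(coords = coords, energy = energy_fn(coords),
              converged = converged, max_force = maxF)
  if (!is.null(conf)) out$conformer <- set_coords(conf, coords)
  if (!converged) {
    warning("geometry optimization did not reach force_tol (max |F| = ",
            signif(maxF, 4), ")")
  }
  out
}

#' Write a trajectory as multi-frame XYZ plus an energy table
#'
#' @param traj an \code{md_trajectory}
#' @param conf the \code{conformer} providing species
#' @param xyz_path output XYZ path
#' @param table_path optional path for the per-frame energy table
#'   (TSV: step, time fs, E_pot, E_kin, E_tot)
#' @return invisibly, \code{xyz_path}
#' @export
write_trajectory <- function(traj, conf, xyz_path, table_path = NULL) {
  confs <- lapply(seq_along(traj$positions), function(i) {
    set_coords(conf, traj$positions[[i]])
  })
  write_xyz(confs, xyz_path)
  if (!is.null(table_path)) {
    utils::write.table(traj$table, table_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(xyz_path)
}
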