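# Metropolis Monte Carlo engine for polyene conformer sampling: collective
# multi-stretch moves plus torsional moves (angle perturbations and
# cis <-> trans flips) over a pluggable energy surface, together with
# cis-trans conformer enumeration.

#' Polyene chain topology
#'
#' Minimal description of a conjugated chain for conformer bookkeeping: the
#' sites, the bonds, which bonds can undergo cis-trans isomerization, and
#' which are treated as rotatable in the sampling.
#'
#' @param n_sites Number of sites (atoms / united atoms) on the chain.
#' @param bonds Character vector of bond labels (e.g. `"2,3"`, `"8,8p"`).
#' @param isomerizable Labels of the bonds that can flip cis/trans; must be a
#'   subset of `bonds`.
#' @param rotatable Labels of the bonds the torsional MC move acts on
#'   (default: the isomerizable set).
#' @return Object of class `chain_topology`.
#' @export
chain_topology <- function(n_sites, bonds, isomerizable,
                           rotatable = isomerizable) {
  bonds <- as.character(bonds)
  if (anyDuplicated(bonds)) stop("bond labels must be unique", call. = FALSE)
  if (!all(isomerizable %in% bonds)) {
    stop("isomerizable bonds must be a subset of the bond list", call. = FALSE)
  }
  if (!all(rotatable %in% bonds)) {
    stop("rotatable bonds must be a subset of the bond list", call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites), bonds = bonds,
                 isomerizable = as.character(isomerizable),
                 rotatable = as.character(rotatable)),
            class = "chain_topology")
}

#' Built-in chain topologies
#'
#' `me2crocetin_topology()` is the di-methyl ester model of crocetin: a
#' conjugated C20 backbone whose seven double bonds
#' (2,3), (4,5), (6,7), (8,8'), (6',7'), (4',5'), (2',3') can each undergo a
#' single cis-trans isomerization. `radical_topology()` describes the
#' H-abstracted radical, in which the unpaired electron delocalizes over the
#' chain and all 13 chain CC bonds become isomerizable.
#'
#' @return A [chain_topology()].
#' @export
me2crocetin_topology <- function() {
  dbl <- c("2,3", "4,5", "6,7", "8,8p", "6p,7p", "4p,5p", "2p,3p")
  sgl <- c("1,2", "3,4", "5,6", "7,8", "7p,8p", "5p,6p", "3p,4p", "1p,2p")
  chain_topology(n_sites = 20L, bonds = c(dbl, sgl), isomerizable = dbl)
}

#' @rdname me2crocetin_topology
#' @export
radical_topology <- function() {
  bonds <- c("1,2", "2,3", "3,4", "4,5", "5,6", "6,7", "7,8", "8,8p",
             "7p,8p", "6p,7p", "5p,6p", "4p,5p", "3p,4p")
  chain_topology(n_sites = 20L, bonds = bonds, isomerizable = bonds)
}

#' Enumerate the all-trans and single-cis conformers of a chain
#'
#' @param topology A [chain_topology()].
#' @return List of conformer states. Each state is a named logical vector
#'   over the isomerizable bonds (`TRUE` = cis) with attribute `label`
#'   (`"all-trans"` or `"cis(<bond>)"`).
#' @examples
#' length(enumerate_single_cis(me2crocetin_topology())) # 8 = all-trans + 7
#' length(enumerate_single_cis(radical_topology()))     # 14 = all-trans + 13
#' @export
enumerate_single_cis <- function(topology) {
  stopifnot(inherits(topology, "chain_topology"))
  iso <- topology$isomerizable
  base <- stats::setNames(rep(FALSE, length(iso)), iso)
  out <- list(structure(base, label = "all-trans"))
  for (b in iso) {
    st <- base
    st[b] <- TRUE
    out <- c(out, list(structure(st, label = sprintf("cis(%s)", b))))
  }
  out
}

#' Monte Carlo sampling settings
#'
#' @param total_steps Total number of MC steps.
#' @param burn_in Steps discarded before recording (must be < total).
#' @param p_multi_stretch,p_torsional Move-type probabilities (>= 0, summing
#'   to 1). Defaults 0.8 / 0.2.
#' @param temperature_k Simulation temperature in K. 295 K by default;
#'   conformer searches use 1000 K.
#' @param stride Record every `stride`-th configuration after the burn-in.
#' @param seed Integer seed making the trajectory fully reproducible.
#' @param stretch_amplitude Standard deviation of the collective Gaussian
#'   site displacement (surrogate length units).
#' @param torsion_delta Half-width of the uniform torsional angle
#'   perturbation (radians).
#' @return Object of class `mc_settings`.
#' @export
mc_settings <- function(total_steps = 60000L, burn_in = 20000L,
                        p_multi_stretch = 0.8, p_torsional = 0.2,
                        temperature_k = 295, stride = 100L, seed = 1L,
                        stretch_amplitude = 0.05, torsion_delta = 0.5) {
  if (p_multi_stretch < 0 || p_torsional < 0 ||
      abs(p_multi_stretch + p_torsional - 1) > 1e-12) {
    stop("move probabilities must be nonnegative and sum to 1", call. = FALSE)
  }
  if (burn_in >= total_steps) {
    stop("burn_in must be smaller than total_steps", call. = FALSE)
  }
  if (temperature_k <= 0) stop("temperature must be > 0", call. = FALSE)
  structure(list(total_steps = as.integer(total_steps),
                 burn_in = as.integer(burn_in),
                 p_multi_stretch = p_multi_stretch,
                 p_torsional = p_torsional,
                 temperature_k = temperature_k,
                 stride = as.integer(stride), seed = as.integer(seed),
                 stretch_amplitude = stretch_amplitude,
                 torsion_delta = torsion_delta),
            class = "mc_settings")
}

#' Surrogate torsional + stretch energy surface
#'
#' A testable stand-in for the quantum-mechanical energy of the chain: a sum
#' of per-torsion two-state terms (a cis well offset by `cis_gap_ev` above
#' the trans well, a bond counted cis when cos(angle) < 0) plus harmonic
#' stretch terms on the site coordinates. Its stationary distribution is
#' analytic, which makes Boltzmann-recovery tests possible.
#'
#' @param topology A [chain_topology()].
#' @param cis_gap_ev Energy offset of a cis bond relative to trans, eV
#'   (scalar or one per rotatable bond).
#' @param stretch_k Harmonic constant of the site displacements,
#'   eV / unit^2.
#' @return A function `state -> energy (eV)` usable by [run_mc()].
#' @export
make_torsion_energy <- function(topology, cis_gap_ev = 0.07, stretch_k = 1) {
  nb <- length(topology$rotatable)
  gaps <- rep_len(cis_gap_ev, nb)
  function(state) {
    cis <- cos(state$torsions) < 0
    sum(gaps[cis]) + 0.5 * stretch_k * sum(state$coords^2)
  }
}

#' Initial configuration for the MC engine
#'
#' @param topology A [chain_topology()].
#' @param cis Character vector of rotatable-bond labels started in the cis
#'   well (angle pi); all others start trans (angle 0).
#' @return A configuration: list with `coords` (numeric, one per site) and
#'   `torsions` (named numeric angles in radians, one per rotatable bond).
#' @export
mc_state <- function(topology, cis = character(0)) {
  torsions <- stats::setNames(rep(0, length(topology$rotatable)),
                              topology$rotatable)
  torsions[cis] <- pi
  list(coords = rep(0, topology$n_sites), torsions = torsions)
}

conformer_label <- function(torsions) {
  cis <- names(torsions)[cos(torsions) < 0]
  if (length(cis) == 0) "all-trans"
  else paste0("cis(", paste(sort(cis), collapse = ";"), ")")
}

#' Metropolis Monte Carlo run
#'
#' Samples a configuration space with two move types drawn per step with the
#' configured probabilities: a *multi-stretch* move (collective Gaussian
#' displacement of all site coordinates) and a *torsional* move about one
#' uniformly chosen rotatable bond, which with equal probability either
#' perturbs the angle uniformly in `[-delta, delta]` or proposes a
#' cis <-> trans flip (angle + pi). Proposals are accepted with the
#' Metropolis probability `min(1, exp(-dE / kT))`. Every `stride`-th
#' configuration after the burn-in is recorded. The trajectory is a
#' deterministic function of the seed.
#'
#' @param energy Function `state -> energy (eV)`; must be finite on every
#'   reachable state (see [make_torsion_energy()] for a surrogate).
#' @param settings An [mc_settings()].
#' @param topology A [chain_topology()].
#' @param initial Initial configuration (default [mc_state()] all-trans);
#'   must have finite energy.
#' @param frozen_torsions Labels of rotatable bonds excluded from torsional
#'   moves (constrained sampling keeping a conformer fixed). If all bonds are
#'   frozen, every torsional draw falls back to a multi-stretch move.
#' @return Object of class `mc_trajectory`: list with `records` (data.frame:
#'   step, conformer, energy_ev), `states` (list of recorded configurations),
#'   `acceptance` (overall rate), `move_counts` (attempted moves by type),
#'   `acceptance_by_move`, and `settings`.
#' @export
run_mc <- function(energy, settings, topology,
                   initial = mc_state(topology),
                   frozen_torsions = character(0)) {
  stopifnot(inherits(settings, "mc_settings"),
            inherits(topology, "chain_topology"))
  if (!all(frozen_torsions %in% topology$rotatable)) {
    stop("frozen_torsions must be rotatable bonds", call. = FALSE)
  }
  free_bonds <- setdiff(topology$rotatable, frozen_torsions)
  state <- initial
  e_cur <- energy(state)
  if (!is.finite(e_cur)) {
    stop("initial configuration has non-finite energy", call. = FALSE)
  }
  beta <- 1 / (KB_EV * settings$temperature_k)

  set.seed(settings$seed)
  n_rec <- (settings$total_steps - settings$burn_in) %/% settings$stride
  rec_step <- integer(n_rec)
  rec_conf <- character(n_rec)
  rec_e <- numeric(n_rec)
  states <- vector("list", n_rec)
  attempted <- c(multi_stretch = 0L, torsional = 0L)
  accepted <- c(multi_stretch = 0L, torsional = 0L)
  ri <- 0L

  for (step in seq_len(settings$total_steps)) {
    torsional <- stats::runif(1) < settings$p_torsional &&
      length(free_bonds) > 0
    prop <- state
    if (torsional) {
      attempted["torsional"] <- attempted["torsional"] + 1L
      bond <- if (length(free_bonds) == 1) free_bonds else
        sample(free_bonds, 1)
      if (stats::runif(1) < 0.5) {
        prop$torsions[bond] <- prop$torsions[bond] +
          stats::runif(1, -settings$torsion_delta, settings$torsion_delta)
      } else {
        prop$torsions[bond] <- prop$torsions[bond] + pi
      }
    } else {
      attempted["multi_stretch"] <- attempted["multi_stretch"] + 1L
      prop$coords <- prop$coords +
        stats::rnorm(length(prop$coords), sd = settings$stretch_amplitude)
    }
    e_prop <- energy(prop)
    if (!is.finite(e_prop)) {
      stop(sprintf("non-finite energy at step %d", step), call. = FALSE)
    }
    if (e_prop <= e_cur || stats::runif(1) < exp(-beta * (e_prop - e_cur))) {
      state <- prop
      e_cur <- e_prop
      key <- if (torsional) "torsional" else "multi_stretch"
      accepted[key] <- accepted[key] + 1L
    }
    if (step > settings$burn_in &&
        (step - settings$burn_in) %% settings$stride == 0L) {
      ri <- ri + 1L
      rec_step[ri] <- step
      rec_conf[ri] <- conformer_label(state$torsions)
      rec_e[ri] <- e_cur
      states[[ri]] <- state
    }
  }
  structure(list(
    records = data.frame(step = rec_step[seq_len(ri)],
                         conformer = rec_conf[seq_len(ri)],
                         energy_ev = rec_e[seq_len(ri)]),
    states = states[seq_len(ri)],
    acceptance = sum(accepted) / sum(attempted),
    move_counts = attempted,
    acceptance_by_move = ifelse(attempted > 0, accepted / attempted, NA_real_),
    settings = settings),
    class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf(
    "MC trajectory: %d recorded configurations, acceptance %.1f%% (stretch %.1f%%, torsion %.1f%%)\n",
    nrow(x$records), 100 * x$acceptance,
    100 * x$acceptance_by_move[["multi_stretch"]],
    100 * x$acceptance_by_move[["torsional"]]))
  invisible(x)
}

#' Constrained conformer run
#'
#' Convenience wrapper over [run_mc()] that freezes a set of torsions so the
#' trajectory samples vibrations of a fixed conformer (all torsions frozen
#' leaves multi-stretch moves only). With an empty frozen set it is
#' byte-for-byte identical to [run_mc()] at equal seed.
#'
#' @inheritParams run_mc
#' @param frozen_torsions Labels of the bonds to freeze (default: all
#'   rotatable bonds).
#' @return An `mc_trajectory` (see [run_mc()]).
#' @export
constrain_conformer <- function(energy, settings, topology,
                                initial = mc_state(topology),
                                frozen_torsions = topology$rotatable) {
  run_mc(energy, settings, topology, initial = initial,
         frozen_torsions = frozen_torsions)
}
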