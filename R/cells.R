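#' Cell and synapse dynamics configuration
#'
#' Returns the full set of biophysical parameters used by the simulation
#' engine, as a nested list that can be inspected, modified and passed to
#' \code{\link{assemble_network}}.  Units: mV, ms, nF, uS.
#'
#' The model uses conductance-based multi-compartment neurons.  Pyramidal
#' cells have four compartments (soma, initial segment, basal dendrite,
#' apical dendrite); basket cells, RSNP interneurons and relay cells have
#' three (soma, initial segment, dendrite).  Spike-generating Na/K
#' currents of Hodgkin-Huxley form are placed on the initial segment;
#' soma and dendrites are passive.  A spike-triggered calcium pool on the
#' soma drives a potassium after-hyperpolarization current, producing
#' spike-frequency adaptation: full gain on pyramidal cells, reduced gain
#' on RSNP interneurons, none on basket or relay cells.  All synaptic
#' channels (AMPA/kainate, voltage-dependent NMDA, GABA_A) carry
#' single-release-variable short-term depression.  Relay cells are driven
#' as scheduled spike sources (their firing times come from the stimulus
#' protocol), so they carry no compartments in the default configuration.
#'
#' @param adaptation_tau calcium pool time constant in ms (default 300;
#'   the near-second adaptation range is 300-1000).
#' @param depression_U release fraction consumed per spike (default 0.2).
#' @param depression_tau recovery time constant of the release variable
#'   in ms (default 350; attractors must re-ignite from one presentation
#'   to the next at the 1 s protocol spacing).
#' @param background_rate Poisson background rate in Hz applied to every
#'   non-relay cell (default 300).
#' @return A nested list of class \code{"dynamics_config"}.
#' @export
dynamics_config <- function(adaptation_tau = 300,
                            depression_U = 0.2,
                            depression_tau = 350,
                            background_rate = 300) {
  cfg <- list(
    cells = list(
      pyramidal = list(
        compartments = c("soma", "initial_segment", "basal", "apical"),
        soma = list(C = 0.05, gL = 0.005, EL = -70),
        initial_segment = list(C = 0.01, gL = 0.001, EL = -70,
                               g_couple = 0.03, gNa = 0.5, gK = 0.15),
        basal = list(C = 0.05, gL = 0.005, EL = -70, g_couple = 0.03),
        apical = list(C = 0.05, gL = 0.005, EL = -70, g_couple = 0.03),
        ca_inc = 1, ca_tau = adaptation_tau, g_ahp = 0.0005,
        thresh = -15, refractory = 2,
        U = depression_U, tau_rec = depression_tau
      ),
      basket = list(
        compartments = c("soma", "initial_segment", "dend"),
        soma = list(C = 0.02, gL = 0.002, EL = -70),
        initial_segment = list(C = 0.005, gL = 0.0005, EL = -70,
                               g_couple = 0.015, gNa = 0.3, gK = 0.09),
        dend = list(C = 0.02, gL = 0.002, EL = -70, g_couple = 0.015),
        ca_inc = 0, ca_tau = adaptation_tau, g_ahp = 0,
        thresh = -15, refractory = 2,
        U = depression_U, tau_rec = depression_tau
      ),
      rsnp = list(
        compartments = c("soma", "initial_segment", "dend"),
        soma = list(C = 0.02, gL = 0.002, EL = -70),
        initial_segment = list(C = 0.005, gL = 0.0005, EL = -70,
                               g_couple = 0.015, gNa = 0.3, gK = 0.09),
        dend = list(C = 0.02, gL = 0.002, EL = -70, g_couple = 0.015),
        ca_inc = 1, ca_tau = adaptation_tau, g_ahp = 0.0002,
        thresh = -15, refractory = 2,
        U = depression_U, tau_rec = depression_tau
      ),
      relay = list(
        compartments = character(0),   # scheduled spike source
        ca_inc = 0, ca_tau = adaptation_tau, g_ahp = 0,
        thresh = NA_real_, refractory = 2,
        U = depression_U, tau_rec = depression_tau
      )
    ),
    receptors = list(
      tau_ampa = 5, tau_nmda_rise = 5, tau_nmda_decay = 150, tau_gaba = 10,
      e_exc = 0, e_gaba = -85,
      mg_eta = 0.2801, mg_gamma = 0.062   # 1 mM Mg block of the NMDA channel
    ),
    hh = list(vt = -55, ena = 50, ek = -90),
    background = list(rate = background_rate, weight = 8e-4)
  )
  class(cfg) <- "dynamics_config"
  cfg
}

#' Validate a dynamics configuration
#'
#' Checks the structural invariants: pyramidal cells have 4 compartments
#' and the others at most 3; adaptation gain is ordered
#' pyramidal > rsnp > basket = relay = 0; the GABA_A reversal lies below
#' rest; NMDA decay is slower than AMPA; depression parameters lie in
#' their valid ranges.
#'
#' @param cfg a \code{dynamics_config}.
#' @return \code{TRUE} invisibly; errors name the offending key.
#' @export
validate_dynamics <- function(cfg) {
  stopifnot(inherits(cfg, "dynamics_config"))
  cc <- cfg$cells
  if (length(cc$pyramidal$compartments) != 4L) {
    stop("cells$pyramidal$compartments: pyramidal cells must have 4 compartments")
  }
  for (cl in c("basket", "rsnp")) {
    if (length(cc[[cl]]$compartments) != 3L) {
      stop(sprintf("cells$%s$compartments: interneurons must have 3 compartments", cl))
    }
  }
  if (!(cc$pyramidal$g_ahp > cc$rsnp$g_ahp)) {
    stop("adaptation gain must satisfy pyramidal > rsnp")
  }
  if (!(cc$rsnp$g_ahp > 0) || cc$basket$g_ahp != 0 || cc$relay$g_ahp != 0) {
    stop("adaptation gain must satisfy rsnp > basket = relay = 0")
  }
  rp <- cfg$receptors
  if (rp$e_gaba >= cc$pyramidal$soma$EL) {
    stop("receptors$e_gaba: GABA_A reversal must lie below the resting potential")
  }
  if (rp$tau_nmda_decay <= rp$tau_ampa) {
    stop("receptors$tau_nmda_decay: NMDA must be slower than AMPA")
  }
  for (cl in names(cc)) {
    if (cc[[cl]]$U < 0 || cc[[cl]]$U > 1) stop(sprintf("cells$%s$U out of [0,1]", cl))
    if (cc[[cl]]$tau_rec <= 0) stop(sprintf("cells$%s$tau_rec must be positive", cl))
  }
  if (cfg$background$rate < 0) stop("background$rate must be non-negative")
  invisible(TRUE)
}

#' Short-term synaptic depression update
#'
#' Single-release-variable depression: on a presynaptic spike the release
#' variable first recovers exponentially toward 1 over the time elapsed
#' since the previous spike, is read out as the synaptic efficacy of the
#' spike, and is then reduced by the factor \eqn{(1 - U)}.
#'
#' @param release current release variable in [0, 1].
#' @param U release fraction consumed per spike.
#' @param tau_rec recovery time constant (ms).
#' @param dt_since_last time since the previous presynaptic spike (ms);
#'   \code{Inf} for the first spike.
#' @return list with \code{efficacy} (release available to this spike)
#'   and \code{release} (post-spike value).
#' @export
apply_depression <- function(release, U, tau_rec, dt_since_last = Inf) {
  stopifnot(release >= 0, release <= 1, U >= 0, U <= 1, tau_rec > 0)
  x <- 1 - (1 - release) * exp(-dt_since_last / tau_rec)
  list(efficacy = x, release = x * (1 - U))
}

#' Steady-state release under periodic firing
#'
#' Closed-form fixed point of the depression recursion for a presynaptic
#' spike train at fixed rate: with inter-spike interval \eqn{T},
#' \eqn{x^* = (1 - e^{-T/\tau}) / (1 - (1-U) e^{-T/\tau})}.
#'
#' @param U release fraction per spike.
#' @param tau_rec recovery time constant (ms).
#' @param rate firing rate (Hz).
#' @return the steady-state efficacy seen by each spike.
#' @export
depression_steady_state <- function(U, tau_rec, rate) {
  if (rate <= 0) return(1)
  e <- exp(-1000 / (rate * tau_rec))
  (1 - e) / (1 - (1 - U) * e)
}

#' Homogeneous Poisson event times
#'
#' Draws event times on (0, duration] with exponential inter-event
#' intervals, reproducibly from a seed.  This is the process used for the
#' background drive of all non-relay cells.
#'
#' @param rate events per second (Hz).
#' @param duration interval length in ms.
#' @param seed integer seed.
#' @return numeric vector of event times (ms), strictly increasing.
#' @export
poisson_background <- function(rate, duration, seed = 1L) {
  stopifnot(rate >= 0, duration >= 0)
  if (rate == 0 || duration == 0) return(numeric(0))
  with_seed(seed, {
    n_guess <- ceiling(rate * duration / 1000 + 6 * sqrt(rate * duration / 1000) + 10)
    t <- cumsum(stats::rexp(n_guess, rate = rate / 1000))
    while (t[length(t)] <= duration) {
      t <- c(t, t[length(t)] + cumsum(stats::rexp(n_guess, rate = rate / 1000)))
    }
    t[t <= duration]
  })
}
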