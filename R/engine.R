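CLASS_CODES <- c(pyramidal = 0L, basket = 1L, rsnp = 2L, relay = 3L)

#' Assemble a complete simulatable network
#'
#' Combines geometry, stored attractor patterns, and all wiring stages
#' (LGN feedforward, within-area microcircuits, long-range within-pattern
#' connections, inter-areal projections) into the flat compartment and
#' synapse arrays consumed by the integration engine.  All randomness in
#' wiring is driven by \code{individual_seed}: regenerating with the same
#' seed reproduces the connection matrices bit-identically, while
#' different seeds give a different simulated individual with the same
#' geometry.
#'
#' @param geom a \code{\link{build_geometry}} result.
#' @param v1_patterns,v2_patterns \code{pattern_set}s for the two areas.
#' @param linkage a \code{\link{link_patterns}} result.
#' @param wc a \code{\link{wiring_config}}.
#' @param dyn a \code{\link{dynamics_config}}.
#' @param individual_seed integer seed for all wiring randomness.
#' @param feedback_enabled wire V2-to-V1 feedback projections?
#' @return An object of class \code{"cortical_network"}.
#' @export
assemble_network <- function(geom, v1_patterns, v2_patterns, linkage,
                             wc = wiring_config(geom$config$model),
                             dyn = dynamics_config(),
                             individual_seed = 1L,
                             feedback_enabled = TRUE) {
  stopifnot(inherits(geom, "network_geometry"))
  validate_dynamics(dyn)
  # Projections are always wired with feedback so that the feedback-off
  # network is the identical individual minus its V2-to-V1 synapses
  # (paired comparisons across the feedback conditions).
  frag <- with_seed(individual_seed, {
    f <- frag_bind(list(
      wire_lgn(geom, wc),
      wire_microcircuit(geom, wc, "V1"),
      wire_microcircuit(geom, wc, "V2"),
      wire_longrange(geom, v1_patterns, wc, "V1"),
      wire_longrange(geom, v2_patterns, wc, "V2"),
      wire_projections(geom, v1_patterns, v2_patterns, linkage, wc,
                       feedback_enabled = TRUE)
    ))
    # per-synapse lognormal weight heterogeneity (mean-preserving)
    sj <- wc$weight_jitter %||% 0
    if (sj > 0 && length(f$w)) {
      f$w <- f$w * exp(stats::rnorm(length(f$w), 0, sj) - sj^2 / 2)
    }
    f
  })
  if (!feedback_enabled) {
    v2_first <- geom$area_base[["V2"]] + 1L
    keep <- !(frag$src >= v2_first & frag$tgt < v2_first)
    frag <- lapply(frag, `[`, keep)
  }
  # apply global conductance scale factors
  is_inh <- frag$rec == REC_GABA
  frag$w[is_inh] <- frag$w[is_inh] * wc$g_inh
  frag$w[!is_inh] <- frag$w[!is_inh] * wc$g_exc
  cells <- cell_table(geom)
  net <- structure(list(
    geom = geom, wc = wc, dyn = dyn,
    v1_patterns = v1_patterns, v2_patterns = v2_patterns, linkage = linkage,
    feedback_enabled = feedback_enabled,
    individual_seed = individual_seed,
    frag = frag,
    cells = cells,
    comp = build_comp_tables(geom, dyn, cells)
  ), class = "cortical_network")
  net
}

#' @export
print.cortical_network <- function(x, ...) {
  cat(sprintf("Cortical network (%s): %d cells, %d compartments, %d synapses\n",
              x$geom$config$model, x$geom$n_cells,
              length(x$comp$comp_C), length(x$frag$src)))
  cat(sprintf("  %d linked pattern pairs; feedback %s; individual seed %d\n",
              nrow(x$linkage), if (x$feedback_enabled) "on" else "off",
              x$individual_seed))
  invisible(x)
}

# Flat compartment tables in the engine's layout:
# [initial segments][somata][proximal dendrites][apical dendrites],
# each section ordered by cortical cell id.  Relay cells own no
# compartments; they fire only as scheduled events.
build_comp_tables <- function(geom, dyn, cells) {
  cortical <- cells[cells$class != "relay", ]
  nc <- nrow(cortical)
  cls <- cortical$class
  is_pyr <- cls == "pyramidal"
  n_is <- nc; n_soma <- nc
  n_prox <- nc; n_apic <- sum(is_pyr)
  n_comps <- n_is + n_soma + n_prox + n_apic

  getp <- function(class, compartment, field) {
    dyn$cells[[class]][[compartment]][[field]]
  }
  vec <- function(compartment, field, subset = rep(TRUE, nc)) {
    out <- numeric(sum(subset))
    cl <- cls[subset]
    for (k in unique(cl)) {
      out[cl == k] <- getp(k, compartment, field)
    }
    out
  }
  vec_prox <- function(field) {
    out <- numeric(nc)
    out[is_pyr] <- getp("pyramidal", "basal", field)
    for (k in c("basket", "rsnp")) {
      sel <- cls == k
      if (any(sel)) out[sel] <- getp(k, "dend", field)
    }
    out
  }

  # section offsets (0-based for the engine)
  is_idx <- seq_len(nc) - 1L
  soma_idx <- n_is + seq_len(nc) - 1L
  prox_idx <- n_is + n_soma + seq_len(nc) - 1L
  apic_idx <- rep(NA_integer_, nc)
  apic_idx[is_pyr] <- n_is + n_soma + n_prox + seq_len(n_apic) - 1L

  cell0 <- cortical$id - 1L  # 0-based engine cell ids

  comp_C <- c(vec("initial_segment", "C"), vec("soma", "C"),
              vec_prox("C"), rep(getp("pyramidal", "apical", "C"), n_apic))
  comp_gL <- c(vec("initial_segment", "gL"), vec("soma", "gL"),
               vec_prox("gL"), rep(getp("pyramidal", "apical", "gL"), n_apic))
  comp_EL <- c(vec("initial_segment", "EL"), vec("soma", "EL"),
               vec_prox("EL"), rep(getp("pyramidal", "apical", "EL"), n_apic))
  comp_gc <- c(vec("initial_segment", "g_couple"), rep(0, nc),
               vec_prox("g_couple"), rep(getp("pyramidal", "apical", "g_couple"), n_apic))
  comp_parent <- c(soma_idx, rep(-1L, nc), soma_idx, soma_idx[is_pyr])
  comp_cell <- c(cell0, cell0, cell0, cell0[is_pyr])

  cellv <- function(field) {
    out <- numeric(max(cells$id))
    for (k in names(dyn$cells)) {
      sel <- cells$class == k
      if (any(sel)) out[cells$id[sel]] <- dyn$cells[[k]][[field]]
    }
    out
  }
  n_all <- nrow(cells)
  cell_is_comp <- rep(-1L, n_all); cell_is_comp[cortical$id] <- is_idx
  cell_soma_comp <- rep(-1L, n_all); cell_soma_comp[cortical$id] <- soma_idx
  prox_comp <- rep(-1L, n_all); prox_comp[cortical$id] <- prox_idx
  dist_comp <- rep(-1L, n_all)
  dist_comp[cortical$id] <- ifelse(is.na(apic_idx), prox_idx, apic_idx)

  bg_rate <- rep(0, n_all)
  bg_rate[cortical$id] <- dyn$background$rate
  bg_w <- rep(dyn$background$weight, n_all)

  thr <- cellv("thresh"); thr[is.na(thr)] <- 1e9  # relays never threshold-spike

  list(
    comp_C = comp_C, comp_gL = comp_gL, comp_EL = comp_EL, comp_gc = comp_gc,
    comp_parent = comp_parent, comp_cell = comp_cell,
    n_is = n_is, n_soma = n_soma,
    is_gNa = vec("initial_segment", "gNa"),
    is_gK = vec("initial_segment", "gK"),
    is_cell = cell0,
    cell_is_comp = cell_is_comp, cell_soma_comp = cell_soma_comp,
    prox_comp = prox_comp, dist_comp = dist_comp,
    cell_thresh = thr,
    cell_ca_inc = cellv("ca_inc"), cell_ca_tau = cellv("ca_tau"),
    cell_g_ahp = cellv("g_ahp"),
    cell_bg_rate = bg_rate, cell_bg_w = bg_w,
    cell_U = cellv("U"), cell_tau_rec = cellv("tau_rec"),
    cell_refractory = cellv("refractory")
  )
}

#' Build forced-spike schedule entries
#'
#' Listed cells emit spikes at exactly the listed times regardless of
#' membrane state (used to drive LGN relay cells from the stimulus
#' protocol, and available for any cell in probing experiments).
#'
#' @param net a \code{cortical_network} (for id validation).
#' @param cells integer cell ids.
#' @param times spike times in ms (recycled against \code{cells}).
#' @return data.frame with columns \code{cell}, \code{time}.
#' @export
force_spikes <- function(net, cells, times) {
  if (length(cells) == 0L) return(data.frame(cell = integer(0), time = numeric(0)))
  n <- max(length(cells), length(times))
  cells <- rep_len(as.integer(cells), n)
  times <- rep_len(as.numeric(times), n)
  bad <- cells < 1L | cells > net$geom$n_cells
  if (any(bad)) stop("unknown cell id(s): ", paste(utils::head(cells[bad]), collapse = ", "))
  if (any(times < 0)) stop("spike times must be non-negative")
  data.frame(cell = cells, time = times)
}

#' Run the network simulation
#'
#' Integrates the assembled network for \code{duration} ms with fixed
#' step \code{dt}, delivering synaptic events through a circular
#' delay-line buffer (delays are quantized to the nearest step) and
#' recording every spike.  The same (network, schedule, trial seed)
#' triple replays bit-identically.
#'
#' @param net a \code{\link{assemble_network}} result.
#' @param schedule forced-spike data.frame from \code{\link{force_spikes}}
#'   (or any data.frame with \code{cell}, \code{time} columns); may be
#'   empty.
#' @param duration simulated time in ms.
#' @param dt integration step in ms (default 0.1; must be <= 0.1).
#' @param seed trial seed driving the background noise.
#' @param background logical; set \code{FALSE} to silence the Poisson
#'   background drive.
#' @param trace_cells optional cell ids whose somatic potential is
#'   recorded every \code{trace_every} steps (diagnostics).
#' @param trace_every trace sampling stride in steps.
#' @param inject optional data.frame of step-current injections with
#'   columns \code{cell}, \code{compartment} (\code{"soma"},
#'   \code{"initial_segment"}, \code{"proximal"} or \code{"distal"}),
#'   \code{amp} (nA), \code{from}, \code{to} (ms).
#' @return A \code{spike_raster} object.
#' @export
run_network <- function(net, schedule = NULL, duration = 1000, dt = 0.1,
                        seed = 1L, background = TRUE,
                        trace_cells = integer(0), trace_every = 10L,
                        inject = NULL) {
  stopifnot(inherits(net, "cortical_network"))
  if (dt > 0.1 + 1e-12 || dt <= 0) stop("dt must be positive and at most 0.1 ms")
  n_steps <- as.integer(round(duration / dt))
  if (is.null(schedule)) schedule <- data.frame(cell = integer(0), time = numeric(0))
  if (nrow(schedule)) {
    if (any(schedule$time >= duration)) {
      stop("schedule overflow: forced spike at or beyond the simulation end")
    }
    if (any(schedule$cell < 1L | schedule$cell > net$geom$n_cells)) {
      stop("unknown cell id in schedule")
    }
  }
  ord <- order(schedule$time)
  f_cell <- as.integer(schedule$cell[ord]) - 1L
  f_step <- as.integer(round(schedule$time[ord] / dt))
  f_step[f_step >= n_steps] <- n_steps - 1L

  en <- net$comp
  frag <- net$frag
  # synapse CSR by source cell, targets resolved to compartment indices
  tgt_comp <- integer(length(frag$src))
  tgt_comp[frag$slot == SLOT_PROX] <- en$prox_comp[frag$tgt[frag$slot == SLOT_PROX]]
  tgt_comp[frag$slot == SLOT_DIST] <- en$dist_comp[frag$tgt[frag$slot == SLOT_DIST]]
  tgt_comp[frag$slot == SLOT_SOMA] <- en$cell_soma_comp[frag$tgt[frag$slot == SLOT_SOMA]]
  if (any(tgt_comp < 0L)) stop("synapse onto a cell with no compartments")
  o <- order(frag$src)
  src0 <- frag$src[o] - 1L
  syn_ptr <- c(0L, cumsum(tabulate(frag$src, nbins = net$geom$n_cells)))
  w <- frag$w[o]
  rec <- frag$rec[o]
  # fold the NMDA peak normalization into the stored weight
  rp <- net$dyn$receptors
  nmda_norm <- local({
    tr <- rp$tau_nmda_rise; td <- rp$tau_nmda_decay
    tpk <- tr * td / (td - tr) * log(td / tr)
    1 / (exp(-tpk / td) - exp(-tpk / tr))
  })
  w[rec == REC_NMDA] <- w[rec == REC_NMDA] * nmda_norm
  delay_steps <- pmax(1L, as.integer(round(frag$delay[o] / dt)))

  bg_rate <- en$cell_bg_rate
  if (!background) bg_rate <- rep(0, length(bg_rate))

  engine_net <- list(
    comp_C = en$comp_C, comp_gL = en$comp_gL, comp_EL = en$comp_EL,
    comp_gc = en$comp_gc, comp_parent = en$comp_parent, comp_cell = en$comp_cell,
    n_is = en$n_is, n_soma = en$n_soma,
    is_gNa = en$is_gNa, is_gK = en$is_gK, is_cell = en$is_cell,
    cell_is_comp = en$cell_is_comp, cell_soma_comp = en$cell_soma_comp,
    cell_thresh = en$cell_thresh, cell_ca_inc = en$cell_ca_inc,
    cell_ca_tau = en$cell_ca_tau, cell_g_ahp = en$cell_g_ahp,
    cell_bg_rate = bg_rate, cell_bg_w = en$cell_bg_w,
    cell_U = en$cell_U, cell_tau_rec = en$cell_tau_rec,
    cell_refr_steps = as.integer(round(en$cell_refractory / dt)),
    syn_ptr = syn_ptr, syn_tgt = tgt_comp[o], syn_rec = rec,
    syn_w = w, syn_delay = delay_steps,
    receptors = rp, hh = net$dyn$hh
  )
  trace_comps <- integer(0)
  if (length(trace_cells)) {
    trace_comps <- en$cell_soma_comp[as.integer(trace_cells)]
    if (any(trace_comps < 0L)) stop("cannot trace a cell with no compartments")
  }
  inj_comp <- integer(0); inj_amp <- numeric(0)
  inj_from <- integer(0); inj_to <- integer(0)
  if (!is.null(inject) && nrow(inject)) {
    slot_of <- function(cell, compartment) {
      switch(compartment,
             soma = en$cell_soma_comp[cell],
             initial_segment = en$cell_is_comp[cell],
             proximal = en$prox_comp[cell],
             distal = en$dist_comp[cell],
             stop("unknown compartment: ", compartment))
    }
    inj_comp <- mapply(slot_of, as.integer(inject$cell), as.character(inject$compartment))
    if (any(inj_comp < 0L)) stop("cannot inject into a cell with no compartments")
    inj_amp <- as.numeric(inject$amp)
    inj_from <- as.integer(round(inject$from / dt))
    inj_to <- pmin(as.integer(round(inject$to / dt)), n_steps)
  }
  res <- .engine_run(engine_net, f_cell, f_step, n_steps, dt,
                     as.double(seed %% 2^31), trace_comps, as.integer(trace_every),
                     as.integer(inj_comp), inj_amp, inj_from, inj_to)
  ev <- data.frame(time = res$spike_step * dt, cell = res$spike_cell + 1L)
  meta <- net$cells[ev$cell, c("area", "layer", "mc", "hc", "class")]
  ev <- cbind(ev, meta)
  rownames(ev) <- NULL
  out <- structure(list(events = ev, duration = duration, dt = dt,
                        n_cells = net$geom$n_cells, seed = seed),
                   class = "spike_raster")
  if (!is.null(res$trace)) {
    attr(out, "trace") <- res$trace
    attr(out, "trace_cells") <- trace_cells
    attr(out, "trace_dt") <- dt * trace_every
  }
  out
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d events over %g ms (%d cells)\n",
              nrow(x$events), x$duration, x$n_cells))
  if (nrow(x$events)) {
    tab <- table(x$events$area)
    cat("  events by area:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.spike_raster <- function(object, ...) {
  ev <- object$events
  agg <- stats::aggregate(list(spikes = ev$time),
                          by = list(area = ev$area, layer = ev$layer, class = ev$class),
                          FUN = length)
  agg
}

#' Plot a spike raster
#'
#' Spike times against cell id, coloured by area, in the style of the
#' classic backward-masking trial rasters.
#'
#' @param x a \code{spike_raster}.
#' @param ... passed to \code{plot}.
#' @export
plot.spike_raster <- function(x, ...) {
  ev <- x$events
  if (!nrow(ev)) {
    plot(NA, xlim = c(0, x$duration), ylim = c(0, x$n_cells),
         xlab = "time (ms)", ylab = "cell id", main = "spike raster (empty)")
    return(invisible(x))
  }
  cols <- c(LGN = "grey40", V1 = "firebrick", V2 = "navy")[ev$area]
  plot(ev$time, ev$cell, pch = ".", col = cols,
       xlab = "time (ms)", ylab = "cell id", ...)
  invisible(x)
}

#' Write a spike raster as a tab-separated event table
#'
#' Columns: time_ms, cell_id, area, layer, minicolumn, class.
#'
#' @param raster a \code{spike_raster}.
#' @param path output file path.
#' @return \code{path} invisibly.
#' @export
write_raster_tsv <- function(raster, path) {
  ev <- raster$events
  out <- data.frame(time_ms = ev$time, cell_id = ev$cell, area = ev$area,
                    layer = ev$layer, minicolumn = ev$mc, class = ev$class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spike raster written by \code{\link{write_raster_tsv}}
#'
#' @param path file path.
#' @param duration,n_cells raster bounds (recovered from the data when
#'   omitted).
#' @return A \code{spike_raster}.
#' @export
read_raster_tsv <- function(path, duration = NULL, n_cells = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ev <- data.frame(time = tab$time_ms, cell = tab$cell_id, area = tab$area,
                   layer = tab$layer, mc = tab$minicolumn, hc = NA_integer_,
                   class = tab$class)
  structure(list(events = ev,
                 duration = duration %||% (if (nrow(ev)) max(ev$time) else 0),
                 dt = NA_real_,
                 n_cells = n_cells %||% (if (nrow(ev)) max(ev$cell) else 0L),
                 seed = NA_integer_),
            class = "spike_raster")
}
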