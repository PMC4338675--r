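#' Wiring configuration
#'
#' Connection probabilities, synaptic weights (uS, full-scale), and
#' axonal delays (ms) for every projection class in the model.  Weights
#' are specified at full scale; when a desk-scale geometry is assembled,
#' excitatory and inhibitory weights are multiplied by the ratio of
#' full-scale to scaled presynaptic counts (\code{scale_compensation}),
#' so that total synaptic drive per cell is approximately preserved.
#'
#' The lateral inhibition profile gives the absolute basket-to-pyramidal
#' connection probability by horizontal hypercolumn distance.  Model 1
#' confines lateral inhibition to the home hypercolumn; model 2 extends
#' it along the grid row: 0.5 one hypercolumn away and 0.25 two away,
#' zero beyond, for competition between parallel vertical lines.
#'
#' `g_exc` and `g_inh` are the global excitatory/inhibitory conductance
#' scale factors set by \code{\link{calibrate}}.
#'
#' @param model \code{"model1"} or \code{"model2"} (selects the lateral
#'   inhibition profile default).
#' @param lateral_profile absolute basket-to-pyramidal probabilities at
#'   hypercolumn distance 0, 1, 2, ...; must be nonincreasing.
#' @param basket_delay_extra additional basket-to-pyramidal synaptic
#'   delay in ms (0 by default; 3 models lagged inhibition).
#' @param g_exc,g_inh global conductance scale factors applied to all
#'   excitatory / inhibitory weights.
#' @param feedback_l23_ratio strength of the V2 L4 to V1 L2/3 feedback
#'   relative to the V2 L4 to V1 L5 feedback (default 0.10).
#' @param ff_l23_ratio strength of the V1 L2/3 to V2 L2/3 feedforward
#'   relative to the L4 to L4 feedforward (default 0.25 for model 1,
#'   0.4 for model 2).
#' @param v2_boost conductance boost on V2 interlaminar excitation
#'   (default 1.5), compensating for the absence of areas above V2.
#' @param nmda_ratio NMDA weight as a fraction of the AMPA weight on
#'   excitatory synapses onto pyramidal and RSNP cells.
#' @param scale_compensation multiply weights by full/scaled presynaptic
#'   count ratios on desk-scale networks.
#' @param ... named overrides for any probability, weight or delay field.
#' @return A list of class \code{"wiring_config"}.
#' @export
wiring_config <- function(model = c("model1", "model2"),
                          lateral_profile = NULL,
                          basket_delay_extra = NULL,
                          g_exc = 1, g_inh = 1,
                          feedback_l23_ratio = 0.10,
                          ff_l23_ratio = NULL,
                          v2_boost = 1.5,
                          nmda_ratio = 0.6,
                          scale_compensation = TRUE,
                          ...) {
  model <- match.arg(model)
  if (is.null(lateral_profile)) {
    lateral_profile <- if (model == "model1") c(0.7) else c(0.7, 0.5, 0.25)
  }
  # model 2 defaults to lagged basket inhibition (3 ms), which protects
  # targets at the shortest SOAs; model 1 keeps instantaneous inhibition
  if (is.null(basket_delay_extra)) {
    basket_delay_extra <- if (model == "model1") 0 else 3
  }
  # model 2's V2 leans on a stronger, faster feedforward cue: its line
  # attractors must complete across 9 hypercolumn rows from a 4-minicolumn cue
  if (is.null(ff_l23_ratio)) {
    ff_l23_ratio <- if (model == "model1") 0.25 else 0.4
  }
  if (any(diff(lateral_profile) > 0)) {
    stop("lateral_profile must be nonincreasing with distance")
  }
  if (any(lateral_profile < 0 | lateral_profile > 1)) {
    stop("lateral_profile probabilities must lie in [0,1]")
  }
  wc <- list(
    model = model,
    # probabilities
    p_recurrent = 0.25,       # pyramidal-pyramidal within minicolumn+layer
    p_pyr_basket = 0.7,       # pyramidal to basket within hypercolumn
    lateral_profile = lateral_profile,
    p_interlaminar = 0.25,    # L4 to L2/3 and L4 to L5 within minicolumn
    p_rsnp_pyr = 0.7,         # RSNP to pyramidal within its minicolumn
    p_longrange_pyr = 0.25,   # destination pyramidal hit probability
    p_longrange_rsnp = 0.7,   # di-synaptic RSNP hit probability
    p_pair_l23 = 1.0,         # pairwise minicolumn connection prob., L2/3
    p_pair_l4 = 0.5,          # weaker long-range connectivity in L4
    p_lgn_pyr = 0.7,
    p_lgn_basket = 1.0,
    proj_fanin = 4L,          # destination minicolumns per pattern projection
    feedback_l23_ratio = feedback_l23_ratio,
    ff_l23_ratio = ff_l23_ratio,
    v2_boost = v2_boost,
    nmda_ratio = nmda_ratio,
    weight_jitter = 0.35,     # lognormal weight heterogeneity (sd of log)
    # weights (uS, full scale)
    w_recurrent = 0.003,
    w_interlaminar = if (model == "model1") 0.002 else 0.0025,
    w_longrange = 0.018,
    w_pyr_basket = 0.0035,
    w_basket_pyr = 0.036,
    w_rsnp_pyr = 0.021,
    w_longrange_rsnp = 0.006,
    w_relay = if (model == "model1") 0.012 else 0.010,
    # feedforward relay->basket inhibition: strong inside shared hypercolumns
    # (model 1 noise masks); weak for model 2, where masking is carried by
    # competition between ignited line attractors
    w_relay_basket = if (model == "model1") 0.008 else 0.002,
    w_ff = if (model == "model1") 0.016 else 0.024,
    w_fb = if (model == "model1") 0.08 else 0.035,
    w_fb_rsnp = if (model == "model1") 0.012 else 0.006,
    # delays (ms)
    delay_local = 1,
    delay_interareal = 10,
    delay_lgn = 1,
    basket_delay_extra = basket_delay_extra,
    # calibration scales
    g_exc = g_exc, g_inh = g_inh,
    scale_compensation = scale_compensation
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(wc))
  if (length(unknown)) stop("unknown wiring_config fields: ", paste(unknown, collapse = ", "))
  wc[names(dots)] <- dots
  class(wc) <- "wiring_config"
  wc
}

# --- fragment helpers ------------------------------------------------------

# slot codes: 1 proximal excitatory (basal / interneuron dendrite),
#             2 distal excitatory (apical / interneuron dendrite),
#             3 somatic (GABA_A and background)
SLOT_PROX <- 1L; SLOT_DIST <- 2L; SLOT_SOMA <- 3L
REC_AMPA <- 0L; REC_NMDA <- 1L; REC_GABA <- 2L

empty_frag <- function() {
  list(src = integer(0), tgt = integer(0), slot = integer(0),
       rec = integer(0), w = numeric(0), delay = numeric(0))
}

frag_bind <- function(frags) {
  frags <- Filter(function(f) length(f$src) > 0L, frags)
  if (!length(frags)) return(empty_frag())
  list(src = unlist(lapply(frags, `[[`, "src"), use.names = FALSE),
       tgt = unlist(lapply(frags, `[[`, "tgt"), use.names = FALSE),
       slot = unlist(lapply(frags, `[[`, "slot"), use.names = FALSE),
       rec = unlist(lapply(frags, `[[`, "rec"), use.names = FALSE),
       w = unlist(lapply(frags, `[[`, "w"), use.names = FALSE),
       delay = unlist(lapply(frags, `[[`, "delay"), use.names = FALSE))
}

frag_as_table <- function(frag) {
  data.frame(src = frag$src, tgt = frag$tgt, slot = frag$slot,
             receptor = c("AMPA", "NMDA", "GABA_A")[frag$rec + 1L],
             weight = frag$w, delay = frag$delay)
}

# All-to-all Bernoulli pairs between two id vectors, self-pairs removed.
bernoulli_pairs <- function(src_ids, tgt_ids, p) {
  ns <- length(src_ids); nt <- length(tgt_ids)
  if (ns == 0L || nt == 0L || p <= 0) return(list(src = integer(0), tgt = integer(0)))
  hit <- which(stats::runif(ns * nt) < p)
  if (!length(hit)) return(list(src = integer(0), tgt = integer(0)))
  src <- src_ids[((hit - 1L) %/% nt) + 1L]
  tgt <- tgt_ids[((hit - 1L) %% nt) + 1L]
  keep <- src != tgt
  list(src = src[keep], tgt = tgt[keep])
}

# Excitatory synapse bundle: AMPA plus (optionally) NMDA at ratio, on a slot.
exc_frag <- function(src, tgt, slot, w, delay, nmda_ratio, with_nmda = TRUE) {
  n <- length(src)
  if (n == 0L) return(empty_frag())
  if (with_nmda && nmda_ratio > 0) {
    list(src = c(src, src), tgt = c(tgt, tgt),
         slot = rep(slot, 2L * n),
         rec = rep(c(REC_AMPA, REC_NMDA), each = n),
         w = c(rep(w, n), rep(w * nmda_ratio, n)),
         delay = rep(delay, 2L * n))
  } else {
    list(src = src, tgt = tgt, slot = rep(slot, n),
         rec = rep(REC_AMPA, n), w = rep(w, n), delay = rep(delay, n))
  }
}

inh_frag <- function(src, tgt, w, delay) {
  n <- length(src)
  if (n == 0L) return(empty_frag())
  list(src = src, tgt = tgt, slot = rep(SLOT_SOMA, n),
       rec = rep(REC_GABA, n), w = rep(w, n), delay = rep(delay, n))
}

# Split a desk-scale compensation factor between connection probability and
# weight: probability is raised toward 1 first (keeping the expected total
# drive exact while reducing input-count variance on small cell pools), the
# remainder multiplies the weight.
comp_pw <- function(p, w, f) {
  p2 <- min(1, p * f)
  if (p2 <= 0) return(list(p = 0, w = w))
  list(p = p2, w = w * (p * f / p2))
}

# presynaptic-count compensation factors for desk-scale networks
comp_factors <- function(geom, wc) {
  cfg <- geom$config
  if (!isTRUE(wc$scale_compensation)) {
    return(c(pyr = 1, basket = 1, rsnp = 1, relay = 1))
  }
  c(pyr = cfg$pyramidal_full / cfg$pyramidal,
    basket = if (cfg$basket > 0) cfg$basket_full / cfg$basket else 1,
    rsnp = if (cfg$rsnp > 0) cfg$rsnp_full / cfg$rsnp else 1,
    relay = cfg$relays_full / cfg$relays)
}

# --- microcircuit ----------------------------------------------------------

#' Wire the within-area microcircuit of one cortical area
#'
#' Per minicolumn and layer: recurrent pyramidal-pyramidal excitation;
#' pyramidal-to-basket excitation pooled over the hypercolumn;
#' basket-to-pyramidal lateral inhibition onto \emph{other} minicolumns
#' following the hypercolumn-distance probability profile (horizontal
#' distance along the grid row); RSNP-to-pyramidal inhibition within the
#' RSNP's own minicolumn (the second leg of di-synaptic inhibition); and
#' L4-to-L2/3 plus L4-to-L5 interlaminar excitation within the
#' minicolumn (boosted in V2).
#'
#' Uses R's RNG stream; seed it (e.g. via the individual seed in
#' \code{\link{assemble_network}}) for reproducible wiring.
#'
#' @param geom a \code{network_geometry}.
#' @param wc a \code{\link{wiring_config}}.
#' @param area \code{"V1"} or \code{"V2"}.
#' @return A synapse fragment (internal list form; see
#'   \code{\link{synapse_table}}).
#' @export
wire_microcircuit <- function(geom, wc, area = "V1") {
  stopifnot(inherits(geom, "network_geometry"), inherits(wc, "wiring_config"))
  cf <- comp_factors(geom, wc)
  frags <- list()
  boost <- if (area == "V2") wc$v2_boost else 1
  d_inh <- wc$delay_local + wc$basket_delay_extra
  for (layer in c("L23", "L4", "L5")) {
    # recurrent excitation within each minicolumn
    if (wc$p_recurrent > 0 && geom$counts[["pyramidal"]] > 1L) {
      rec <- comp_pw(wc$p_recurrent, wc$w_recurrent, cf[["pyr"]])
      for (m in seq_len(geom$n_mc)) {
        ids <- cell_ids(geom, area, layer, m, "pyramidal")
        pr <- bernoulli_pairs(ids, ids, rec$p)
        frags[[length(frags) + 1L]] <-
          exc_frag(pr$src, pr$tgt, SLOT_PROX, rec$w,
                   wc$delay_local, wc$nmda_ratio)
      }
    }
    # hypercolumn-level basket circuitry.  Each minicolumn excites its own
    # allocated basket cells (they reside just outside it); those baskets
    # inhibit the pyramidal cells of *other* minicolumns - within the home
    # hypercolumn, and along the grid row for extended lateral profiles.
    pb_pw <- comp_pw(wc$p_pyr_basket, wc$w_pyr_basket, cf[["pyr"]])
    for (hc in seq_len(geom$n_hc)) {
      mcs <- which(geom$hc_of_mc == hc)
      bas <- cell_ids(geom, area, layer, mcs, "basket")
      if (length(bas)) {
        for (m in mcs) {
          bm <- cell_ids(geom, area, layer, m, "basket")
          pm <- cell_ids(geom, area, layer, m, "pyramidal")
          pb <- bernoulli_pairs(pm, bm, pb_pw$p)
          frags[[length(frags) + 1L]] <-
            exc_frag(pb$src, pb$tgt, SLOT_PROX, pb_pw$w,
                     wc$delay_local, wc$nmda_ratio, with_nmda = FALSE)
        }
        for (d in seq_along(wc$lateral_profile)) {
          p_d <- wc$lateral_profile[d]
          if (p_d <= 0) next
          if (d == 1L) {
            # within hypercolumn, excluding each basket's home minicolumn
            for (m in mcs) {
              bm <- cell_ids(geom, area, layer, m, "basket")
              tgt <- cell_ids(geom, area, layer, setdiff(mcs, m), "pyramidal")
              bp <- bernoulli_pairs(bm, tgt, p_d)
              frags[[length(frags) + 1L]] <-
                inh_frag(bp$src, bp$tgt, wc$w_basket_pyr * cf[["basket"]], d_inh)
            }
          } else {
            dist <- d - 1L
            neigh <- which(geom$hc_row == geom$hc_row[hc] &
                           abs(geom$hc_col - geom$hc_col[hc]) == dist)
            for (nh in neigh) {
              tgt <- cell_ids(geom, area, layer, which(geom$hc_of_mc == nh), "pyramidal")
              bp <- bernoulli_pairs(bas, tgt, p_d)
              frags[[length(frags) + 1L]] <-
                inh_frag(bp$src, bp$tgt, wc$w_basket_pyr * cf[["basket"]], d_inh)
            }
          }
        }
      }
      # RSNP inhibition within each minicolumn
      if (geom$counts[["rsnp"]] > 0L && wc$p_rsnp_pyr > 0) {
        for (m in mcs) {
          rs <- cell_ids(geom, area, layer, m, "rsnp")
          py <- cell_ids(geom, area, layer, m, "pyramidal")
          rp <- bernoulli_pairs(rs, py, wc$p_rsnp_pyr)
          frags[[length(frags) + 1L]] <-
            inh_frag(rp$src, rp$tgt, wc$w_rsnp_pyr * cf[["rsnp"]], wc$delay_local)
        }
      }
    }
  }
  # interlaminar excitation within each minicolumn: L4 -> L2/3, L4 -> L5
  il_pw <- comp_pw(wc$p_interlaminar, wc$w_interlaminar, cf[["pyr"]])
  for (m in seq_len(geom$n_mc)) {
    l4 <- cell_ids(geom, area, "L4", m, "pyramidal")
    for (dst_layer in c("L23", "L5")) {
      dst <- cell_ids(geom, area, dst_layer, m, "pyramidal")
      il <- bernoulli_pairs(l4, dst, il_pw$p)
      frags[[length(frags) + 1L]] <-
        exc_frag(il$src, il$tgt, SLOT_PROX, il_pw$w * boost,
                 wc$delay_local, wc$nmda_ratio)
    }
  }
  frag_bind(frags)
}

# --- long-range within-pattern wiring --------------------------------------

#' Wire long-range within-pattern connections
#'
#' For every ordered pair of minicolumns inside each stored attractor
#' memory, a pairwise connection probability (per layer; weaker in L4)
#' decides whether the pair is connected.  If so, one randomly chosen
#' pyramidal cell in the source minicolumn originates the axon;
#' destination pyramidal cells receive a synapse with probability 0.25,
#' and RSNP interneurons in the surrounding minicolumns of the
#' destination hypercolumn (outside the pattern) receive synapses,
#' providing di-synaptic inhibition between patterns sharing
#' hypercolumns.  All excitatory long-range synapses share one weight, as
#' do all di-synaptic ones.
#'
#' @param geom a \code{network_geometry}.
#' @param patterns a \code{pattern_set} for the area being wired.
#' @param wc a \code{\link{wiring_config}}.
#' @param area \code{"V1"} or \code{"V2"}.
#' @return A synapse fragment.
#' @export
wire_longrange <- function(geom, patterns, wc, area = "V1") {
  stopifnot(inherits(patterns, "pattern_set"))
  frags <- list()
  layer_p <- c(L23 = wc$p_pair_l23, L4 = wc$p_pair_l4)
  for (pat in patterns$patterns) {
    if (length(pat) < 2L) next
    in_pattern <- pat
    for (layer in names(layer_p)) {
      p_pair <- layer_p[[layer]]
      if (p_pair <= 0) next
      for (a in pat) for (b in pat) {
        if (a == b || stats::runif(1) >= p_pair) next
        src <- resample(cell_ids(geom, area, layer, a, "pyramidal"), 1L)
        dst <- cell_ids(geom, area, layer, b, "pyramidal")
        hit <- dst[stats::runif(length(dst)) < wc$p_longrange_pyr]
        frags[[length(frags) + 1L]] <-
          exc_frag(rep(src, length(hit)), hit, SLOT_DIST, wc$w_longrange,
                   wc$delay_local, wc$nmda_ratio)
        # di-synaptic leg: RSNP cells of surrounding minicolumns in the
        # destination hypercolumn, outside the pattern
        if (geom$counts[["rsnp"]] > 0L && wc$p_longrange_rsnp > 0) {
          surround <- setdiff(which(geom$hc_of_mc == geom$hc_of_mc[b]), in_pattern)
          if (length(surround)) {
            rs <- cell_ids(geom, area, layer, surround, "rsnp")
            hit_r <- rs[stats::runif(length(rs)) < wc$p_longrange_rsnp]
            frags[[length(frags) + 1L]] <-
              exc_frag(rep(src, length(hit_r)), hit_r, SLOT_DIST, wc$w_longrange_rsnp,
                       wc$delay_local, wc$nmda_ratio)
          }
        }
      }
    }
  }
  frag_bind(frags)
}

# --- LGN and inter-areal projections ---------------------------------------

#' Wire the LGN-to-V1 feedforward projection
#'
#' Each LGN location projects to the pyramidal cells of its V1 layer 4
#' minicolumn (AMPA+NMDA) and to that minicolumn's own layer 4 basket
#' cells, which in turn inhibit the surrounding minicolumns of the
#' hypercolumn (feedforward lateral inhibition).
#'
#' @param geom a \code{network_geometry}.
#' @param wc a \code{\link{wiring_config}}.
#' @return A synapse fragment.
#' @export
wire_lgn <- function(geom, wc) {
  cf <- comp_factors(geom, wc)
  frags <- list()
  lgn_pw <- comp_pw(wc$p_lgn_pyr, wc$w_relay, cf[["relay"]])
  for (m in seq_len(geom$n_mc)) {
    relays <- cell_ids(geom, "LGN", mc = m, class = "relay")
    pyr <- cell_ids(geom, "V1", "L4", m, "pyramidal")
    pr <- bernoulli_pairs(relays, pyr, lgn_pw$p)
    frags[[length(frags) + 1L]] <-
      exc_frag(pr$src, pr$tgt, SLOT_PROX, lgn_pw$w,
               wc$delay_lgn, wc$nmda_ratio)
    bas <- cell_ids(geom, "V1", "L4", m, "basket")
    if (length(bas)) {
      rb <- bernoulli_pairs(relays, bas, wc$p_lgn_basket)
      frags[[length(frags) + 1L]] <-
        exc_frag(rb$src, rb$tgt, SLOT_PROX, wc$w_relay_basket * cf[["relay"]],
                 wc$delay_lgn, wc$nmda_ratio, with_nmda = FALSE)
    }
  }
  frag_bind(frags)
}

#' Wire the inter-areal pattern projections between V1 and V2
#'
#' For each linked attractor-memory pair, four destination minicolumns
#' are selected (uniformly, without replacement, fixed for the
#' individual) on the destination side.  Feedforward: V1 L4 to V2 L4
#' (strong) and V1 L2/3 to V2 L2/3 (weaker).  Feedback (if enabled):
#' V2 L4 to V1 L5 (strong) and V2 L4 to V1 L2/3 at 10\% of that
#' strength, plus a di-synaptic leg onto RSNP cells surrounding the
#' destination minicolumns.  Per (source minicolumn, destination
#' minicolumn) pair one randomly chosen source pyramidal cell originates
#' the axon and destination pyramidal cells are hit with probability
#' 0.25.  Every inter-areal synapse carries the configured latency
#' (default 10 ms).
#'
#' @param geom a \code{network_geometry}.
#' @param v1_patterns,v2_patterns \code{pattern_set}s of the two areas.
#' @param linkage a \code{\link{link_patterns}} result.
#' @param wc a \code{\link{wiring_config}}.
#' @param feedback_enabled logical; omit all V2-to-V1 synapses if FALSE.
#' @return A synapse fragment.
#' @export
wire_projections <- function(geom, v1_patterns, v2_patterns, linkage, wc,
                             feedback_enabled = TRUE) {
  if (is.null(linkage) || nrow(linkage) == 0L) {
    if (feedback_enabled && is.null(linkage)) {
      stop("feedback requested but no pattern linkage is defined")
    }
    return(empty_frag())
  }
  frags <- list()
  one_direction <- function(src_area, dst_area, src_pat, dst_pat, entries) {
    fanin <- min(wc$proj_fanin, length(dst_pat))
    dest <- resample(dst_pat, fanin)
    for (sm in src_pat) for (dm in dest) {
      for (e in entries) {
        src <- resample(cell_ids(geom, src_area, e$src_layer, sm, "pyramidal"), 1L)
        dst <- cell_ids(geom, dst_area, e$dst_layer, dm, "pyramidal")
        hit <- dst[stats::runif(length(dst)) < wc$p_longrange_pyr]
        frags[[length(frags) + 1L]] <<-
          exc_frag(rep(src, length(hit)), hit, SLOT_DIST, e$w,
                   wc$delay_interareal, wc$nmda_ratio)
        if (isTRUE(e$disynaptic) && geom$counts[["rsnp"]] > 0L) {
          surround <- setdiff(which(geom$hc_of_mc == geom$hc_of_mc[dm]), dst_pat)
          if (length(surround)) {
            rs <- cell_ids(geom, dst_area, e$dst_layer, surround, "rsnp")
            hit_r <- rs[stats::runif(length(rs)) < wc$p_longrange_rsnp]
            frags[[length(frags) + 1L]] <<-
              exc_frag(rep(src, length(hit_r)), hit_r, SLOT_DIST, wc$w_fb_rsnp,
                       wc$delay_interareal, wc$nmda_ratio)
          }
        }
      }
    }
  }
  ff_entries <- list(
    list(src_layer = "L4", dst_layer = "L4", w = wc$w_ff, disynaptic = FALSE),
    list(src_layer = "L23", dst_layer = "L23", w = wc$w_ff * wc$ff_l23_ratio,
         disynaptic = FALSE))
  # Feedback: strong V2 L4 -> V1 L5, plus V2 L4 -> V1 L2/3 at 10% strength.
  # The di-synaptic inhibitory leg rides on the L2/3 projection: L2/3 is
  # where attractor competition between patterns plays out.
  fb_entries <- list(
    list(src_layer = "L4", dst_layer = "L5", w = wc$w_fb, disynaptic = FALSE),
    list(src_layer = "L4", dst_layer = "L23", w = wc$w_fb * wc$feedback_l23_ratio,
         disynaptic = TRUE))
  for (i in seq_len(nrow(linkage))) {
    p1 <- v1_patterns$patterns[[linkage$v1[i]]]
    p2 <- v2_patterns$patterns[[linkage$v2[i]]]
    one_direction("V1", "V2", p1, p2, ff_entries)
    if (feedback_enabled) one_direction("V2", "V1", p2, p1, fb_entries)
  }
  frag_bind(frags)
}

#' Synapse table of an assembled network
#'
#' Returns the complete connection list as a data.frame: source cell,
#' target cell, target compartment slot, receptor, weight (uS, after all
#' scale factors) and axonal delay (ms).
#'
#' @param net an \code{\link{assemble_network}} result.
#' @return data.frame with one row per synapse.
#' @export
synapse_table <- function(net) {
  stopifnot(inherits(net, "cortical_network"))
  out <- frag_as_table(net$frag)
  out$target <- c("proximal", "distal", "soma")[out$slot]
  out
}
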