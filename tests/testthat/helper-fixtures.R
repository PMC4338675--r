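# Shared fixtures: tiny networks are built once per test run and reused.

tiny1 <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- fixture_network("tiny_model1", individual_seed = 1L)
    net
  }
})

tiny2 <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- fixture_network("tiny_model2", individual_seed = 1L)
    net
  }
})

# a synthetic spike raster from an event table (analysis-level tests)
make_raster <- function(events, duration = 1000) {
  events$hc <- events$hc %||% NA_integer_
  structure(list(events = events, duration = duration,
                 dt = 0.1, n_cells = max(events$cell %||% 1L, 1L), seed = 0L),
            class = "spike_raster")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# events data.frame helper: n spikes in minicolumn mc (pyramidal, L23)
l23_events <- function(mc, n, area = "V1", t0 = 10) {
  if (n == 0) {
    return(data.frame(time = numeric(0), cell = integer(0), area = character(0),
                      layer = character(0), mc = integer(0), hc = integer(0),
                      class = character(0)))
  }
  data.frame(time = t0 + seq_len(n), cell = seq_len(n), area = area,
             layer = "L23", mc = mc, hc = NA_integer_, class = "pyramidal")
}
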