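#' Geometry configuration for the LGN/V1/V2 model
#'
#' Defines the structural skeleton of one model instantiation: the
#' hypercolumn grid shared by V1 and V2, the number of minicolumns per
#' hypercolumn, the per-minicolumn cell complement in each of the three
#' modelled layers (L2/3, L4, L5), and the LGN relay stack size.  Two
#' presets are provided: \code{"model1"} (4 x 4 hypercolumns with 16
#' minicolumns each, used with an abstract noise mask) and \code{"model2"}
#' (9 x 9 hypercolumns with 8 minicolumns each, used with vertical-line
#' stimuli).
#'
#' The \code{scale} argument is a desk-scale divisor applied to the
#' per-minicolumn cell counts (and the relay stack) so that reduced-size
#' networks can be simulated on a single workstation.  Scaling never
#' changes the geometry itself (grids, minicolumn counts), so stored
#' pattern structure and the completion analysis are scale-invariant.
#' Counts are rounded half up; pyramidal and relay counts are floored at 1.
#'
#' @param model \code{"model1"} or \code{"model2"} (selects the preset
#'   grid and minicolumn count).
#' @param grid integer pair \code{c(rows, cols)} of hypercolumns;
#'   defaults to the preset.
#' @param minicolumns_per_hypercolumn minicolumns inside each hypercolumn;
#'   defaults to the preset (16 for model 1, 8 for model 2).
#' @param pyramidal,basket,rsnp full-scale cells per minicolumn per layer
#'   (defaults 20, 2, 2).
#' @param relays full-scale relay cells per LGN location (default 10).
#' @param scale positive desk-scale divisor applied to cell counts.
#' @return An object of class \code{"geometry_config"}.
#' @examples
#' cfg <- geometry_config("model1")
#' total_cells(cfg)   # 39424
#' @export
geometry_config <- function(model = c("model1", "model2"),
                            grid = NULL,
                            minicolumns_per_hypercolumn = NULL,
                            pyramidal = 20L, basket = 2L, rsnp = 2L,
                            relays = 10L, scale = 1) {
  model <- match.arg(model)
  if (is.null(grid)) {
    grid <- if (model == "model1") c(4L, 4L) else c(9L, 9L)
  }
  if (is.null(minicolumns_per_hypercolumn)) {
    minicolumns_per_hypercolumn <- if (model == "model1") 16L else 8L
  }
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) {
    stop("configuration error: 'grid' must be two positive integers (rows, cols)")
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("configuration error: 'scale' must be a positive number")
  }
  counts <- c(pyramidal = pyramidal, basket = basket, rsnp = rsnp, relays = relays)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("configuration error: cell counts must be non-negative integers")
  }
  if (pyramidal < 1L) {
    stop("configuration error: at least one pyramidal cell per minicolumn per layer is required")
  }
  sc <- function(x) as.integer(floor(x * scale + 0.5))  # round half up
  structure(list(
    model = model,
    grid = grid,
    minicolumns_per_hypercolumn = as.integer(minicolumns_per_hypercolumn),
    layers = c("L23", "L4", "L5"),
    pyramidal_full = as.integer(pyramidal),
    basket_full = as.integer(basket),
    rsnp_full = as.integer(rsnp),
    relays_full = as.integer(relays),
    scale = scale,
    pyramidal = max(1L, sc(pyramidal)),
    basket = sc(basket),
    rsnp = sc(rsnp),
    relays = max(1L, sc(relays))
  ), class = "geometry_config")
}

#' @export
print.geometry_config <- function(x, ...) {
  cat(sprintf("Geometry config (%s): %d x %d hypercolumns, %d minicolumns each\n",
              x$model, x$grid[1], x$grid[2], x$minicolumns_per_hypercolumn))
  cat(sprintf("  per minicolumn per layer: %d pyramidal, %d basket, %d RSNP (scale %g)\n",
              x$pyramidal, x$basket, x$rsnp, x$scale))
  cat(sprintf("  LGN: %d relay cells per location; total cells %d\n",
              x$relays, total_cells(x)))
  invisible(x)
}

#' Closed-form total cell count
#'
#' \eqn{N = L \times r + 2 \times M \times 3 \times (p + b + s)} where
#' \eqn{L} is the number of LGN locations (one per V1 minicolumn), \eqn{r}
#' the relay stack size, \eqn{M} the minicolumns per area, and
#' \eqn{p, b, s} the per-minicolumn per-layer pyramidal, basket and RSNP
#' counts.
#'
#' @param x a \code{geometry_config} or \code{network_geometry}.
#' @return integer cell count.
#' @export
total_cells <- function(x) {
  cfg <- if (inherits(x, "network_geometry")) x$config else x
  stopifnot(inherits(cfg, "geometry_config"))
  n_mc <- prod(cfg$grid) * cfg$minicolumns_per_hypercolumn
  as.integer(n_mc * cfg$relays +
             2L * n_mc * 3L * (cfg$pyramidal + cfg$basket + cfg$rsnp))
}

#' Build the complete network geometry
#'
#' Deterministically lays out cell index ranges for every
#' (area, layer, minicolumn, cell class) tuple.  Cell ids are assigned
#' contiguously: LGN relay cells first (grouped by location), then V1 and
#' V2, each ordered by layer (L2/3, L4, L5), minicolumn, and class
#' (pyramidal, basket, RSNP).  There is one LGN location per V1
#' minicolumn.
#'
#' @param config a \code{\link{geometry_config}}.
#' @return An object of class \code{"network_geometry"} with the
#'   hypercolumn maps, counts, and index arithmetic needed by the wiring
#'   and analysis stages.
#' @export
build_geometry <- function(config) {
  stopifnot(inherits(config, "geometry_config"))
  rows <- config$grid[1]; cols <- config$grid[2]
  n_hc <- rows * cols
  mc_per_hc <- config$minicolumns_per_hypercolumn
  n_mc <- n_hc * mc_per_hc
  # hypercolumn ids are row-major over the grid
  hc_row <- rep(seq_len(rows), each = cols)
  hc_col <- rep(seq_len(cols), times = rows)
  hc_of_mc <- rep(seq_len(n_hc), each = mc_per_hc)
  mc_index_in_hc <- rep(seq_len(mc_per_hc), times = n_hc)

  P <- config$pyramidal; B <- config$basket; S <- config$rsnp
  per_mc_layer <- P + B + S
  per_layer <- n_mc * per_mc_layer
  per_area <- 3L * per_layer
  lgn_total <- n_mc * config$relays

  geom <- structure(list(
    config = config,
    n_hc = n_hc, grid = config$grid,
    mc_per_hc = mc_per_hc, n_mc = n_mc,
    hc_of_mc = hc_of_mc, mc_index_in_hc = mc_index_in_hc,
    hc_row = hc_row, hc_col = hc_col,
    lgn_locations = n_mc,
    counts = c(pyramidal = P, basket = B, rsnp = S, relays = config$relays),
    per_mc_layer = per_mc_layer, per_layer = per_layer, per_area = per_area,
    lgn_total = lgn_total,
    area_base = c(LGN = 0L, V1 = lgn_total, V2 = lgn_total + per_area),
    n_cells = as.integer(lgn_total + 2L * per_area)
  ), class = "network_geometry")
  stopifnot(geom$n_cells == total_cells(config))
  geom
}

#' @export
print.network_geometry <- function(x, ...) {
  cat(sprintf("Network geometry (%s): %d cells, %d hypercolumns x %d minicolumns per area\n",
              x$config$model, x$n_cells, x$n_hc, x$mc_per_hc))
  cat(sprintf("  LGN: %d locations x %d relays = %d relay cells\n",
              x$lgn_locations, x$counts[["relays"]], x$lgn_total))
  invisible(x)
}

layer_index <- function(layer) {
  i <- match(layer, c("L23", "L4", "L5"))
  if (anyNA(i)) stop("unknown layer: ", paste(layer[is.na(i)], collapse = ", "))
  i
}

#' Cell ids for an (area, layer, minicolumn, class) tuple
#'
#' Pure index arithmetic on the deterministic layout; vectorized over
#' \code{mc}.
#'
#' @param geom a \code{network_geometry}.
#' @param area \code{"LGN"}, \code{"V1"} or \code{"V2"}.
#' @param layer \code{"L23"}, \code{"L4"} or \code{"L5"} (ignored for LGN).
#' @param mc minicolumn id(s) (1-based; for the LGN this is the location id).
#' @param class \code{"pyramidal"}, \code{"basket"}, \code{"rsnp"} or
#'   \code{"relay"}.
#' @return integer vector of cell ids.
#' @export
cell_ids <- function(geom, area, layer = "L23", mc, class = "pyramidal") {
  stopifnot(inherits(geom, "network_geometry"))
  mc <- as.integer(mc)
  if (any(mc < 1L) || any(mc > geom$n_mc)) stop("minicolumn id out of range")
  if (area == "LGN") {
    r <- geom$counts[["relays"]]
    return(as.integer(outer(seq_len(r), (mc - 1L) * r, `+`)))
  }
  P <- geom$counts[["pyramidal"]]; B <- geom$counts[["basket"]]; S <- geom$counts[["rsnp"]]
  base <- geom$area_base[[area]] + (layer_index(layer) - 1L) * geom$per_layer +
    (mc - 1L) * geom$per_mc_layer
  off <- switch(class,
                pyramidal = seq_len(P),
                basket = if (B > 0L) P + seq_len(B) else integer(0),
                rsnp = if (S > 0L) P + B + seq_len(S) else integer(0),
                stop("unknown cell class: ", class))
  if (length(off) == 0L) return(integer(0))
  as.integer(outer(off, base, `+`))
}

#' Full cell metadata table
#'
#' One row per cell: id, area, layer, minicolumn (LGN location for
#' relays), hypercolumn, and cell class, in id order.  Used to annotate
#' spike rasters.
#'
#' @param geom a \code{network_geometry}.
#' @return data.frame with columns id, area, layer, mc, hc, class.
#' @export
cell_table <- function(geom) {
  stopifnot(inherits(geom, "network_geometry"))
  P <- geom$counts[["pyramidal"]]; B <- geom$counts[["basket"]]; S <- geom$counts[["rsnp"]]
  r <- geom$counts[["relays"]]
  lgn <- data.frame(
    id = seq_len(geom$lgn_total),
    area = "LGN", layer = NA_character_,
    mc = rep(seq_len(geom$n_mc), each = r),
    class = "relay", stringsAsFactors = FALSE)
  mk_area <- function(area) {
    cls <- c(rep("pyramidal", P), rep("basket", B), rep("rsnp", S))
    data.frame(
      id = geom$area_base[[area]] + seq_len(geom$per_area),
      area = area,
      layer = rep(c("L23", "L4", "L5"), each = geom$per_layer),
      mc = rep(rep(seq_len(geom$n_mc), each = geom$per_mc_layer), times = 3L),
      class = rep(cls, times = 3L * geom$n_mc),
      stringsAsFactors = FALSE)
  }
  out <- rbind(lgn, mk_area("V1"), mk_area("V2"))
  out$hc <- geom$hc_of_mc[out$mc]
  rownames(out) <- NULL
  out
}

#' Chebyshev distance between hypercolumns on the grid
#'
#' @param geom a \code{network_geometry}.
#' @param a,b hypercolumn ids (vectorized).
#' @return integer distances (max of row and column offsets).
#' @export
hc_distance <- function(geom, a, b) {
  pmax(abs(geom$hc_row[a] - geom$hc_row[b]), abs(geom$hc_col[a] - geom$hc_col[b]))
}
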