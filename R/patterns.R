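#' Attractor memory patterns
#'
#' A stored attractor memory is an ordered set of minicolumns, at most one
#' per hypercolumn, wired together (by \code{\link{wire_longrange}}) with
#' long-range recurrent excitation so that partial stimulation can
#' complete the whole pattern.  Two generators are provided:
#' \code{generate_patterns_random} draws sparse orthogonal patterns
#' (model 1: random linked orientation preferences) and
#' \code{generate_patterns_lines} builds one vertically oriented feature
#' detector per (grid column, minicolumn index) pair (model 2).
#'
#' @name attractor_patterns
NULL

new_pattern_set <- function(patterns, geom, area, kind, meta = NULL) {
  structure(list(
    patterns = patterns,
    area = area,
    kind = kind,
    meta = meta,
    n_mc = geom$n_mc,
    grid = geom$grid,
    mc_per_hc = geom$mc_per_hc
  ), class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  sizes <- lengths(x$patterns)
  cat(sprintf("Pattern set (%s, %s): %d patterns of %s minicolumns\n",
              x$area, x$kind, length(x$patterns),
              if (length(sizes) && length(unique(sizes)) == 1L) sizes[1]
              else paste(range(sizes), collapse = "-")))
  invisible(x)
}

#' @export
length.pattern_set <- function(x) length(x$patterns)

#' Generate sparse orthogonal attractor memories
#'
#' Each pattern is created by randomly choosing one minicolumn from
#' \code{hypercolumns_sampled} of the available hypercolumns, with the
#' restriction that no minicolumn is ever chosen for more than one
#' pattern, keeping the stored memories sparse and orthogonal.
#' Hypercolumns are sampled uniformly among those that still have free
#' minicolumns.  If a draw strands capacity (a later pattern cannot find
#' enough hypercolumns with free minicolumns), the whole set is redrawn,
#' up to \code{max_retries} times, after which a generation error naming
#' the violated constraint is raised.
#'
#' @param geom a \code{\link{build_geometry}} result.
#' @param n_patterns number of stored memories (default 18).
#' @param minicolumns_per_pattern minicolumns per memory (default 10).
#' @param hypercolumns_sampled distinct hypercolumns each memory spans
#'   (default \code{minicolumns_per_pattern}).
#' @param seed integer seed making the draw reproducible.
#' @param area area label attached to the set (\code{"V1"} or \code{"V2"}).
#' @param max_retries whole-set redraws before declaring infeasibility.
#' @return A \code{pattern_set} of disjoint patterns, each using distinct
#'   hypercolumns.
#' @export
generate_patterns_random <- function(geom, n_patterns = 18L,
                                     minicolumns_per_pattern = 10L,
                                     hypercolumns_sampled = minicolumns_per_pattern,
                                     seed = 1L, area = "V1",
                                     max_retries = 1000L) {
  stopifnot(inherits(geom, "network_geometry"))
  n_patterns <- as.integer(n_patterns)
  k <- as.integer(minicolumns_per_pattern)
  h <- as.integer(hypercolumns_sampled)
  if (h < k) stop("generation error: need at least as many hypercolumns as minicolumns per pattern")
  if (h > geom$n_hc) {
    stop(sprintf("generation error: %d hypercolumns requested but the grid has %d", h, geom$n_hc))
  }
  if (n_patterns * k > geom$n_mc) {
    stop(sprintf("generation error: capacity exceeded (%d x %d minicolumns requested, %d available)",
                 n_patterns, k, geom$n_mc))
  }
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      used <- rep(FALSE, geom$n_mc)
      pats <- vector("list", n_patterns)
      ok <- TRUE
      for (p in seq_len(n_patterns)) {
        free_per_hc <- tabulate(geom$hc_of_mc[!used], nbins = geom$n_hc)
        avail_hc <- which(free_per_hc > 0L)
        if (length(avail_hc) < h) { ok <- FALSE; break }
        hcs <- resample(avail_hc, h)
        hcs <- hcs[seq_len(k)]  # one minicolumn from k of the h sampled hypercolumns
        mcs <- vapply(hcs, function(hc) {
          free <- which(!used & geom$hc_of_mc == hc)
          resample(free, 1L)
        }, integer(1))
        used[mcs] <- TRUE
        pats[[p]] <- as.integer(mcs)
      }
      if (ok) {
        return(new_pattern_set(pats, geom, area, "random_orthogonal"))
      }
    }
    stop(sprintf(paste0("generation error: a hypercolumn set with free minicolumns could not be ",
                        "completed after %d whole-set redraws (disjointness constraint)"),
                 max_retries))
  })
}

#' Generate vertical-line feature detectors
#'
#' One pattern per (grid column, minicolumn index) pair: the pattern with
#' index \code{(c, k)} contains the \code{k}-th minicolumn of every
#' hypercolumn in grid column \code{c}.  On the model 2 defaults (9 x 9
#' grid, 8 minicolumns per hypercolumn) this yields 72 patterns of 9
#' minicolumns that exactly partition all minicolumns.  The construction
#' is deterministic (no randomness).
#'
#' @param geom a \code{\link{build_geometry}} result.
#' @param area area label attached to the set.
#' @return A \code{pattern_set} of kind \code{"vertical_line"}; its
#'   \code{meta} data.frame records each pattern's grid column and
#'   minicolumn index.
#' @export
generate_patterns_lines <- function(geom, area = "V1") {
  stopifnot(inherits(geom, "network_geometry"))
  cols <- geom$grid[2]; rows <- geom$grid[1]
  kmax <- geom$mc_per_hc
  pats <- vector("list", cols * kmax)
  meta <- data.frame(pattern = seq_len(cols * kmax),
                     column = rep(seq_len(cols), each = kmax),
                     mc_index = rep(seq_len(kmax), times = cols))
  for (i in seq_len(nrow(meta))) {
    cc <- meta$column[i]; k <- meta$mc_index[i]
    hcs <- which(geom$hc_col == cc)          # one hypercolumn per grid row
    pats[[i]] <- as.integer((hcs - 1L) * kmax + k)
  }
  new_pattern_set(pats, geom, area, "vertical_line", meta = meta)
}

#' Link corresponding attractor memories across V1 and V2
#'
#' Pattern \code{i} in V1 is paired with pattern \code{i} in V2.  Both
#' generators index patterns identically given the same geometry, so for
#' vertical-line sets the linkage preserves grid-column identity.
#'
#' @param v1_patterns,v2_patterns \code{pattern_set}s of equal length.
#' @return A \code{pattern_linkage} data.frame with columns \code{v1},
#'   \code{v2}.
#' @export
link_patterns <- function(v1_patterns, v2_patterns) {
  stopifnot(inherits(v1_patterns, "pattern_set"), inherits(v2_patterns, "pattern_set"))
  n1 <- length(v1_patterns); n2 <- length(v2_patterns)
  if (n1 != n2) stop(sprintf("pattern count mismatch: %d in V1 vs %d in V2", n1, n2))
  structure(data.frame(v1 = seq_len(n1), v2 = seq_len(n1)),
            class = c("pattern_linkage", "data.frame"))
}

#' Validate pattern-set invariants
#'
#' Checks that patterns are pairwise disjoint in minicolumns and that
#' every pattern uses distinct hypercolumns (random kind) or exactly one
#' minicolumn per hypercolumn of one grid column (line kind).
#'
#' @param ps a \code{pattern_set}.
#' @param geom the geometry it was generated from.
#' @return \code{TRUE} invisibly; errors describe any violation.
#' @export
validate_patterns <- function(ps, geom) {
  all_mc <- unlist(ps$patterns)
  if (anyDuplicated(all_mc)) stop("pattern sets must be pairwise disjoint in minicolumns")
  for (p in ps$patterns) {
    hcs <- geom$hc_of_mc[p]
    if (anyDuplicated(hcs)) stop("a pattern uses the same hypercolumn twice")
    if (ps$kind == "vertical_line" &&
        length(unique(geom$hc_col[hcs])) != 1L) {
      stop("a vertical-line pattern spans more than one grid column")
    }
  }
  invisible(TRUE)
}
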