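#' Attractor completion criterion
#'
#' A stored pattern counts as fully activated ("complete") in an area
#' when at least \code{min_minicolumns} of its minicolumns each
#' accumulate at least \code{min_spikes} pyramidal spikes in the analysed
#' layer within the counting window.  The default minicolumn threshold is
#' \code{ceiling(0.7 * n)} for an n-minicolumn pattern: 7 of 10 for the
#' model 1 memories and 7 of 9 for the model 2 lines.
#'
#' @param min_minicolumns absolute minicolumn threshold, or \code{NULL}
#'   to derive it from the pattern size via \code{fraction}.
#' @param fraction fraction of the pattern's minicolumns required
#'   (default 0.7, rounded up).
#' @param min_spikes pyramidal spikes required per minicolumn (default 10).
#' @param layer analysed layer (default \code{"L23"}).
#' @return list of class \code{"completion_criterion"}.
#' @export
completion_criterion <- function(min_minicolumns = NULL, fraction = 0.7,
                                 min_spikes = 10L, layer = "L23") {
  stopifnot(min_spikes > 0, fraction > 0, fraction <= 1)
  structure(list(min_minicolumns = min_minicolumns, fraction = fraction,
                 min_spikes = as.integer(min_spikes), layer = layer),
            class = "completion_criterion")
}

criterion_minicolumns <- function(criterion, n) {
  criterion$min_minicolumns %||% as.integer(ceiling(criterion$fraction * n))
}

#' Detect attractor completion in a spike raster
#'
#' Counts pyramidal spikes of the analysed layer per pattern minicolumn
#' inside the window and applies the completion criterion per area.  The
#' \code{both} scope requires simultaneous completion in V1 and V2 (the
#' proxy for regional activation and hence possible conscious
#' perception).
#'
#' @param raster a \code{spike_raster}.
#' @param pattern list with elements \code{V1} and/or \code{V2}: the
#'   pattern's minicolumn ids in each area.
#' @param criterion a \code{\link{completion_criterion}}.
#' @param window numeric pair (start, end) in ms.
#' @return named logical vector with elements \code{V1}, \code{V2} and
#'   \code{both} (area entries are \code{NA} when that area's pattern is
#'   not supplied).
#' @export
detect_completion <- function(raster, pattern, criterion = completion_criterion(),
                              window = c(0, raster$duration)) {
  stopifnot(inherits(raster, "spike_raster"), is.list(pattern))
  bad <- setdiff(names(pattern), c("V1", "V2"))
  if (length(bad)) stop("pattern/raster area mismatch: unknown area(s) ", paste(bad, collapse = ", "))
  ev <- raster$events
  sel <- ev$layer == criterion$layer & ev$class == "pyramidal" &
    ev$time >= window[1] & ev$time < window[2]
  ev <- ev[which(sel), ]
  out <- c(V1 = NA, V2 = NA)
  for (area in c("V1", "V2")) {
    mcs <- pattern[[area]]
    if (is.null(mcs)) next
    counts <- tabulate(ev$mc[ev$area == area], nbins = max(mcs))
    out[[area]] <- sum(counts[mcs] >= criterion$min_spikes) >=
      criterion_minicolumns(criterion, length(mcs))
  }
  c(out, both = unname(out[["V1"]] & out[["V2"]]))
}

#' Aggregate an experiment into masking curves
#'
#' Computes the completion percentage per (feedback condition, SOA,
#' scope) with exact integer arithmetic (100 * completed / trials), plus
#' the target-only and mask-only control rates.
#'
#' @param results a \code{\link{run_experiment}} data.frame.
#' @return A data.frame of class \code{"masking_curve"} with columns
#'   feedback, condition, soa, scope, n, completed, percent.
#' @export
masking_curve <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  rows <- list()
  for (fb in unique(results$feedback)) {
    sub_fb <- results[results$feedback == fb, ]
    cells <- unique(sub_fb[, c("condition", "soa")])
    for (i in seq_len(nrow(cells))) {
      cond <- cells$condition[i]; soa <- cells$soa[i]
      sub <- sub_fb[sub_fb$condition == cond &
                      (is.na(soa) & is.na(sub_fb$soa) |
                         !is.na(sub_fb$soa) & !is.na(soa) & sub_fb$soa == soa), ]
      for (scope in c("V1", "V2", "both")) {
        col <- c(V1 = "complete_v1", V2 = "complete_v2", both = "complete_both")[[scope]]
        n <- nrow(sub); k <- sum(sub[[col]])
        rows[[length(rows) + 1L]] <- data.frame(
          feedback = fb, condition = cond, soa = soa, scope = scope,
          n = n, completed = k, percent = 100 * k / n)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$feedback, out$condition, out$scope, out$soa), ]
  rownames(out) <- NULL
  class(out) <- c("masking_curve", "data.frame")
  out
}

#' Classify a masking function as type A or type B
#'
#' Operates on the completion percentages of the target+mask condition
#' in ascending SOA order.  Within \code{tolerance} percentage points:
#' a flat curve (range at most the tolerance) is \code{"flat"}; a curve
#' nondecreasing in SOA is \code{"type_A"} (the masking effect fades
#' monotonically); a curve with an interior SOA lower than both the
#' first and last SOA by more than the tolerance is \code{"type_B"} (the
#' U-shaped visibility function of metacontrast masking); anything else
#' is \code{"ambiguous"}.
#'
#' @param percents completion percentages in ascending SOA order (>= 4
#'   points), or a \code{masking_curve} from which the target+mask rows
#'   of one scope are taken.
#' @param tolerance classification tolerance in percentage points;
#'   defaults to one trial's worth for a 25-trial set (4 points).
#' @param scope,feedback used to select rows when a \code{masking_curve}
#'   is supplied.
#' @return one of \code{"type_A"}, \code{"type_B"}, \code{"flat"},
#'   \code{"ambiguous"}.
#' @export
classify_masking_type <- function(percents, tolerance = 4, scope = "both",
                                  feedback = TRUE) {
  if (inherits(percents, "masking_curve")) {
    sub <- percents[percents$condition == "target_mask" &
                      percents$scope == scope & percents$feedback == feedback, ]
    sub <- sub[order(sub$soa), ]
    percents <- sub$percent
  }
  v <- as.numeric(percents)
  if (length(v) < 4L) stop("need at least 4 SOA points to classify")
  eps <- 1e-9 * max(1, tolerance)   # guard exact-tolerance ties against rounding
  if (max(v) - min(v) <= tolerance + eps) return("flat")
  if (all(diff(v) >= -tolerance - eps)) return("type_A")
  interior <- v[-c(1L, length(v))]
  if (any(interior < v[1] - tolerance - eps & interior < v[length(v)] - tolerance - eps)) {
    return("type_B")
  }
  "ambiguous"
}

#' @export
print.masking_curve <- function(x, ...) {
  cat("Masking curves (completion % by SOA)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Plot masking curves
#'
#' Completion percentage against SOA, one panel style per scope, solid
#' lines for feedback-on and dashed for feedback-off.
#'
#' @param x a \code{masking_curve}.
#' @param scopes scopes to draw.
#' @param ... passed to \code{matplot}.
#' @export
plot.masking_curve <- function(x, scopes = c("V1", "V2", "both"), ...) {
  sub <- x[x$condition == "target_mask" & x$scope %in% scopes, ]
  soas <- sort(unique(sub$soa))
  combos <- unique(sub[, c("feedback", "scope")])
  ys <- sapply(seq_len(nrow(combos)), function(i) {
    s <- sub[sub$feedback == combos$feedback[i] & sub$scope == combos$scope[i], ]
    s$percent[match(soas, s$soa)]
  })
  graphics::matplot(soas, ys, type = "b", pch = 19,
                    lty = ifelse(combos$feedback, 1, 2),
                    col = match(combos$scope, scopes),
                    xlab = "SOA (ms)", ylab = "targets completed (%)",
                    ylim = c(0, 100), ...)
  graphics::legend("bottomright",
                   legend = paste0(combos$scope,
                                   ifelse(combos$feedback, " (fb)", " (no fb)")),
                   lty = ifelse(combos$feedback, 1, 2),
                   col = match(combos$scope, scopes), pch = 19, bty = "n")
  invisible(x)
}

#' Write / read experiment results as CSV
#'
#' @param results a \code{masking_experiment} data.frame.
#' @param path file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  res <- utils::read.csv(path, stringsAsFactors = FALSE)
  res$soa <- as.numeric(res$soa)
  class(res) <- c("masking_experiment", "data.frame")
  res
}
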