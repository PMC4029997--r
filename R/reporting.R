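#' Rank-ordering, landscape and profile analytics
#'
#' Post-processing of replica-exchange refinement runs: culling the cold
#' (T_min) ensemble from an occupancy trace, population-density landscapes
#' over (delta-E, f_N), rank-order selection by a scoring function, and the
#' aggregation arithmetic over target x method x scoring-function grids of
#' f_N values as printed in refinement benchmark tables.
#'
#' @name reporting
NULL

#' Load a refinement score table
#'
#' A score table is a grid over (target, sampling method, scoring function)
#' holding the f_N of the top-scoring conformer (\code{top_fn}) and the mean
#' over the top-scoring 16 (\code{mean16_fn}). The packaged fixture
#' \code{system.file("extdata", "refinement_scores.csv", package =
#' "adaptrex")} carries the published benchmark of eight 49-92 residue
#' targets, two sampling methods (adaptive, static) and four scoring
#' functions (FF = force field, GOAP, dDFIRE, RWplus).
#'
#' @param path CSV with columns target, method, fn, top_fn, mean16_fn;
#'   defaults to the packaged fixture.
#' @return a data frame of class \code{score_table}.
#' @export
read_score_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "refinement_scores.csv",
                        package = "adaptrex", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "method", "fn", "top_fn", "mean16_fn")
  if (!all(need %in% names(df))) stop("score table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(df$top_fn < 0 | df$top_fn > 1, na.rm = TRUE))
    stop("f_N values must lie in [0,1]")
  class(df) <- c("score_table", class(df))
  df
}

#' Aggregate a score table over a margin
#'
#' Means of the top-scoring f_N over the selected cells, reported raw and
#' rounded to 2 decimals (the table's printed precision). Selectors:
#' \code{method} and/or \code{fn} restrict the margin; both omitted pools
#' the whole grid.
#'
#' @param table a \code{score_table}.
#' @param method optional sampling method ("adaptive"/"static").
#' @param fn optional scoring-function id ("FF", "GOAP", "dDFIRE", "RWplus").
#' @param value which column to average, \code{"top_fn"} (default) or
#'   \code{"mean16_fn"}.
#' @return list with \code{mean} (raw), \code{rounded} (2 dp), \code{n_cells}.
#' @export
aggregate_score_table <- function(table, method = NULL, fn = NULL,
                                  value = c("top_fn", "mean16_fn")) {
  value <- match.arg(value)
  sel <- rep(TRUE, nrow(table))
  if (!is.null(method)) sel <- sel & table$method == method
  if (!is.null(fn)) sel <- sel & table$fn == fn
  sub <- table[sel, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no cells match the selector")
  # completeness: every (target, method, fn) combination in the margin
  grid <- expand.grid(target = unique(table$target),
                      method = if (is.null(method)) unique(table$method) else method,
                      fn = if (is.null(fn)) unique(table$fn) else fn,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$target, d$method, d$fn)
  missing <- setdiff(key(grid), key(sub))
  if (length(missing) > 0L)
    stop("incomplete table, missing cells: ", paste(missing, collapse = "; "))
  m <- mean(sub[[value]])
  list(mean = m, rounded = round(m, 2L), n_cells = nrow(sub))
}

#' Cull the cold ensemble from an occupancy trace
#'
#' @param trace data frame with columns \code{step}, \code{replica_id},
#'   \code{window_index} (1-based).
#' @param frames steps to extract (default: all recorded steps).
#' @return data frame (step, replica_id) of the replica occupying window 1
#'   at each requested frame.
#' @export
extract_cold_ensemble <- function(trace, frames = NULL) {
  cold <- trace[trace$window_index == 1L, c("step", "replica_id")]
  if (is.null(frames)) frames <- sort(unique(trace$step))
  if (!all(frames %in% cold$step)) stop("trace does not cover requested frames")
  out <- cold[match(frames, cold$step), , drop = FALSE]
  if (anyDuplicated(cold$step)) stop("trace has multiple replicas in window 1")
  rownames(out) <- NULL
  out
}

#' Population-density landscape over (delta-E, f_N)
#'
#' 2D histogram of conformational energy (as a change from the observed
#' minimum) against fraction of native contacts, on a log(count + 1) scale.
#'
#' @param energies,fn_values equal-length numeric vectors.
#' @param bins bins per axis (single value or length-2), >= 2.
#' @return list of class \code{landscape_grid}: \code{log_density} matrix,
#'   \code{counts}, \code{de_breaks}, \code{fn_breaks}.
#' @export
population_density <- function(energies, fn_values, bins = 50L) {
  if (length(energies) == 0L) stop("empty input")
  if (length(energies) != length(fn_values)) stop("length mismatch")
  bins <- rep_len(as.integer(bins), 2L)
  if (any(bins < 2L)) stop("need at least 2 bins per axis")
  de <- energies - min(energies)
  de_breaks <- seq(0, max(de) + 1e-9, length.out = bins[1L] + 1L)
  fn_breaks <- seq(min(fn_values) - 1e-9, max(fn_values) + 1e-9,
                   length.out = bins[2L] + 1L)
  ix <- findInterval(de, de_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(fn_values, fn_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0, bins[1L], bins[2L])
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  structure(list(log_density = log(counts + 1), counts = counts,
                 de_breaks = de_breaks, fn_breaks = fn_breaks),
            class = "landscape_grid")
}

#' Select the top-k conformers by score
#'
#' Lower score = better (energy convention). Ties are broken by conformer id
#' so the selection is stable.
#'
#' @param scores numeric scores per conformer.
#' @param fn_values f_N per conformer.
#' @param k number to select, \code{1 <= k <= length(scores)}.
#' @param ids conformer identifiers (default 1..n).
#' @return list: \code{ids} (selected, best first), \code{mean_fn}.
#' @export
rank_and_select <- function(scores, fn_values, k, ids = seq_along(scores)) {
  n <- length(scores)
  if (length(fn_values) != n || length(ids) != n) stop("length mismatch")
  if (k < 1L || k > n) stop("k must lie in [1, n]")
  o <- order(scores, ids)[seq_len(k)]
  list(ids = ids[o], mean_fn = mean(fn_values[o]))
}

#' Ladder snapshots at requested times
#'
#' @param history list with \code{times} (ascending numeric) and
#'   \code{ladders} (list of \code{temperature_ladder}, one per time).
#' @param times requested times; each must be at or after the first record.
#' @return list of \code{temperature_ladder}: for each requested time, the
#'   ladder recorded at the greatest recorded time <= t.
#' @export
temperature_profile_snapshots <- function(history, times) {
  if (length(history$times) == 0L) stop("empty ladder history")
  if (any(times < history$times[1L]))
    stop("requested time precedes first recorded ladder")
  idx <- findInterval(times, history$times)
  lapply(idx, function(i) history$ladders[[i]])
}

#' Running average over a sliding window
#'
#' Window default 150 frames (the midpoint of the usual 100-200 frame
#' smoothing for refinement time series).
#'
#' @param x numeric series.
#' @param window odd-ish window length in frames.
#' @return centered running mean, same length as x (edges use the available
#'   part of the window).
#' @export
running_average <- function(x, window = 150L) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}
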