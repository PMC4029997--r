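#' Temperature ladders and feedback-driven adaptation
#'
#' A temperature ladder is the ordered set of client temperatures spanning
#' \code{[t_min, t_max]} in a replica-exchange simulation. Static ladders are
#' geometric; adaptive runs periodically re-place the interior temperatures so
#' that the fraction-cold profile becomes linear in client index, which
#' concentrates clients near sharp energetic transitions and maximizes
#' round-trip flow between the temperature extremes.
#'
#' @name ladder
NULL

#' Construct a temperature ladder object
#'
#' @param temps numeric vector of strictly increasing temperatures; the first
#'   and last entries are taken as the ladder bounds.
#' @return an object of class \code{temperature_ladder} with fields
#'   \code{temps}, \code{t_min}, \code{t_max}, \code{n}.
#' @export
temperature_ladder <- function(temps) {
  temps <- as.numeric(temps)
  if (length(temps) < 2L)
    stop("a temperature ladder needs at least 2 temperatures")
  if (any(!is.finite(temps)) || any(temps <= 0))
    stop("temperatures must be finite and positive")
  if (any(diff(temps) <= 0))
    stop("temperatures must be strictly increasing")
  structure(
    list(temps = temps, t_min = temps[1L], t_max = temps[length(temps)],
         n = length(temps)),
    class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("<temperature_ladder> n = %d on [%g, %g]\n", x$n, x$t_min, x$t_max))
  print(x$temps)
  invisible(x)
}

#' Geometrically spaced temperature ladder
#'
#' Temperatures are spaced geometrically in n - 1 intervals from \code{t_min}
#' to \code{t_max}: \code{T_i = t_min * (t_max/t_min)^(i/(n-1))} for
#' \code{i = 0, ..., n-1}. Endpoints are set exactly (no accumulated rounding).
#'
#' @param t_min,t_max ladder bounds, \code{t_max > t_min > 0} (kelvin, or
#'   reduced units when \code{k_B = 1}).
#' @param n number of replica clients, at least 2.
#' @return a \code{temperature_ladder}.
#' @examples
#' geometric_ladder(275, 350, 16)
#' @export
geometric_ladder <- function(t_min, t_max, n) {
  if (!is.numeric(t_min) || !is.numeric(t_max) || t_min <= 0 || t_max <= t_min)
    stop("need t_max > t_min > 0")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("need n >= 2")
  i <- seq_len(n) - 1L
  temps <- t_min * (t_max / t_min)^(i / (n - 1L))
  temps[1L] <- t_min
  temps[n] <- t_max
  temperature_ladder(temps)
}

#' Geometric spacing ratio of a ladder
#'
#' The constant neighbor ratio \code{r = (t_max/t_min)^(1/(n-1))} a geometric
#' ladder with these bounds and size would have. Used as the spacing unit of
#' the adaptation constraint (no neighbor pair may exceed \code{r^2}).
#'
#' @param ladder a \code{temperature_ladder}.
#' @return the spacing ratio, a scalar > 1.
#' @export
spacing_ratio <- function(ladder) {
  stopifnot(inherits(ladder, "temperature_ladder"))
  (ladder$t_max / ladder$t_min)^(1 / (ladder$n - 1L))
}

#' Per-window cold/hot visit histogram
#'
#' Accumulators for the number of cold-labeled and hot-labeled clients seen in
#' each temperature window.
#'
#' @param n_cold,n_hot nonnegative integer vectors of equal length (one entry
#'   per ladder window).
#' @return an object of class \code{visit_histogram}.
#' @export
visit_histogram <- function(n_cold, n_hot) {
  if (length(n_cold) != length(n_hot))
    stop("n_cold and n_hot must have equal length")
  if (any(n_cold < 0) || any(n_hot < 0))
    stop("visit counts must be nonnegative")
  structure(list(n_cold = as.numeric(n_cold), n_hot = as.numeric(n_hot)),
            class = "visit_histogram")
}

#' Fraction-cold profile from a visit histogram
#'
#' For each window, \code{f = n_cold / (n_cold + n_hot)}. Windows with no
#' labeled visits are undefined and returned as \code{NA}; they are excluded
#' from interpolation rather than imputed.
#'
#' @param hist a \code{visit_histogram}.
#' @param temps optional temperatures matching the windows (carried along for
#'   interpolation).
#' @return an object of class \code{fraction_profile} with fields \code{f}
#'   (values in \code{[0,1]} or \code{NA}) and \code{temps} (or \code{NULL}).
#' @export
fraction_cold <- function(hist, temps = NULL) {
  stopifnot(inherits(hist, "visit_histogram"))
  tot <- hist$n_cold + hist$n_hot
  f <- ifelse(tot > 0, hist$n_cold / tot, NA_real_)
  if (!is.null(temps) && length(temps) != length(f))
    stop("temps length must match histogram")
  structure(list(f = f, temps = temps), class = "fraction_profile")
}

#' Target fraction-cold value for a window index
#'
#' The adaptation goal is a fraction-cold profile linear in client index with
#' value 1 at the cold end (window 0) and 0 at the hot end (window n-1):
#' \code{1 - i/(n-1)} with 0-based index \code{i}.
#'
#' @param i 0-based window index, \code{0 <= i <= n-1}. Vectorized.
#' @param n number of windows.
#' @return target fraction(s) in \code{[0,1]}.
#' @export
target_fraction <- function(i, n) {
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2")
  if (any(i < 0L) || any(i > n - 1L)) stop("window index out of range")
  1 - i / (n - 1L)
}

#' Invert an empirical fraction-cold profile
#'
#' Finite-sample profiles need not be monotone, so defined entries are first
#' regressed onto a non-increasing function of temperature (isotonic
#' regression), then the piecewise-linear interpolant through the regressed
#' knots is inverted: the returned temperature is where the regressed profile
#' equals \code{target}. Results are clamped to the profile's temperature
#' range. Flat stretches equal to \code{target} resolve to the mean
#' temperature of the tied knots.
#'
#' @param profile a \code{fraction_profile} with temperatures attached and at
#'   least 2 defined entries.
#' @param target requested fraction in \code{[0,1]}. Vectorized.
#' @return temperature(s) at which the regressed profile equals \code{target}.
#' @export
interpolate_inverse <- function(profile, target) {
  stopifnot(inherits(profile, "fraction_profile"))
  if (is.null(profile$temps)) stop("profile has no temperatures attached")
  if (any(target < 0 | target > 1)) stop("target must lie in [0,1]")
  ok <- !is.na(profile$f)
  if (sum(ok) < 2L)
    stop("insufficient data: need at least 2 defined profile entries")
  tt <- profile$temps[ok]
  ff <- profile$f[ok]
  o <- order(tt)
  tt <- tt[o]; ff <- ff[o]
  # decreasing isotonic fit: isoreg() fits non-decreasing, so fit -f
  fhat <- -stats::isoreg(tt, -ff)$yf
  if (diff(range(fhat)) == 0) {
    # fully flat fit (e.g. an increasing empirical profile): the regressed
    # profile is a constant c, so any target > c maps to the cold end,
    # any target < c to the hot end, and c itself to the middle
    out <- ifelse(abs(target - fhat[1L]) <= 1e-12, mean(range(tt)),
                  ifelse(target > fhat[1L], min(tt), max(tt)))
    return(out)
  }
  # invert the piecewise-linear interpolant; fhat non-increasing in tt
  xr <- rev(fhat); yr <- rev(tt)
  out <- stats::approx(xr, yr, xout = target, ties = mean, rule = 2)$y
  pmin(pmax(out, min(tt)), max(tt))
}

#' Project temperatures onto the geometric spacing constraint
#'
#' Adaptation must not let all windows cluster around one temperature and
#' deplete exchanges at the extremes: no neighboring temperatures may be more
#' than two geometric spacing units apart, \code{temps[i+1]/temps[i] <= r^2}.
#' The projection is a forward sweep lowering any upper neighbor above
#' \code{temps[i] * r^2}, then a backward sweep raising any lower neighbor
#' below \code{temps[i+1] / r^2}, with the endpoints re-clamped to
#' \code{t_min}/\code{t_max}.
#'
#' @param temps sorted ascending temperatures with endpoints at the bounds.
#' @param r geometric spacing unit (ratio > 1).
#' @param t_min,t_max fixed ladder bounds.
#' @return temperatures satisfying the constraint, sorted, endpoints exact.
#' @export
enforce_spacing_constraint <- function(temps, r, t_min, t_max) {
  n <- length(temps)
  if (n < 2L) stop("need at least 2 temperatures")
  if (r <= 1) stop("spacing ratio must exceed 1")
  r2 <- r * r
  # feasibility: the widest allowed ladder must still span [t_min, t_max]
  if (t_max / t_min > r2^(n - 1L) * (1 + 1e-12))
    stop("infeasible constraint: t_max/t_min exceeds r^(2(n-1))")
  temps <- sort(as.numeric(temps))
  temps[1L] <- t_min
  temps[n] <- t_max
  for (i in seq_len(n - 1L))          # forward: lower anything too far above
    temps[i + 1L] <- min(temps[i + 1L], temps[i] * r2)
  temps[n] <- t_max
  for (i in rev(seq_len(n - 1L)))     # backward: raise anything too far below
    temps[i] <- max(temps[i], temps[i + 1L] / r2)
  temps[1L] <- t_min
  temps
}

# resolve runs of (numerically) tied temperatures by respreading each run
# geometrically between its distinct neighbors; endpoints are distinct by
# construction so every run has an anchor on both sides
.make_strictly_increasing <- function(temps, rel_eps = 1e-12) {
  n <- length(temps)
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && temps[j + 1L] <= temps[i] * (1 + rel_eps)) j <- j + 1L
    if (j > i) {
      lo <- if (i == 1L) temps[1L] else temps[i - 1L]
      hi <- if (j == n) temps[n] else temps[j + 1L]
      if (i == 1L && j == n) stop("degenerate ladder: all temperatures tied")
      if (i == 1L) {
        # tied run anchored at t_min: spread upward toward hi
        k <- seq.int(0L, j - i)
        temps[i:j] <- temps[1L] * (hi / temps[1L])^(k / (j - i + 1L))
      } else if (j == n) {
        k <- seq.int(1L, j - i + 1L)
        temps[i:j] <- lo * (temps[n] / lo)^(k / (j - i + 1L))
        temps[n] <- hi
      } else {
        k <- seq.int(1L, j - i + 1L)
        temps[i:j] <- lo * (hi / lo)^(k / (j - i + 2L))
      }
    }
    i <- j + 1L
  }
  temps
}

#' Re-place ladder temperatures from fraction-cold feedback
#'
#' Computes the fraction-cold profile of \code{hist} on the current ladder,
#' inverts it at the index-linear targets \code{target_fraction(i, n)} for the
#' interior windows, pins the endpoints at \code{t_min}/\code{t_max}, and
#' projects the result onto the geometric spacing constraint
#' (\code{\link{enforce_spacing_constraint}} with the ladder's own
#' \code{\link{spacing_ratio}}). Tied interior temperatures (possible when the
#' profile is step-like) are respread geometrically so the result is a valid,
#' strictly increasing ladder.
#'
#' @param ladder current \code{temperature_ladder}.
#' @param hist a \code{visit_histogram} over the ladder's windows; both
#'   endpoint windows must have labeled visits.
#' @return the adapted \code{temperature_ladder}.
#' @export
adapt_temperatures <- function(ladder, hist) {
  stopifnot(inherits(ladder, "temperature_ladder"),
            inherits(hist, "visit_histogram"))
  if (length(hist$n_cold) != ladder$n)
    stop("histogram window count must match ladder")
  prof <- fraction_cold(hist, temps = ladder$temps)
  ok <- !is.na(prof$f)
  if (!ok[1L] || !ok[ladder$n])
    stop("insufficient data: endpoint windows have no labeled visits")
  if (sum(ok) < 2L) stop("insufficient data: need >= 2 defined windows")
  n <- ladder$n
  idx <- seq_len(n) - 1L
  new_temps <- interpolate_inverse(prof, target_fraction(idx, n))
  new_temps[1L] <- ladder$t_min
  new_temps[n] <- ladder$t_max
  r <- spacing_ratio(ladder)
  new_temps <- enforce_spacing_constraint(sort(new_temps), r,
                                          ladder$t_min, ladder$t_max)
  new_temps <- .make_strictly_increasing(new_temps)
  temperature_ladder(new_temps)
}

#' Read/write ladders and histograms as CSV
#'
#' Ladders serialize as \code{index,temperature_K} (0-based index); histograms
#' as \code{index,temperature_K,n_cold,n_hot}.
#'
#' @param ladder a \code{temperature_ladder}.
#' @param hist a \code{visit_histogram}.
#' @param path file path.
#' @name ladder_io
NULL

#' @rdname ladder_io
#' @export
write_ladder_csv <- function(ladder, path) {
  stopifnot(inherits(ladder, "temperature_ladder"))
  df <- data.frame(index = seq_len(ladder$n) - 1L, temperature_K = ladder$temps)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ladder_io
#' @export
read_ladder_csv <- function(path) {
  df <- utils::read.csv(path)
  temperature_ladder(df$temperature_K[order(df$index)])
}

#' @rdname ladder_io
#' @export
write_histogram_csv <- function(hist, ladder, path) {
  df <- data.frame(index = seq_along(hist$n_cold) - 1L,
                   temperature_K = ladder$temps,
                   n_cold = hist$n_cold, n_hot = hist$n_hot)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ladder_io
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$index), ]
  list(hist = visit_histogram(df$n_cold, df$n_hot),
       ladder = temperature_ladder(df$temperature_K))
}
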