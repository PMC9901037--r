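#' Construct a MeltCurve
#'
#' @param temperature degrees C, strictly increasing.
#' @param fluorescence numeric vector or points x replicates matrix,
#'   arbitrary units.
#' @return a \linkS4class{MeltCurve}.
#' @export
MeltCurve <- function(temperature, fluorescence) {
  if (!is.matrix(fluorescence)) fluorescence <- cbind(fluorescence)
  new("MeltCurve", temperature = as.numeric(temperature),
      fluorescence = fluorescence)
}

#' Read a melt curve from a two-column (plus replicates) table
#'
#' @param path TSV/CSV with temperature in column 1 and fluorescence in the
#'   remaining columns (replicates).
#' @param sep field separator; guessed from the extension by default.
#' @return a \linkS4class{MeltCurve}.
#' @export
readMeltCurve <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep)
  MeltCurve(d[[1]], as.matrix(d[, -1, drop = FALSE]))
}

# centered moving average with truncated windows at the edges
.movingAverage <- function(x, w) {
  n <- length(x)
  half <- (w - 1) %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Extract the melting temperature from a denaturation curve
#'
#' Replicates are averaged pointwise, the averaged curve is smoothed by a
#' centered moving average, the first derivative is taken by central
#' differences, and Tm is the temperature of the selected derivative
#' extremum - the minimum of dF/dT by default, matching curves plotted as
#' decreasing fluorescence intensity versus temperature; dye-based melts
#' that peak in +dF/dT can use \code{extremum = "maximum"}. The extremum is
#' refined by parabolic interpolation over its two neighbors.
#'
#' @param curve a \linkS4class{MeltCurve}.
#' @param window smoothing window in points, odd, >= 3 (default 11).
#' @param extremum "minimum" (default) or "maximum" of dF/dT.
#' @return a \linkS4class{MeltResult}; \code{tmAll} lists all interior
#'   local extrema (global first) for multi-transition curves.
#' @export
meltingTemperature <- function(curve, window = 11L,
                               extremum = c("minimum", "maximum")) {
  extremum <- match.arg(extremum)
  stopifnot(is(curve, "MeltCurve"))
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  tt <- curve@temperature
  f <- rowMeans(curve@fluorescence)
  if (diff(range(f)) < 1e-12 * max(abs(f), 1))
    stop("flat curve: no transition")
  fs <- .movingAverage(f, window)
  n <- length(tt)
  # central differences (one-sided at the ends)
  der <- numeric(n)
  der[2:(n - 1)] <- (fs[3:n] - fs[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  der[1] <- (fs[2] - fs[1]) / (tt[2] - tt[1])
  der[n] <- (fs[n] - fs[n - 1]) / (tt[n] - tt[n - 1])
  # differentiation amplifies residual noise; the derivative gets the same
  # window before the extremum is located
  der <- .movingAverage(der, window)
  g <- if (extremum == "minimum") der else -der
  # interior samples are unaffected by edge truncation of the two windows
  interior <- (window + 2):(n - window - 1)
  if (diff(range(g[interior])) < 1e-9 * max(abs(g[interior]), 1e-12))
    stop("derivative is constant: no transition (linear curve)")
  iBest <- which.min(g)
  if (iBest <= window + 1 || iBest >= n - window)
    stop("no interior transition: derivative extremum at grid boundary")
  # all interior local minima of g (multi-transition support)
  interior <- 2:(n - 1)
  isLoc <- interior[g[interior] <= g[interior - 1] &
                      g[interior] <= g[interior + 1]]
  refine <- function(i) {
    y0 <- g[i - 1]; y1 <- g[i]; y2 <- g[i + 1]
    denom <- y0 - 2 * y1 + y2
    off <- if (abs(denom) < 1e-15) 0 else 0.5 * (y0 - y2) / denom
    off <- max(-0.5, min(0.5, off))
    tt[i] + off * (tt[i + 1] - tt[i])
  }
  tmAll <- vapply(isLoc, refine, numeric(1))
  # global extremum refined by the half-depth centroid of its peak: for a
  # symmetric transition the centroid is unbiased and averages residual
  # noise over the whole peak rather than three grid points
  half <- (g[iBest] + stats::median(g)) / 2
  lo <- iBest; while (lo > 1 && g[lo - 1] <= half) lo <- lo - 1
  hi <- iBest; while (hi < n && g[hi + 1] <= half) hi <- hi + 1
  wgt <- pmax(0, half - g[lo:hi])
  tm <- if (sum(wgt) > 0) sum(tt[lo:hi] * wgt) / sum(wgt) else refine(iBest)
  ord <- order(abs(tmAll - tm))           # global first
  new("MeltResult", tm = tm, derivValue = der[iBest],
      window = as.integer(window), extremum = extremum,
      tmAll = tmAll[ord])
}
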