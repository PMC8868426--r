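#' @include io.R
NULL

## trapezoidal integral; x in minutes, returned in x-units
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## Robust noise estimate: upper-sided MAD (x 1.4826) of the residuals.
## Equivalent to the ordinary MAD for symmetric noise, but does not
## collapse when the lower tail is censored by the zero clamp on
## detector counts (saturated-noise regime).
.robustNoise <- function(resid) {
  if (length(resid) < 4L) return(0)
  med <- stats::median(resid)
  upper <- resid[resid >= med] - med
  1.4826 * stats::median(upper)
}

#' Smooth a chromatogram trace
#'
#' Length-preserving smoothing for apex and boundary finding; the raw
#' trace is kept for area integration. `moving_average` shrinks the
#' window symmetrically at the trace ends; `savitzky_golay`
#' (polynomial order 2, via the signal package) falls back to the
#' shrinking moving average within half a window of the ends.
#'
#' @param trace a [ChromatogramTrace-class].
#' @param window odd integer window length >= 3, < trace length.
#' @param method `"moving_average"` (default) or `"savitzky_golay"`.
#' @return a smoothed [ChromatogramTrace-class].
#' @export
smoothTrace <- function(trace, window = 5L,
                        method = c("moving_average",
                                   "savitzky_golay")) {
  method <- match.arg(method)
  n <- length(trace@times)
  if (window %% 2 == 0) stop("'window' must be odd")
  if (window < 3) stop("'window' must be >= 3")
  if (window >= n) stop("'window' must be smaller than the trace length")
  y <- trace@intensities
  sm <- .movingAverage(y, window)
  if (method == "savitzky_golay") {
    sg <- signal::sgolayfilt(y, p = 2, n = window)
    h <- (window - 1L) %/% 2L
    core <- (h + 1L):(n - h)
    sm[core] <- sg[core]
  }
  new("ChromatogramTrace", sampleId = trace@sampleId,
      species = trace@species, times = trace@times,
      intensities = pmax(sm, 0))
}

## centered moving average with window shrinkage at the ends
.movingAverage <- function(y, window) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect and integrate the target peak in a retention-time window
#'
#' Procedure: (1) a linear baseline is interpolated between the
#' peak-free regions flanking `rtWindow` (robust medians anchored at
#' the region mid-times; with drift this reproduces a linear baseline
#' exactly); (2) the apex is the maximum of the smoothed,
#' baseline-subtracted signal inside the window; (3) boundaries walk
#' outward from the apex to the first point that is both at or below
#' `boundaryFrac` of the height and a local minimum, or to the window
#' edge; (4) the area is the trapezoidal integral of the *raw*
#' baseline-subtracted signal between the boundaries (intensity x
#' seconds); (5) noise is the upper-sided MAD spread (x 1.4826) of the
#' baseline-subtracted signal outside the peak (one-sided so that the
#' zero clamp on counts cannot deflate it); (6) the peak is
#' detected iff `snr = height / noise >= minSnr`. On numerically
#' zero-noise traces the S/N is capped at 1e6 with a `zero_noise` QC
#' flag. Undetected traces report zero area/height with a `no_peak`
#' flag.
#'
#' @param trace a [ChromatogramTrace-class].
#' @param rtWindow numeric length-2, (min, max) minutes; must lie
#'   within the trace span.
#' @param minSnr detection threshold on S/N (default 3).
#' @param smoothWindow odd window for the apex-finding smoother.
#' @param boundaryFrac boundary threshold as a fraction of height
#'   (default 0.05).
#' @return a [PeakResult-class].
#' @examples
#' sc <- SimScenario(seed = 5, species = "FA 18:2-OOMxP", noiseSd = 0)
#' tr <- simulateTrace(sc, "FA 18:2-OOMxP")
#' rt <- retentionTimes(sc)[["FA 18:2-OOMxP"]]
#' findPeak(tr, c(rt - 0.3, rt + 0.3))
#' @export
findPeak <- function(trace, rtWindow, minSnr = 3, smoothWindow = 5L,
                     boundaryFrac = 0.05) {
  t <- trace@times
  y <- trace@intensities
  if (length(rtWindow) != 2L || rtWindow[1] >= rtWindow[2])
    stop("'rtWindow' must be (min, max) with min < max")
  if (rtWindow[1] < min(t) || rtWindow[2] > max(t))
    stop("'rtWindow' must lie within the trace time span")
  inWin <- t >= rtWindow[1] & t <= rtWindow[2]
  if (!any(inWin)) stop("'rtWindow' contains no data points")

  ## baseline from the flanking peak-free regions
  leftIdx <- which(t < rtWindow[1])
  rightIdx <- which(t > rtWindow[2])
  baseline <- .interpolateBaseline(t, y, leftIdx, rightIdx, inWin)
  corr <- y - baseline

  smoothed <- .movingAverage(corr, min(smoothWindow,
                                       .largestOddBelow(length(y))))
  winIdx <- which(inWin)
  apexLocal <- which.max(smoothed[winIdx])
  apex <- winIdx[apexLocal]
  height <- smoothed[apex]

  qc <- character()
  if (height <= 0) {
    return(new("PeakResult", apexTime = t[apex], height = 0, area = 0,
               leftBoundary = rtWindow[1], rightBoundary = rtWindow[2],
               noiseSd = .robustNoise(corr[-winIdx]),
               snr = 0, detected = FALSE, qcFlags = "no_peak"))
  }

  thresh <- boundaryFrac * height
  lb <- .walkBoundary(smoothed, apex, winIdx[1], thresh, -1L)
  rb <- .walkBoundary(smoothed, apex, winIdx[length(winIdx)], thresh,
                      +1L)
  if (smoothed[lb] > thresh || smoothed[rb] > thresh)
    qc <- c(qc, "boundary_truncated")

  ## robust noise from outside the integrated peak
  outside <- setdiff(seq_along(t), lb:rb)
  noise <- .robustNoise(corr[outside])

  if (noise <= .Machine$double.eps * max(1, height)) {
    snrVal <- 1e6
    qc <- c(qc, "zero_noise")
  } else {
    snrVal <- height / noise
    if (snrVal > 1e6) {
      snrVal <- 1e6
      qc <- c(qc, "zero_noise")
    }
  }

  detected <- snrVal >= minSnr
  if (!detected) {
    return(new("PeakResult", apexTime = t[apex], height = 0, area = 0,
               leftBoundary = t[lb], rightBoundary = t[rb],
               noiseSd = noise, snr = snrVal, detected = FALSE,
               qcFlags = unique(c(qc, "no_peak"))))
  }
  area <- max(0, .trapz(t[lb:rb] * 60, corr[lb:rb]))
  new("PeakResult", apexTime = t[apex], height = height, area = area,
      leftBoundary = t[lb], rightBoundary = t[rb], noiseSd = noise,
      snr = snrVal, detected = TRUE,
      qcFlags = if (length(qc)) qc else "ok")
}

.largestOddBelow <- function(n) {
  w <- min(5L, n - 1L)
  if (w %% 2L == 0L) w <- w - 1L
  max(w, 1L)
}

## median of a flanking region anchored at its mid-time; empty regions
## fall back to the window-edge values on the other side
.interpolateBaseline <- function(t, y, leftIdx, rightIdx, inWin) {
  anchor <- function(idx) {
    if (length(idx) >= 3L)
      c(stats::median(t[idx]), stats::median(y[idx]))
    else NULL
  }
  la <- anchor(leftIdx)
  ra <- anchor(rightIdx)
  if (is.null(la) && is.null(ra)) return(rep(min(y), length(t)))
  if (is.null(la)) return(rep(ra[2], length(t)))
  if (is.null(ra)) return(rep(la[2], length(t)))
  slope <- (ra[2] - la[2]) / (ra[1] - la[1])
  la[2] + slope * (t - la[1])
}

## walk from the apex towards `limit` (window edge); stop at the first
## index at/below `thresh` that is a local minimum, or at the limit
.walkBoundary <- function(sm, apex, limit, thresh, step) {
  i <- apex
  while (i != limit) {
    nxt <- i + step
    if (sm[i] <= thresh && sm[nxt] >= sm[i]) return(i)
    i <- nxt
  }
  i
}

## ---- PeakResult accessors --------------------------------------------

#' @rdname peak-accessors
#' @export
setMethod("peakArea", "PeakResult", function(x) x@area)

#' @rdname peak-accessors
#' @export
setMethod("peakHeight", "PeakResult", function(x) x@height)

#' @rdname peak-accessors
#' @export
setMethod("apexTime", "PeakResult", function(x) x@apexTime)

#' @rdname peak-accessors
#' @export
setMethod("snr", "PeakResult", function(x) x@snr)

#' @rdname peak-accessors
#' @export
setMethod("noiseSd", "PeakResult", function(x) x@noiseSd)

#' @rdname peak-accessors
#' @export
setMethod("isDetected", "PeakResult", function(x) x@detected)

#' @rdname peak-accessors
#' @export
setMethod("qcFlags", "PeakResult", function(x) x@qcFlags)

setMethod("show", "PeakResult", function(object) {
  cat(sprintf(
    "PeakResult: %s, apex %.3f min, height %.4g, area %.4g, S/N %.3g [%s]\n",
    if (object@detected) "detected" else "not detected",
    object@apexTime, object@height, object@area, object@snr,
    paste(object@qcFlags, collapse = ",")))
})

#' Integrate every trace of a sample set
#'
#' Runs [findPeak()] on each trace in a [SampleSet-class] using a
#' +/- `rtHalfWidth` window around each species' expected retention
#' time and returns a tidy peak table joined with the design metadata.
#'
#' @param set a [SampleSet-class].
#' @param rtMap named numeric of expected retention times (minutes);
#'   defaults to the generating scenario's.
#' @param rtHalfWidth half-width of the integration window (minutes,
#'   default 0.3).
#' @param minSnr detection threshold (default 3).
#' @param smoothWindow smoother window for [findPeak()].
#' @return a data.frame with one row per trace: design columns from
#'   `sampleInfo()` plus `area`, `height`, `snr`, `detected`,
#'   `apex_time`, `qc`.
#' @export
integrateSampleSet <- function(set, rtMap = NULL, rtHalfWidth = 0.3,
                               minSnr = 3, smoothWindow = 5L) {
  stopifnot(is(set, "SampleSet"))
  if (is.null(rtMap)) rtMap <- retentionTimes(set@scenario)
  info <- sampleInfo(set)
  res <- lapply(seq_len(nrow(info)), function(i) {
    sp <- info$species[i]
    tr <- getTrace(set, info$sample_id[i], sp)
    rt <- rtMap[[sp]]
    if (is.null(rt))
      stop(sprintf("no expected retention time for '%s'", sp))
    win <- c(max(min(tr@times), rt - rtHalfWidth),
             min(max(tr@times), rt + rtHalfWidth))
    pk <- findPeak(tr, win, minSnr = minSnr,
                   smoothWindow = smoothWindow)
    data.frame(area = pk@area, height = pk@height, snr = pk@snr,
               detected = pk@detected, apex_time = pk@apexTime,
               qc = paste(pk@qcFlags, collapse = ","))
  })
  cbind(info, do.call(rbind, res))
}
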