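#' Band-stop and band-pass filter specifications
#'
#' Chebyshev Type I IIR designs. The passband ripple parameter (0.4 dB by
#' default) is the defining quantity of this family. Comb elements use
#' narrow 6 Hz stopbands; the SUA band-pass uses 300--3000 Hz at order 2.
#' Band-stop elements default to order 3: odd-order Chebyshev Type I
#' filters have exactly unity far-from-band gain, so a cascade of many
#' narrow notches leaves the rest of the passband untouched (an even-order
#' design sits at -ripple dB far from the notch, which compounds ruinously
#' over a ~170-element comb).
#'
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high`.
#' @param order filter order of the lowpass prototype.
#' @param ripple passband ripple in dB.
#' @return an object of class `"bandstop_spec"` / `"bandpass_spec"`.
#' @export
bandstop_spec <- function(f_low, f_high, order = 3, ripple = 0.4) {
  if (!(is.numeric(f_low) && is.numeric(f_high) && f_low > 0 && f_low < f_high))
    stop("bandstop_spec: need 0 < f_low < f_high")
  structure(list(f_low = f_low, f_high = f_high, order = order, ripple = ripple),
            class = "bandstop_spec")
}

#' @rdname bandstop_spec
#' @export
bandpass_spec <- function(f_low = 300, f_high = 3000, order = 2, ripple = 0.4) {
  if (!(f_low > 0 && f_low < f_high))
    stop("bandpass_spec: need 0 < f_low < f_high")
  structure(list(f_low = f_low, f_high = f_high, order = order, ripple = ripple),
            class = "bandpass_spec")
}

# factor a transfer function given as z^-1 polynomials (b, a) into
# second-order sections: conjugate pole pairs matched with the nearest
# zero pairs, poles closest to the unit circle first. Narrow notches are
# numerically fragile in direct form (the 6th-order polynomials of a 6 Hz
# stopband at 20 kHz nearly cancel), while the biquad cascade is
# well-conditioned.
to_sos <- function(b, a, type = c("stop", "pass")) {
  type <- match.arg(type)
  k <- b[1] / a[1]
  snap_zeros <- function(z) {
    # multiple roots are ill-conditioned for polyroot, but the zeros of
    # these designs are known: a band-stop has one conjugate pair on the
    # unit circle repeated n times; a band-pass has zeros at exactly +-1
    if (type == "pass") return(as.complex(round(Re(z))))
    theta <- mean(abs(Arg(z)))
    complex(modulus = 1, argument = sign(Arg(z)) * theta)
  }
  pair_up <- function(r) {
    r <- r[order(Im(r))]
    cplx <- r[abs(Im(r)) > 1e-8]
    re <- sort(Re(r[abs(Im(r)) <= 1e-8]))
    pairs <- list()
    up <- cplx[Im(cplx) > 0]
    for (z in up) pairs[[length(pairs) + 1L]] <- c(z, Conj(z))
    while (length(re) >= 2) {
      pairs[[length(pairs) + 1L]] <- c(re[1], re[2]); re <- re[-(1:2)]
    }
    if (length(re)) pairs[[length(pairs) + 1L]] <- re[1]
    pairs
  }
  zp <- pair_up(snap_zeros(polyroot(rev(b))))
  pp <- pair_up(polyroot(rev(a)))
  # poles nearest the unit circle first, each matched to the closest zeros
  pp <- pp[order(-vapply(pp, function(p) max(Mod(p)), numeric(1)))]
  poly2 <- function(r) {
    if (length(r) == 2) Re(c(1, -(r[1] + r[2]), r[1] * r[2]))
    else Re(c(1, -r[1], 0))
  }
  sos <- vector("list", length(pp))
  used <- logical(length(zp))
  for (i in seq_along(pp)) {
    d <- vapply(seq_along(zp), function(j)
      if (used[j]) Inf else Mod(zp[[j]][1] - pp[[i]][1]), numeric(1))
    if (length(d) && any(is.finite(d))) {
      j <- which.min(d); used[j] <- TRUE
      bq <- poly2(zp[[j]])
    } else bq <- c(1, 0, 0)
    sos[[i]] <- list(b = bq, a = poly2(pp[[i]]))
  }
  sos[[1]]$b <- sos[[1]]$b * k
  sos
}

design_cheby <- function(spec, sampling_rate, type) {
  nyq <- sampling_rate / 2
  if (spec$f_high >= nyq)
    stop("filter band (", spec$f_low, ", ", spec$f_high,
         ") Hz exceeds the Nyquist frequency ", nyq, " Hz")
  flt <- signal::cheby1(spec$order, spec$ripple,
                        c(spec$f_low, spec$f_high) / nyq, type = type)
  r <- max(Mod(polyroot(rev(flt$a))))
  if (r >= 1)
    stop("unstable filter design for band (", spec$f_low, ", ", spec$f_high, ") Hz")
  structure(list(b = as.numeric(flt$b), a = as.numeric(flt$a),
                 sos = to_sos(as.numeric(flt$b), as.numeric(flt$a), type),
                 spec = spec, sampling_rate = sampling_rate, pole_radius = r),
            class = "iir_filter")
}

#' Design a zero-phase-ready IIR filter from a spec
#'
#' @param spec a [bandstop_spec()] or [bandpass_spec()].
#' @param sampling_rate sampling frequency in Hz.
#' @return an `"iir_filter"`: numerator `b`, denominator `a`, the spec, and
#'   the maximum pole radius (used to size edge padding).
#' @export
design_bandstop <- function(spec, sampling_rate) {
  stopifnot(inherits(spec, "bandstop_spec"))
  design_cheby(spec, sampling_rate, "stop")
}

#' @rdname design_bandstop
#' @export
design_bandpass <- function(spec, sampling_rate) {
  stopifnot(inherits(spec, "bandpass_spec"))
  design_cheby(spec, sampling_rate, "pass")
}

#' Single-pass magnitude response of a designed filter
#'
#' Evaluates `|H(f)|` on an arbitrary frequency grid. Zero-phase
#' (forward-backward) application realizes the squared response
#' `|H(f)|^2`.
#'
#' @param filt an `"iir_filter"` from [design_bandstop()]/[design_bandpass()].
#' @param freqs frequencies in Hz.
#' @return numeric vector of single-pass magnitude gains.
#' @export
freq_response <- function(filt, freqs) {
  vapply(freqs, function(f) {
    z <- exp(-1i * 2 * pi * f / filt$sampling_rate)
    Mod(sum(filt$b * z^(seq_along(filt$b) - 1)) /
        sum(filt$a * z^(seq_along(filt$a) - 1)))
  }, numeric(1))
}

pad_length <- function(filt, n) {
  nc <- max(length(filt$b), length(filt$a))
  min(n - 1, max(3L * (nc - 1L), ceiling(8 / (1 - filt$pole_radius))))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward then backward so that the net phase shift is
#' zero at every frequency and the effective magnitude response is the
#' squared single-pass response. Edge transients are suppressed by
#' extending the signal before filtering; the extension length adapts to
#' the filter's pole radius (narrow notches ring for thousands of samples,
#' so a fixed short pad is not enough).
#'
#' Two extension policies are available. `"reflect"` (default) uses odd
#' reflection about the end points, the standard choice for generic
#' signals. `"periodic"` extends the signal with a copy of itself shifted
#' by a whole number of artifact periods (`period` samples, possibly
#' non-integer; the shift is chosen to minimize the phase error). When the
#' signal is dominated by a huge periodic component lying inside a notch,
#' odd reflection flips its phase at the boundary and the notch rings for
#' hundreds of milliseconds; the periodic extension keeps every harmonic
#' phase-continuous and removes that ringing.
#'
#' @param filt an `"iir_filter"`.
#' @param x numeric signal vector.
#' @param pad `"reflect"` or `"periodic"`.
#' @param period artifact period in samples (required for `pad = "periodic"`).
#' @return filtered signal, same length as `x`.
#' @export
zero_phase_apply <- function(filt, x, pad = c("reflect", "periodic"), period = NULL) {
  pad <- match.arg(pad)
  n <- length(x)
  ord <- max(length(filt$b), length(filt$a)) - 1
  if (n <= 3 * ord)
    stop("signal too short for zero-phase filtering: need length > ", 3 * ord)
  np <- pad_length(filt, n)
  if (pad == "periodic") {
    if (is.null(period) || period <= 0) stop("pad = 'periodic' requires a positive period")
    kmax <- floor((n - 1) / period)
    if (kmax < 1 || round(kmax * period) < np) {
      pad <- "reflect"  # too short to hold a whole period plus padding
    } else {
      ks <- seq_len(kmax)
      ks <- ks[round(ks * period) >= np]
      err <- abs(ks * period - round(ks * period))
      s <- round(ks[which.min(err)] * period)
      xe <- c(x[(1 + s - np):s], x, x[(n - s + 1):(n - s + np)])
    }
  }
  if (pad == "reflect")
    xe <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  one_pass <- function(v) {
    if (is.null(filt$sos)) return(iir_filter_cpp(filt$b, filt$a, v))
    for (s in filt$sos) v <- iir_filter_cpp(s$b, s$a, v)
    v
  }
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  y[(np + 1):(np + n)]
}

#' Band-pass filter a recording into the SUA band
#'
#' Second-order Chebyshev Type I band-pass between 300 and 3000 Hz
#' (passband ripple 0.4 dB), applied zero-phase to every channel. This is
#' the standard first step for highlighting single-unit activity; it does
#' not remove the periodic laser artifact, whose harmonics lie inside the
#' band.
#'
#' @param x a [recording()] or a numeric vector.
#' @param sampling_rate required when `x` is a vector.
#' @param f_low,f_high band edges in Hz.
#' @param order,ripple design parameters, see [bandpass_spec()].
#' @return object of the same type as `x`, filtered.
#' @export
bandpass_sua <- function(x, sampling_rate = NULL, f_low = 300, f_high = 3000,
                         order = 2, ripple = 0.4) {
  if (inherits(x, "recording")) {
    filt <- design_bandpass(bandpass_spec(f_low, f_high, order, ripple),
                            x$sampling_rate)
    out <- x
    for (i in seq_len(nrow(x$samples)))
      out$samples[i, ] <- zero_phase_apply(filt, x$samples[i, ])
    return(out)
  }
  if (is.null(sampling_rate)) stop("sampling_rate is required for vector input")
  filt <- design_bandpass(bandpass_spec(f_low, f_high, order, ripple), sampling_rate)
  zero_phase_apply(filt, x)
}
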