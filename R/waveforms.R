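#' Pulsatile flow waveform specification
#'
#' Describes the volumetric flow waveform carried by one vessel segment over
#' the cardiac cycle. Three template classes cover the waveform morphologies
#' seen in the fetal circulation: a peaked arterial waveform (large systolic
#' lobe over a low diastolic baseline), a biphasic venous waveform (two
#' unequal lobes, the S- and D-waves of central venous return), and a
#' near-constant waveform (umbilical venous return, decoupled from
#' intracardiac pressure swings). Template shapes are parameters, not fixed
#' curves; every generated waveform is renormalized so its cycle mean equals
#' `mean_flow` exactly.
#'
#' @param kind one of `"arterial"`, `"venous_biphasic"`, `"constant"`.
#' @param period cardiac period in ms.
#' @param mean_flow cycle-mean volumetric flow in mL/min (non-negative).
#' @param peak_frac fraction of the cycle occupied by the (first) systolic
#'   lobe, dimensionless in (0, 1).
#' @param peak_to_mean ratio of peak flow to cycle-mean flow (> 1 for the
#'   pulsatile classes).
#' @param second_peak_ratio amplitude of the second (diastolic) lobe relative
#'   to the first, for `"venous_biphasic"` only.
#' @param phase_shift fraction of the cycle by which the waveform is rotated
#'   (used to stagger venous vs arterial timing).
#'
#' @return An object of class `waveform_spec`.
#' @examples
#' w <- waveform_spec("arterial", period = 430, mean_flow = 284 * 2.8)
#' q <- waveform_flux(w, seq(0, 430, length.out = 9)[1:8])
#' mean(q) * 60  # back to ~ mean_flow, mL/min
#' @export
waveform_spec <- function(kind = c("arterial", "venous_biphasic", "constant"),
                          period, mean_flow,
                          peak_frac = NULL, peak_to_mean = NULL,
                          second_peak_ratio = 0.6, phase_shift = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(period) || period <= 0) stopf("period must be > 0 (ms)")
  if (!is.numeric(mean_flow) || mean_flow < 0)
    stopf("mean_flow must be >= 0 (mL/min)")
  peak_frac <- peak_frac %||% switch(kind, arterial = 0.35,
                                     venous_biphasic = 0.3, constant = 0)
  peak_to_mean <- peak_to_mean %||% switch(kind, arterial = 2.8,
                                           venous_biphasic = 1.6, constant = 1)
  if (kind != "constant") {
    if (peak_frac <= 0 || peak_frac >= 1) stopf("peak_frac must be in (0,1)")
    if (peak_to_mean <= 1) stopf("peak_to_mean must exceed 1")
  }
  spec <- structure(list(kind = kind, period = period, mean_flow = mean_flow,
                         peak_frac = peak_frac, peak_to_mean = peak_to_mean,
                         second_peak_ratio = second_peak_ratio,
                         phase_shift = phase_shift, norm = 1),
                    class = "waveform_spec")
  # Renormalize: force the cycle mean of the generated waveform onto
  # mean_flow. The templates have unit analytic mean already; the numerical
  # renormalization guards parameter combinations where the baseline clips.
  if (mean_flow > 0) {
    u <- seq(0, 1, length.out = 4097)[-4097]
    m <- mean(.waveform_shape(spec, u))
    spec$norm <- 1 / m
  }
  spec
}

# Unit-mean template shape evaluated at cycle phase u in [0, 1).
.waveform_shape <- function(spec, u) {
  u <- (u - spec$phase_shift) %% 1
  f <- spec$peak_frac
  p <- spec$peak_to_mean
  lobe <- function(u0, width) {
    inside <- u >= u0 & u < u0 + width
    s <- numeric(length(u))
    s[inside] <- 0.5 * (1 - cos(2 * pi * (u[inside] - u0) / width))
    s
  }
  switch(spec$kind,
    constant = rep(1, length(u)),
    arterial = {
      amp <- (p - 1) / (1 - f / 2)
      base <- 1 - amp * f / 2
      pmax(base, 0) + amp * lobe(0, f)
    },
    venous_biphasic = {
      r <- spec$second_peak_ratio
      amp <- (p - 1) / (1 - f * (1 + r) / 2)
      base <- 1 - amp * f * (1 + r) / 2
      pmax(base, 0) + amp * (lobe(0.05, f) + r * lobe(0.55, f))
    })
}

#' Evaluate a waveform as volumetric flux
#'
#' @param spec a [waveform_spec()].
#' @param t_ms times in ms (wrapped periodically).
#' @return flux in mL/s at each time.
#' @export
waveform_flux <- function(spec, t_ms) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (spec$mean_flow == 0) return(numeric(length(t_ms)))
  u <- (t_ms / spec$period) %% 1
  spec$mean_flow / 60 * spec$norm * .waveform_shape(spec, u)
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf("<waveform_spec> %s: mean %.1f mL/min, period %.0f ms\n",
              x$kind, x$mean_flow, x$period))
  invisible(x)
}
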