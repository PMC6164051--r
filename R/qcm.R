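#' Quartz resonator constants
#'
#' Constants of the Sauerbrey frequency-to-mass conversion for a QCM sensor:
#' nominal resonance frequency `fq` (Hz), equipment constant `C_equip`
#' (cm s^-1), quartz density `rho_q` (g cm^-3) and active electrode area `S`
#' (cm^2). Defaults describe a 6 MHz gold-coated crystal.
#'
#' @param fq nominal frequency, Hz.
#' @param C_equip equipment constant, cm s^-1.
#' @param rho_q quartz density, g cm^-3.
#' @param S active area, cm^2.
#' @return an object of class `quartz_params`.
#' @export
quartz_params <- function(fq = 6e6, C_equip = 1.65e5, rho_q = 2.65, S = 0.5) {
  vals <- c(fq = fq, C_equip = C_equip, rho_q = rho_q, S = S)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all quartz parameters must be finite and > 0")
  structure(as.list(vals), class = "quartz_params")
}

#' Sauerbrey conversion between frequency shift and sorbed mass
#'
#' The Sauerbrey equation relates a small rigid mass load to the resonance
#' frequency shift: \eqn{\Delta f = -f_q^2\, \Delta m / (C \rho_q S)},
#' inverted here as \eqn{m = -\Delta f\, C \rho_q S / f_q^2}. A negative
#' frequency shift therefore corresponds to a positive sorbed mass. The unit
#' chain \eqn{C \rho_q S / f_q^2} is (cm s^-1)(g cm^-3)(cm^2)/Hz^2 = g per
#' Hz; the interface exposes micrograms.
#'
#' @param delta_f frequency shift(s) relative to the loaded dry quartz, Hz.
#' @param q a [quartz_params()].
#' @return sorbed mass, ug (same length as `delta_f`).
#' @examples
#' sauerbrey_mass(-1)  # ~6.073e-3 ug per -1 Hz at default constants
#' @export
sauerbrey_mass <- function(delta_f, q = quartz_params()) {
  stopifnot(inherits(q, "quartz_params"))
  if (any(!is.finite(delta_f))) stop("`delta_f` must be finite")
  -delta_f * q$C_equip * q$rho_q * q$S / q$fq^2 * 1e6
}

#' @rdname sauerbrey_mass
#' @param mass_ug sorbed mass, ug.
#' @return `inverse_sauerbrey`: the frequency shift in Hz producing that mass.
#' @export
inverse_sauerbrey <- function(mass_ug, q = quartz_params()) {
  stopifnot(inherits(q, "quartz_params"))
  if (any(!is.finite(mass_ug))) stop("`mass_ug` must be finite")
  -mass_ug * 1e-6 * q$fq^2 / (q$C_equip * q$rho_q * q$S)
}

#' Deposited sample mass from pristine vs loaded resonance frequencies
#'
#' @param f_pristine resonance frequency of the bare quartz, Hz.
#' @param f_loaded resonance frequency after sample deposition, Hz.
#' @param q a [quartz_params()].
#' @return deposited mass, ug (positive when `f_loaded < f_pristine`).
#' @export
initial_load_mass <- function(f_pristine, f_loaded, q = quartz_params()) {
  sauerbrey_mass(f_loaded - f_pristine, q)
}

#' Frequency trace and relative-humidity step schedule
#'
#' `frequency_trace` holds a QCM time series (time in s, frequency shift in
#' Hz relative to the loaded dry quartz); `rh_schedule` the programmed
#' sequence of constant-RH steps.
#'
#' @param t_s times, s (strictly increasing).
#' @param delta_f_hz frequency shifts, Hz.
#' @return a data.frame of class `frequency_trace` / `rh_schedule`.
#' @export
frequency_trace <- function(t_s, delta_f_hz) {
  if (base::length(t_s) != base::length(delta_f_hz))
    stop("`t_s` and `delta_f_hz` must have equal length")
  if (any(!is.finite(t_s)) || any(!is.finite(delta_f_hz)))
    stop("trace values must be finite")
  if (any(diff(t_s) <= 0)) stop("`t_s` must be strictly increasing")
  structure(data.frame(t_s = t_s, delta_f_hz = delta_f_hz),
            class = c("frequency_trace", "data.frame"))
}

#' @rdname frequency_trace
#' @param start_s,end_s step start/end times, s.
#' @param rh_percent step relative humidities, percent.
#' @param rh_max upper admissible RH, percent (default 80).
#' @export
rh_schedule <- function(start_s, end_s, rh_percent, rh_max = 80) {
  n <- base::length(start_s)
  if (base::length(end_s) != n || base::length(rh_percent) != n)
    stop("schedule columns must have equal length")
  if (any(end_s <= start_s)) stop("each step must have end_s > start_s")
  if (n > 1 && any(start_s[-1] < end_s[-n]))
    stop("steps must be ordered and non-overlapping")
  if (any(rh_percent < 0 | rh_percent > rh_max))
    stop("rh_percent must lie in [0, ", rh_max, "]")
  structure(data.frame(start_s = start_s, end_s = end_s,
                       rh_percent = rh_percent),
            class = c("rh_schedule", "data.frame"))
}

#' Read / write traces and schedules
#'
#' Traces are CSV with columns `t_s`, `delta_f_hz`. Schedules are either CSV
#' with columns `start_s`, `end_s`, `rh_percent`, or YAML with a top-level
#' `steps:` list carrying the same fields.
#'
#' @param path file path.
#' @export
read_trace <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("t_s", "delta_f_hz") %in% names(tab)))
    stop("trace CSV must have columns t_s, delta_f_hz")
  frequency_trace(tab$t_s, tab$delta_f_hz)
}

#' @rdname read_trace
#' @param trace a [frequency_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frequency_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_trace
#' @export
read_schedule <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    steps <- if (!is.null(y$steps)) y$steps else y
    tab <- do.call(rbind, lapply(steps, function(s)
      data.frame(start_s = s$start_s, end_s = s$end_s,
                 rh_percent = s$rh_percent)))
  } else {
    tab <- utils::read.csv(path)
  }
  if (!all(c("start_s", "end_s", "rh_percent") %in% names(tab)))
    stop("schedule must have fields start_s, end_s, rh_percent")
  rh_schedule(tab$start_s, tab$end_s, tab$rh_percent)
}

#' Segment a multi-step trace into per-step sorption curves
#'
#' Cuts the frequency trace along the RH schedule and converts each step
#' window to an incremental sorbed-mass curve: within a step,
#' `mass_ug(t_rel) = sauerbrey_mass(delta_f(t)) - sauerbrey_mass(delta_f at
#' step start)`, so every step starts at `t_rel = 0`, `mass = 0`. Each step
#' is flagged as equilibrated when the relative mass change over the trailing
#' 10% of the window is below 0.1%.
#'
#' @param trace a [frequency_trace()].
#' @param sched an [rh_schedule()] contained in the trace time span.
#' @param q a [quartz_params()].
#' @param min_samples minimum samples per step window (default 5).
#' @return list of `sorption_step` objects: data.frames with columns
#'   `t_rel_s`, `mass_ug` and attributes `rh_percent`, `equilibrium`.
#' @export
segment_steps <- function(trace, sched, q = quartz_params(),
                          min_samples = 5L) {
  stopifnot(inherits(trace, "frequency_trace"), inherits(sched, "rh_schedule"))
  mass <- sauerbrey_mass(trace$delta_f_hz, q)
  out <- vector("list", nrow(sched))
  for (k in seq_len(nrow(sched))) {
    sel <- which(trace$t_s >= sched$start_s[k] & trace$t_s <= sched$end_s[k])
    if (base::length(sel) < min_samples)
      stop("step ", k, " (RH ", sched$rh_percent[k], "%) window contains ",
           base::length(sel), " samples (< ", min_samples, ")")
    m <- mass[sel] - mass[sel[1]]
    t_rel <- trace$t_s[sel] - trace$t_s[sel[1]]
    tail_i <- which(t_rel >= 0.9 * max(t_rel))
    m_end <- m[base::length(m)]
    eq <- if (abs(m_end) > 0)
      max(abs(m[tail_i] - m_end)) < 1e-3 * abs(m_end) else TRUE
    out[[k]] <- structure(data.frame(t_rel_s = t_rel, mass_ug = m),
                          rh_percent = sched$rh_percent[k], equilibrium = eq,
                          class = c("sorption_step", "data.frame"))
  }
  out
}

#' @export
print.sorption_step <- function(x, ...) {
  cat("<sorption_step> RH ", attr(x, "rh_percent"), "%, ", nrow(x),
      " samples over ", format(max(x$t_rel_s)), " s, final mass ",
      format(x$mass_ug[nrow(x)], digits = 4), " ug",
      if (isTRUE(attr(x, "equilibrium"))) " (equilibrated)" else
        " (not equilibrated)", "\n", sep = "")
  invisible(x)
}
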