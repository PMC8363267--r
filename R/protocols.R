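.INPUT_SPECIES <- c("calcium", "cAMP", "Gibg")
.LLTP_ITIS <- c(3, 20, 40, 80, 300)

#' Construct a stimulation protocol
#'
#' A protocol is pure data: a schedule of timed clamp windows during which a
#' free input species (`calcium`, `cAMP`, or `Gibg`) is driven toward a target
#' peak concentration with a fast time constant (tau = 10 ms) and then
#' released to the network's own clearance. Peak concentrations are thereby
#' reproduced independently of clearance parameters.
#'
#' @param injections data frame with columns `species`, `onset_s`,
#'   `duration_s`, `target_nM`.
#' @param series optional data frame `(time_s, species, value_nM)` replayed as
#'   a piecewise-constant forcing (file-based protocols).
#' @param trains optional list describing train structure (kept as metadata).
#' @param id protocol identifier string.
#' @return an object of class `protocol`.
#' @export
protocol <- function(injections = NULL, series = NULL, trains = NULL,
                     id = "protocol") {
  if (is.null(injections))
    injections <- data.frame(species = character(), onset_s = numeric(),
                             duration_s = numeric(), target_nM = numeric(),
                             stringsAsFactors = FALSE)
  injections <- as.data.frame(injections, stringsAsFactors = FALSE)
  if (nrow(injections)) {
    bad <- setdiff(injections$species, .INPUT_SPECIES)
    if (length(bad))
      stop("unknown input species: ", paste(unique(bad), collapse = ", "),
           " (inputs are ", paste(.INPUT_SPECIES, collapse = ", "), ")")
    if (any(injections$target_nM <= 0)) stop("target_peak must be > 0")
    if (any(injections$duration_s < 0)) stop("durations must be >= 0")
    injections <- injections[injections$duration_s > 0, , drop = FALSE]
    injections <- injections[order(injections$onset_s, injections$species), ,
                             drop = FALSE]
    rownames(injections) <- NULL
  }
  if (!is.null(series)) {
    series <- as.data.frame(series, stringsAsFactors = FALSE)
    stopifnot(all(c("time_s", "species", "value_nM") %in% names(series)))
    for (sp in unique(series$species)) {
      tt <- series$time_s[series$species == sp]
      if (any(diff(tt) <= 0))
        stop("non-monotone time points in series for species '", sp, "'")
    }
  }
  structure(list(injections = injections, series = series, trains = trains,
                 id = id, source = if (is.null(series)) "synthetic" else "file"),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol '", x$id, "'> ", nrow(x$injections), " injection(s), source ",
      x$source, "\n", sep = "")
  invisible(x)
}

#' Single-pulse stimulation
#'
#' One clamp window holding the free input at the stated peak for the stated
#' duration (the single-pathway duration/amplitude scans).
#'
#' @param species one of `calcium`, `cAMP`, `Gibg`.
#' @param amplitude_nM peak free concentration in nM (> 0).
#' @param duration_s pulse duration in s; 0 yields an empty protocol.
#' @param onset_s pulse onset (default 0).
#' @return a `protocol`.
#' @export
single_pulse_protocol <- function(species, amplitude_nM, duration_s,
                                  onset_s = 0) {
  if (!species %in% .INPUT_SPECIES)
    stop("unknown input species '", species, "'")
  if (amplitude_nM <= 0) stop("amplitude must be > 0")
  if (duration_s < 0) stop("duration must be >= 0")
  inj <- if (duration_s > 0)
    data.frame(species = species, onset_s = onset_s, duration_s = duration_s,
               target_nM = amplitude_nM, stringsAsFactors = FALSE)
  else NULL
  protocol(inj, id = sprintf("%s_%gnM_%gs", species, amplitude_nM, duration_s))
}

# one 100 Hz train: n pulses of width 1/freq tiling [onset, onset+duration)
.train_pulses <- function(species, onset, target, freq = 100, duration = 1) {
  n <- round(freq * duration)
  data.frame(species = species,
             onset_s = onset + (seq_len(n) - 1) / freq,
             duration_s = 1 / freq, target_nM = target,
             stringsAsFactors = FALSE)
}

#' L-LTP induction protocol: four 100 Hz trains
#'
#' Four 1 s trains of 100 Hz pulses separated by an intertrain interval (ITI)
#' of 3, 20, or 40 s (massed) or 80 or 300 s (spaced). Within a train the
#' 10 ms pulses tile the second contiguously, so the clamp is maintained for
#' the full train (pulses fuse; the inter-pulse gap is below the clearance
#' timescale).
#'
#' @param iti intertrain interval in s; one of 3, 20, 40, 80, 300.
#' @param inputs named numeric vector of per-pulse peak concentrations in nM,
#'   names among `calcium`, `cAMP`, `Gibg`; co-named inputs share the exact
#'   same pulse timing.
#' @param n_trains number of trains (default 4).
#' @param freq intra-train frequency in Hz (default 100).
#' @param train_duration_s train length in s (default 1).
#' @param onset_s onset of the first train.
#' @return a `protocol`.
#' @export
lltp_protocol <- function(iti, inputs, n_trains = 4, freq = 100,
                          train_duration_s = 1, onset_s = 0) {
  if (!iti %in% .LLTP_ITIS)
    stop("invalid ITI ", iti, "; valid values: ",
         paste(.LLTP_ITIS, collapse = ", "))
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    stop("inputs must be a named vector")
  inj <- do.call(rbind, lapply(names(inputs), function(sp) {
    do.call(rbind, lapply(seq_len(n_trains) - 1, function(k) {
      .train_pulses(sp, onset_s + k * (train_duration_s + iti), inputs[[sp]],
                    freq, train_duration_s)
    }))
  }))
  protocol(inj,
           trains = list(frequency = freq, pulses_per_train = round(freq * train_duration_s),
                         n_trains = n_trains, iti = iti),
           id = sprintf("lltp_iti%g", iti))
}

#' The two validation protocols
#'
#' `rasgtp_uncaging`: a single 60 s plateau of 0.5 uM calcium (glutamate
#' uncaging surrogate). `llp_2x100Hz`: two 1 s, 100 Hz trains separated by a
#' 20 s interval, co-injecting 5 uM calcium, 1 uM cAMP and 0.1 uM Gibg.
#'
#' @return a named list of `protocol` objects.
#' @export
validation_protocols <- function() {
  p1 <- single_pulse_protocol("calcium", 500, 60)
  p1$id <- "rasgtp_uncaging"
  gap <- 20
  peaks <- c(calcium = 5000, cAMP = 1000, Gibg = 100)
  inj <- do.call(rbind, lapply(names(peaks), function(sp) {
    rbind(.train_pulses(sp, 0, peaks[[sp]]),
          .train_pulses(sp, 1 + gap, peaks[[sp]]))
  }))
  p2 <- protocol(inj, trains = list(frequency = 100, pulses_per_train = 100,
                                    n_trains = 2, iti = gap),
                 id = "llp_2x100Hz")
  list(rasgtp_uncaging = p1, llp_2x100Hz = p2)
}

#' Load a file-based input time series as a protocol
#'
#' Reads a CSV with columns `time_s`, `species`, `value_nM` (e.g. the
#' ISO-style bath/train inputs) and replays it as a piecewise-constant forcing
#' of the input species.
#'
#' @param file path to the CSV file.
#' @param id protocol identifier (defaults to the file name).
#' @return a `protocol` with `source = "file"`.
#' @export
load_timeseries_protocol <- function(file, id = basename(file)) {
  series <- read.delim(file, sep = ",", stringsAsFactors = FALSE)
  protocol(series = series, id = id)
}

# ---- compilation to clamp segments ----------------------------------------

# merge clamp windows per (species, target): contiguous/overlapping equal-target
# windows fuse into one
.clamp_windows <- function(prot, t_end) {
  win <- NULL
  if (nrow(prot$injections)) {
    inj <- prot$injections
    win <- data.frame(species = inj$species, start = inj$onset_s,
                      end = inj$onset_s + inj$duration_s,
                      target = inj$target_nM, stringsAsFactors = FALSE)
  }
  if (!is.null(prot$series)) {
    ser <- prot$series
    sw <- do.call(rbind, lapply(split(ser, ser$species), function(d) {
      d <- d[order(d$time_s), ]
      data.frame(species = d$species[1], start = d$time_s,
                 end = c(d$time_s[-1], t_end), target = d$value_nM,
                 stringsAsFactors = FALSE)
    }))
    win <- rbind(win, sw)
  }
  if (is.null(win) || !nrow(win)) return(NULL)
  win <- win[win$start < t_end, , drop = FALSE]
  win$end <- pmin(win$end, t_end)
  win <- win[win$end > win$start, , drop = FALSE]
  merged <- list()
  for (sp in unique(win$species)) {
    w <- win[win$species == sp, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    cur <- w[1, ]
    for (i in seq_len(nrow(w))[-1]) {
      if (w$start[i] <= cur$end + 1e-9 && w$target[i] == cur$target) {
        cur$end <- max(cur$end, w$end[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- w[i, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  do.call(rbind, merged)
}

# Segment the timeline at clamp-window edges. Returns breaks and, per input
# species, a source-rate (nM/s) and sink-rate (/s) per segment implementing
# d[x]/dt = (target - x)/tau inside a window.
.protocol_segments <- function(prot, t_end, tau_clamp = 0.01) {
  win <- if (is.null(prot)) NULL else .clamp_windows(prot, t_end)
  if (is.null(win) || !nrow(win))
    return(list(breaks = c(0, t_end), clamp = NULL))
  edges <- sort(unique(c(0, win$start, win$end, t_end)))
  edges <- edges[edges >= 0 & edges <= t_end]
  nseg <- length(edges) - 1
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  clamp <- lapply(split(win, win$species), function(w) {
    src <- numeric(nseg); snk <- numeric(nseg)
    for (i in seq_len(nrow(w))) {
      act <- mids >= w$start[i] & mids < w$end[i]
      src[act] <- w$target[i] / tau_clamp
      snk[act] <- 1 / tau_clamp
    }
    list(source_nM_s = src, sink_per_s = snk)
  })
  list(breaks = edges, clamp = clamp)
}
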