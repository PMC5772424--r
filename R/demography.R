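#' Turn a parameter draw into a piecewise demographic realization
#'
#' Builds the backward-time demography of one scenario: a set of demes, each
#' with a piecewise size trajectory `N(t)` (t in generations before
#' sampling, exponential within segments), merge events for the fragmented
#' models, and a single constant-size ancestral deme of size `N_Anc` beyond
#' the oldest event.  Gradual size changes are exponential: a population of
#' size `N_Cur` at present founded by `N_shrink` individuals `T_shrink`
#' generations ago has `N(t) = N_Cur (N_shrink/N_Cur)^(t/T_shrink)`.
#'
#' Scenario shapes (backward in time):
#' * `ID` — constant `N_Cur`, jumping to `N_Anc` at `T_shrink`.
#' * `ED` — exponential from `N_Cur` (present) to `N_Anc` at `T_shrink`.
#' * `AC`/`RI` — exponential from `N_Cur` back to the founder size
#'   `N_shrink` at `T_shrink`, then `N_Anc`; the two differ only in priors.
#' * `TI` — founder event at `T_shrink` (size `N_shrink` out of an
#'   intermediate population of size `N_Sulu`) preceded by a founder event
#'   at `T_first` (size `N_shrink1` out of `N_Anc`).
#' * `ACS`/`RIS` — as AC/RI but fragmented into 4 equal demes (each
#'   `N(t)/4`, no migration) from `T_split` to the present.
#'
#' @param model_id scenario identifier.
#' @param params single-row data.frame or named list/vector of parameters
#'   (as produced by [draw_params()]).
#' @return an object of class `"demography"`: `segments` (deme, t0, t1, N0,
#'   g with `N(t) = N0 exp(g (t - t0))`), `merges`, `events`, `n_demes`.
#' @export
build_demography <- function(model_id, params) {
  core <- demography_core(model_id, params)
  segments <- as.data.frame(core$segments)
  segments <- segments[order(segments$deme, segments$t0), ]
  rownames(segments) <- NULL
  merges <- as.data.frame(core$merges)
  events <- data.frame(time = core$event_times, type = core$event_types)
  events <- events[order(events$time), ]
  structure(list(model_id = core$model_id, n_demes = core$n_demes,
                 segments = segments, merges = merges, events = events,
                 params = core$params),
            class = "demography")
}

# matrix-based construction shared by build_demography() and the simulation
# hot loops (data.frame overhead matters at 1e5+ simulations)
demography_core <- function(model_id, params) {
  model_id <- match.arg(model_id, MODEL_IDS)
  p <- as.list(params)
  need <- model_required_params(model_id)
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop(sprintf("model %s: missing parameter(s) %s", model_id,
                 paste(missing, collapse = ", ")))
  p <- lapply(p, as.numeric)
  sizes <- unlist(p[startsWith(names(p), "N_")])
  if (any(sizes < 1)) stop("population sizes must be >= 1")
  times <- unlist(p[startsWith(names(p), "T_")])
  if (any(times <= 0)) stop("event times must be > 0")
  grate <- function(t0, t1, N0, Nend)
    if (is.finite(t1) && t1 > t0 && Nend != N0) log(Nend / N0) / (t1 - t0)
    else 0
  no_merge <- matrix(numeric(0), 0L, 3L,
                     dimnames = list(NULL, c("time", "from", "to")))
  merges <- no_merge
  n_demes <- 1L
  cn <- c("deme", "t0", "t1", "N0", "g")
  if (model_id == "ID") {
    segments <- rbind(c(0, 0, p$T_shrink, p$N_Cur, 0),
                      c(0, p$T_shrink, Inf, p$N_Anc, 0))
    ev_t <- p$T_shrink; ev_k <- "size_change"
  } else if (model_id == "ED") {
    segments <- rbind(
      c(0, 0, p$T_shrink, p$N_Cur, grate(0, p$T_shrink, p$N_Cur, p$N_Anc)),
      c(0, p$T_shrink, Inf, p$N_Anc, 0))
    ev_t <- p$T_shrink; ev_k <- "growth_offset"
  } else if (model_id %in% c("AC", "RI")) {
    segments <- rbind(
      c(0, 0, p$T_shrink, p$N_Cur,
        grate(0, p$T_shrink, p$N_Cur, p$N_shrink)),
      c(0, p$T_shrink, Inf, p$N_Anc, 0))
    ev_t <- p$T_shrink; ev_k <- "founder"
  } else if (model_id == "TI") {
    if (p$T_first <= p$T_shrink) stop("TI requires T_first > T_shrink")
    segments <- rbind(
      c(0, 0, p$T_shrink, p$N_Cur,
        grate(0, p$T_shrink, p$N_Cur, p$N_shrink)),
      c(0, p$T_shrink, p$T_first, p$N_Sulu,
        grate(p$T_shrink, p$T_first, p$N_Sulu, p$N_shrink1)),
      c(0, p$T_first, Inf, p$N_Anc, 0))
    ev_t <- c(p$T_shrink, p$T_first); ev_k <- c("founder", "founder")
  } else { # ACS / RIS
    if (p$T_split <= 0 || p$T_split > p$T_shrink)
      stop(sprintf("%s requires 0 < T_split <= T_shrink", model_id))
    n_demes <- 4L
    g <- grate(0, p$T_shrink, p$N_Cur, p$N_shrink)
    N_at_split <- p$N_Cur * exp(g * p$T_split)
    segments <- rbind(
      cbind(0:3, 0, p$T_split, p$N_Cur / 4, g),
      c(0, p$T_split, p$T_shrink, N_at_split, g),
      c(0, p$T_shrink, Inf, p$N_Anc, 0))
    merges <- cbind(time = rep(p$T_split, 3), from = 1:3, to = 0)
    colnames(merges) <- c("time", "from", "to")
    ev_t <- c(p$T_split, p$T_shrink); ev_k <- c("split", "founder")
  }
  colnames(segments) <- cn
  list(model_id = model_id, n_demes = n_demes, segments = segments,
       merges = merges, event_times = ev_t, event_types = ev_k, params = p)
}

#' Evaluate a deme's size trajectory
#'
#' @param demog a [build_demography()] result.
#' @param t times in generations before sampling (vectorized).
#' @param deme 1-based deme index.
#' @return effective diploid size `N(t)` for each `t`.
#' @export
deme_size <- function(demog, t, deme = 1L) {
  s <- demog$segments[demog$segments$deme == deme - 1L, ]
  vapply(t, function(ti) {
    row <- which(s$t0 <= ti & ti < s$t1)
    if (!length(row)) return(NA_real_)
    row <- row[length(row)]
    s$N0[row] * exp(s$g[row] * (ti - s$t0[row]))
  }, numeric(1))
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("demography: model %s, %d present-day deme(s), %d event(s)\n",
              x$model_id, x$n_demes, nrow(x$events)))
  print(x$segments)
  invisible(x)
}
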