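#' Prior specification for a demographic parameter
#'
#' Priors are uniform or log10-uniform.  For `"loguniform"` the bounds are
#' base-10 exponents (so `prior_spec("loguniform", 4, 5)` spans 1e4--1e5
#' effective individuals), matching the way size and rate priors are usually
#' tabulated.  An optional `scale_by` names another parameter whose drawn
#' value multiplies the draw; this expresses relative priors such as a
#' fragmentation time uniform on (0, T_shrink].
#'
#' @param kind `"uniform"` or `"loguniform"`.
#' @param min,max lower and upper bound (exponents for `"loguniform"`).
#'   `min == max` gives a degenerate point prior.
#' @param scale_by optional name of another parameter used as a multiplier.
#' @return an object of class `"prior_spec"`.
#' @export
prior_spec <- function(kind = c("uniform", "loguniform"), min, max,
                       scale_by = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(min) || !is.numeric(max) || length(min) != 1L ||
      length(max) != 1L || is.na(min) || is.na(max))
    stop("prior bounds must be single finite numbers")
  if (min > max)
    stop(sprintf("inverted prior bounds: min (%g) > max (%g)", min, max))
  structure(list(kind = kind, min = min, max = max, scale_by = scale_by),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("%s [%g, %g]%s\n", x$kind, x$min, x$max,
              if (is.null(x$scale_by)) "" else paste0(" x ", x$scale_by)))
  invisible(x)
}

# draw n values from a prior on its natural scale (before scale_by)
draw_prior <- function(spec, n = 1L) {
  u <- stats::runif(n, spec$min, spec$max)
  if (spec$kind == "loguniform") 10^u else u
}

MODEL_IDS <- c("ID", "ED", "AC", "RI", "TI", "ACS", "RIS")

# parameters each demography builder requires
model_required_params <- function(model_id) {
  switch(model_id,
    ID  = c("N_Anc", "N_Cur", "T_shrink"),
    ED  = c("N_Anc", "N_Cur", "T_shrink"),
    AC  = c("N_Anc", "N_Cur", "T_shrink", "N_shrink"),
    RI  = c("N_Anc", "N_Cur", "T_shrink", "N_shrink"),
    TI  = c("N_Anc", "N_Sulu", "N_Cur", "T_shrink", "N_shrink", "T_first",
            "N_shrink1"),
    ACS = c("N_Anc", "N_Cur", "T_shrink", "N_shrink", "T_split"),
    RIS = c("N_Anc", "N_Cur", "T_shrink", "N_shrink", "T_split"),
    stop(sprintf("unknown model id '%s'", model_id)))
}

#' Demographic model specification
#'
#' Bundles a model identifier with the prior for every parameter the model's
#' demography builder needs, plus the mutation-model priors (`mu`, `p_gsm`)
#' shared by all models.  The seven built-in scenarios are: instantaneous
#' decline (ID), exponential decline (ED), ancient colonization with a
#' founder event (AC), recent introduction (RI), two successive introductions
#' (TI), and the fragmented variants ACS and RIS in which the present-day
#' population is split into four demes since `T_split`.
#'
#' @param model_id one of `"ID" "ED" "AC" "RI" "TI" "ACS" "RIS"`.
#' @param priors named list of [prior_spec()] objects.
#' @param n_demes number of present-day demes (1, or 4 for ACS/RIS).
#' @param generation_time_years used only to convert times for reporting.
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(model_id, priors, n_demes = if (model_id %in%
                         c("ACS", "RIS")) 4L else 1L,
                       generation_time_years = 15) {
  model_id <- match.arg(model_id, MODEL_IDS)
  stopifnot(generation_time_years > 0)
  need <- c(model_required_params(model_id), "mu", "p_gsm")
  missing <- setdiff(need, names(priors))
  if (length(missing))
    stop(sprintf("model %s: missing PriorSpec for parameter(s) %s", model_id,
                 paste(missing, collapse = ", ")))
  for (nm in names(priors))
    if (!inherits(priors[[nm]], "prior_spec"))
      stop(sprintf("prior for '%s' is not a prior_spec", nm))
  structure(list(model_id = model_id, priors = priors,
                 n_demes = as.integer(n_demes),
                 generation_time_years = generation_time_years),
            class = "model_spec")
}

#' Read model/prior configuration from a YAML file
#'
#' One document listing `generation_time_years` and a `models:` map of
#' model id to `parameter: {kind, min, max[, scale_by]}` entries.  The file
#' shipped at `system.file("extdata", "models.yaml", package = "demabc")`
#' holds the package defaults.
#'
#' @param path YAML file path.
#' @return named list of [model_spec()] objects.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gt <- if (is.null(cfg$generation_time_years)) 15 else cfg$generation_time_years
  out <- lapply(names(cfg$models), function(id) {
    m <- cfg$models[[id]]
    priors <- lapply(m$priors, function(p)
      prior_spec(p$kind, p$min, p$max, scale_by = p$scale_by))
    names(priors) <- names(m$priors)
    model_spec(id, priors,
               n_demes = if (is.null(m$demes)) {
                 if (id %in% c("ACS", "RIS")) 4L else 1L
               } else as.integer(m$demes),
               generation_time_years = gt)
  })
  names(out) <- names(cfg$models)
  out
}

#' Built-in model specifications
#'
#' The default prior set for the seven scenarios.  AC/RI/ACS/RIS priors are
#' the published ones (sizes log10-uniform, times and founder counts
#' uniform); the ID, ED and TI priors and the ACS/RIS fragmentation time are
#' package defaults documented in the methods vignette.  The mean
#' microsatellite mutation rate prior is log-uniform on 1e-5--1e-3 per locus
#' per generation, shared by every model.
#'
#' @param models optional subset of model ids.
#' @return named list of [model_spec()] objects.
#' @export
default_model_specs <- function(models = MODEL_IDS) {
  path <- system.file("extdata", "models.yaml", package = "demabc")
  specs <- read_model_config(path)
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  specs[models]
}

#' Draw parameters from a model's priors
#'
#' Draws every parameter independently from its prior; `scale_by` priors are
#' multiplied by the referenced parameter's draw.  Structural constraints
#' (for TI, `T_first > T_shrink`) are enforced by resampling the offending
#' parameter.
#'
#' @param spec a [model_spec()].
#' @param n number of draws.
#' @return a data.frame with one row per draw and one column per parameter.
#' @export
draw_params <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  pr <- spec$priors
  # draw base parameters first, then scaled ones
  base <- names(pr)[vapply(pr, function(p) is.null(p$scale_by), logical(1))]
  scaled <- setdiff(names(pr), base)
  out <- as.data.frame(lapply(pr[base], draw_prior, n = n))
  for (nm in scaled) {
    ref <- pr[[nm]]$scale_by
    if (!ref %in% names(out))
      stop(sprintf("prior for '%s' scales by unknown parameter '%s'", nm, ref))
    out[[nm]] <- draw_prior(pr[[nm]], n) * out[[ref]]
  }
  if (spec$model_id == "TI") {
    if (pr$T_first$max <= pr$T_shrink$min)
      stop("cannot satisfy T_first > T_shrink under these priors")
    bad <- which(out$T_first <= out$T_shrink)
    if (length(bad) && pr$T_first$kind == "uniform") {
      # resampling T_first | T_first > T_shrink is a truncated uniform
      lo <- pmax(pr$T_first$min, out$T_shrink[bad])
      out$T_first[bad] <- stats::runif(length(bad), lo, pr$T_first$max)
    } else {
      guard <- 0L
      while (length(bad)) {
        out$T_first[bad] <- draw_prior(pr$T_first, length(bad))
        bad <- bad[out$T_first[bad] <= out$T_shrink[bad]]
        guard <- guard + 1L
        if (guard > 10000L)
          stop("cannot satisfy T_first > T_shrink under these priors")
      }
    }
  }
  out[names(pr)]
}
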