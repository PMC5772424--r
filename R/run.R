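#' Run configuration for a full ABC analysis
#'
#' Collects everything a run needs so that any result is reconstructible
#' from its configuration and seed alone.  Seeds must be explicit; times
#' are reported in generations with a years conversion through
#' `generation_time_years`.
#'
#' @param specs named list of [model_spec()] objects.
#' @param shape a [dataset_shape()].
#' @param n_sims_per_model reference-table rows per model.
#' @param tolerances retained fractions for model choice / estimation.
#' @param seed integer seed.
#' @param generation_time_years years per generation (reporting only).
#' @param out_dir output directory for artifacts.
#' @return an object of class `"run_config"` with a stable `hash`.
#' @export
run_config <- function(specs, shape = dataset_shape(),
                       n_sims_per_model = 10000L,
                       tolerances = c(0.001, 0.01), seed,
                       generation_time_years = 15, out_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  stopifnot(all(tolerances > 0), all(tolerances <= 1),
            n_sims_per_model >= 1L)
  cfg <- list(specs = specs, shape = shape,
              n_sims_per_model = as.integer(n_sims_per_model),
              tolerances = tolerances, seed = as.integer(seed),
              generation_time_years = generation_time_years,
              out_dir = out_dir)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

config_hash <- function(x) {
  x$hash <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}

#' Model-choice report
#'
#' Runs rejection and multinomial-logistic model choice at each tolerance
#' and lays the result out as a posterior-probability table with Bayes
#' factors of the best-supported model against each other model.
#'
#' @param table a `"reference_table"`.
#' @param observed named statistic vector (same layout as the table).
#' @param tolerances retained fractions.
#' @return data.frame with columns `method`, `tolerance`, one probability
#'   column per model, and the matching Bayes factors (`bf_*`).
#' @export
run_model_choice <- function(table, observed, tolerances = c(0.001, 0.01)) {
  rows <- list()
  for (tol in tolerances) {
    retained <- abc_reject(table, observed, tol)
    for (method in c("rejection", "regression")) {
      p <- if (method == "rejection") model_posterior_rejection(retained)
           else model_posterior_logistic(table, observed, tol)
      best <- which.max(p)
      bf <- p[best] / p
      row <- data.frame(method = method, tolerance = tol, t(p),
                        check.names = FALSE)
      names(bf) <- paste0("bf_", names(p))
      rows[[length(rows) + 1L]] <- cbind(row, t(bf))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter-estimation report
#'
#' Rejection + local-linear adjustment for one model, summarised like a
#' posterior table: 5% quantile, mean, median, mode and 95% HPD bounds per
#' parameter (linear scale), with times also converted to years.
#'
#' @param table a `"reference_table"`.
#' @param observed named statistic vector.
#' @param spec the [model_spec()] to estimate under.
#' @param tolerance retained fraction.
#' @return data.frame of summaries; attribute `"posterior"` carries the
#'   full [loclinear_adjust()] object.
#' @export
run_parameter_estimation <- function(table, observed, spec,
                                     tolerance = 0.01) {
  retained <- abc_reject(table, observed, tolerance)
  post <- loclinear_adjust(retained, spec)
  sm <- posterior_summaries(post)
  gt <- spec$generation_time_years
  time_rows <- grepl("^T_", sm$parameter)
  sm$mean_years <- ifelse(time_rows, sm$mean * gt, NA_real_)
  sm$median_years <- ifelse(time_rows, sm$median * gt, NA_real_)
  attr(sm, "posterior") <- post
  sm
}

#' Write a delimited report with a provenance header
#'
#' Every artifact embeds the configuration hash and seed so a run is
#' reconstructible from its outputs.
#'
#' @param x data.frame.
#' @param path output path.
#' @param config optional [run_config()] whose hash/seed to embed.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, config = NULL) {
  header <- c(sprintf("# demabc %s", as.character(utils::packageVersion("demabc"))),
              sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (!is.null(config))
    header <- c(header, sprintf("# config_hash: %s", config$hash),
                sprintf("# seed: %d", config$seed))
  writeLines(header, path)
  suppressWarnings(utils::write.table(x, path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(path)
}
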