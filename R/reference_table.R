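#' Build an ABC reference table by coalescent simulation
#'
#' For every model: draw parameters from the priors, simulate a full
#' microsatellite dataset, and record the summary-statistic panel.  The
#' result is the substrate for model choice, parameter estimation and
#' cross-validation.  Simulation proceeds in chunks; with `path` set each
#' chunk is appended to a delimited text file as it is produced, so memory
#' use is constant in the number of rows.
#'
#' @param specs named list of [model_spec()] objects.
#' @param n_per_model simulations per model (scalar or per-model vector).
#' @param sample a [sample_config()] describing the pseudo-observed shape.
#' @param seed integer seed (required: the table must be reproducible).
#' @param path optional TSV output path (streamed, constant memory).
#' @param chunk_size simulations per chunk.
#' @param progress print a line per chunk.
#' @return an object of class `"reference_table"`: `model` (factor),
#'   `params` (data.frame, `NA` for parameters a model lacks), `stats`
#'   (matrix), `seed`, `n_per_model`.  With `path`, the table is also on
#'   disk (readable with [read_reference_table()]) and returned invisibly.
#' @export
build_reference_table <- function(specs, n_per_model, sample, seed,
                                  path = NULL, chunk_size = 1000L,
                                  progress = FALSE) {
  stopifnot(is.list(specs), length(specs) >= 1L,
            inherits(sample, "sample_config"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (length(n_per_model) == 1L)
    n_per_model <- rep(n_per_model, length(specs))
  stopifnot(length(n_per_model) == length(specs))
  set.seed(seed)
  param_names <- unique(unlist(lapply(specs, function(s) names(s$priors))))
  model_ids <- vapply(specs, function(s) s$model_id, character(1))
  stream <- !is.null(path)
  if (stream && file.exists(path)) file.remove(path)
  first_chunk <- TRUE
  stat_names <- NULL
  acc <- list()
  for (mi in seq_along(specs)) {
    spec <- specs[[mi]]
    n <- n_per_model[mi]
    done <- 0L
    while (done < n) {
      nc <- min(chunk_size, n - done)
      draws <- draw_params(spec, nc)
      dm <- as.matrix(draws) # row extraction from a matrix is much cheaper
      stats_chunk <- NULL
      for (i in seq_len(nc)) {
        s <- sim_panel_stats(spec$model_id, as.list(dm[i, ]), sample)
        if (is.null(stats_chunk))
          stats_chunk <- matrix(NA_real_, nc, length(s),
                                dimnames = list(NULL, names(s)))
        stats_chunk[i, ] <- s
      }
      if (is.null(stat_names)) stat_names <- colnames(stats_chunk)
      params_chunk <- as.data.frame(
        stats::setNames(rep(list(rep(NA_real_, nc)), length(param_names)),
                        param_names))
      params_chunk[names(draws)] <- draws
      chunk <- data.frame(model = spec$model_id, params_chunk,
                          stats_chunk, check.names = FALSE)
      if (stream) {
        if (first_chunk) {
          header <- c("# demabc reference table",
                      sprintf("# seed: %d", seed),
                      sprintf("# models: %s", paste(model_ids, collapse = ",")),
                      sprintf("# n_per_model: %s",
                              paste(n_per_model, collapse = ",")),
                      sprintf("# param_cols: %s",
                              paste(param_names, collapse = ",")),
                      sprintf("# stat_cols: %s",
                              paste(stat_names, collapse = ",")))
          writeLines(header, path)
          suppressWarnings(utils::write.table(chunk, path, sep = "\t",
                                              row.names = FALSE,
                                              col.names = TRUE,
                                              append = TRUE, quote = FALSE))
        } else {
          utils::write.table(chunk, path, sep = "\t", row.names = FALSE,
                             col.names = FALSE, append = TRUE, quote = FALSE)
        }
      } else {
        acc[[length(acc) + 1L]] <- chunk
      }
      first_chunk <- FALSE
      done <- done + nc
      if (progress)
        message(sprintf("model %s: %d / %d", spec$model_id, done, n))
    }
  }
  if (stream) {
    out <- read_reference_table(path)
    return(invisible(out))
  }
  all <- do.call(rbind, acc)
  reference_table(model = factor(all$model, levels = model_ids),
                  params = all[param_names],
                  stats = as.matrix(all[stat_names]),
                  seed = seed, n_per_model = n_per_model)
}

#' Reference-table constructor
#'
#' @param model factor of model labels (one per row).
#' @param params data.frame of drawn parameters.
#' @param stats numeric matrix of summary statistics.
#' @param seed,n_per_model provenance metadata.
#' @return an object of class `"reference_table"`.
#' @export
reference_table <- function(model, params, stats, seed = NA_integer_,
                            n_per_model = NA_integer_) {
  stats <- as.matrix(stats)
  stopifnot(length(model) == nrow(stats), nrow(params) == nrow(stats))
  if (any(table(model) < 1L))
    warning("some declared models have no reference rows")
  structure(list(model = as.factor(model), params = params, stats = stats,
                 seed = seed, n_per_model = n_per_model),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("reference_table: %d rows, %d statistic(s), seed %s\n",
              nrow(x$stats), ncol(x$stats), x$seed))
  print(table(x$model))
  invisible(x)
}

#' Read a streamed reference table
#'
#' @param path TSV written by [build_reference_table()].
#' @return a `"reference_table"`.
#' @export
read_reference_table <- function(path) {
  header <- readLines(path, n = 20L)
  header <- header[startsWith(header, "#")]
  get_field <- function(key) {
    line <- grep(sprintf("^# %s:", key), header, value = TRUE)
    if (!length(line)) return(NULL)
    strsplit(sub(sprintf("^# %s: *", key), "", line[1]), ",")[[1]]
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  param_cols <- get_field("param_cols")
  stat_cols <- get_field("stat_cols")
  models <- get_field("models")
  seed <- suppressWarnings(as.integer(get_field("seed")))
  reference_table(model = factor(tab$model, levels = models),
                  params = tab[param_cols],
                  stats = as.matrix(tab[stat_cols]),
                  seed = if (length(seed)) seed else NA_integer_,
                  n_per_model = suppressWarnings(
                    as.integer(get_field("n_per_model"))))
}

#' Subset a reference table by row index
#' @param table a `"reference_table"`.
#' @param rows integer index of rows to keep.
#' @return a `"reference_table"`.
#' @export
subset_reference_table <- function(table, rows) {
  reference_table(model = table$model[rows],
                  params = table$params[rows, , drop = FALSE],
                  stats = table$stats[rows, , drop = FALSE],
                  seed = table$seed, n_per_model = NA_integer_)
}
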