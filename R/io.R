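.read_table_checked <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          colClasses = NA, comment.char = "",
                          quote = "\"")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  df
}

.numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.character(x)) {
    xn <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(xn) & !is.na(x))
    if (length(bad))
      stop(sprintf("%s: non-numeric value '%s' in column '%s' at data row %d",
                   path, x[bad[1L]], col, bad[1L]))
    x <- xn
  }
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("%s: missing/non-finite value in column '%s' at data row %d",
                 path, col, bad[1L]))
  x
}

#' Read a long-format table of concentration curves
#'
#' Parses a delimited text table (TSV, or CSV by extension) with header
#' columns `subject`, `region`, `time_min`, `conc_mM` — optional `stage`
#' and `roi` columns are carried along — into a list of per-(subject,
#' region) curves. Rows are sorted by time within each curve; duplicated
#' or non-finite times and non-numeric cells are parse errors reporting
#' the offending row.
#'
#' @param path Path to the table.
#' @return A list of records, each a list with `subject`, `region`,
#'   `stage` (NA if absent), `roi` (NA if absent) and `curve`
#'   (a [concentration_curve]).
#' @export
read_curves <- function(path) {
  df <- .read_table_checked(path, c("subject", "region", "time_min",
                                    "conc_mM"))
  df$time_min <- .numeric_col(df, "time_min", path)
  df$conc_mM <- .numeric_col(df, "conc_mM", path)
  if (!"stage" %in% names(df)) df$stage <- NA_character_
  if (!"roi" %in% names(df)) df$roi <- NA_character_
  key <- interaction(df$subject, df$region, drop = TRUE, sep = "\r")
  lapply(split(seq_len(nrow(df)), key), function(i) {
    i <- i[order(df$time_min[i])]
    tms <- df$time_min[i]
    if (anyDuplicated(tms))
      stop(sprintf(
        "%s: duplicated time %g min in curve (subject '%s', region '%s')",
        path, tms[which(duplicated(tms))[1L]],
        df$subject[i[1L]], df$region[i[1L]]))
    list(subject = as.character(df$subject[i[1L]]),
         region = as.character(df$region[i[1L]]),
         stage = as.character(df$stage[i[1L]]),
         roi = as.character(df$roi[i[1L]]),
         curve = concentration_curve(tms, df$conc_mM[i]))
  })
}

#' Write curves to a long-format TSV
#'
#' Inverse of [read_curves()]; numbers are written with 17 significant
#' digits so a read/write round trip preserves values to full double
#' precision. Accepts either the record list returned by [read_curves()]
#' or a long data.frame like the `curves` element of a cohort.
#'
#' @param curves Record list or long data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curves <- function(curves, path) {
  if (is.data.frame(curves)) {
    df <- curves
  } else {
    df <- do.call(rbind, lapply(curves, function(r) {
      data.frame(subject = r$subject, region = r$region,
                 stage = if (is.null(r$stage)) NA_character_ else r$stage,
                 roi = if (is.null(r$roi)) NA_character_ else r$roi,
                 time_min = r$curve$times, conc_mM = r$curve$values,
                 stringsAsFactors = FALSE)
    }))
  }
  num <- vapply(df, is.numeric, logical(1L))
  for (cl in names(df)[num]) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSF-rates table
#'
#' TSV/CSV with columns `subject`, `region`, `stage`, `k_in_prime`,
#' `k_out_prime`, as consumed by [iof_analysis()].
#'
#' @param path Path to the table.
#' @return A validated data.frame.
#' @export
read_rates <- function(path) {
  df <- .read_table_checked(path, c("subject", "region", "stage",
                                    "k_in_prime", "k_out_prime"))
  df$k_in_prime <- .numeric_col(df, "k_in_prime", path)
  df$k_out_prime <- .numeric_col(df, "k_out_prime", path)
  .check_rates(df)
}

.fits_to_df <- function(fits) {
  if (inherits(fits, "dcekin_fit")) fits <- list(fits)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    p <- unclass(f$params)
    id <- names(fits)[i]
    if (is.null(id) || !nzchar(id)) id <- sprintf("fit_%d", i)
    cbind(data.frame(id = id, model = f$model, stringsAsFactors = FALSE),
          as.data.frame(p, stringsAsFactors = FALSE),
          data.frame(rss = f$rss, converged = f$converged,
                     n_iter = f$n_iter,
                     bounds_hit = paste(f$bounds_hit, collapse = ","),
                     stringsAsFactors = FALSE))
  })
  if (length(unique(vapply(rows, function(r) paste(names(r), collapse = ","),
                           character(1L)))) > 1L)
    stop("cannot tabulate fits of different models together")
  do.call(rbind, rows)
}

#' Write fit or IOF results to disk
#'
#' Serializes a results table (an IOF table, a rates table, or a list of
#' `dcekin_fit` objects) as TSV or JSON with a deterministic column order.
#' Numbers are written with 10 significant digits in both dialects.
#'
#' @param results Data.frame, `dcekin_fit`, or list of `dcekin_fit`.
#' @param path Output path.
#' @param format "tsv" or "json".
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "dcekin_fit") ||
      (is.list(results) && !is.data.frame(results) &&
       all(vapply(results, inherits, logical(1L), "dcekin_fit"))))
    results <- .fits_to_df(results)
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("'results' must be a non-empty table or fit list")
  if (format == "tsv") {
    out <- results
    num <- vapply(out, is.numeric, logical(1L))
    for (cl in names(out)[num]) out[[cl]] <- sprintf("%.10g", out[[cl]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = 10,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

.CONFIG_KEYS <- list(
  top = c("input", "output_dir", "control_stage", "v_ees_fixed", "t_end",
          "seed", "format", "hct", "fit", "cohort"),
  fit = c("ftol", "ptol", "maxiter"),
  cohort = c("n_per_stage", "stages", "regions", "control", "time_start",
             "time_stop", "time_step", "noise_sd", "hct", "scale"))

#' Read and validate a YAML run configuration
#'
#' Loads a run configuration for the command-line interface. Unknown keys
#' at any level are errors, not warnings — a silently ignored typo in a
#' rate name would corrupt the science downstream. The optional `cohort`
#' section is turned into a [cohort_spec]; its `scale` subsection is a map
#' stage -> parameter -> factor applied through [scale_stage()].
#'
#' @param path Path to the YAML file.
#' @return A list of class `run_config` with elements `input`,
#'   `output_dir`, `control_stage`, `v_ees_fixed`, `t_end`, `seed`,
#'   `format`, `hct`, `fit` (tolerance list) and `cohort`
#'   (a [cohort_spec] or NULL).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), .CONFIG_KEYS$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$fit)) {
    unknown <- setdiff(names(cfg$fit), .CONFIG_KEYS$fit)
    if (length(unknown))
      stop("unknown fit config key(s): ", paste(unknown, collapse = ", "))
  }
  cohort <- NULL
  if (!is.null(cfg$cohort)) {
    unknown <- setdiff(names(cfg$cohort), .CONFIG_KEYS$cohort)
    if (length(unknown))
      stop("unknown cohort config key(s): ", paste(unknown, collapse = ", "))
    scale <- cfg$cohort$scale
    args <- cfg$cohort
    args$scale <- NULL
    if (!is.null(args$stages)) args$stages <- as.character(args$stages)
    if (!is.null(args$regions)) args$regions <- as.character(args$regions)
    cohort <- do.call(cohort_spec, args)
    for (stage in names(scale))
      for (param in names(scale[[stage]]))
        cohort <- scale_stage(cohort, stage, param,
                              scale[[stage]][[param]])
  }
  structure(list(
    input = cfg$input,
    output_dir = if (is.null(cfg$output_dir)) "." else cfg$output_dir,
    control_stage = if (is.null(cfg$control_stage)) "control"
                    else cfg$control_stage,
    v_ees_fixed = if (is.null(cfg$v_ees_fixed)) 0.20 else cfg$v_ees_fixed,
    t_end = if (is.null(cfg$t_end)) Inf else cfg$t_end,
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    format = if (is.null(cfg$format)) "tsv" else cfg$format,
    hct = if (is.null(cfg$hct)) 0.45 else cfg$hct,
    fit = cfg$fit,
    cohort = cohort,
    path = path
  ), class = "run_config")
}
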