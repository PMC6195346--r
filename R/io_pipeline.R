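## File formats and orchestration. Sweep tables are long-format delimited
## text with a fixed column set; results are emitted as JSON with
## provenance. The package's functions are the interface; run_pipeline()
## ties the analysis chain together in the order the data reduction
## requires: pre-pulse normalization -> QC -> model fits -> sigma series ->
## Hill fits.

.SWEEP_COLS <- c("patch_id", "epoch", "ligand", "conc_nM", "prepulse_mV",
                 "prepulse_pA", "V_mV", "I_pA")

.check_sweep_cols <- function(df) {
  missing <- setdiff(.SWEEP_COLS, names(df))
  if (length(missing))
    stop("sweep table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a sweep table
#'
#' Reads a tab-delimited long-format sweep table with header columns
#' exactly `patch_id, epoch, ligand, conc_nM, prepulse_mV, prepulse_pA,
#' V_mV, I_pA`. Rows with non-numeric values in numeric columns are
#' collected into an error report attached as attribute `"malformed"`
#' rather than silently dropped.
#'
#' @param path file path
#' @return data frame of typed sweeps
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  .check_sweep_cols(df)
  num_cols <- c("epoch", "conc_nM", "prepulse_mV", "prepulse_pA", "V_mV",
                "I_pA")
  if (nrow(df) == 0L) {
    for (cc in num_cols) df[[cc]] <- numeric(0)
    df$epoch <- integer(0)
    attr(df, "malformed") <- df[0, ]
    return(df)
  }
  suppress <- function(x) suppressWarnings(as.numeric(x))
  parsed <- lapply(df[num_cols], suppress)
  bad <- Reduce(`|`, lapply(parsed, is.na))
  malformed <- df[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]
  for (cc in num_cols) df[[cc]] <- suppress(df[[cc]])
  df$epoch <- as.integer(df$epoch)
  if (nrow(malformed))
    warning(sprintf("%d malformed row(s) collected in attr(, 'malformed')",
                    nrow(malformed)), call. = FALSE)
  attr(df, "malformed") <- malformed
  df
}

#' Write a sweep table
#'
#' @param sweeps sweep table (see [read_sweeps()] for the column set)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_sweeps <- function(sweeps, path) {
  .check_sweep_cols(sweeps)
  utils::write.table(sweeps[.SWEEP_COLS], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' @param input path to a sweep table, or a sweep data frame
#' @param condition an [ion_condition()]
#' @param qc a [qc_policy()]
#' @param ref_V reference voltage for normalization (mV)
#' @param fix_h_to_one constrain the Hill coefficient of the sigma-series
#'   fits to 1
#' @param exclude_tol tolerance of [exclude_low_affinity_phase()]
#' @param n_starts multi-start count for [fit_iv()]
#' @param seed integer seed recorded in the provenance
#' @return a `run_config` list
#' @export
run_config <- function(input = NULL, condition = ion_condition(),
                       qc = qc_policy(), ref_V = 120,
                       fix_h_to_one = FALSE, exclude_tol = 0.05,
                       n_starts = 5L, seed = 1L) {
  structure(list(input = input, condition = condition, qc = qc,
                 ref_V = ref_V, fix_h_to_one = fix_h_to_one,
                 exclude_tol = exclude_tol, n_starts = as.integer(n_starts),
                 seed = as.integer(seed)), class = "run_config")
}

#' Build a run configuration from a plain list, rejecting unknown keys
#'
#' @param x named list (e.g. parsed from JSON)
#' @return a [run_config()]
#' @export
as_run_config <- function(x) {
  stopifnot(is.list(x))
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, x)
}

.input_digest <- function(input) {
  if (is.character(input) && length(input) == 1L && file.exists(input))
    return(unname(tools::md5sum(input)))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(input, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis chain on a sweep table
#'
#' Normalizes pre-pulse rundown, applies bracketed zero-ligand quality
#' control per patch, reference-normalizes every retained test recording,
#' averages the normalized I-V curves across patches at each (ligand,
#' concentration), fits the three-barrier model to each mean curve, builds
#' per-ligand concentration series of the fitted sigma parameters and fits
#' them to the Hill equation with the low-affinity exclusion rule. Fitting
#' the cross-patch mean curve (rather than averaging per-patch parameters)
#' is what stabilizes the weakly determined central-barrier rate at low
#' ligand; per-recording fits are also returned for inspection.
#' Deterministic given inputs and configuration; every bundle carries
#' provenance.
#'
#' @param config a [run_config()] whose `input` is a sweep-table path or
#'   data frame
#' @return a result bundle: `fits` (per-mean-curve data frame, one row per
#'   ligand and concentration), `patch_fits` (per-recording data frame),
#'   `series` (list of [sigma_series()]), `hill` (list of `hill_fit`),
#'   `qc_log` (per-patch decisions), `provenance`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input)) stop("config has no input", call. = FALSE)
  sweeps <- if (is.character(config$input)) read_sweeps(config$input)
            else .check_sweep_cols(config$input)
  digest <- .input_digest(config$input)
  sweeps <- normalize_prepulse(sweeps)
  recs <- sweeps_to_recordings(sweeps)
  patches <- split(recs, vapply(recs, `[[`, "", "patch_id"))
  qc_log <- list()
  kept <- list()
  for (pid in names(patches)) {
    q <- qc_filter(patches[[pid]], config$qc)
    qc_log[[pid]] <- list(kept = length(q$kept) > 0L, reasons = q$reasons)
    kept <- c(kept, q$kept)
  }
  patch_fits <- data.frame()
  fits <- data.frame()
  if (length(kept)) {
    kept <- lapply(kept, normalize_reference, ref_V = config$ref_V)
    rows <- lapply(kept, function(r) {
      f <- fit_iv(r, condition = config$condition,
                  n_starts = config$n_starts)
      data.frame(patch_id = r$patch_id, ligand = r$ligand, conc_nM = r$conc,
                 epoch = r$epoch, A = f$A, sigma_h = f$sigma_h,
                 sigma_beta = f$sigma_beta, rss = f$rss,
                 converged = f$converged)
    })
    patch_fits <- do.call(rbind, rows)
    ## mean normalized I-V per (ligand, concentration) across patches
    key <- paste(vapply(kept, `[[`, "", "ligand"),
                 vapply(kept, `[[`, 0, "conc"), sep = "\r")
    rows <- lapply(split(kept, key), function(recs) {
      V <- recs[[1L]]$V
      for (r in recs) if (length(r$V) != length(V) ||
                          any(abs(r$V - V) > 1e-9))
        stop("recordings do not share the voltage grid", call. = FALSE)
      Im <- rowMeans(matrix(vapply(recs, `[[`, numeric(length(V)), "I"),
                            nrow = length(V)))
      f <- fit_iv(data.frame(V = V, I = Im), condition = config$condition,
                  n_starts = config$n_starts)
      data.frame(ligand = recs[[1L]]$ligand, conc_nM = recs[[1L]]$conc,
                 n_patches = length(recs), A = f$A, sigma_h = f$sigma_h,
                 sigma_beta = f$sigma_beta,
                 sigma_beta_ci95 = f$ci95[["sigma_beta"]],
                 sigma_h_ci95 = f$ci95[["sigma_h"]],
                 rss = f$rss, converged = f$converged)
    })
    fits <- do.call(rbind, rows)
    rownames(fits) <- NULL
    fits <- fits[order(fits$ligand, fits$conc_nM), , drop = FALSE]
    fits <- fits[fits$converged, , drop = FALSE]
  }
  series <- list()
  hill <- list()
  if (nrow(fits)) {
    pv <- sweeps$prepulse_mV[1L]
    for (lig in unique(fits$ligand)) {
      sub <- fits[fits$ligand == lig, , drop = FALSE]
      series[[paste0(lig, ".sigma_beta")]] <-
        sigma_series(sub$conc_nM, sub$sigma_beta, "sigma_beta",
                     ligand = lig, voltage_mV = pv,
                     ci95 = sub$sigma_beta_ci95)
      series[[paste0(lig, ".sigma_h")]] <-
        sigma_series(sub$conc_nM, sub$sigma_h, "sigma_h",
                     ligand = lig, voltage_mV = pv,
                     ci95 = sub$sigma_h_ci95)
    }
    for (nm in names(series)) {
      hill[[nm]] <- tryCatch(
        fit_sigma_series(series[[nm]],
                         fix_h_to_one = config$fix_h_to_one,
                         tol = config$exclude_tol),
        error = function(e) structure(list(error = conditionMessage(e)),
                                      class = "hill_fit_error"))
    }
  }
  list(fits = fits, patch_fits = patch_fits, series = series, hill = hill,
       qc_log = qc_log,
       provenance = list(
         package = "ionbarrier",
         version = as.character(utils::packageVersion("ionbarrier")),
         input_digest = digest, seed = config$seed,
         qc = unclass(config$qc), ref_V = config$ref_V,
         fix_h_to_one = config$fix_h_to_one,
         exclude_tol = config$exclude_tol, n_starts = config$n_starts))
}

#' Write a result bundle as JSON
#'
#' Serializes the plain-data parts of a [run_pipeline()] bundle (fits,
#' sigma series, Hill parameters, QC log, provenance) to JSON.
#'
#' @param bundle a [run_pipeline()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results_json <- function(bundle, path) {
  hill <- lapply(bundle$hill, function(h) {
    if (inherits(h, "hill_fit_error")) return(list(error = h$error))
    list(ec50 = h$ec50, h = h$h, floor = h$floor, ceiling = h$ceiling,
         ci95 = as.list(h$ci95), unidentifiable = h$unidentifiable)
  })
  series <- lapply(bundle$series, function(s)
    list(param = attr(s, "param"), ligand = attr(s, "ligand"),
         voltage_mV = attr(s, "voltage_mV"),
         points = as.data.frame(s)))
  out <- list(fits = bundle$fits, series = series, hill = hill,
              qc_log = bundle$qc_log, provenance = bundle$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
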