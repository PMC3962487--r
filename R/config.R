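#' Pipeline configuration
#'
#' Bundles the calling thresholds, the random seed, optional input table paths
#' and the output directory for [run_pipeline()]. Every threshold defaults to
#' the published value used by the in vivo reactivation analysis:
#' steady-state differential expression at raw P < 0.01, a minimum 1.8-fold
#' decay over the 4-hour reactivation window, permutation P < 0.1, at most 20%
#' control drift between the pre-heat-shock and 4 h control points, and at
#' most a 50% pre-heat-shock difference between rescue and control conditions.
#'
#' @param de_alpha Significance threshold for the NB exact test, in (0,1).
#' @param fold_decay_min Minimum pre/4 h fold decay in the rescue condition.
#' @param perm_alpha Permutation-test threshold, in (0,1).
#' @param control_drift_max Maximum tolerated fractional change of the control
#'   series between the pre and 4 h points (0.20 = 20%).
#' @param leaky_diff_max Maximum tolerated fractional difference between
#'   conditions at the pre point (0.50 = 50%).
#' @param rng_seed Integer seed; fixing it makes every stochastic stage
#'   reproduce byte-identical outputs.
#' @param out_dir Output directory for stage tables.
#' @param counts_path,timecourse_path,annotation_path Optional input TSV paths;
#'   when `NULL` the synthetic generator supplies the stage inputs.
#' @param generator A [generator_config()] used when inputs are simulated.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(de_alpha = 0.01,
                            fold_decay_min = 1.8,
                            perm_alpha = 0.1,
                            control_drift_max = 0.20,
                            leaky_diff_max = 0.50,
                            rng_seed = 1L,
                            out_dir = tempfile("nmdreact_run_"),
                            counts_path = NULL,
                            timecourse_path = NULL,
                            annotation_path = NULL,
                            generator = generator_config()) {
  cfg <- list(
    de_alpha = de_alpha, fold_decay_min = fold_decay_min,
    perm_alpha = perm_alpha, control_drift_max = control_drift_max,
    leaky_diff_max = leaky_diff_max, rng_seed = as.integer(rng_seed),
    out_dir = out_dir, counts_path = counts_path,
    timecourse_path = timecourse_path, annotation_path = annotation_path,
    generator = generator
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  num <- c("de_alpha", "fold_decay_min", "perm_alpha",
           "control_drift_max", "leaky_diff_max")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("config field '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  for (nm in c("de_alpha", "perm_alpha")) {
    if (cfg[[nm]] >= 1) stop("config field '", nm, "' must lie in (0,1)",
                             call. = FALSE)
  }
  if (!is.finite(cfg$rng_seed)) stop("rng_seed must be a finite integer",
                                     call. = FALSE)
  invisible(cfg)
}

#' Read / write a flat key=value configuration file
#'
#' The on-disk format is one `key = value` pair per line; `#` starts a
#' comment. Unknown keys are rejected. Thresholds left out of the file keep
#' their published defaults.
#'
#' @param path File path.
#' @return For `read_config`, a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: '", lines[bad][1], "'",
                     call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  allowed <- c("de_alpha", "fold_decay_min", "perm_alpha",
               "control_drift_max", "leaky_diff_max", "rng_seed", "out_dir",
               "counts_path", "timecourse_path", "annotation_path")
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) stop("unknown config key(s): ",
                                paste(unknown, collapse = ", "), call. = FALSE)
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    args[[k]] <- if (k %in% c("out_dir", "counts_path", "timecourse_path",
                              "annotation_path")) vals[i] else as.numeric(vals[i])
  }
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  keys <- c("de_alpha", "fold_decay_min", "perm_alpha", "control_drift_max",
            "leaky_diff_max", "rng_seed", "out_dir")
  lines <- vapply(keys, function(k) {
    paste0(k, " = ", format(cfg[[k]], scientific = FALSE))
  }, "")
  for (k in c("counts_path", "timecourse_path", "annotation_path")) {
    if (!is.null(cfg[[k]])) lines <- c(lines, paste0(k, " = ", cfg[[k]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("nmdreact pipeline configuration\n")
  cat(sprintf("  DE alpha:            %g\n", x$de_alpha))
  cat(sprintf("  min 4 h fold decay:  %g\n", x$fold_decay_min))
  cat(sprintf("  permutation alpha:   %g\n", x$perm_alpha))
  cat(sprintf("  control drift max:   %g\n", x$control_drift_max))
  cat(sprintf("  leaky diff max:      %g\n", x$leaky_diff_max))
  cat(sprintf("  rng seed:            %d\n", x$rng_seed))
  invisible(x)
}
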