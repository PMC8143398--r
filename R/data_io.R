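#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline. Window widths follow the
#' study design: 18 degrees when profiling a single participant's 200 trials,
#' 4 degrees for the pooled "combined participant".
#'
#' @param window_individual_deg sliding-window width for individual
#'   participants (degrees).
#' @param window_combined_deg sliding-window width for the combined
#'   participant (degrees).
#' @param grid_step_deg orientation grid step (degrees).
#' @param n_bootstrap number of bootstrap resamples for inference.
#' @param rng_seed integer seed used by stochastic stages.
#' @param kappa_cap clamp for degenerate concentration estimates.
#' @param enforce_period_90 fold orientations modulo 90 degrees before
#'   windowing, imposing the 90-degree periodicity of the oblique effect.
#' @param cardinal_norm normalizer of the cardinal mixture component:
#'   `"analytic"` uses 1/(pi - 2) (the density then integrates to exactly 1),
#'   `"printed"` uses the rounded constant 0.877.
#' @return a list of class `orienc_config`.
#' @export
analysis_config <- function(window_individual_deg = 18,
                            window_combined_deg = 4,
                            grid_step_deg = 1,
                            n_bootstrap = 5000,
                            rng_seed = 1L,
                            kappa_cap = 1e4,
                            enforce_period_90 = TRUE,
                            cardinal_norm = c("analytic", "printed")) {
  cardinal_norm <- match.arg(cardinal_norm)
  stopifnot(window_individual_deg > grid_step_deg,
            window_combined_deg > grid_step_deg,
            n_bootstrap >= 1, kappa_cap > 0)
  structure(list(window_individual_deg = window_individual_deg,
                 window_combined_deg = window_combined_deg,
                 grid_step_deg = grid_step_deg,
                 n_bootstrap = as.integer(n_bootstrap),
                 rng_seed = as.integer(rng_seed),
                 kappa_cap = kappa_cap,
                 enforce_period_90 = enforce_period_90,
                 cardinal_norm = cardinal_norm),
            class = "orienc_config")
}

cardinal_norm_const <- function(config = NULL) {
  if (!is.null(config) && identical(config$cardinal_norm, "printed")) 0.877
  else 1 / (pi - 2)
}

trial_columns <- c("participant_id", "group", "block", "trial_index",
                   "target_deg", "response_deg", "rt_s")

block_levels <- c("woFB", "wFB1", "wFB2")
group_levels <- c("NT", "ASD")

#' Validate and canonicalize trial-level data
#'
#' Reduces angles modulo 180, checks the group/block factor levels and the
#' uniqueness of (participant, block, trial) triples, and attaches a
#' provenance tag.
#'
#' @param df data frame with the canonical trial columns
#'   (`participant_id, group, block, trial_index, target_deg, response_deg,
#'   rt_s`; `rt_s` optional).
#' @param provenance free-text source tag.
#' @return a `trial_data` tibble.
#' @export
as_trial_data <- function(df, provenance = "memory") {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(setdiff(trial_columns, "rt_s"), names(df))
  if (length(missing_cols)) {
    rlang::abort(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "orienc_schema_error")
  }
  if (!"rt_s" %in% names(df)) df$rt_s <- NA_real_
  bad_group <- !df$group %in% group_levels
  bad_block <- !df$block %in% block_levels
  if (any(bad_group) || any(bad_block)) {
    rows <- which(bad_group | bad_block)
    rlang::abort(paste0("invalid group/block label on row(s): ",
                        paste(utils::head(rows, 10), collapse = ", ")),
                 class = "orienc_schema_error")
  }
  for (col in c("target_deg", "response_deg")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      rows <- which(!is.finite(suppressWarnings(as.numeric(v))))
      rlang::abort(paste0("non-numeric ", col, " on row(s): ",
                          paste(utils::head(rows, 10), collapse = ", ")),
                   class = "orienc_parse_error")
    }
    df[[col]] <- wrap_ori(v)
  }
  df$trial_index <- as.integer(df$trial_index)
  df$rt_s <- as.numeric(df$rt_s)
  key <- paste(df$participant_id, df$block, df$trial_index)
  if (anyDuplicated(key)) {
    rlang::abort("duplicate (participant_id, block, trial_index) triples",
                 class = "orienc_schema_error")
  }
  df <- df[, trial_columns]
  attr(df, "provenance") <- provenance
  class(df) <- c("trial_data", class(df))
  df
}

#' Read trial-level data from a delimited text file
#'
#' @param path CSV/TSV file with a header row.
#' @param delim field delimiter (guessed from the extension by default).
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(target_deg = "orientation")`. Matching is case-insensitive.
#' @return a `trial_data` tibble; provenance is the file path.
#' @export
read_trials <- function(path, delim = NULL, col_map = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "orienc_io_error")
  }
  if (is.null(delim)) delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0) {
    rlang::abort(paste0("empty dataset: ", path),
                 class = "orienc_empty_error")
  }
  # case-insensitive canonicalization, then user-supplied mapping
  lower <- tolower(names(df))
  for (col in trial_columns) {
    hit <- which(lower == tolower(col))
    if (length(hit)) names(df)[hit[1]] <- col
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      hit <- which(tolower(names(df)) == tolower(col_map[[canon]]))
      if (length(hit)) names(df)[hit[1]] <- canon
    }
  }
  as_trial_data(df, provenance = path)
}

#' Write trial-level data to CSV
#'
#' @param data a `trial_data` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data)[, trial_columns], path)
  invisible(path)
}

profile_attr_names <- function(type) {
  switch(type,
         bias_profile = c("window_deg", "period_deg"),
         fisher_profile = c("total", "total_fi_alt", "n_floored"))
}

#' Write a bias/variance or Fisher profile to CSV
#'
#' Scalar metadata (window width, totals) is stored in `#`-prefixed header
#' lines so a round trip through `read_profile()` reproduces the object.
#'
#' @param profile a `bias_profile` or `fisher_profile` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  type <- intersect(class(profile), c("bias_profile", "fisher_profile"))[1]
  if (is.na(type)) {
    rlang::abort("profile must be a bias_profile or fisher_profile",
                 class = "orienc_type_error")
  }
  if (nrow(profile) == 0) {
    rlang::abort("refusing to write an empty profile",
                 class = "orienc_empty_error")
  }
  num <- vapply(profile, is.numeric, logical(1))
  vals <- as.matrix(profile[, num])
  if (any(!is.finite(vals) & !is.na(vals))) {
    rlang::abort("profile contains non-finite values",
                 class = "orienc_validation_error")
  }
  meta <- c(paste0("# type: ", type),
            vapply(profile_attr_names(type), function(a) {
              paste0("# ", a, ": ", format(attr(profile, a), digits = 17))
            }, character(1)))
  body <- readr::format_csv(tibble::as_tibble(profile))
  writeLines(c(meta, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  body <- lines[!grepl("^# ", lines)]
  df <- readr::read_csv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE, progress = FALSE)
  kv <- sub("^# ", "", meta)
  keys <- sub(":.*$", "", kv)
  vals <- sub("^[^:]*: ", "", kv)
  type <- vals[keys == "type"]
  for (a in profile_attr_names(type)) {
    attr(df, a) <- as.numeric(vals[keys == a])
  }
  class(df) <- c(type, class(df))
  df
}
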