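#' Validate a trial data frame
#'
#' A trial dataset is a long-format tibble with one row per individual and
#' columns `arm` (0 = control, 1 = intervention), `cluster` (cluster id,
#' numbered 1..k within each arm), `individual` (id within cluster), `x`
#' (continuous baseline covariate) and `y` (binary outcome, `NA` when
#' missing). The missingness indicator `r` is 1 when `y` is observed and 0
#' otherwise, and is derived from `y` if absent. Both arms must contain the
#' same number of clusters before any missingness is imposed.
#'
#' @param data A data frame with the columns described above.
#' @param balanced Require both arms to have the same number of clusters
#'   (`TRUE` for freshly generated/loaded data; complete-records subsets may
#'   legitimately be unbalanced).
#' @return The validated data as a tibble, with `r` present and columns in
#'   canonical order.
#' @export
validate_trial <- function(data, balanced = TRUE) {
  stopifnot(is.data.frame(data))
  needed <- c("arm", "cluster", "individual", "x", "y")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("trial data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- tibble::as_tibble(data)
  if (!all(data$arm %in% c(0L, 1L))) {
    stop("`arm` must be 0 (control) or 1 (intervention)")
  }
  bad_y <- !is.na(data$y) & !(data$y %in% c(0, 1))
  if (any(bad_y)) {
    stop("`y` must be 0, 1 or missing; offending row(s): ",
         paste(utils::head(which(bad_y), 5L), collapse = ", "))
  }
  if (!"r" %in% names(data)) {
    data$r <- as.integer(!is.na(data$y))
  }
  if (any((data$r == 0) != is.na(data$y))) {
    stop("`r` inconsistent with `y`: r must be 0 exactly when y is absent")
  }
  key <- paste(data$arm, data$cluster, data$individual)
  if (anyDuplicated(key)) {
    stop("(arm, cluster, individual) triples must be unique")
  }
  if (balanced) {
    k0 <- dplyr::n_distinct(data$cluster[data$arm == 0])
    k1 <- dplyr::n_distinct(data$cluster[data$arm == 1])
    if (k0 != k1) {
      stop("design unbalanced: ", k0, " control vs ", k1,
           " intervention clusters")
    }
  }
  dplyr::select(data, "arm", "cluster", "individual", "x", "y", "r")
}

#' Number of clusters per arm actually present in a dataset
#'
#' @param data A trial tibble.
#' @return Named integer vector `c(k0, k1)`.
#' @export
clusters_per_arm <- function(data) {
  c(k0 = dplyr::n_distinct(data$cluster[data$arm == 0]),
    k1 = dplyr::n_distinct(data$cluster[data$arm == 1]))
}

#' Read a trial dataset from CSV
#'
#' Expects a header `arm,cluster,individual,x,y` with `y` left empty for
#' missing outcomes. The missingness indicator is derived from the presence
#' of `y` and the usual invariants are validated.
#'
#' @param path Path to a CSV file.
#' @return A validated trial tibble.
#' @export
read_trial_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      arm = readr::col_integer(),
      cluster = readr::col_integer(),
      individual = readr::col_integer(),
      # parsed via strtod below: the fast readr double parser can be one
      # ulp off, which would break exact round trips
      x = readr::col_character(),
      y = readr::col_integer()
    )
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed CSV at line(s): ",
         paste(utils::head(probs$row, 5L), collapse = ", "))
  }
  x_num <- as.numeric(raw$x)
  if (any(is.na(x_num) & !is.na(raw$x))) {
    stop("malformed CSV: non-numeric covariate at line(s): ",
         paste(utils::head(which(is.na(x_num) & !is.na(raw$x)), 5L),
               collapse = ", "))
  }
  raw$x <- x_num
  validate_trial(raw)
}

#' Write a trial dataset to CSV
#'
#' Missing outcomes are serialised as empty fields so that
#' `read_trial_csv(write_trial_csv(d, p))` round-trips exactly.
#'
#' @param data A trial tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  data <- validate_trial(data, balanced = FALSE)
  out <- dplyr::select(data, -"r")
  # 17 significant digits guarantee an exact double round trip
  out$x <- sprintf("%.17g", out$x)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Restrict a dataset to complete records
#'
#' Keeps only individuals with an observed outcome (`r == 1`). Clusters left
#' with no observed outcomes disappear from the result, so downstream
#' analyses use the realised per-arm cluster counts. Idempotent.
#'
#' @param data A trial tibble.
#' @return A trial tibble containing only observed records.
#' @export
complete_records <- function(data) {
  data <- validate_trial(data, balanced = FALSE)
  out <- dplyr::filter(data, .data$r == 1)
  for (a in 0:1) {
    if (a %in% data$arm && !a %in% out$arm) {
      stop("arm ", a, " has no observed outcomes")
    }
  }
  out
}
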