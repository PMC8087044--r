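#' Read and write ramet transition tables
#'
#' The on-disk format is a plain CSV with header
#' \code{ramet_id,size_t,survived,size_t1,flowered,n_flowers,is_recruit},
#' sizes in natural-log m^2 and absent values as empty fields.
#' \code{read_ramet_table()} validates every row against the record
#' invariants (dead ramets have no size at t+1; flowering is equivalent to a
#' positive flower count; recruits have no time-t fields) and fails with the
#' offending row numbers.
#'
#' @param path file path.
#' @return \code{read_ramet_table()}: a validated ramet \code{data.frame};
#'   \code{write_ramet_table()}: \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' d <- simulate_ramets(reference_params(), 50, seed = 1)
#' write_ramet_table(d, f)
#' identical(read_ramet_table(f)$size_t, d$size_t)
#' @export
read_ramet_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("ramet_id", "size_t", "survived", "size_t1", "flowered",
            "n_flowers", "is_recruit")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  d <- d[cols]
  as_num <- function(col, label, integer = FALSE) {
    raw <- ifelse(is.na(col), "", col)
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(nzchar(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric ", label, " at row(s): ", paste(bad, collapse = ", "))
    num[!nzchar(raw)] <- NA
    if (integer) as.integer(num) else num
  }
  d$size_t <- as_num(d$size_t, "size_t")
  d$size_t1 <- as_num(d$size_t1, "size_t1")
  d$survived <- as_num(d$survived, "survived", integer = TRUE)
  d$flowered <- as_num(d$flowered, "flowered", integer = TRUE)
  d$n_flowers <- as_num(d$n_flowers, "n_flowers", integer = TRUE)
  d$is_recruit <- as_num(d$is_recruit, "is_recruit", integer = TRUE)
  validate_ramet_table(d)
  d
}

#' @rdname read_ramet_table
#' @param data a ramet \code{data.frame} as produced by [simulate_ramets()].
#' @export
write_ramet_table <- function(data, path) {
  validate_ramet_table(data)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(ramet_id = data$ramet_id,
                    size_t = fmt(data$size_t),
                    survived = ifelse(is.na(data$survived), "", data$survived),
                    size_t1 = fmt(data$size_t1),
                    flowered = ifelse(is.na(data$flowered), "", data$flowered),
                    n_flowers = ifelse(is.na(data$n_flowers), "", data$n_flowers),
                    is_recruit = data$is_recruit,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate ramet record invariants
#'
#' Checks ID uniqueness and the per-record consistency rules; violations are
#' reported with their row numbers.
#'
#' @param data a ramet \code{data.frame}.
#' @return \code{data}, invisibly, if valid; otherwise an error.
#' @export
validate_ramet_table <- function(data) {
  req <- c("ramet_id", "size_t", "survived", "size_t1", "flowered",
           "n_flowers", "is_recruit")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(data) == 0) return(invisible(data))
  if (anyDuplicated(data$ramet_id))
    stop("duplicated ramet_id: ",
         paste(unique(data$ramet_id[duplicated(data$ramet_id)]), collapse = ", "))
  viol <- character(0)
  chk <- function(bad, msg) {
    i <- which(bad)
    if (length(i)) viol <<- c(viol, paste0(msg, " at row(s) ",
                                           paste(i, collapse = ", ")))
  }
  est <- data$is_recruit %in% 0L   # established (time-t) ramets
  chk(est & !is.na(data$survived) & data$survived == 0L & !is.na(data$size_t1),
      "dead ramet with size_t1 present")
  chk(est & !is.na(data$flowered) &
        ((data$flowered == 1L) != (!is.na(data$n_flowers) & data$n_flowers >= 1L)),
      "flowered inconsistent with n_flowers")
  chk(data$is_recruit == 1L & !is.na(data$size_t), "recruit with size_t present")
  chk(data$is_recruit == 1L & is.na(data$size_t1), "recruit without size_t1")
  chk(est & is.na(data$size_t), "established ramet without size_t")
  if (length(viol)) stop(paste(viol, collapse = "; "))
  invisible(data)
}

#' Ground-truth size calibration
#'
#' Computes the multiplicative correction converting imagery-measured areas
#' to true areas, from targets of known size re-measured on the orthomosaic.
#' The default is the mean of per-target \code{known/measured} ratios; a
#' pooled ratio-of-sums variant is available.
#'
#' @param measured_areas,known_areas equal-length positive vectors (m^2).
#' @param method \code{"mean_ratio"} (default) or \code{"pooled"}
#'   (\code{sum(known)/sum(measured)}).
#' @return An object of class \code{"size_calibration"} with fields
#'   \code{ratio} (> 0) and \code{n_targets}.
#' @examples
#' calibrate_sizes(c(0.88), c(1.00))$ratio   # ~1.136, a ~12% underestimate
#' @export
calibrate_sizes <- function(measured_areas, known_areas,
                            method = c("mean_ratio", "pooled")) {
  method <- match.arg(method)
  if (length(measured_areas) != length(known_areas))
    stop("'measured_areas' and 'known_areas' must have equal length")
  if (length(measured_areas) == 0) stop("calibration needs at least one target")
  if (any(measured_areas <= 0) || any(known_areas <= 0))
    stop("areas must all be > 0")
  ratio <- switch(method,
                  mean_ratio = mean(known_areas / measured_areas),
                  pooled = sum(known_areas) / sum(measured_areas))
  structure(list(ratio = ratio, n_targets = length(measured_areas),
                 method = method),
            class = "size_calibration")
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf("Size calibration: ratio = %.4f (%s, %d targets)\n",
              x$ratio, x$method, x$n_targets))
  if (x$ratio > 1)
    cat(sprintf("  measured areas underestimate truth by ~%.0f%%\n",
                100 * (1 - 1 / x$ratio)))
  invisible(x)
}

#' Apply the size calibration and log-transform
#'
#' Takes a ramet table whose \code{size_t}/\code{size_t1} columns hold raw
#' measured areas in m^2, rescales them by the calibration ratio, and
#' replaces them with natural-log corrected areas. Row order and IDs are
#' preserved.
#'
#' @param data ramet \code{data.frame} with raw areas (m^2, > 0 where present).
#' @param calibration a [calibrate_sizes()] result.
#' @return The dataset with size columns in natural-log m^2.
#' @export
apply_size_correction <- function(data, calibration) {
  stopifnot(inherits(calibration, "size_calibration"))
  for (sc in c("size_t", "size_t1")) {
    a <- data[[sc]]
    bad <- which(!is.na(a) & a <= 0)
    if (length(bad))
      stop("nonpositive ", sc, " for ramet_id: ",
           paste(data$ramet_id[bad], collapse = ", "))
    data[[sc]] <- log(a * calibration$ratio)
  }
  data
}

#' Serialise IPM results to JSON
#'
#' Writes the growth rate, eigenvectors' summaries, sub-kernel elasticities,
#' confidence intervals, grid settings and provenance to a JSON file that
#' round-trips to full double precision. Missing optional fields (e.g. CIs
#' when no bootstrap was run) are serialised as \code{null}.
#'
#' @param result a \code{"ramet_ipm"} object (see [ipm_fit()]).
#' @param path output file path.
#' @param seed,parameterization optional provenance strings/numbers recorded
#'   verbatim in the file.
#' @return \code{path}, invisibly.
#' @export
write_ipm_results <- function(result, path, seed = NULL,
                              parameterization = NULL) {
  stopifnot(inherits(result, "ramet_ipm"))
  num <- function(x) if (is.null(x)) NULL else unname(as.numeric(x))
  payload <- list(
    lambda = result$lambda,
    ci_lambda = num(result$ci_lambda),
    e_P = result$e_P,
    e_F = result$e_F,
    ci_e_P = num(result$ci_e_P),
    ci_e_F = num(result$ci_e_F),
    grid = list(L = result$grid$L, U = result$grid$U,
                n_mesh = result$grid$n_mesh),
    params = unclass(result$params),
    provenance = list(seed = seed, parameterization = parameterization,
                      package = "rametipm")
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_ipm_results
#' @export
read_ipm_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
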