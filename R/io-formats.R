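#' @importFrom utils read.csv write.csv head tail packageVersion
#' @importFrom stats rnorm runif approx optimize median sd lm coef residuals setNames
NULL

# closed vocabulary of plate-map roles
PLATE_ROLES <- c("sample", "buffer", "detergent_max", "ligand_only",
                 "vehicle_protein")

#' Assemble an assay plate object
#'
#' An `assay_plate` bundles a shared axis (time in seconds, or temperature in
#' degrees C for melt curves) with one signal column per well and a plate map
#' describing each well's condition, role, doses and replicate id.
#'
#' @param axis numeric, strictly increasing (time or temperature).
#' @param signal numeric matrix, one row per axis value, one named column per
#'   well.
#' @param map data frame with columns `well`, `condition`, `role`, `dose_a`,
#'   `dose_b`, `replicate`.
#' @param axis_name column name used when writing the plate CSV
#'   (e.g. `"time_s"`).
#' @return an object of class `assay_plate`.
#' @export
assay_plate <- function(axis, signal, map, axis_name = "time_s") {
  signal <- as.matrix(signal)
  if (length(axis) != nrow(signal))
    stop("axis length and signal rows differ", call. = FALSE)
  if (any(!is.finite(axis)) || any(diff(axis) <= 0))
    stop("plate axis must be finite and strictly increasing", call. = FALSE)
  map <- validate_plate_map(map)
  wells <- colnames(signal)
  if (is.null(wells) || anyDuplicated(wells))
    stop("signal columns must carry unique well names", call. = FALSE)
  unmapped <- setdiff(wells, map$well)
  if (length(unmapped))
    stop("wells missing from plate map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(map$well, wells)
  if (length(extra))
    stop("plate map rows without data columns: ",
         paste(extra, collapse = ", "), call. = FALSE)
  # canonical well order = map order, so parsing is column-order independent
  signal <- signal[, map$well, drop = FALSE]
  structure(list(axis = as.numeric(axis), signal = signal, map = map,
                 axis_name = axis_name),
            class = "assay_plate")
}

validate_plate_map <- function(map) {
  need <- c("well", "condition", "role")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("plate map lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(map$well))
    stop("plate map well ids must be unique", call. = FALSE)
  bad <- setdiff(unique(map$role), PLATE_ROLES)
  if (length(bad))
    stop("unknown plate roles: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(PLATE_ROLES, collapse = ", "), ")",
         call. = FALSE)
  if (is.null(map$dose_a)) map$dose_a <- 0
  if (is.null(map$dose_b)) map$dose_b <- 0
  if (is.null(map$replicate)) map$replicate <- 1L
  map[c("well", "condition", "role", "dose_a", "dose_b", "replicate")]
}

#' @export
print.assay_plate <- function(x, ...) {
  cat(sprintf("<assay_plate> %d wells x %d readings (%s %.4g to %.4g)\n",
              ncol(x$signal), length(x$axis), x$axis_name,
              min(x$axis), max(x$axis)))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$map$role)),
                              table(x$map$role)), collapse = " "), "\n")
  invisible(x)
}

#' Read a wide plate CSV plus its sidecar plate map
#'
#' The plate CSV holds the shared axis in its first column (header names the
#' axis, e.g. `time_s` or `temperature_c`) followed by one column per well.
#' The plate map CSV holds `well`, `condition`, `role`, `dose_a`, `dose_b`,
#' `replicate`. Wells are re-ordered to plate-map order so shuffled data
#' columns parse identically.
#'
#' @param data_file path to the wide plate CSV.
#' @param map_file path to the plate-map CSV.
#' @return an [assay_plate()].
#' @export
read_plate <- function(data_file, map_file) {
  dat <- read.csv(data_file, check.names = FALSE)
  if (ncol(dat) < 2) stop("plate CSV needs an axis column plus wells",
                          call. = FALSE)
  map <- read.csv(map_file, check.names = FALSE)
  axis <- dat[[1]]
  if (any(diff(axis) <= 0))
    stop("non-monotone axis column in ", data_file, call. = FALSE)
  assay_plate(axis, as.matrix(dat[-1]), map, axis_name = names(dat)[1])
}

#' Write an assay plate to the wide CSV dialect
#'
#' @param plate an [assay_plate()].
#' @param data_file,map_file output paths.
#' @return the two paths, invisibly.
#' @export
write_plate <- function(plate, data_file, map_file) {
  stopifnot(inherits(plate, "assay_plate"))
  out <- data.frame(axis = plate$axis, plate$signal, check.names = FALSE)
  names(out)[1] <- plate$axis_name
  write.csv(out, data_file, row.names = FALSE, quote = FALSE)
  write.csv(plate$map, map_file, row.names = FALSE, quote = FALSE)
  invisible(c(data_file, map_file))
}

#' Write tidy result tables and JSON fit reports
#'
#' Tables are written as CSV, reports as JSON with deterministic field
#' ordering; each report gains a `provenance` block recording the package
#' version and any configuration passed in `config`.
#'
#' @param tables named list of data frames (may be empty).
#' @param reports named list of report lists (may be empty).
#' @param out_dir output directory, created if needed.
#' @param config optional named list recorded verbatim in each report.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(tables = list(), reports = list(), out_dir = ".",
                          config = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(reports)) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    rep <- reports[[nm]]
    rep$provenance <- list(package = "bafkit",
                           version = as.character(packageVersion("bafkit")),
                           config = config)
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}
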