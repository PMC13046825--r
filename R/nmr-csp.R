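# Chemical-shift perturbation analysis of paired 1H-15N HSQC peak lists:
# weighted per-residue CSPs, mean + 1/2 SD significance thresholds, and
# averaging across a ligand concentration series.

#' Weighted chemical-shift perturbation
#'
#' \deqn{\Delta\delta = \sqrt{\frac{(\Delta^1H)^2 + 0.2\,(\Delta^{15}N)^2}{2}}}
#' The 0.2 weight compensates the larger 15N chemical-shift range relative
#' to 1H. Non-negative and even in each argument.
#'
#' @param d_h,d_n 1H and 15N shift differences (ppm), vectorized.
#' @return combined perturbation (ppm).
#' @export
csp <- function(d_h, d_n) {
  sqrt((d_h^2 + 0.2 * d_n^2) / 2)
}

#' Per-residue CSP table from paired peak lists
#'
#' Matches reference and treated peak lists by residue number and computes
#' [csp()] wherever both spectra carry a confident assignment. Prolines
#' (no backbone amide) are carried with status `"proline"` and residues
#' unassigned/overlapped in either list with status `"missing"`; neither
#' carries a perturbation value nor enters downstream statistics.
#'
#' @param reference,treated peak-list data frames with columns
#'   `residue_number`, `residue_name`, `h_ppm`, `n_ppm`, and optionally
#'   `assigned` (inferred from non-missing shifts if absent).
#' @return data frame with columns `residue_number`, `residue_name`, `d_h`,
#'   `d_n`, `delta_delta`, `status`.
#' @export
csp_table <- function(reference, treated) {
  if (!setequal(reference$residue_number, treated$residue_number))
    stop("residue numbering mismatch between peak lists", call. = FALSE)
  reference <- reference[order(reference$residue_number), ]
  treated <- treated[match(reference$residue_number,
                           treated$residue_number), ]
  ok <- function(pl) {
    a <- if (!is.null(pl$assigned)) pl$assigned else TRUE
    a & is.finite(pl$h_ppm) & is.finite(pl$n_ppm)
  }
  pro <- reference$residue_name == "PRO" | treated$residue_name == "PRO"
  measured <- ok(reference) & ok(treated) & !pro
  status <- ifelse(pro, "proline", ifelse(measured, "measured", "missing"))
  d_h <- ifelse(measured, treated$h_ppm - reference$h_ppm, NA_real_)
  d_n <- ifelse(measured, treated$n_ppm - reference$n_ppm, NA_real_)
  data.frame(residue_number = reference$residue_number,
             residue_name = reference$residue_name,
             d_h = d_h, d_n = d_n,
             delta_delta = ifelse(measured, csp(d_h, d_n), NA_real_),
             status = status, row.names = NULL)
}

#' Significance thresholds and classification of CSPs
#'
#' Thresholds are the mean perturbation across all measurable residues plus
#' one (`theta1`) or two (`theta2`) standard deviations; residues strictly
#' exceeding a threshold are classed `above_1sd` / `above_2sd` (the higher
#' class wins), all other measured residues `ns`. Prolines and missing
#' residues never enter the mean/SD.
#'
#' @param records a [csp_table()].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return list with `theta1`, `theta2`, `sd_type`, `n_measured`, and
#'   `table` (the input with a `class` column).
#' @export
csp_significance <- function(records, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  dd <- records$delta_delta[records$status == "measured"]
  if (length(dd) < 2)
    stop("need >= 2 measured residues for threshold statistics",
         call. = FALSE)
  m <- mean(dd)
  s <- sd(dd)
  if (sd_type == "population") s <- s * sqrt((length(dd) - 1) / length(dd))
  theta1 <- m + s; theta2 <- m + 2 * s
  cls <- rep(NA_character_, nrow(records))
  meas <- records$status == "measured"
  cls[meas] <- ifelse(records$delta_delta[meas] > theta2, "above_2sd",
                      ifelse(records$delta_delta[meas] > theta1,
                             "above_1sd", "ns"))
  records$class <- cls
  list(theta1 = theta1, theta2 = theta2, sd_type = sd_type,
       n_measured = length(dd), table = records)
}

#' Average CSP tables across a concentration series
#'
#' Per residue, the mean perturbation over the tables in which the residue
#' is measured; residues measurable in no table are dropped. Status is
#' `proline` if any table marks it so, otherwise `measured`. Thresholds are
#' typically recomputed on the averaged table with [csp_significance()].
#'
#' @param series non-empty list of [csp_table()] data frames sharing residue
#'   numbering.
#' @return averaged CSP table.
#' @export
average_csp <- function(series) {
  if (length(series) == 0) stop("empty series", call. = FALSE)
  base <- series[[1]]
  for (tab in series[-1])
    if (!setequal(tab$residue_number, base$residue_number))
      stop("residue numbering mismatch across series", call. = FALSE)
  res <- sort(base$residue_number)
  rows <- lapply(res, function(r) {
    recs <- lapply(series, function(tab) tab[tab$residue_number == r, ])
    meas <- vapply(recs, function(x) x$status == "measured", TRUE)
    pro <- any(vapply(recs, function(x) x$status == "proline", TRUE))
    if (!any(meas)) {
      if (!pro) return(NULL)   # unmeasured everywhere: excluded
      return(data.frame(residue_number = r,
                        residue_name = recs[[1]]$residue_name,
                        d_h = NA_real_, d_n = NA_real_,
                        delta_delta = NA_real_, status = "proline"))
    }
    data.frame(residue_number = r, residue_name = recs[[1]]$residue_name,
               d_h = mean(vapply(recs[meas], `[[`, 0, "d_h")),
               d_n = mean(vapply(recs[meas], `[[`, 0, "d_n")),
               delta_delta = mean(vapply(recs[meas], `[[`, 0,
                                         "delta_delta")),
               status = "measured")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
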