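# FLAMBE: kinetic fluorescence-polarization monitoring of early BAX
# activation via binding/dissociation of a labeled BAK-BH3 peptide. Traces
# are parameterized non-parametrically into (Tmax, EP), normalized to the
# ligand-only and protein-vehicle controls, and compared via a Euclidean
# shift distance.

#' Polarization from polarized emission intensities
#'
#' \deqn{mP = 1000 \, (I_\parallel - I_\perp) / (I_\parallel + I_\perp)}
#' Values lie in \[-1000, 1000\] and are invariant under common scaling of
#' both intensities.
#'
#' @param i_par,i_perp parallel and perpendicular emission intensities,
#'   >= 0 with positive total.
#' @return milli-polarization units (mP).
#' @export
polarization <- function(i_par, i_perp) {
  if (any(i_par < 0) || any(i_perp < 0))
    stop("intensities must be >= 0", call. = FALSE)
  tot <- i_par + i_perp
  if (any(tot <= 0))
    stop("zero total intensity: polarization undefined", call. = FALSE)
  (i_par - i_perp) / tot * 1000
}

#' Parameterize a kinetic polarization trace into (Tmax, EP)
#'
#' `Tmax` is the time of the highest polarization reading and `EP` the final
#' (endpoint) polarization. A trace with no binding kinetics - rise
#' amplitude `max(mp) - mp[1]` below `no_binding_threshold` times the
#' reference rise amplitude, or no rise at all - has `Tmax` set to 0 and is
#' flagged, so noise in a flat trace cannot masquerade as a late peak.
#' Traces should be replicate-averaged before parameterization to reduce
#' noise (see [flambe_metrics()]).
#'
#' @param time seconds.
#' @param mp milli-polarization readings.
#' @param ref_rise rise amplitude of the protein vehicle control, used by the
#'   no-binding rule; `NULL` restricts the rule to traces with zero/negative
#'   rise.
#' @param no_binding_threshold fraction of `ref_rise` below which a trace is
#'   declared non-binding (default 0.1).
#' @return object of class `flambe_metrics` with fields `tmax`, `ep`,
#'   `no_binding`, `normalized` (FALSE).
#' @export
parameterize_flambe <- function(time, mp, ref_rise = NULL,
                                no_binding_threshold = 0.1) {
  if (length(time) == 0 || length(time) != length(mp))
    stop("empty trace or length mismatch", call. = FALSE)
  rise <- max(mp) - mp[1]
  no_binding <- rise <= 0 ||
    (!is.null(ref_rise) && rise < no_binding_threshold * ref_rise)
  tmax <- if (no_binding) 0 else time[which.max(mp)]
  flambe_metrics(tmax, mp[length(mp)], no_binding = no_binding)
}

#' @rdname parameterize_flambe
#' @param tmax,ep metric values.
#' @param no_binding logical flag from the no-binding rule.
#' @param normalized whether the metrics are on the control-normalized scale.
#' @export
flambe_metrics <- function(tmax, ep, no_binding = FALSE,
                           normalized = FALSE) {
  structure(list(tmax = tmax, ep = ep, no_binding = no_binding,
                 normalized = normalized),
            class = "flambe_metrics")
}

#' @export
print.flambe_metrics <- function(x, ...) {
  cat(sprintf("<flambe_metrics%s> tmax = %.4g%s, ep = %.4g%s%s\n",
              if (x$normalized) " (normalized)" else "",
              x$tmax, if (x$normalized) "" else " s",
              x$ep, if (x$normalized) "" else " mP",
              if (x$no_binding) " [no binding]" else ""))
  invisible(x)
}

#' Normalize FLAMBE metrics to the assay controls
#'
#' Each metric is mapped affinely so the ligand-only (free labeled peptide)
#' control sits at 0 and the protein vehicle control at 1:
#' `norm = (value - ligand) / (protein - ligand)` per axis.
#'
#' @param m raw `flambe_metrics` for the condition of interest.
#' @param ligand_ctrl,protein_ctrl raw `flambe_metrics` of the two controls.
#' @return normalized `flambe_metrics`.
#' @export
normalize_flambe <- function(m, ligand_ctrl, protein_ctrl) {
  for (ax in c("tmax", "ep"))
    if (protein_ctrl[[ax]] == ligand_ctrl[[ax]])
      stop("degenerate controls: ligand and protein ", ax, " coincide",
           call. = FALSE)
  flambe_metrics(
    (m$tmax - ligand_ctrl$tmax) / (protein_ctrl$tmax - ligand_ctrl$tmax),
    (m$ep - ligand_ctrl$ep) / (protein_ctrl$ep - ligand_ctrl$ep),
    no_binding = m$no_binding, normalized = TRUE)
}

#' Shift distance between two parameterized conditions
#'
#' Euclidean distance in the normalized (Tmax, EP) plane:
#' \deqn{\Delta s = \sqrt{(\Delta Tmax)^2 + (\Delta EP)^2}}
#' Used to quantify how far a treatment (e.g. adding activator BH3 peptide)
#' moves a condition in parameterized-metric space.
#'
#' @param m_without,m_with `flambe_metrics` normalized on the same controls,
#'   or numeric vectors `c(tmax, ep)`.
#' @export
shift_distance <- function(m_without, m_with) {
  p <- function(m) if (inherits(m, "flambe_metrics")) c(m$tmax, m$ep)
                   else as.numeric(m[1:2])
  sqrt(sum((p(m_with) - p(m_without))^2))
}

#' Trapezoidal area under a trace
#'
#' @param time seconds, strictly increasing.
#' @param y trace values.
#' @export
trace_auc <- function(time, y) {
  if (length(time) < 2 || length(time) != length(y))
    stop("need >= 2 points with matching lengths", call. = FALSE)
  sum(diff(time) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Control-normalized area under a polarization trace
#'
#' Trapezoidal AUC mapped with the same 0/1 affine convention as the other
#' FLAMBE metrics: `(AUC - AUC_ligand) / (AUC_protein - AUC_ligand)`. All
#' traces must share one time grid.
#'
#' @param time shared time grid (s).
#' @param mp trace of interest (mP).
#' @param mp_ligand,mp_protein ligand-only and protein vehicle control
#'   traces on the same grid.
#' @export
flambe_auc <- function(time, mp, mp_ligand, mp_protein) {
  if (length(mp_ligand) != length(time) ||
      length(mp_protein) != length(time))
    stop("traces and controls must share one time grid", call. = FALSE)
  a <- trace_auc(time, mp)
  al <- trace_auc(time, mp_ligand)
  ap <- trace_auc(time, mp_protein)
  if (ap == al) stop("degenerate controls: equal control AUCs",
                     call. = FALSE)
  (a - al) / (ap - al)
}

#' Parameterize every condition on a FLAMBE plate
#'
#' Averages replicate wells per condition, identifies the ligand-only and
#' protein vehicle controls from the plate map, applies the no-binding rule
#' using the protein control's rise amplitude, and reports raw and
#' control-normalized (Tmax, EP) plus normalized AUC for every condition.
#'
#' @param plate an [assay_plate()] of polarization traces whose map contains
#'   exactly one `ligand_only` and one `vehicle_protein` condition.
#' @param no_binding_threshold passed to [parameterize_flambe()].
#' @return tidy data frame, one row per condition.
#' @export
flambe_metrics_plate <- function(plate, no_binding_threshold = 0.1) {
  stopifnot(inherits(plate, "assay_plate"))
  map <- plate$map
  cond_of <- function(role) unique(map$condition[map$role == role])
  lig <- cond_of("ligand_only"); pro <- cond_of("vehicle_protein")
  if (length(lig) != 1 || length(pro) != 1)
    stop("plate needs exactly one ligand_only and one vehicle_protein ",
         "condition", call. = FALSE)
  avg <- function(cond) {
    wells <- map$well[map$condition == cond]
    rowMeans(plate$signal[, wells, drop = FALSE])
  }
  time <- plate$axis
  pro_trace <- avg(pro); lig_trace <- avg(lig)
  ref_rise <- max(pro_trace) - pro_trace[1]
  par_of <- function(trace) parameterize_flambe(time, trace, ref_rise,
                                                no_binding_threshold)
  lig_m <- par_of(lig_trace); pro_m <- par_of(pro_trace)
  conds <- unique(map$condition)
  rows <- lapply(conds, function(cond) {
    tr <- avg(cond)
    m <- par_of(tr)
    nm <- normalize_flambe(m, lig_m, pro_m)
    data.frame(condition = cond,
               role = map$role[match(cond, map$condition)],
               tmax_raw = m$tmax, ep_raw = m$ep,
               tmax_norm = nm$tmax, ep_norm = nm$ep,
               auc_norm = flambe_auc(time, tr, lig_trace, pro_trace),
               no_binding = m$no_binding, row.names = NULL)
  })
  do.call(rbind, rows)
}
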