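# Seeded generators for every input the pipeline consumes. All generators are
# pure functions of (spec, seed): they save and restore the caller's RNG
# state, so repeated calls with the same arguments are bit-identical and
# never perturb surrounding code.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a simulated kinetic plate
#'
#' Describes a uniform read schedule, a set of conditions with per-condition
#' model parameters and replicate counts, and an additive Gaussian noise
#' level, for [sim_luv_plate()] or [sim_flambe_plate()].
#'
#' @param t_start,t_step,n_time uniform time grid (seconds): first read, read
#'   interval, number of reads. `t_start` may be 0 (plate readers emit a t=0
#'   read); model evaluation treats it as the x -> 0 limit.
#' @param conditions list of condition entries built with [plate_condition()].
#' @param noise_sd additive i.i.d. Gaussian noise SD per reading, in signal
#'   units. Must be >= 0.
#' @param seed integer RNG seed.
#' @return object of class `sim_plate_spec`.
#' @export
sim_plate_spec <- function(t_start, t_step, n_time, conditions,
                           noise_sd = 0, seed = 1L) {
  if (t_step <= 0 || n_time < 1)
    stop("time grid must be strictly increasing (t_step > 0, n_time >= 1)",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  labs <- vapply(conditions, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("condition labels must be unique", call. = FALSE)
  for (cn in conditions) {
    if (!cn$role %in% PLATE_ROLES)
      stop("unknown role: ", cn$role, call. = FALSE)
    if (cn$n_rep < 1) stop("replicate_count must be >= 1", call. = FALSE)
  }
  structure(list(time = t_start + t_step * (seq_len(n_time) - 1),
                 conditions = conditions, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_plate_spec")
}

#' Describe one simulated plate condition
#'
#' @param label condition label (unique within a plate).
#' @param role one of `sample`, `buffer`, `detergent_max`, `ligand_only`,
#'   `vehicle_protein`.
#' @param params named list of model parameters; see [sim_luv_plate()] and
#'   [sim_flambe_plate()] for what each role expects.
#' @param n_rep number of replicate wells.
#' @param dose_a,dose_b compound doses recorded in the plate map (uM).
#' @export
plate_condition <- function(label, role, params = list(), n_rep = 1L,
                            dose_a = 0, dose_b = 0) {
  list(label = label, role = role, params = params, n_rep = as.integer(n_rep),
       dose_a = dose_a, dose_b = dose_b)
}

build_plate <- function(spec, model_fun, axis_name) {
  wells <- list(); map <- list()
  for (cn in spec$conditions) {
    mu <- model_fun(cn, spec$time)
    for (r in seq_len(cn$n_rep)) {
      wid <- sprintf("%s_r%d", cn$label, r)
      wells[[wid]] <- mu
      map[[wid]] <- data.frame(well = wid, condition = cn$label,
                               role = cn$role, dose_a = cn$dose_a,
                               dose_b = cn$dose_b, replicate = r)
    }
  }
  sig <- do.call(cbind, wells)
  colnames(sig) <- names(wells)
  if (spec$noise_sd > 0)
    sig <- sig + matrix(rnorm(length(sig), 0, spec$noise_sd),
                        nrow(sig), ncol(sig))
  assay_plate(spec$time, sig, do.call(rbind, map), axis_name = axis_name)
}

#' Simulate a LUV dye-release plate
#'
#' Sample (and `vehicle_protein`) conditions are drawn from the modified
#' five-parameter sigmoid \eqn{y = B + (T-B)/(1+(E/x)^H)^S} plus additive
#' Gaussian noise; `buffer` wells fluctuate about `params$level` (the 0%
#' reference) and `detergent_max` wells about their stated maximum (the
#' detergent-solubilized 100% reference). Every LUV plate must contain at
#' least one buffer and one detergent_max condition.
#'
#' @param spec a [sim_plate_spec()]. Sample parameters are
#'   `list(b, t, e, h, s)` with `t >= b`, `e > 0`, `h > 0`, `0 < s <= 10`;
#'   control parameters are `list(level)`.
#' @return an [assay_plate()] of kinetic traces plus plate map.
#' @export
sim_luv_plate <- function(spec) {
  stopifnot(inherits(spec, "sim_plate_spec"))
  roles <- vapply(spec$conditions, `[[`, "", "role")
  if (!any(roles == "buffer") || !any(roles == "detergent_max"))
    stop("a LUV plate needs >= 1 buffer and >= 1 detergent_max condition",
         call. = FALSE)
  model <- function(cn, time) {
    if (cn$role %in% c("buffer", "detergent_max")) {
      if (is.null(cn$params$level))
        stop("control condition '", cn$label, "' needs params$level",
             call. = FALSE)
      rep(cn$params$level, length(time))
    } else {
      p <- cn$params
      check_5pl_params(p$b, p$t, p$e, p$h, p$s)
      eval_5pl(time, p$b, p$t, p$e, p$h, p$s)
    }
  }
  with_seed(spec$seed, build_plate(spec, model, "time_s"))
}

check_5pl_params <- function(b, t, e, h, s) {
  if (is.null(b) || is.null(t) || is.null(e) || is.null(h) || is.null(s))
    stop("5PL parameters require b, t, e, h, s", call. = FALSE)
  if (t < b) stop("invalid 5PL parameters: need T >= B", call. = FALSE)
  if (e <= 0) stop("invalid 5PL parameters: need E > 0", call. = FALSE)
  if (h <= 0) stop("invalid 5PL parameters: need H > 0", call. = FALSE)
  if (s <= 0 || s > 10)
    stop("invalid 5PL parameters: need 0 < S <= 10", call. = FALSE)
  invisible(TRUE)
}

#' Rise-then-decay polarization model
#'
#' \eqn{P(t) = P_{free} + A (1 - e^{-k_a t}) e^{-k_d t}}: association of the
#' labeled BH3 peptide onto BAX (rate `k_a`) followed by activation-induced
#' dissociation (rate `k_d`). With `k_d > 0` the noiseless peak time is
#' \eqn{\ln(1 + k_a/k_d)/k_a}; with `k_d = 0` the trace saturates at
#' `p_free + a`.
#'
#' @param time seconds.
#' @param p_free free-peptide polarization baseline (mP).
#' @param a rise amplitude (mP), >= 0.
#' @param k_a association rate (1/s), > 0.
#' @param k_d dissociation rate (1/s), >= 0.
#' @export
eval_rise_decay <- function(time, p_free, a, k_a, k_d) {
  if (a < 0 || k_a <= 0 || k_d < 0)
    stop("invalid rise-decay parameters: need a >= 0, k_a > 0, k_d >= 0",
         call. = FALSE)
  p_free + a * (1 - exp(-k_a * time)) * exp(-k_d * time)
}

#' Simulate a FLAMBE polarization plate
#'
#' `sample` and `vehicle_protein` conditions follow [eval_rise_decay()] with
#' `params = list(p_free, a, k_a, k_d)`; `ligand_only` conditions are flat at
#' `params$p_free` (the free labeled-peptide control).
#'
#' @param spec a [sim_plate_spec()]; noise is in mP units.
#' @return an [assay_plate()] of polarization traces plus plate map.
#' @export
sim_flambe_plate <- function(spec) {
  stopifnot(inherits(spec, "sim_plate_spec"))
  model <- function(cn, time) {
    p <- cn$params
    if (cn$role == "ligand_only") {
      if (is.null(p$p_free))
        stop("ligand_only condition '", cn$label, "' needs params$p_free",
             call. = FALSE)
      rep(p$p_free, length(time))
    } else {
      eval_rise_decay(time, p$p_free, p$a, p$k_a, p$k_d)
    }
  }
  with_seed(spec$seed, build_plate(spec, model, "time_s"))
}

#' Simulate microscale thermophoresis timetraces
#'
#' Each concentration yields one timetrace: flat at `y0` during the pre-IR
#' window (t < 0), then a one-phase decay
#' \eqn{y = (Y_0 - Y_{plateau}) e^{-K t} + Y_{plateau}} once the IR laser
#' switches on at t = 0, plus additive Gaussian noise.
#'
#' @param conc ligand concentrations (uM), one trace each.
#' @param y0,plateau,k decay parameters, recycled along `conc`; `k > 0`.
#' @param t_pre,t_post extent of the pre-IR and heating windows (s).
#' @param dt read interval (s).
#' @param noise_sd additive noise SD (normalized fluorescence counts).
#' @param seed integer RNG seed.
#' @return data frame with columns `time_s`, `fluorescence`,
#'   `concentration_um`.
#' @export
sim_mst_traces <- function(conc, y0, plateau, k, t_pre = 5, t_post = 40,
                           dt = 0.5, noise_sd = 0, seed = 1L) {
  if (any(k <= 0)) stop("decay constant k must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- length(conc)
  y0 <- rep_len(y0, n); plateau <- rep_len(plateau, n); k <- rep_len(k, n)
  time <- seq(-t_pre, t_post, by = dt)
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      mu <- ifelse(time < 0, y0[i],
                   (y0[i] - plateau[i]) * exp(-k[i] * time) + plateau[i])
      data.frame(time_s = time,
                 fluorescence = mu + rnorm(length(time), 0, noise_sd),
                 concentration_um = conc[i])
    })
    do.call(rbind, out)
  })
}

#' Simulate two-state protein melt curves
#'
#' A logistic unfolding transition
#' \eqn{F(T) = F_{low} + (F_{high}-F_{low}) / (1 + e^{-(T - T_m)/w})}
#' whose first derivative is maximal exactly at `tm`, plus additive noise.
#'
#' @param tm melting temperature (degrees C).
#' @param steepness transition width `w` (degrees C), > 0.
#' @param baseline_low,baseline_high folded / unfolded fluorescence levels.
#' @param t_min,t_max,t_step thermal ramp (degrees C).
#' @param n_rep replicate curves.
#' @param noise_sd additive noise SD (fluorescence units).
#' @param seed integer RNG seed.
#' @return data frame with columns `temperature_c`, `fluorescence`,
#'   `replicate`.
#' @export
sim_melt_curves <- function(tm, steepness, baseline_low = 0,
                            baseline_high = 1, t_min = 25, t_max = 95,
                            t_step = 0.5, n_rep = 1, noise_sd = 0,
                            seed = 1L) {
  if (steepness <= 0) stop("steepness must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  temp <- seq(t_min, t_max, by = t_step)
  mu <- baseline_low + (baseline_high - baseline_low) /
    (1 + exp(-(temp - tm) / steepness))
  with_seed(seed, {
    out <- lapply(seq_len(n_rep), function(r)
      data.frame(temperature_c = temp,
                 fluorescence = mu + rnorm(length(temp), 0, noise_sd),
                 replicate = r))
    do.call(rbind, out)
  })
}

#' Simulate paired HSQC peak lists
#'
#' Generates a reference peak list (random but seed-reproducible 1H/15N
#' positions) and a treated list in which designated residues carry injected
#' chemical-shift perturbations; all assigned treated peaks receive Gaussian
#' positional jitter. Prolines have no backbone amide and are unassigned in
#' both lists; `missing_positions` model overlapped/unassignable resonances
#' in the treated spectrum.
#'
#' @param n_residues number of residues (numbered 1..n).
#' @param proline_positions,missing_positions integer residue numbers.
#' @param perturbed data frame with columns `residue_number`, `d_h`, `d_n`
#'   (ppm offsets added to the treated peaks). Perturbed residues must be
#'   measurable: not proline and not missing.
#' @param jitter_sd Gaussian jitter SD (ppm) applied to both dimensions of
#'   every assigned treated peak.
#' @param seed integer RNG seed.
#' @return list with `reference` and `treated` peak-list data frames
#'   (`residue_number`, `residue_name`, `h_ppm`, `n_ppm`, `assigned`).
#' @export
sim_hsqc_peaklists <- function(n_residues, proline_positions = integer(),
                               missing_positions = integer(),
                               perturbed = NULL, jitter_sd = 0, seed = 1L) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (!is.null(perturbed)) {
    bad <- intersect(perturbed$residue_number,
                     c(proline_positions, missing_positions))
    if (length(bad))
      stop("perturbed residues must not be proline or missing: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(!perturbed$residue_number %in% seq_len(n_residues)))
      stop("perturbed residue numbers outside 1..n_residues", call. = FALSE)
  }
  aa <- c("ALA", "GLY", "LEU", "VAL", "SER", "THR", "PHE", "LYS", "ASP",
          "GLU", "ILE", "MET", "TRP", "ARG", "GLN")
  with_seed(seed, {
    res <- seq_len(n_residues)
    name <- sample(aa, n_residues, replace = TRUE)
    name[proline_positions] <- "PRO"
    h <- runif(n_residues, 7, 9.5)
    n15 <- runif(n_residues, 105, 130)
    assigned_ref <- !(res %in% proline_positions)
    reference <- data.frame(residue_number = res, residue_name = name,
                            h_ppm = ifelse(assigned_ref, h, NA_real_),
                            n_ppm = ifelse(assigned_ref, n15, NA_real_),
                            assigned = assigned_ref)
    assigned_tr <- assigned_ref & !(res %in% missing_positions)
    dh <- dn <- numeric(n_residues)
    if (!is.null(perturbed)) {
      dh[perturbed$residue_number] <- perturbed$d_h
      dn[perturbed$residue_number] <- perturbed$d_n
    }
    jit_h <- rnorm(n_residues, 0, jitter_sd)
    jit_n <- rnorm(n_residues, 0, jitter_sd)
    treated <- data.frame(residue_number = res, residue_name = name,
                          h_ppm = ifelse(assigned_tr, h + dh + jit_h,
                                         NA_real_),
                          n_ppm = ifelse(assigned_tr, n15 + dn + jit_n,
                                         NA_real_),
                          assigned = assigned_tr)
    list(reference = reference, treated = treated)
  })
}

#' Simulate an endpoint dose matrix with injected Bliss excess
#'
#' Builds a two-compound response matrix whose combination cells equal the
#' Bliss independence expectation of the monotherapy margins plus a constant
#' injected excess, then adds Gaussian noise. Fractional responses; the
#' double-vehicle cell is 0.
#'
#' @param doses_a,doses_b dose grids including 0 (ascending).
#' @param mono_a,mono_b monotherapy fractional responses at the non-zero
#'   doses of each compound (lengths `length(doses_a) - 1` etc.).
#' @param excess constant Bliss excess injected into every combination cell.
#' @param noise_sd additive Gaussian noise SD (fraction scale) applied to
#'   every cell.
#' @param seed integer RNG seed.
#' @return a [dose_matrix()].
#' @export
sim_dose_matrix <- function(doses_a, doses_b, mono_a, mono_b, excess = 0,
                            noise_sd = 0, seed = 1L) {
  if (doses_a[1] != 0 || doses_b[1] != 0)
    stop("dose grids must start at 0 (vehicle)", call. = FALSE)
  if (length(mono_a) != length(doses_a) - 1 ||
      length(mono_b) != length(doses_b) - 1)
    stop("monotherapy responses must match the non-zero doses", call. = FALSE)
  a <- c(0, mono_a); b <- c(0, mono_b)
  resp <- outer(a, b, function(x, y) x + y - x * y)
  resp[-1, -1] <- resp[-1, -1] + excess
  if (noise_sd > 0)
    resp <- with_seed(seed,
                      resp + matrix(rnorm(length(resp), 0, noise_sd),
                                    nrow(resp), ncol(resp)))
  dose_matrix(doses_a, doses_b, resp)
}
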