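#' Equivalent uniform dose (generalized power mean)
#'
#' `EUD = (sum_i v_i d_i^a)^(1/a)` over the dose distribution within a
#' structure. For targets a negative exponent (default convention `a = -8`)
#' makes the EUD cold-spot sensitive: a single under-dosed voxel pulls the
#' EUD down sharply, which is the mechanism coupling under-contouring to
#' tumour-control loss. Doses below `eps_gy` are clamped to `eps_gy` when
#' `a < 0`, since `d^a` diverges at 0.
#'
#' @param voxel_doses_gy nonnegative voxel doses in Gy.
#' @param volumes_frac fractional volumes summing to 1; default equal
#'   weights.
#' @param a_exponent nonzero power-mean exponent (`a = 0`, the geometric
#'   mean limit, is not part of this model and raises an error).
#' @param eps_gy cold-voxel clamp applied when `a < 0` (default 0.01 Gy).
#' @return EUD in Gy, always within `[min(dose), max(dose)]`.
#' @export
eud <- function(voxel_doses_gy, volumes_frac = NULL, a_exponent = -8,
                eps_gy = 0.01) {
  if (a_exponent == 0) stop("a = 0 (geometric-mean limit) is not supported")
  if (any(voxel_doses_gy < 0)) stop("doses must be nonnegative")
  n <- length(voxel_doses_gy)
  if (is.null(volumes_frac)) volumes_frac <- rep(1 / n, n)
  if (length(volumes_frac) != n) stop("volumes and doses differ in length")
  if (abs(sum(volumes_frac) - 1) > 1e-9)
    stop("volume fractions must sum to 1")
  d <- voxel_doses_gy
  if (a_exponent < 0) d <- pmax(d, eps_gy)
  # accumulate in log space relative to max dose for numerical stability at
  # large |a|
  dmax <- max(d)
  s <- sum(volumes_frac * (d / dmax)^a_exponent)
  dmax * s^(1 / a_exponent)
}

#' Tumour control probability (logistic dose-response in EUD)
#'
#' `TCP = 1 / (1 + (TCD50 / EUD)^(4 gamma50))`: TCD50 is the dose giving 50%
#' control and gamma50 the normalized slope at that point, so
#' `TCP(EUD = TCD50) = 0.5` exactly for any slope. Default parameters are
#' the Okunieff nasopharynx fit: TCD50 = 61.69 Gy, gamma50 = 3.38 (with the
#' target EUD exponent a = -8).
#'
#' @param eud_gy equivalent uniform dose in Gy (> 0).
#' @param tcd50_gy dose at 50% control probability.
#' @param gamma50 normalized slope at TCD50; the exponent is `4 * gamma50`.
#' @return TCP in (0, 1), strictly increasing in EUD.
#' @export
tcp <- function(eud_gy, tcd50_gy = 61.69, gamma50 = 3.38) {
  if (any(eud_gy <= 0)) stop("EUD must be positive")
  1 / (1 + (tcd50_gy / eud_gy)^(4 * gamma50))
}

#' Normal tissue complication probability (modified linear-quadratic model)
#'
#' `NTCP(D, V) = exp[ -N0 V^(-k) exp(-alpha D Gamma) ]` with the
#' fractionation factor `Gamma = 1 + d_f / (alpha/beta)` where
#' `d_f = D / n_fractions` is the dose per fraction (the standard LQ
#' correction; `gamma_mode = "total_dose"` instead uses
#' `Gamma = 1 + D / (alpha/beta)`). `D` is the organ's class-appropriate
#' summary dose (serial: Dmax or D1cc; parallel: Dmean or D1cc) and `V` the
#' relative irradiated volume (1 under the uniform-summary convention).
#' `N0 = 0` would force NTCP = 1 at any dose and is rejected.
#'
#' @param dose_gy summary dose D in Gy (>= 0).
#' @param rel_volume relative irradiated volume V in (0, 1].
#' @param n0 positive tissue-specific scale parameter (functional-subunit /
#'   clonogen number analogue).
#' @param k nonnegative volume-effect exponent (0: no volume effect).
#' @param alpha lethal-damage coefficient per Gy (> 0).
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @param n_fractions number of treatment fractions (default 33).
#' @param gamma_mode fractionation convention, see above.
#' @return NTCP in (0, 1], nondecreasing in `dose_gy`.
#' @export
ntcp <- function(dose_gy, rel_volume = 1, n0, k = 0, alpha, alpha_beta,
                 n_fractions = 33,
                 gamma_mode = c("per_fraction", "total_dose")) {
  gamma_mode <- match.arg(gamma_mode)
  if (any(dose_gy < 0)) stop("dose must be nonnegative")
  if (rel_volume <= 0 || rel_volume > 1)
    stop("relative volume must be in (0, 1]")
  if (n0 <= 0) stop("n0 must be positive (n0 = 0 degenerates to NTCP = 1)")
  if (k < 0 || alpha <= 0 || alpha_beta <= 0 || n_fractions < 1)
    stop("invalid radiobiological parameters")
  gam <- switch(gamma_mode,
                per_fraction = 1 + (dose_gy / n_fractions) / alpha_beta,
                total_dose = 1 + dose_gy / alpha_beta)
  exp(-n0 * rel_volume^(-k) * exp(-alpha * dose_gy * gam))
}

#' Default radiobiological parameter set
#'
#' Target parameters are the published nasopharynx logistic-TCP fit
#' (TCD50 = 61.69 Gy, gamma50 = 3.38, a = -8; 33 fractions). The per-organ
#' NTCP parameters shipped here are a synthetic placeholder set with
#' plausible serial/parallel behaviour — they are configuration defaults to
#' be replaced by institution-specific fits, not published organ fits.
#'
#' @return named list: per structure label either
#'   `list(model = "tcp", tcd50_gy, gamma50, a_exponent)` or
#'   `list(model = "ntcp", n0, k, alpha, alpha_beta, n_fractions, summary)`.
#' @export
radiobio_params <- function() {
  list(
    PTVnx = list(model = "tcp", tcd50_gy = 61.69, gamma50 = 3.38,
                 a_exponent = -8),
    SpinalCord = list(model = "ntcp", n0 = 1e6, k = 0.1, alpha = 0.25,
                      alpha_beta = 2, n_fractions = 33, summary = "dmax"),
    OpticNerve_L = list(model = "ntcp", n0 = 1e4, k = 0.1, alpha = 0.25,
                        alpha_beta = 3, n_fractions = 33, summary = "dmax"),
    OpticNerve_R = list(model = "ntcp", n0 = 1e4, k = 0.1, alpha = 0.25,
                        alpha_beta = 3, n_fractions = 33, summary = "dmax"),
    Parotid_L = list(model = "ntcp", n0 = 100, k = 0.2, alpha = 0.08,
                     alpha_beta = 3, n_fractions = 33, summary = "dmean"),
    Parotid_R = list(model = "ntcp", n0 = 100, k = 0.2, alpha = 0.08,
                     alpha_beta = 3, n_fractions = 33, summary = "dmean"))
}

#' Per-plan radiobiological endpoints on the gold-standard anatomy
#'
#' For the target: EUD over the exact voxel doses within the gold-standard
#' PTV and the logistic TCP. For each OAR: the class-appropriate summary
#' dose and the modified linear-quadratic NTCP.
#'
#' @param dose a [dose_grid()] (one observer's plan, or the standard plan).
#' @param standard_set gold-standard [structure_set()] (must contain every
#'   parametrised label).
#' @param params parameter list as from [radiobio_params()].
#' @param gamma_mode passed to [ntcp()].
#' @return data.frame: `structure_label`, `model`, `summary_dose_gy`,
#'   `eud_gy` (targets), `probability` (TCP or NTCP).
#' @export
plan_endpoints <- function(dose, standard_set, params = radiobio_params(),
                           gamma_mode = "per_fraction") {
  rows <- lapply(names(params), function(label) {
    prm <- params[[label]]
    mask <- standard_set$masks[[label]]
    if (is.null(mask)) stop("structure '", label, "' missing from the set")
    if (identical(prm$model, "tcp")) {
      e <- eud(structure_doses(dose, mask), a_exponent = prm$a_exponent)
      data.frame(structure_label = label, model = "tcp",
                 summary_dose_gy = NA_real_, eud_gy = e,
                 probability = tcp(e, prm$tcd50_gy, prm$gamma50),
                 stringsAsFactors = FALSE)
    } else {
      cls <- if (identical(prm$summary, "dmean")) "parallel" else "serial"
      ds <- dose_summary(dose, mask, cls)
      dsum <- switch(prm$summary, dmax = ds$Dmax_gy, dmean = ds$Dmean_gy,
                     d1cc = ds$D1cc_gy)
      data.frame(structure_label = label, model = "ntcp",
                 summary_dose_gy = dsum, eud_gy = NA_real_,
                 probability = ntcp(dsum, 1, prm$n0, prm$k, prm$alpha,
                                    prm$alpha_beta, prm$n_fractions,
                                    gamma_mode),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Endpoint differences between an observer plan and the standard plan
#'
#' `dTCP = 100 x (TCP_observer - TCP_standard)` in percentage points, and
#' analogously `dNTCP`, matched by structure label.
#'
#' @param observer_endpoints,standard_endpoints data.frames from
#'   [plan_endpoints()].
#' @param observer_id,patient_id identifiers for the emitted rows.
#' @return data.frame of metric records (`dTCP` / `dNTCP` rows, one per
#'   parametrised structure).
#' @export
endpoint_deltas <- function(observer_endpoints, standard_endpoints,
                            observer_id = "observer",
                            patient_id = "patient") {
  if (!setequal(observer_endpoints$structure_label,
                standard_endpoints$structure_label)) {
    mism <- c(setdiff(observer_endpoints$structure_label,
                      standard_endpoints$structure_label),
              setdiff(standard_endpoints$structure_label,
                      observer_endpoints$structure_label))
    stop("unmatched structure labels: ", paste(mism, collapse = ", "))
  }
  std <- standard_endpoints[match(observer_endpoints$structure_label,
                                  standard_endpoints$structure_label), ]
  rows <- lapply(seq_len(nrow(observer_endpoints)), function(i) {
    name <- if (identical(observer_endpoints$model[i], "tcp")) "dTCP" else "dNTCP"
    metric_record(patient_id, observer_id,
                  observer_endpoints$structure_label[i], name,
                  100 * (observer_endpoints$probability[i] -
                           std$probability[i]))
  })
  do.call(rbind, rows)
}
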