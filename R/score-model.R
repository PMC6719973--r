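# Score model: weights, geometry tolerances and unit conversions of the
# five-term empirical binding free-energy function
#
#   dG_binding = dG0 + dG_polar + dG_apolar + dG_solv + dG_flexi   [kcal/mol]
#
# and its conversion to the dimensionless affinity score
#
#   score = -100 * dG / (ln(10) * R * T) = -100 * log10(Ki).
#
# Default weights are LUDI-style literature values in kcal/mol; the paper
# behind this pipeline names the five terms but prints no weights, so all of
# them are configuration, not constants.

# CODATA gas constant in kcal mol^-1 K^-1.
#' @keywords internal
GAS_CONSTANT_KCAL <- 1.9872041e-3

#' Empirical binding score model
#'
#' Bundles every tunable of the scoring function. Favourable interaction
#' weights (`w_hbond`, `w_ionic`, `w_lipo`, `w_aromatic`) are negative
#' (kcal/mol per ideal contact, or per A^2 for `w_lipo`); penalties
#' (`w_solv` per A^2 buried uncompensated polar surface, `w_rot` per
#' rotatable bond) are positive. Hydrogen-bond geometry is scored with a
#' piecewise-linear penalty: full weight within `dR_tol` of `R_ideal`
#' (`dA_tol` of the ideal donor angle), falling linearly to zero at
#' `dR_max` (`dA_max`).
#'
#' @param dG0 constant term, kcal/mol.
#' @param w_hbond,w_ionic weight per ideal neutral / ionic polar contact.
#' @param w_lipo weight per A^2 lipophilic contact area.
#' @param w_aromatic weight per stacked aromatic ring pair.
#' @param w_solv desolvation penalty per A^2 buried uncompensated polar area.
#' @param w_rot penalty per side-chain rotatable bond.
#' @param R_ideal ideal donor-acceptor heavy-atom distance, A.
#' @param dR_tol,dR_max distance-penalty knots, A.
#' @param dA_tol,dA_max donor-angle-penalty knots, degrees.
#' @param aromatic_cutoff ring-centroid distance counting a stacked pair, A.
#' @param probe solvent probe radius for surface areas, A.
#' @param n_sphere_points surface sample points per atom.
#' @param temperature Kelvin.
#' @param clash_tolerance allowed vdW overlap for rotamer feasibility, A.
#' @return object of class `score_model`.
#' @export
#' @examples
#' m <- score_model()
#' dg_to_score(-10, m)
score_model <- function(dG0 = 1.29, w_hbond = -1.12, w_ionic = -1.98,
                        w_lipo = -0.0406, w_aromatic = -0.17,
                        w_solv = 0.01, w_rot = 0.335,
                        R_ideal = 2.9, dR_tol = 0.2, dR_max = 0.6,
                        dA_tol = 30, dA_max = 80,
                        aromatic_cutoff = 5.0, probe = 1.4,
                        n_sphere_points = 240L, temperature = 298,
                        clash_tolerance = 0.4) {
  m <- list(dG0 = dG0, w_hbond = w_hbond, w_ionic = w_ionic,
            w_lipo = w_lipo, w_aromatic = w_aromatic, w_solv = w_solv,
            w_rot = w_rot, R_ideal = R_ideal, dR_tol = dR_tol,
            dR_max = dR_max, dA_tol = dA_tol, dA_max = dA_max,
            aromatic_cutoff = aromatic_cutoff, probe = probe,
            n_sphere_points = as.integer(n_sphere_points),
            temperature = temperature, clash_tolerance = clash_tolerance)
  if (any(c(m$w_hbond, m$w_ionic, m$w_lipo) > 0))
    stop("interaction weights w_hbond, w_ionic, w_lipo must be <= 0")
  if (m$w_rot < 0 || m$w_solv < 0)
    stop("penalty weights w_rot, w_solv must be >= 0")
  if (m$dR_tol >= m$dR_max || m$dA_tol >= m$dA_max)
    stop("penalty knots must satisfy tol < max")
  if (m$temperature <= 0) stop("temperature must be positive")
  structure(m, class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model> dG0=", x$dG0, " w_hbond=", x$w_hbond,
      " w_ionic=", x$w_ionic, " w_lipo=", x$w_lipo, "/A^2",
      " w_aromatic=", x$w_aromatic, " w_solv=", x$w_solv, "/A^2",
      " w_rot=", x$w_rot, " T=", x$temperature, "K\n", sep = "")
  invisible(x)
}

#' Read a score model from a JSON config file
#'
#' Keys are the arguments of [score_model()]; missing keys keep defaults.
#'
#' @param path JSON file path.
#' @return a `score_model`.
#' @export
score_model_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(score_model))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown score-model key(s): ", paste(bad, collapse = ", "))
  do.call(score_model, cfg)
}

#' Free energy to affinity-score conversion coefficient
#'
#' The factor `100 / (ln(10) * R * T)` linking a binding free energy in
#' kcal/mol to the dimensionless score `-100 log10(Ki)`. At T = 298 K it is
#' 73.34 (the conventional printed value 73.33 arises from the textbook
#' truncation ln(10) = 2.303).
#'
#' @param temperature Kelvin.
#' @return numeric scalar, (kcal/mol)^-1.
#' @export
#' @examples
#' score_coefficient(298)
score_coefficient <- function(temperature = 298) {
  100 / (log(10) * GAS_CONSTANT_KCAL * temperature)
}

#' Convert a binding free energy to the affinity score
#'
#' `score = -coef(T) * dG`, so favourable (negative) free energies give
#' positive scores. The score is self-consistently `-100 log10(Ki)`.
#'
#' @param dG binding free energy, kcal/mol (vectorized).
#' @param model a [score_model()] (supplies the temperature).
#' @return dimensionless score.
#' @export
dg_to_score <- function(dG, model = score_model()) {
  -score_coefficient(model$temperature) * dG
}

#' Convert an affinity score to a dissociation constant
#'
#' `Ki = 10^(-score/100)` (molar), the self-consistent inverse of
#' `score = -100 log10(Ki)`: higher score means tighter binding. (The sign
#' convention is documented rather than inherited: the two printed formulas
#' `score = -73.33 dG` and `score = 100 log Ki` are mutually inconsistent
#' for sub-molar Ki.)
#'
#' @param score dimensionless score (vectorized).
#' @param model a [score_model()] (unused beyond interface symmetry).
#' @return Ki in mol/L.
#' @export
#' @examples
#' score_to_ki(300)  # 1e-3 M
score_to_ki <- function(score, model = score_model()) {
  10^(-score / 100)
}
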