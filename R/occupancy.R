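#' Cargo geometry
#'
#' Geometry of a spherical membrane-bound cargo: its diameter, the
#' cargo-microtubule contact area `A_CONTACT` (the membrane patch from which
#' a motor can reach the microtubule), and the lateral diffusion coefficient
#' of membrane proteins.
#'
#' @param diameter Cargo diameter in nm.
#' @param contact_area Contact area in um^2. For a 750-nm phagosome the
#'   working value is 0.08 um^2, about 4% of the surface.
#' @param lipid_diffusion Scalar or range of membrane-protein diffusion
#'   coefficients, um^2/s.
#' @return Object of class `cargo_geometry`.
#' @export
cargo_geometry <- function(diameter = 750, contact_area = 0.08,
                           lipid_diffusion = c(1.4, 10)) {
  .check_scalar(diameter, "diameter", positive = TRUE)
  .check_scalar(contact_area, "contact_area", nonneg = TRUE)
  stopifnot(is.numeric(lipid_diffusion), all(lipid_diffusion > 0))
  surf <- 4 * pi * (diameter / 2000)^2 # um^2
  if (contact_area > surf) {
    stop("contact_area exceeds the total surface area 4*pi*R^2",
         call. = FALSE)
  }
  structure(list(diameter = diameter, contact_area = contact_area,
                 lipid_diffusion = lipid_diffusion, surface_area = surf),
            class = "cargo_geometry")
}

#' Motor species on a cargo
#'
#' @param name Species label, e.g. `"dynein"`.
#' @param direction `"plus"` (kinesin-like) or `"minus"` (dynein-like).
#' @param single_motor_force Unitary stall force, pN.
#' @param k_on,k_off Microtubule attachment / detachment rates, 1/s.
#' @param total_count Total copies of this motor on the whole cargo.
#' @return Object of class `motor_population`.
#' @export
motor_population <- function(name, direction = c("plus", "minus"),
                             single_motor_force, k_on, k_off, total_count) {
  direction <- match.arg(direction)
  .check_scalar(single_motor_force, "single_motor_force", positive = TRUE)
  .check_scalar(k_on, "k_on", nonneg = TRUE)
  .check_scalar(k_off, "k_off", nonneg = TRUE)
  .check_scalar(total_count, "total_count", nonneg = TRUE, integerish = TRUE)
  structure(list(name = name, direction = direction,
                 single_motor_force = single_motor_force,
                 k_on = k_on, k_off = k_off,
                 total_count = as.integer(round(total_count))),
            class = "motor_population")
}

#' Default dynein / kinesin populations for a 750-nm phagosome
#'
#' Dynein: 240 copies, 1.1 pN unitary force, K_ON = 1.6 1/s, K_OFF = 0.27
#' 1/s. Kinesin: 40 copies, 6 pN, K_ON = 5 1/s, K_OFF = 1 1/s.
#'
#' @return A [motor_population()].
#' @export
default_dynein <- function() {
  motor_population("dynein", "minus", single_motor_force = 1.1,
                   k_on = 1.6, k_off = 0.27, total_count = 240L)
}

#' @rdname default_dynein
#' @export
default_kinesin <- function() {
  motor_population("kinesin", "plus", single_motor_force = 6,
                   k_on = 5, k_off = 1, total_count = 40L)
}

#' Binomial occupancy model of the contact zone
#'
#' Motors are distributed uniformly over the cargo surface, so each motor
#' lands in the contact zone independently with probability `p` (the
#' contact fraction). A rapid reversal requires at least
#' `team_threshold_dynein` dyneins *and* `team_threshold_kinesin` kinesins
#' inside the zone simultaneously; the joint probability is the product of
#' two binomial tails (see [joint_reversal_probability()]).
#'
#' @param geometry A [cargo_geometry()].
#' @param dynein,kinesin [motor_population()] objects.
#' @param contact_fraction Success probability `p`; defaults to the working
#'   value 0.04 (approximately [contact_fraction()] of the default
#'   geometry, which gives 0.0453 — both are available, see Details).
#' @param team_threshold_dynein,team_threshold_kinesin Minimum team sizes
#'   (defaults 6 and 1).
#' @details The default `p = 0.04` follows the rounded "4% of the surface"
#'   working value rather than the exact area ratio 0.0453; pass
#'   `contact_fraction = contact_fraction(geometry)` for the geometric
#'   value.
#' @return Object of class `occupancy_model`.
#' @export
occupancy_model <- function(geometry = cargo_geometry(),
                            dynein = default_dynein(),
                            kinesin = default_kinesin(),
                            contact_fraction = 0.04,
                            team_threshold_dynein = 6L,
                            team_threshold_kinesin = 1L) {
  stopifnot(inherits(geometry, "cargo_geometry"),
            inherits(dynein, "motor_population"),
            inherits(kinesin, "motor_population"))
  .check_prob(contact_fraction, "contact_fraction")
  .check_scalar(team_threshold_dynein, "team_threshold_dynein",
                nonneg = TRUE, integerish = TRUE)
  .check_scalar(team_threshold_kinesin, "team_threshold_kinesin",
                nonneg = TRUE, integerish = TRUE)
  if (team_threshold_dynein > dynein$total_count ||
      team_threshold_kinesin > kinesin$total_count) {
    stop("team thresholds cannot exceed the total motor counts",
         call. = FALSE)
  }
  structure(list(geometry = geometry, dynein = dynein, kinesin = kinesin,
                 contact_fraction = contact_fraction,
                 team_threshold_dynein = as.integer(team_threshold_dynein),
                 team_threshold_kinesin = as.integer(team_threshold_kinesin)),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat("<occupancy_model>\n")
  cat(sprintf("  cargo: %g nm, A_contact = %g um^2 (p = %.4g)\n",
              x$geometry$diameter, x$geometry$contact_area,
              x$contact_fraction))
  cat(sprintf("  dynein : N = %d, threshold >= %d\n",
              x$dynein$total_count, x$team_threshold_dynein))
  cat(sprintf("  kinesin: N = %d, threshold >= %d\n",
              x$kinesin$total_count, x$team_threshold_kinesin))
  cat(sprintf("  joint reversal probability = %.4f\n",
              joint_reversal_probability(x)))
  invisible(x)
}

#' Geometric contact fraction
#'
#' Fraction of the cargo surface within reach of the microtubule:
#' `contact_area / (4 pi R^2)`.
#'
#' @param geometry A [cargo_geometry()].
#' @return Fraction in `[0, 1]`.
#' @examples
#' contact_fraction(cargo_geometry(750, 0.08)) # ~0.045
#' @export
contact_fraction <- function(geometry) {
  stopifnot(inherits(geometry, "cargo_geometry"))
  geometry$contact_area / geometry$surface_area
}

#' Scale a motor count between cargo sizes by surface area
#'
#' Motor copy number is assumed proportional to membrane area, so a count
#' measured on a reference cargo scales by `(d_target / d_ref)^2`. Example:
#' 3.5 motors on a 90-nm vesicle scale to 3.5 x (750/90)^2 = 243.1, i.e. 240
#' at two significant figures, on a 750-nm phagosome.
#'
#' @param count_ref Count on the reference cargo.
#' @param diameter_ref,diameter_target Diameters in nm.
#' @return List with the `raw` scaled value and `rounded` (2 significant
#'   figures).
#' @export
scale_motor_count <- function(count_ref, diameter_ref, diameter_target) {
  .check_scalar(count_ref, "count_ref", nonneg = TRUE)
  .check_scalar(diameter_ref, "diameter_ref", positive = TRUE)
  .check_scalar(diameter_target, "diameter_target", positive = TRUE)
  raw <- count_ref * (diameter_target / diameter_ref)^2
  list(raw = raw, rounded = signif(raw, 2))
}

#' Expected number of motors inside the contact zone
#'
#' @param total_count Motors on the whole cargo.
#' @param p Contact fraction.
#' @return List with `raw` (`total_count * p`) and `rounded` (nearest
#'   integer).
#' @examples
#' expected_in_contact(240, 0.04) # 9.6 -> 10
#' @export
expected_in_contact <- function(total_count, p) {
  .check_scalar(total_count, "total_count", nonneg = TRUE)
  .check_prob(p, "p")
  raw <- total_count * p
  list(raw = raw, rounded = round(raw))
}

#' Binomial occupancy probabilities
#'
#' `occupancy_pmf` is the exact probability that exactly `k` of `n` motors
#' lie inside the contact zone; `occupancy_tail` is the probability that at
#' least `m` do, `P(X >= m)`, with `occupancy_tail(n, p, 0) = 1`.
#'
#' @param n Total motors on the cargo.
#' @param p Contact fraction.
#' @param k,m Occupancy count / minimum team size.
#' @return A probability.
#' @export
occupancy_pmf <- function(n, p, k) {
  .check_scalar(n, "n", nonneg = TRUE, integerish = TRUE)
  .check_prob(p, "p")
  .check_scalar(k, "k", nonneg = TRUE, integerish = TRUE)
  if (k > n) stop("'k' cannot exceed 'n'", call. = FALSE)
  stats::dbinom(k, size = n, prob = p)
}

#' @rdname occupancy_pmf
#' @export
occupancy_tail <- function(n, p, m) {
  .check_scalar(n, "n", nonneg = TRUE, integerish = TRUE)
  .check_prob(p, "p")
  .check_scalar(m, "m", nonneg = TRUE, integerish = TRUE)
  if (m > n) stop("'m' cannot exceed 'n'", call. = FALSE)
  if (m == 0) return(1)
  stats::pbinom(m - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Joint probability of a reversal-competent motor configuration
#'
#' Probability that at least `m_D` dyneins *and* at least `m_K` kinesins
#' occupy the contact zone at once, the product of two binomial tails:
#' `P(X_D >= m_D | N_D, p) * P(X_K >= m_K | N_K, p)`. With the defaults
#' (N_D = 240, N_K = 40, p = 0.04, thresholds 6 and 1) this is 0.7406,
#' i.e. 74%: the predicted fraction of rapid reversals.
#'
#' @param model An [occupancy_model()].
#' @return A probability.
#' @export
joint_reversal_probability <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  p <- model$contact_fraction
  occupancy_tail(model$dynein$total_count, p, model$team_threshold_dynein) *
    occupancy_tail(model$kinesin$total_count, p, model$team_threshold_kinesin)
}

#' Kinesin team-size probabilities
#'
#' Splits the kinesin occupancy distribution into zero, exactly one, and
#' more than one kinesin inside the contact zone. With `n = 40`, `p = 0.04`
#' this gives 0.195 / 0.326 / 0.479 (printed as 20% / 32% / 48%), matching
#' the observed ~40/60 single/multi-kinesin stall-force split once
#' conditioned on at least one kinesin.
#'
#' @param n Total kinesins on the cargo.
#' @param p Contact fraction.
#' @return Named list `P_0K`, `P_1K`, `P_gt1K`; the three sum to 1.
#' @export
kinesin_team_probabilities <- function(n, p) {
  p0 <- occupancy_pmf(n, p, 0L)
  p1 <- if (n >= 1) occupancy_pmf(n, p, 1L) else 0
  list(P_0K = p0, P_1K = p1, P_gt1K = 1 - p0 - p1)
}

#' Residence time of a diffusing membrane protein in the contact zone
#'
#' Mean time a protein diffusing with coefficient `D` spends inside a patch
#' of area `A`: `T ~ A / (4 D)`. For `A = 0.08` um^2 this ranges from 2 ms
#' (`D = 10` um^2/s) to ~14 ms (`D = 1.4` um^2/s) — much shorter than the
#' ~1 s duration of a stall, so lateral diffusion does not bias averaged
#' stall forces.
#'
#' @param contact_area Patch area, um^2.
#' @param D Diffusion coefficient, um^2/s.
#' @param unit `"s"` (default) or `"ms"`.
#' @return Residence time in the requested unit.
#' @export
lipid_residence_time <- function(contact_area, D, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  .check_scalar(contact_area, "contact_area", nonneg = TRUE)
  .check_scalar(D, "D", positive = TRUE)
  t_s <- contact_area / (4 * D)
  if (unit == "ms") t_s * 1000 else t_s
}

#' RMS rotation of a trapped sphere by rotational diffusion
#'
#' Root-mean-square rotation angle accumulated in `duration` seconds,
#' `sqrt(2 D_rot t)` with `D_rot = k_B T / (8 pi eta R^3)`. Used to bound
#' how far a cargo can rotate during a millisecond-scale fly-back (about a
#' degree for a 750-nm sphere in water), which is why the same contact-zone
#' motors still face the microtubule after a reversal.
#'
#' @param diameter Sphere diameter, nm.
#' @param viscosity Medium viscosity, Pa s (water ~1e-3).
#' @param temperature Temperature, K.
#' @param duration Interval, s.
#' @return RMS angle in degrees.
#' @export
rotational_rms_angle <- function(diameter, viscosity = 1e-3,
                                 temperature = 295, duration) {
  .check_scalar(diameter, "diameter", positive = TRUE)
  .check_scalar(viscosity, "viscosity", positive = TRUE)
  .check_scalar(temperature, "temperature", positive = TRUE)
  .check_scalar(duration, "duration", nonneg = TRUE)
  R <- diameter / 2
  eta <- viscosity * .pa_s_to_pn_s_nm2  # pN s / nm^2
  d_rot <- kbt(temperature) / (8 * pi * eta * R^3) # rad^2 / s
  sqrt(2 * d_rot * duration) * 180 / pi
}
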