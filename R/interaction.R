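#' Two-agent interaction index
#'
#' Combines two potency-normalized agent levels into a single interaction
#' index `I = Un_A + Un_B + sigma * Un_A * Un_B`. The bilinear term encodes
#' synergy: `sigma = 0` is plain additivity of normalized levels, larger
#' `sigma` bends the iso-effect contours (isoboles) inward.
#'
#' @param un_a,un_b nonnegative normalized levels (level / its C50).
#' @param sigma nonnegative synergy coefficient.
#' @return The interaction index, same length as the inputs (recycled).
#' @examples
#' interaction_index(1, 1, 4)  # 6
#' @export
interaction_index <- function(un_a, un_b, sigma) {
  if (any(un_a < 0) || any(un_b < 0))
    stop("interaction_index: normalized levels must be >= 0")
  if (any(sigma < 0)) stop("interaction_index: sigma must be >= 0")
  un_a + un_b + sigma * un_a * un_b
}

#' Hill dose-effect surface
#'
#' Sigmoid effect of an interaction index, `emax * I^gamma / (1 + I^gamma)`.
#' At `I = 1` (agents jointly at their half-effect potency) the effect is
#' `emax / 2` for every `gamma`; at `I = 0` the effect is 0.
#'
#' @param i nonnegative interaction index (vectorized).
#' @param gamma positive sigmoidicity exponent; interpreted as patient
#'   responsiveness / drug resistance.
#' @param emax maximum effect, a fraction in `[0, 1]`.
#' @return Effect fraction in `[0, emax]`.
#' @examples
#' hill_surface(1, 2.5, 1)   # 0.5
#' hill_surface(0, 2.5, 0.7) # 0
#' @export
hill_surface <- function(i, gamma, emax = 1) {
  if (any(i < 0)) stop("hill_surface: index must be >= 0")
  if (gamma <= 0) stop("hill_surface: gamma must be > 0")
  if (emax < 0 || emax > 1) stop("hill_surface: emax must lie in [0, 1]")
  ig <- i^gamma
  out <- emax * ig / (1 + ig)
  # i^gamma overflows for huge indices; the surface saturates at emax there
  out[!is.finite(ig) & i > 0] <- emax
  out[i == 0] <- 0
  out
}

#' Potency-normalized agent levels
#'
#' Normalizes the current model state to half-effect potencies: the tumor
#' level as percent of initial volume over `C50_t`, and each effect-site
#' drug level over its `C50`. The radiotherapy states carry Gy/day-equivalent
#' units throughout, so dividing by `C50_r` (Gy/day) absorbs the physical
#' Gy-to-model-unit conversion.
#'
#' @param state named state vector with fields
#'   `x1, x2, x3, xe3, x4, xe4, x5, xe5` (see [simulate_combined()]).
#' @param params a [combined_parameters()] object.
#' @return Named list with elements `tumor`, `AG`, `IM`, `RT`.
#' @export
normalize_levels <- function(state, params) {
  state <- as_state_vector(state)
  list(
    tumor = (100 * state[["x1"]] / params$V0) / params$C50_t,
    AG    = state[["xe3"]] / params$C50_a,
    IM    = state[["xe4"]] / params$C50_i,
    RT    = state[["xe5"]] / params$C50_r
  )
}

#' Combined treatment effect and its pairwise breakdown
#'
#' Evaluates the six pairwise Hill interaction surfaces at the current state
#' and aggregates them into the dimensionless combined effect `E` (converted
#' to a kill rate downstream via `unit_rate`).
#'
#' Tumor-drug components: the full surface value over the (tumor, drug) pair
#' with the drug's `Emax`, reported as `uptake_a`, `uptake_i`, `uptake_r`,
#' modulates the serum-to-effect-site transfer in the PK chain. The kill
#' components `Et_a`, `Et_i`, `Et_r` are the drug-attributable excess of
#' that surface over its drug-free section, `Emax * (H(I(Un_t, Un_d)) -
#' H(Un_t))`, so that an untreated tumor experiences no treatment effect.
#'
#' Drug-drug components `E_ai`, `E_ar`, `E_ir` quantify the interaction
#' among drugs as the effect beyond additivity of normalized levels,
#' `meanEmax * (H(I(Un_A, Un_B)) - H(Un_A + Un_B))`, with the pair's `Emax`
#' taken as the arithmetic mean of the two drugs' maxima. Both choices leave
#' every component in `[0, 1]`, vanish without treatment, and are
#' nondecreasing in `sigma`.
#'
#' Aggregation: `Et_all` and `Ed_all` are the means of the tumor-drug and
#' drug-drug components and `E = (Et_all + Ed_all) / 2`.
#'
#' @inheritParams normalize_levels
#' @return An object of class `effect_breakdown`: a named list with the
#'   normalized levels (`un`), uptake surfaces, kill components, `Et_all`,
#'   `Ed_all` and `E`.
#' @export
combined_effect <- function(state, params) {
  un <- normalize_levels(state, params)
  g <- params$gamma; s <- params$sigma
  H <- function(i) hill_surface(i, g, 1)

  h_t  <- H(un$tumor)
  s_ta <- params$Emax_a * H(interaction_index(un$tumor, un$AG, s))
  s_ti <- params$Emax_i * H(interaction_index(un$tumor, un$IM, s))
  s_tr <- params$Emax_r * H(interaction_index(un$tumor, un$RT, s))

  et_a <- s_ta - params$Emax_a * h_t
  et_i <- s_ti - params$Emax_i * h_t
  et_r <- s_tr - params$Emax_r * h_t

  dd <- function(ua, ub, em1, em2)
    (em1 + em2) / 2 * (H(interaction_index(ua, ub, s)) - H(ua + ub))
  e_ai <- dd(un$AG, un$IM, params$Emax_a, params$Emax_i)
  e_ar <- dd(un$AG, un$RT, params$Emax_a, params$Emax_r)
  e_ir <- dd(un$IM, un$RT, params$Emax_i, params$Emax_r)

  # numeric guard: the excesses are >= 0 analytically, clamp rounding dust
  cl <- function(x) min(max(x, 0), 1)
  et_a <- cl(et_a); et_i <- cl(et_i); et_r <- cl(et_r)
  e_ai <- cl(e_ai); e_ar <- cl(e_ar); e_ir <- cl(e_ir)

  et_all <- (et_a + et_i + et_r) / 3
  ed_all <- (e_ai + e_ar + e_ir) / 3
  structure(list(
    un = un,
    uptake_a = s_ta, uptake_i = s_ti, uptake_r = s_tr,
    Et_a = et_a, Et_i = et_i, Et_r = et_r,
    E_ai = e_ai, E_ar = e_ar, E_ir = e_ir,
    Et_all = et_all, Ed_all = ed_all,
    E = (et_all + ed_all) / 2
  ), class = "effect_breakdown")
}

#' @export
print.effect_breakdown <- function(x, ...) {
  cat(sprintf("Effect breakdown: E = %.4f (Et_all %.4f, Ed_all %.4f)\n",
              x$E, x$Et_all, x$Ed_all))
  cat(sprintf("  tumor-drug kill: AG %.4f  IM %.4f  RT %.4f\n", x$Et_a, x$Et_i, x$Et_r))
  cat(sprintf("  drug-drug:       AI %.4f  AR %.4f  IR %.4f\n", x$E_ai, x$E_ar, x$E_ir))
  invisible(x)
}

#' Grid evaluation of a two-agent Hill surface
#'
#' Evaluates the Hill surface over a grid of normalized levels, for isobole
#' plotting or CSV export.
#'
#' @param un_a,un_b numeric vectors of normalized levels spanning the grid.
#' @param sigma synergy coefficient.
#' @param gamma sigmoidicity exponent.
#' @param emax maximum effect.
#' @return A data.frame with columns `Un_A`, `Un_B`, `Effect`.
#' @export
surface_grid <- function(un_a = seq(0, 2, by = 0.1), un_b = seq(0, 2, by = 0.1),
                         sigma = 4, gamma = 2.5, emax = 1) {
  g <- expand.grid(Un_A = un_a, Un_B = un_b, KEEP.OUT.ATTRS = FALSE)
  g$Effect <- hill_surface(interaction_index(g$Un_A, g$Un_B, sigma), gamma, emax)
  g
}
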