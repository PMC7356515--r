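#' Model coefficients for the combined-therapy PKPD model
#'
#' Builds the full coefficient set of the eight-state combined model:
#' growth/necrosis rates, per-channel clearance rates, half-effect levels
#' (potencies), maximum efficacies, the synergy coefficient `sigma`, the
#' patient-response exponent `gamma`, the initial tumor volume `V0`, and the
#' conversion factor `unit_rate` that turns the dimensionless combined effect
#' into a kill rate. Called with no arguments it returns the default mouse
#' coefficient set; any field can be overridden by name.
#'
#' Units: `a`, `n`, `c_a`, `c_i`, `c_r`, `unit_rate` in 1/day; `C50_a`,
#' `C50_i` in mg/mL; `C50_r` in Gy/day; `C50_t` in percent of initial volume;
#' `Emax_*` as fractions in `[0, 1]`; `gamma`, `sigma` dimensionless; `V0` in
#' mm^3. The immunotherapy clearance is a published whole-body clearance of
#' 11.6 mL/day interpreted per unit (1 mL) distribution volume, i.e.
#' 11.6/24 per day.
#'
#' @param ... named overrides of individual fields, e.g. `sigma = 8`.
#' @return An object of class `combined_parameters` (a validated named list).
#' @examples
#' p <- combined_parameters()
#' p$a          # 0.25 per day
#' p8 <- combined_parameters(sigma = 8)
#' @export
combined_parameters <- function(...) {
  p <- .combined_defaults()
  p <- .apply_overrides(p, list(...), "combined_parameters")
  validate_combined_parameters(p)
}

.combined_defaults <- function() {
  structure(list(
    a         = 0.25,
    n         = 0.10,
    c_a       = 0.1825,
    c_i       = 11.6 / 24,
    c_r       = 3 / 24,
    C50_a     = 0.44,
    C50_i     = 32e-6,
    C50_r     = 20,
    C50_t     = 50,
    Emax_a    = 0.70,
    Emax_i    = 0.43,
    Emax_r    = 0.50,
    gamma     = 2.5,
    sigma     = 4,
    V0        = 1000,
    unit_rate = 1.0
  ), class = "combined_parameters")
}

#' Default combined-model coefficients
#'
#' Convenience wrapper equal to `combined_parameters()` with no overrides.
#'
#' @return A `combined_parameters` object with the default values.
#' @export
default_combined_parameters <- function() combined_parameters()

#' Validate a combined-parameters object
#'
#' Checks the field invariants: rates and `sigma` nonnegative, potencies and
#' `gamma` and `V0` strictly positive, efficacies in `[0, 1]`. Errors name
#' the offending field.
#'
#' @param p a `combined_parameters` object (or plain named list with the
#'   same fields).
#' @return `p`, invisibly classed, if valid.
#' @export
validate_combined_parameters <- function(p) {
  need <- names(.combined_defaults())
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("combined_parameters: missing field(s): ", paste(missing, collapse = ", "))
  for (f in need) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("combined_parameters: field '", f, "' must be a single finite number")
  }
  chk <- function(cond, f, what) if (!cond) stop("combined_parameters: field '", f, "' ", what)
  for (f in c("a", "n", "c_a", "c_i", "c_r", "unit_rate", "sigma"))
    chk(p[[f]] >= 0, f, "must be >= 0")
  for (f in c("C50_a", "C50_i", "C50_r", "C50_t", "gamma", "V0"))
    chk(p[[f]] > 0, f, "must be > 0")
  for (f in c("Emax_a", "Emax_i", "Emax_r"))
    chk(p[[f]] >= 0 && p[[f]] <= 1, f, "must lie in [0, 1]")
  structure(p[need], class = "combined_parameters")
}

#' Coefficients of the single-agent antiangiogenic (Bevacizumab) model
#'
#' Coefficient set of the legacy three-state tumor-growth model under
#' Bevacizumab monotherapy, with saturable (Michaelis-Menten) drug clearance
#' and a saturable inhibition term. Defaults are averaged values identified
#' in mice.
#'
#' Units: `a`, `b_a`, `c_a`, `n_a` in 1/day; `b_ak` in mg/(mL day); `K_Ba`,
#' `ED50_a` in mg/mL.
#'
#' @param ... named overrides of individual fields.
#' @return An object of class `legacy_ag_parameters`.
#' @examples
#' legacy_ag_parameters()$ED50_a   # 5e-05 mg/mL
#' @export
legacy_ag_parameters <- function(...) {
  p <- structure(list(
    a      = 0.4579,
    b_a    = 0.1685,
    c_a    = 0.1825,
    n_a    = 0.1030,
    b_ak   = 1.0839e-6,
    K_Ba   = 0.4409,
    ED50_a = 50e-6
  ), class = "legacy_ag_parameters")
  p <- .apply_overrides(p, list(...), "legacy_ag_parameters")
  for (f in names(p))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] <= 0)
      stop("legacy_ag_parameters: field '", f, "' must be a single positive number")
  p
}

#' @rdname legacy_ag_parameters
#' @export
default_legacy_parameters <- function() legacy_ag_parameters()

.apply_overrides <- function(p, over, what) {
  if (!length(over)) return(p)
  if (is.null(names(over)) || any(!nzchar(names(over))))
    stop(what, ": overrides must be named")
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop(what, ": unknown field(s): ", paste(unknown, collapse = ", "))
  for (f in names(over)) p[[f]] <- over[[f]]
  p
}

#' Load combined-model coefficients from a configuration file
#'
#' Reads a flat key/value document (JSON object, keys a subset of the
#' `combined_parameters` field names) and merges it over the defaults.
#' Unknown keys raise a configuration error; out-of-range values raise a
#' validation error naming the field.
#'
#' @param config path to a JSON file, or a named list of overrides.
#' @return A validated `combined_parameters` object.
#' @seealso [write_parameters()] for the inverse.
#' @export
load_parameters <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("load_parameters: no such file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("load_parameters: config must be a file path or a named list")
  do.call(combined_parameters, config)
}

#' Serialize combined-model coefficients to JSON
#'
#' Writes the parameter set as a flat JSON object so that
#' `load_parameters(path)` round-trips it field-by-field.
#'
#' @param p a `combined_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  p <- validate_combined_parameters(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.combined_parameters <- function(x, ...) {
  cat("Combined-therapy PKPD coefficients\n")
  for (f in names(x)) cat(sprintf("  %-9s %g\n", f, x[[f]]))
  invisible(x)
}

#' @export
print.legacy_ag_parameters <- function(x, ...) {
  cat("Single-agent antiangiogenic model coefficients\n")
  for (f in names(x)) cat(sprintf("  %-7s %g\n", f, x[[f]]))
  invisible(x)
}
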