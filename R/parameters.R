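# Model inputs: rate/probability conversions, age-banded progression
# schedules, and parameter distributions for DSA/PSA.

#' Convert a cumulative incidence to an annual rate
#'
#' Multi-year cumulative incidences reported in the literature are converted
#' to instantaneous annual rates with `r = -log(1 - p) / t`, the standard
#' exponential (constant-hazard) assumption used when populating annual-cycle
#' state-transition models.
#'
#' @param p Cumulative incidence over the interval, in `[0, 1)`.
#' @param t Interval length in years, `> 0`.
#' @return Annual rate (per year, `>= 0`). Vectorised over `p` and `t`.
#' @examples
#' annual_rate_from_cumulative(0.037, 10) # ~0.0038, i.e. 0.38%/year
#' @seealso [prob_from_rate()] for the inverse transform.
#' @export
annual_rate_from_cumulative <- function(p, t) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p >= 1)) {
    stop("`p` must be a cumulative probability in [0, 1); got ",
         paste(format(p), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(t) || anyNA(t) || any(t <= 0)) {
    stop("`t` must be a positive interval length in years; got ",
         paste(format(t), collapse = ", "), call. = FALSE)
  }
  -log1p(-p) / t
}

#' Convert an annual rate to a per-interval probability
#'
#' Inverse of [annual_rate_from_cumulative()]: `p = 1 - exp(-r * t)`, so
#' rate/probability round-trips are exact to machine precision.
#'
#' @param r Annual rate, `>= 0`.
#' @param t Interval length in years, `> 0` (default 1, one model cycle).
#' @return Probability in `[0, 1)`.
#' @export
prob_from_rate <- function(r, t = 1) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0)) {
    stop("`r` must be a non-negative annual rate; got ",
         paste(format(r), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(t) || anyNA(t) || any(t <= 0)) {
    stop("`t` must be a positive interval length in years; got ",
         paste(format(t), collapse = ", "), call. = FALSE)
  }
  -expm1(-r * t)
}

#' Model parameter with an uncertainty description
#'
#' A single numeric model input: a base-case `point` value, the distribution
#' used for probabilistic sensitivity analysis (`beta` parameterised by
#' method of moments from `mean`/`sd`, `normal`, or `fixed`), and an optional
#' stated deterministic-sensitivity range.
#'
#' @param name Identifier.
#' @param kind One of `"beta"`, `"normal"`, `"fixed"`.
#' @param point Base-case value.
#' @param mean,sd Distribution moments (default `mean = point`, `sd = 0`).
#' @param dsa_low,dsa_high Stated one-way sensitivity range; `NULL` if the
#'   range is to be derived as point +/- 10% (see [dsa_range()]).
#' @param domain Legal domain, used for clipping derived DSA ranges; default
#'   `c(0, 1)` (probabilities and utilities). Use e.g. `c(0, Inf)` for costs.
#' @return An object of class `param_dist`.
#' @export
param_dist <- function(name, kind = c("beta", "normal", "fixed"), point,
                       mean = point, sd = 0, dsa_low = NULL, dsa_high = NULL,
                       domain = c(0, 1)) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(point), length(point) == 1L,
            is.numeric(mean), is.numeric(sd), sd >= 0,
            is.numeric(domain), length(domain) == 2L)
  if (kind == "beta") {
    if (point < 0 || point > 1) {
      stop("beta parameter '", name, "': point value ", point,
           " outside [0, 1]", call. = FALSE)
    }
    if (mean <= 0 || mean >= 1) {
      stop("beta parameter '", name, "': mean ", mean,
           " outside (0, 1)", call. = FALSE)
    }
    if (sd > 0 && sd^2 >= mean * (1 - mean)) {
      stop("beta parameter '", name, "': variance infeasible for beta (sd^2 = ",
           format(sd^2), " >= mean(1-mean) = ", format(mean * (1 - mean)), ")",
           call. = FALSE)
    }
  }
  if (!is.null(dsa_low) && !is.null(dsa_high)) {
    if (!(dsa_low <= point && point <= dsa_high)) {
      stop("parameter '", name, "': point ", point,
           " outside stated analysis range [", dsa_low, ", ", dsa_high, "]",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, kind = kind, point = point, mean = mean, sd = sd,
         dsa_low = dsa_low, dsa_high = dsa_high, domain = domain),
    class = "param_dist"
  )
}

#' @export
print.param_dist <- function(x, ...) {
  rng <- if (is.null(x$dsa_low)) "+/-10%" else
    paste0("[", format(x$dsa_low), ", ", format(x$dsa_high), "]")
  cat(sprintf("<param_dist> %s = %s (%s, mean %s, sd %s, DSA %s)\n",
              x$name, format(x$point), x$kind, format(x$mean),
              format(x$sd), rng))
  invisible(x)
}

#' Method-of-moments beta parameterisation
#'
#' Returns the shape parameters of the beta distribution with the requested
#' mean and standard deviation: `nu = mean(1-mean)/sd^2 - 1`,
#' `alpha = mean * nu`, `beta = (1-mean) * nu`.
#'
#' @param mean Target mean, in `(0, 1)`.
#' @param sd Target standard deviation, `> 0` with `sd^2 < mean(1-mean)`.
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @examples
#' beta_params_from_moments(0.5, sqrt(1 / 12)) # alpha = beta = 1, uniform
#' @export
beta_params_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (any(mean <= 0) || any(mean >= 1)) {
    stop("`mean` must lie in (0, 1); got ", paste(format(mean), collapse = ", "),
         call. = FALSE)
  }
  if (any(sd <= 0) || any(sd^2 >= mean * (1 - mean))) {
    stop("variance infeasible for beta: need 0 < sd^2 < mean(1-mean)",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = unname(mean * nu), beta = unname((1 - mean) * nu))
}

#' One-way sensitivity range for a parameter
#'
#' Stated analysis ranges (when present and `use_stated = TRUE`) take
#' precedence; otherwise the range is `point * (1 - fraction, 1 + fraction)`
#' clipped to the parameter's legal domain. The discount rate is special-cased
#' to the conventional 1%-5% band regardless of `fraction`.
#'
#' @param dist A [param_dist()].
#' @param fraction Relative half-width of the derived range (default 0.10).
#' @param use_stated Use the stated `dsa_low`/`dsa_high` when available.
#' @return Numeric vector `c(low, high)`.
#' @export
dsa_range <- function(dist, fraction = 0.10, use_stated = TRUE) {
  stopifnot(inherits(dist, "param_dist"))
  if (dist$name %in% c("discount", "discount_rate")) {
    return(c(low = 0.01, high = 0.05))
  }
  if (use_stated && !is.null(dist$dsa_low) && !is.null(dist$dsa_high)) {
    return(c(low = dist$dsa_low, high = dist$dsa_high))
  }
  lo <- max(dist$point * (1 - fraction), dist$domain[1])
  hi <- min(dist$point * (1 + fraction), dist$domain[2])
  c(low = lo, high = hi)
}

#' Age-banded annual probability schedule
#'
#' Progression risks (nodule growth, nodal metastasis) vary by decade of age.
#' Bands are inclusive integer intervals; they must be contiguous,
#' non-overlapping, and cover at least ages 20-79. Ages above the top band
#' reuse the top band's probability (the cohort ends at the 80-year life
#' expectancy, so this extension only guards the boundary).
#'
#' @param bands `data.frame` with columns `age_low`, `age_high`, `prob`.
#' @param name Identifier (e.g. `"growth"`).
#' @return An object of class `age_schedule`.
#' @export
age_schedule <- function(bands, name = "schedule") {
  stopifnot(is.data.frame(bands),
            all(c("age_low", "age_high", "prob") %in% names(bands)))
  bands <- bands[order(bands$age_low), c("age_low", "age_high", "prob")]
  if (any(bands$age_high < bands$age_low)) {
    stop("age schedule '", name, "': band with age_high < age_low", call. = FALSE)
  }
  if (any(bands$prob < 0 | bands$prob > 1)) {
    stop("age schedule '", name, "': probabilities outside [0, 1]", call. = FALSE)
  }
  if (nrow(bands) > 1L &&
      any(bands$age_low[-1L] != bands$age_high[-nrow(bands)] + 1L)) {
    stop("age schedule '", name, "': bands must be contiguous and non-overlapping",
         call. = FALSE)
  }
  if (bands$age_low[1L] > 20L || bands$age_high[nrow(bands)] < 79L) {
    stop("age schedule '", name, "': bands must cover at least ages 20-79",
         call. = FALSE)
  }
  structure(list(name = name, bands = bands), class = "age_schedule")
}

#' @export
print.age_schedule <- function(x, ...) {
  cat(sprintf("<age_schedule> %s (%d bands, ages %d-%d)\n", x$name,
              nrow(x$bands), x$bands$age_low[1L],
              x$bands$age_high[nrow(x$bands)]))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Look up the annual probability for an age
#'
#' @param schedule An [age_schedule()].
#' @param age Integer age in years.
#' @return The band's annual probability. Band membership is inclusive
#'   (`age_low <= age <= age_high`); ages above the top band carry the top
#'   band forward; ages below the bottom band are an error.
#' @export
lookup_age_prob <- function(schedule, age) {
  stopifnot(inherits(schedule, "age_schedule"), is.numeric(age),
            length(age) == 1L)
  b <- schedule$bands
  if (age < b$age_low[1L]) {
    stop("age ", age, " below schedule '", schedule$name,
         "' (starts at ", b$age_low[1L], "); extend the schedule", call. = FALSE)
  }
  if (age > b$age_high[nrow(b)]) {
    return(b$prob[nrow(b)])
  }
  b$prob[b$age_low <= age & age <= b$age_high]
}

# Index of the band an age falls in (top band for ages beyond it); used to
# cache transition matrices that only change when a band boundary is crossed.
age_band_index <- function(schedule, age) {
  b <- schedule$bands
  if (age > b$age_high[nrow(b)]) return(nrow(b))
  which(b$age_low <= age & age <= b$age_high)
}

#' Assemble a validated parameter set
#'
#' @param probabilities Named list of [param_dist()] (transition probabilities).
#' @param utilities Named list of [param_dist()] (health-state utilities).
#' @param growth_schedule,nodal_schedule [age_schedule()]s for primary tumor
#'   growth and nodal metastasis.
#' @param discount Annual discount rate for both costs and QALYs, in
#'   `[0, 0.05]` (default 0.03).
#' @param meta Optional list of provenance notes (scenario name, load log).
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(probabilities, utilities, growth_schedule,
                          nodal_schedule, discount = 0.03, meta = list()) {
  stopifnot(is.list(probabilities), is.list(utilities),
            inherits(growth_schedule, "age_schedule"),
            inherits(nodal_schedule, "age_schedule"),
            is.numeric(discount), length(discount) == 1L)
  if (discount < 0 || discount > 0.05) {
    stop("discount rate must lie in [0, 0.05]; got ", discount, call. = FALSE)
  }
  for (d in c(probabilities, utilities)) {
    stopifnot(inherits(d, "param_dist"))
    if (d$point < 0 || d$point > 1) {
      stop("parameter '", d$name, "': point value ", d$point,
           " outside [0, 1]", call. = FALSE)
    }
  }
  names(probabilities) <- vapply(probabilities, `[[`, "", "name")
  names(utilities) <- vapply(utilities, `[[`, "", "name")
  structure(
    list(probabilities = probabilities, utilities = utilities,
         growth_schedule = growth_schedule, nodal_schedule = nodal_schedule,
         discount = discount, meta = meta),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "<parameter_set> %s: %d probabilities, %d utilities, discount %.2f\n",
    if (is.null(x$meta$scenario)) "(unnamed)" else x$meta$scenario,
    length(x$probabilities), length(x$utilities), x$discount))
  if (length(x$meta$load_log)) {
    cat("load log:\n")
    cat(paste0("  - ", x$meta$load_log, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Fetch a parameter by name
#'
#' Searches the probability block, then the utility block.
#' @param params A [parameter_set()].
#' @param name Parameter identifier.
#' @return The [param_dist()].
#' @export
get_param <- function(params, name) {
  stopifnot(inherits(params, "parameter_set"))
  if (name %in% names(params$probabilities)) return(params$probabilities[[name]])
  if (name %in% names(params$utilities)) return(params$utilities[[name]])
  stop("unknown parameter '", name, "'", call. = FALSE)
}

#' Replace the working value of a parameter
#'
#' Sets the `point` value (the value the model actually uses) of one
#' parameter, leaving its distribution untouched. Used by the DSA to pin a
#' parameter and by the PSA to install a random draw.
#'
#' @inheritParams get_param
#' @param value New point value.
#' @return The modified `parameter_set`.
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "parameter_set"), is.numeric(value),
            length(value) == 1L)
  if (name %in% names(params$probabilities)) {
    params$probabilities[[name]]$point <- value
  } else if (name %in% names(params$utilities)) {
    params$utilities[[name]]$point <- value
  } else {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  params
}

#' Load a packaged or external parameter file
#'
#' Parameter files are YAML with sections `probabilities`, `utilities`,
#' `age_schedules` (`growth` and `nodal`, decade bands), and `discount`. Two
#' files are packaged:
#' \describe{
#'   \item{`table1_verbatim`}{decade-band values stored exactly as printed in
#'     the source inputs table and used as annual probabilities;}
#'   \item{`text_canonical`}{decade-band values re-interpreted as multi-year
#'     cumulative incidences and converted to annual probabilities via
#'     `r = -log(1-p)/t` (the conversion the source text documents). This is
#'     the default modelling scenario.}
#' }
#' The two interpretations differ by roughly a factor of ten; the conflict is
#' recorded in the returned set's load log, as are utilities whose printed
#' values are implausible for the state they name.
#'
#' @param scenario `"text_canonical"`, `"table1_verbatim"`, or a path to a
#'   parameter YAML file.
#' @param quiet Suppress load-log messages (default `TRUE` inside functions;
#'   set `FALSE` to print the log).
#' @return A [parameter_set()] with `meta$scenario` and `meta$load_log`.
#' @export
load_parameters <- function(scenario = "text_canonical", quiet = TRUE) {
  path <- if (file.exists(scenario)) scenario else
    system.file("extdata", paste0("params_", scenario, ".yaml"),
                package = "ptmcCEA")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown parameter scenario or missing file: '", scenario, "'",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  for (section in c("probabilities", "utilities", "age_schedules")) {
    if (is.null(raw[[section]])) {
      stop("parameter file '", path, "': missing section '", section, "'",
           call. = FALSE)
    }
  }
  mk_block <- function(block, label) {
    out <- lapply(names(block), function(nm) {
      e <- block[[nm]]
      if (is.null(e$point)) {
        stop("parameter file '", path, "': ", label, " '", nm,
             "' has no point value", call. = FALSE)
      }
      param_dist(
        name = nm,
        kind = if (is.null(e$dist)) "fixed" else e$dist,
        point = e$point,
        mean = if (is.null(e$mean)) e$point else e$mean,
        sd = if (is.null(e$sd)) 0 else e$sd,
        dsa_low = if (is.null(e$dsa)) NULL else e$dsa[[1L]],
        dsa_high = if (is.null(e$dsa)) NULL else e$dsa[[2L]]
      )
    })
    names(out) <- names(block)
    out
  }
  mk_schedule <- function(entries, nm) {
    bands <- do.call(rbind, lapply(entries, function(b) {
      data.frame(age_low = b$ages[[1L]], age_high = b$ages[[2L]], prob = b$p)
    }))
    age_schedule(bands, name = nm)
  }
  probs <- mk_block(raw$probabilities, "probability")
  utils_ <- mk_block(raw$utilities, "utility")
  growth <- mk_schedule(raw$age_schedules$growth, "growth")
  nodal <- mk_schedule(raw$age_schedules$nodal, "nodal")

  log <- character()
  if (identical(raw$meta$decade_band_unit, "annual_verbatim")) {
    log <- c(log, paste(
      "decade-band values stored verbatim as annual probabilities;",
      "the source text's own worked conversion (3.7%/10 yr -> 0.38%/yr)",
      "implies values ~10x smaller (see scenario 'text_canonical')"))
  }
  for (nm in names(utils_)) {
    u <- utils_[[nm]]
    if (grepl("^u_(active_surveillance|disease_progression)$", nm) &&
        u$point < 0.6) {
      log <- c(log, paste0(
        "utility '", nm, "' = ", u$point,
        " is implausibly low for an asymptomatic/transient state;",
        " loaded verbatim, not bound to any health state"))
    }
  }
  set <- parameter_set(
    probs, utils_, growth, nodal,
    discount = if (is.null(raw$discount)) 0.03 else raw$discount,
    meta = list(scenario = if (is.null(raw$meta$name)) basename(path) else
      raw$meta$name, path = path, load_log = log)
  )
  if (!quiet && length(log)) {
    message(paste0("ptmcCEA parameter load log (", set$meta$scenario, "):\n",
                   paste0("  - ", log, collapse = "\n")))
  }
  set
}
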