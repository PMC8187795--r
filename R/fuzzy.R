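#' Membership functions
#'
#' A membership function maps a crisp value on a variable's universe to a
#' degree of membership in \[0, 1\].
#'
#' * `mf_triangular(a, b, c)` rises linearly from 0 at `a` to 1 at the peak
#'   `b` and falls back to 0 at `c` (`a <= b <= c`). A degenerate side
#'   (`a == b` or `b == c`) is a vertical shoulder.
#' * `mf_trapezoidal(a, b, c, d)` is 1 on the plateau \[`b`, `c`\] with linear
#'   feet at `a` and `d`.
#' * `mf_gaussian(mean, sigma)` is `exp(-(x - mean)^2 / (2 sigma^2))`, peaking
#'   at 1 over `mean`; `sigma > 0`.
#'
#' Parameter validity is enforced at construction time so that evaluation via
#' [membership_degree()] can never fail.
#'
#' @param a,b,c,d breakpoints in universe units.
#' @param mean,sigma Gaussian center and width in universe units.
#' @return an object of class `membership_function`.
#' @examples
#' membership_degree(mf_triangular(100, 150, 200), 150)  # 1
#' membership_degree(mf_gaussian(15, 5), 20)             # exp(-0.5)
#' @name membership_function
NULL

new_mf <- function(shape, params) {
  structure(list(shape = shape, params = params), class = "membership_function")
}

#' @rdname membership_function
#' @export
mf_triangular <- function(a, b, c) {
  if (!(a <= b && b <= c)) stop("triangular requires a <= b <= c", call. = FALSE)
  if (a == c) stop("triangular requires a < c (non-degenerate support)", call. = FALSE)
  new_mf("triangular", c(a = a, b = b, c = c))
}

#' @rdname membership_function
#' @export
mf_trapezoidal <- function(a, b, c, d) {
  if (!(a <= b && b <= c && c <= d)) {
    stop("trapezoidal requires a <= b <= c <= d", call. = FALSE)
  }
  if (a == d) stop("trapezoidal requires a < d (non-degenerate support)", call. = FALSE)
  new_mf("trapezoidal", c(a = a, b = b, c = c, d = d))
}

#' @rdname membership_function
#' @export
mf_gaussian <- function(mean, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("gaussian requires sigma > 0", call. = FALSE)
  new_mf("gaussian", c(mean = mean, sigma = sigma))
}

#' @export
print.membership_function <- function(x, ...) {
  cat(sprintf("<membership_function> %s(%s)\n", x$shape,
              paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}

#' Degree of membership of a crisp value
#'
#' @param mf a [membership_function].
#' @param x numeric vector of crisp values (finite).
#' @return degrees in \[0, 1\], one per element of `x`.
#' @export
membership_degree <- function(mf, x) {
  if (!inherits(mf, "membership_function")) {
    stop("mf must be a membership_function", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("crisp values must be finite", call. = FALSE)
  p <- mf$params
  out <- switch(mf$shape,
    triangular = {
      up <- if (p["b"] > p["a"]) (x - p["a"]) / (p["b"] - p["a"]) else as.numeric(x >= p["b"])
      dn <- if (p["c"] > p["b"]) (p["c"] - x) / (p["c"] - p["b"]) else as.numeric(x <= p["b"])
      pmin(up, dn)
    },
    trapezoidal = {
      up <- if (p["b"] > p["a"]) (x - p["a"]) / (p["b"] - p["a"]) else as.numeric(x >= p["b"])
      dn <- if (p["d"] > p["c"]) (p["d"] - x) / (p["d"] - p["c"]) else as.numeric(x <= p["c"])
      pmin(up, dn, 1)
    },
    gaussian = exp(-(x - p["mean"])^2 / (2 * p["sigma"]^2)),
    stop("unknown membership shape", call. = FALSE)
  )
  unname(pmin(pmax(out, 0), 1))
}

#' Linguistic variable: a named universe partitioned into fuzzy sets
#'
#' @param name variable name (e.g. `"RightCam BB"`).
#' @param universe closed interval `c(lo, hi)` in the variable's units
#'   (pixels, percent overlap, ...).
#' @param sets named list of [membership_function] objects; labels must be
#'   unique.
#' @param units optional unit string for display.
#' @return an object of class `linguistic_variable`.
#' @export
linguistic_variable <- function(name, universe, sets, units = "") {
  universe <- as.numeric(universe)
  if (length(universe) != 2 || !all(is.finite(universe)) || universe[1] >= universe[2]) {
    stop("universe must be a finite interval c(lo, hi) with lo < hi", call. = FALSE)
  }
  if (length(sets) == 0 || is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be a uniquely named list of membership functions", call. = FALSE)
  }
  ok <- vapply(sets, inherits, logical(1), what = "membership_function")
  if (!all(ok)) stop("every set must be a membership_function", call. = FALSE)
  structure(list(name = name, universe = universe, sets = sets, units = units),
            class = "linguistic_variable")
}

#' @export
print.linguistic_variable <- function(x, ...) {
  cat(sprintf("<linguistic_variable> %s on [%g, %g] %s: %s\n",
              x$name, x$universe[1], x$universe[2], x$units,
              paste(names(x$sets), collapse = ", ")))
  invisible(x)
}

#' Fuzzy IF-THEN rule
#'
#' Antecedents are conjunctive (`and`, interpreted as min); an antecedent may
#' be negated (`not`), contributing the standard complement `1 - degree`. All
#' rules carry equal weight one.
#'
#' @param antecedents list of clauses, each `list(var =, is =, not = FALSE)`.
#' @param consequent a clause `list(var =, is =)` naming an output set.
#' @param id optional rule identifier (e.g. `"R4"`).
#' @return an object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedents, consequent, id = NULL) {
  if (length(antecedents) < 1) stop("a rule needs at least one antecedent", call. = FALSE)
  antecedents <- lapply(antecedents, function(a) {
    if (is.null(a$var) || is.null(a$is)) {
      stop("each antecedent needs fields 'var' and 'is'", call. = FALSE)
    }
    list(var = a$var, is = a$is, not = isTRUE(a$not))
  })
  if (is.null(consequent$var) || is.null(consequent$is)) {
    stop("the consequent needs fields 'var' and 'is'", call. = FALSE)
  }
  structure(list(antecedents = antecedents,
                 consequent = list(var = consequent$var, is = consequent$is),
                 weight = 1, id = id),
            class = "fuzzy_rule")
}

#' @export
print.fuzzy_rule <- function(x, ...) {
  ante <- vapply(x$antecedents, function(a) {
    sprintf("(%s is %s%s)", a$var, if (a$not) "Not " else "", a$is)
  }, character(1))
  cat(sprintf("%s: IF %s THEN (%s is %s)\n", x$id %||% "R?",
              paste(ante, collapse = " and "), x$consequent$var, x$consequent$is))
  invisible(x)
}

#' Mamdani rule base
#'
#' Bundles input variables, one output variable and an ordered rule list, and
#' validates that every referenced variable and set label exists and that all
#' consequents belong to the output variable.
#'
#' @param rules list of [fuzzy_rule()] objects.
#' @param inputs list of input [linguistic_variable()] objects.
#' @param output the output [linguistic_variable()].
#' @return an object of class `rule_base`.
#' @export
rule_base <- function(rules, inputs, output) {
  in_names <- vapply(inputs, function(v) v$name, character(1))
  names(inputs) <- in_names
  for (r in rules) {
    for (a in r$antecedents) {
      if (!a$var %in% in_names) {
        stop(sprintf("rule references unknown input variable '%s'", a$var), call. = FALSE)
      }
      if (!a$is %in% names(inputs[[a$var]]$sets)) {
        stop(sprintf("variable '%s' has no set '%s'", a$var, a$is), call. = FALSE)
      }
    }
    if (r$consequent$var != output$name) {
      stop("every consequent must target the output variable", call. = FALSE)
    }
    if (!r$consequent$is %in% names(output$sets)) {
      stop(sprintf("output variable has no set '%s'", r$consequent$is), call. = FALSE)
    }
  }
  structure(list(rules = rules, inputs = inputs, output = output),
            class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("<rule_base> %d rules | inputs: %s | output: %s\n",
              length(x$rules), paste(names(x$inputs), collapse = ", "),
              x$output$name))
  invisible(x)
}

# clamp crisp inputs to each variable's universe, warning when clipping occurs
clamp_inputs <- function(rb, inputs) {
  out <- inputs
  for (nm in names(inputs)) {
    v <- rb$inputs[[nm]]
    if (is.null(v)) next
    x <- inputs[[nm]]
    cl <- min(max(x, v$universe[1]), v$universe[2])
    if (cl != x) {
      warning(sprintf("input '%s' = %g outside universe [%g, %g]; clamped",
                      nm, x, v$universe[1], v$universe[2]), call. = FALSE)
    }
    out[[nm]] <- cl
  }
  out
}

#' Activation degree of one rule
#'
#' Computes each antecedent's membership degree at the crisp input (after
#' clamping to the variable's universe), complements negated antecedents, and
#' combines by min (logical AND).
#'
#' @param rule a [fuzzy_rule()].
#' @param inputs named list/vector mapping input variable names to crisp
#'   values.
#' @param rulebase the [rule_base()] supplying the variables.
#' @return activation degree in \[0, 1\].
#' @export
evaluate_rule <- function(rule, inputs, rulebase) {
  inputs <- as.list(inputs)
  missing_vars <- setdiff(vapply(rule$antecedents, `[[`, character(1), "var"),
                          names(inputs))
  if (length(missing_vars) > 0) {
    stop(sprintf("missing crisp input for variable(s): %s",
                 paste(missing_vars, collapse = ", ")), call. = FALSE)
  }
  inputs <- clamp_inputs(rulebase, inputs)
  degs <- vapply(rule$antecedents, function(a) {
    d <- membership_degree(rulebase$inputs[[a$var]]$sets[[a$is]], inputs[[a$var]])
    if (a$not) 1 - d else d
  }, numeric(1))
  min(degs)
}

#' Aggregate the fired rules into an output membership function
#'
#' Mamdani inference with the classical operator set: each rule's activation
#' (min over antecedents) clips its consequent set (min implication), and the
#' clipped sets combine by pointwise max over the output universe. Rules with
#' zero activation contribute nothing.
#'
#' @inheritParams evaluate_rule
#' @param rulebase a [rule_base()].
#' @return an object of class `fuzzy_aggregate`: list with the output
#'   `universe`, a vectorized membership function `fun`, and the per-rule
#'   `activations` (named by rule id where available).
#' @export
aggregate_rules <- function(rulebase, inputs) {
  inputs <- clamp_inputs(rulebase, as.list(inputs))
  acts <- vapply(rulebase$rules, evaluate_rule, numeric(1),
                 inputs = inputs, rulebase = rulebase)
  ids <- vapply(seq_along(rulebase$rules), function(i) {
    rulebase$rules[[i]]$id %||% sprintf("rule%d", i)
  }, character(1))
  names(acts) <- ids
  fired <- which(acts > 0)
  cons <- lapply(rulebase$rules, function(r) rulebase$output$sets[[r$consequent$is]])
  fun <- function(x) {
    mu <- numeric(length(x))
    for (i in fired) {
      mu <- pmax(mu, pmin(acts[i], membership_degree(cons[[i]], x)))
    }
    mu
  }
  structure(list(universe = rulebase$output$universe, fun = fun,
                 activations = acts),
            class = "fuzzy_aggregate")
}

#' @export
print.fuzzy_aggregate <- function(x, ...) {
  fired <- x$activations[x$activations > 0]
  cat(sprintf("<fuzzy_aggregate> on [%g, %g]; fired: %s\n",
              x$universe[1], x$universe[2],
              if (length(fired)) paste(sprintf("%s=%.3g", names(fired), fired),
                                       collapse = ", ") else "none"))
  invisible(x)
}

#' Centroid defuzzification
#'
#' Approximates the center of mass of the aggregated output membership,
#' `integral(x mu(x)) / integral(mu(x))`, on a uniform grid over the output
#' universe.
#'
#' @param aggregated a `fuzzy_aggregate` from [aggregate_rules()], or a plain
#'   `list(universe =, fun =)`.
#' @param resolution grid spacing in output-universe units (default 0.1).
#' @return the crisp output value, guaranteed inside the universe.
#' @details An identically-zero aggregate (no rule fired) has no center of
#'   mass; this raises an explicit error so callers can decide a fallback.
#' @export
defuzzify_centroid <- function(aggregated, resolution = 0.1) {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  u <- aggregated$universe
  x <- seq(u[1], u[2], by = resolution)
  if (x[length(x)] < u[2]) x <- c(x, u[2])
  mu <- aggregated$fun(x)
  s <- sum(mu)
  if (s <= 0) {
    stop("no rule fired: aggregated membership is identically zero", call. = FALSE)
  }
  val <- sum(x * mu) / s
  min(max(val, u[1]), u[2])
}
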