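#' Declare a spatiotemporal GLMM structure
#'
#' Declarative description of one response model: observation family,
#' fixed-effect formula, breakpoint (hockey-stick) covariates, time-varying
#' coefficients with their process (stationary AR(1) or random walk),
#' spatially varying coefficients, month random intercept, and the spatial
#' (`omega`, constant in time) and spatiotemporal (`epsilon`, iid by year)
#' Matern GMRF fields.  For the two-predictor Poisson-link delta-gamma
#' family the second linear predictor mirrors the first unless the `*2`
#' arguments override it.
#'
#' @param response Name of the response column in the data.
#' @param family `"tweedie"`, `"poisson_link_delta_gamma"`, or `"gaussian"`
#'   (the latter mostly for exactness checks, where the Laplace
#'   approximation is exact).
#' @param fixed One-sided formula for `X^main beta`, e.g.
#'   `~ depth + I(depth^2) + factor(year)`.  Continuous covariates are
#'   standardized before the formula is evaluated; `year`, `quarter`,
#'   `month` and 0/1 indicators are left alone.
#' @param breakpoint Character vector of covariate names entering as
#'   `b0 * min(x, b1)` on the standardized scale.
#' @param time_varying Named list mapping covariate name (or
#'   `"intercept"`) to `"ar1"` or `"rw"`.
#' @param svc Character vector of covariate names with spatially varying
#'   (GMRF) coefficients.
#' @param month_random_intercept Logical; iid normal month intercepts.
#' @param spatial_field,spatiotemporal_field Logical switches for `omega`
#'   and `epsilon`.
#' @param fixed2,breakpoint2,time_varying2,svc2,month_random_intercept2,spatial_field2,spatiotemporal_field2
#'   Optional overrides for the second linear predictor (delta family
#'   only); `NULL` mirrors the first.
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response,
                       family = c("tweedie", "poisson_link_delta_gamma",
                                  "gaussian"),
                       fixed = ~1,
                       breakpoint = character(),
                       time_varying = list(),
                       svc = character(),
                       month_random_intercept = FALSE,
                       spatial_field = TRUE,
                       spatiotemporal_field = TRUE,
                       fixed2 = NULL,
                       breakpoint2 = NULL,
                       time_varying2 = NULL,
                       svc2 = NULL,
                       month_random_intercept2 = NULL,
                       spatial_field2 = NULL,
                       spatiotemporal_field2 = NULL) {
  family <- match.arg(family)
  stopifnot(is.character(response), length(response) == 1L)
  check_tvc <- function(tv) {
    if (!is.list(tv) || (length(tv) && is.null(names(tv))))
      stop("`time_varying` must be a named list, e.g. list(intercept = \"ar1\")")
    if (anyDuplicated(names(tv)))
      stop("at most one process per time-varying term")
    bad <- !unlist(tv) %in% c("ar1", "rw")
    if (any(bad)) stop("time-varying process must be \"ar1\" or \"rw\"")
    tv
  }
  comp1 <- list(fixed = fixed, breakpoint = breakpoint,
                time_varying = check_tvc(time_varying), svc = svc,
                month_random_intercept = isTRUE(month_random_intercept),
                spatial_field = isTRUE(spatial_field),
                spatiotemporal_field = isTRUE(spatiotemporal_field))
  comp2 <- NULL
  if (family == "poisson_link_delta_gamma") {
    comp2 <- list(
      fixed = if (is.null(fixed2)) fixed else fixed2,
      breakpoint = if (is.null(breakpoint2)) breakpoint else breakpoint2,
      time_varying = check_tvc(
        if (is.null(time_varying2)) time_varying else time_varying2),
      svc = if (is.null(svc2)) svc else svc2,
      month_random_intercept = if (is.null(month_random_intercept2))
        comp1$month_random_intercept else isTRUE(month_random_intercept2),
      spatial_field = if (is.null(spatial_field2))
        comp1$spatial_field else isTRUE(spatial_field2),
      spatiotemporal_field = if (is.null(spatiotemporal_field2))
        comp1$spatiotemporal_field else isTRUE(spatiotemporal_field2))
  }
  structure(list(response = response, family = family,
                 components = list(comp1 = comp1, comp2 = comp2)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$response, "~", x$family, "\n")
  for (nm in names(x$components)) {
    cp <- x$components[[nm]]
    if (is.null(cp)) next
    cat(" ", nm, ": fixed", deparse(cp$fixed),
        if (length(cp$breakpoint)) paste("| breakpoint:", paste(cp$breakpoint, collapse = ", ")) else "",
        if (length(cp$time_varying)) paste("| tvc:", paste(names(cp$time_varying), unlist(cp$time_varying), sep = "=", collapse = ", ")) else "",
        if (length(cp$svc)) paste("| svc:", paste(cp$svc, collapse = ", ")) else "",
        "| omega:", cp$spatial_field, "eps:", cp$spatiotemporal_field,
        "month:", cp$month_random_intercept, "\n")
  }
  invisible(x)
}

## variables in a component, excluding specials never standardized
spec_covariates <- function(spec) {
  specials <- c("year", "quarter", "month")
  vars <- character(0)
  for (cp in spec$components) {
    if (is.null(cp)) next
    vars <- c(vars, all.vars(cp$fixed), cp$breakpoint,
              setdiff(names(cp$time_varying), "intercept"), cp$svc)
  }
  setdiff(unique(vars), specials)
}

## Build the numeric structures the TMB template consumes for one dataset.
## `standardization`, `year_levels`, `xlev` come from a previous (fitting)
## call when building a prediction frame.
build_model_frame <- function(spec, data, standardization = NULL,
                              year_levels = NULL, xlev = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  if (!spec$response %in% names(data) && is.null(standardization))
    stop("response column `", spec$response, "` not found")

  covars <- spec_covariates(spec)
  missing_cov <- setdiff(covars, names(data))
  if (length(missing_cov))
    stop("covariate(s) missing from data: ",
         paste(missing_cov, collapse = ", "))

  fitting <- is.null(standardization)
  if (fitting) {
    standardization <- list()
    for (v in covars) {
      x <- data[[v]]
      if (is.numeric(x) && !all(x %in% c(0, 1))) {
        s <- standardize(x)
        data[[v]] <- s$values
        standardization[[v]] <- c(center = s$center, scale = s$scale)
      }
    }
  } else {
    for (v in names(standardization))
      if (v %in% names(data))
        data[[v]] <- apply_standardize(data[[v]],
                                       standardization[[v]]["center"],
                                       standardization[[v]]["scale"])
  }

  if (!"year" %in% names(data)) stop("data must contain a `year` column")
  if (fitting) year_levels <- seq(min(data$year), max(data$year))
  year_idx <- match(data$year, year_levels)
  if (anyNA(year_idx))
    stop("year(s) outside the fitted range: ",
         paste(unique(data$year[is.na(year_idx)]), collapse = ", "))

  month_idx <- if ("month" %in% names(data)) {
    if (any(!data$month %in% 1:12)) stop("`month` must be in 1..12")
    as.integer(data$month)
  } else rep(1L, nrow(data))

  build_component <- function(cp, tag) {
    if (is.null(cp)) {
      return(list(X = matrix(0, nrow(data), 0), Xbp = matrix(0, nrow(data), 0),
                  Xtvc = matrix(0, nrow(data), 0), tvc_code = integer(0),
                  tvc_names = character(0),
                  Xsvc = matrix(0, nrow(data), 0),
                  include_omega = 0L, include_epsilon = 0L,
                  include_month = 0L, xlev = NULL, coef_names = character(0)))
    }
    mf <- stats::model.frame(cp$fixed, data,
                             xlev = if (!fitting) xlev[[tag]] else NULL,
                             na.action = stats::na.fail)
    X <- stats::model.matrix(cp$fixed, mf)
    lev <- stats::.getXlevels(stats::terms(cp$fixed, data = data), mf)
    Xbp <- as.matrix(data[cp$breakpoint])
    if (!length(cp$breakpoint)) Xbp <- matrix(0, nrow(data), 0)
    tvc_names <- names(cp$time_varying)
    Xtvc <- matrix(0, nrow(data), length(tvc_names))
    for (j in seq_along(tvc_names))
      Xtvc[, j] <- if (tvc_names[j] == "intercept") 1 else data[[tvc_names[j]]]
    tvc_code <- ifelse(unlist(cp$time_varying) == "ar1", 0L, 1L)
    Xsvc <- as.matrix(data[cp$svc])
    if (!length(cp$svc)) Xsvc <- matrix(0, nrow(data), 0)
    list(X = X, Xbp = Xbp, Xtvc = Xtvc,
         tvc_code = as.integer(tvc_code), tvc_names = tvc_names,
         Xsvc = Xsvc,
         include_omega = as.integer(cp$spatial_field),
         include_epsilon = as.integer(cp$spatiotemporal_field),
         include_month = as.integer(cp$month_random_intercept),
         xlev = lev, coef_names = colnames(X))
  }

  c1 <- build_component(spec$components$comp1, "comp1")
  c2 <- build_component(spec$components$comp2, "comp2")

  list(y = if (spec$response %in% names(data)) data[[spec$response]] else NULL,
       data = data, comp1 = c1, comp2 = c2,
       year_idx = as.integer(year_idx), month_idx = month_idx,
       year_levels = year_levels, n_year = length(year_levels),
       standardization = standardization,
       xlev = list(comp1 = c1$xlev, comp2 = c2$xlev),
       locations = as_points(data[, c("x_km", "y_km")]))
}

## R-side evaluation of one component's linear predictor from a parameter
## list (the same arithmetic as the TMB template; used for prediction and
## in hand-assembly tests).
eval_linear_predictor <- function(comp, pars, suffix, year_idx, month_idx,
                                  A, n_year, include_month_effect = TRUE) {
  g <- function(nm) pars[[paste0(nm, suffix)]]
  n <- length(year_idx)
  eta <- if (ncol(comp$X)) as.vector(comp$X %*% g("beta")) else numeric(n)
  if (ncol(comp$Xbp)) {
    b0 <- g("bp_b0_"); b1 <- g("bp_b1_")
    for (k in seq_len(ncol(comp$Xbp)))
      eta <- eta + breakpoint_effect(comp$Xbp[, k], b0[k], b1[k])
  }
  gam <- g("gamma")
  if (length(gam)) {
    gam <- matrix(gam, nrow = length(comp$tvc_code))
    for (gg in seq_len(nrow(gam)))
      eta <- eta + comp$Xtvc[, gg] * gam[gg, year_idx]
  }
  if (comp$include_month && include_month_effect) {
    alpha <- g("alpha")
    eta <- eta + alpha[month_idx]
  }
  if (comp$include_omega)
    eta <- eta + as.vector(A %*% g("omega"))
  if (comp$include_epsilon) {
    eps <- matrix(g("epsilon"), ncol = n_year)
    Aeps <- as.matrix(A %*% eps)
    eta <- eta + Aeps[cbind(seq_len(n), year_idx)]
  }
  if (ncol(comp$Xsvc)) {
    zeta <- matrix(g("zeta"), ncol = ncol(comp$Xsvc))
    for (k in seq_len(ncol(comp$Xsvc)))
      eta <- eta + comp$Xsvc[, k] * as.vector(A %*% zeta[, k])
  }
  eta
}
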