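#' Two-standard-deviation standardization
#'
#' Centers a continuous predictor and divides by twice its standard
#' deviation, so that a one-unit change is comparable with a binary contrast
#' and effect sizes can be compared across continuous and dichotomous terms.
#'
#' @param x numeric vector with positive sd.
#' @return numeric vector with mean 0 and sd 0.5.
#' @export
gelman_standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize constant column: ", deparse(substitute(x)))
  (x - mean(x)) / (2 * s)
}

#' Variance-inflation screen
#'
#' Fits the fixed-effects-only linear model and reports the variance
#' inflation factor of each term (generalized VIF for factors, via the
#' `car` package). Perfect collinearity (aliased terms) is reported as
#' infinite and halts unless `force = TRUE`.
#'
#' @param model_table data.frame of predictors and response.
#' @param response name of the response column.
#' @param terms character vector of fixed-effect term names.
#' @param force continue despite infinite VIFs.
#' @return named numeric vector of VIFs (GVIF for multi-df terms).
#' @export
vif_screen <- function(model_table, response, terms, force = FALSE) {
  stopifnot(length(terms) >= 2)
  f <- stats::reformulate(terms, response = response)
  lm_fit <- stats::lm(f, data = model_table)
  v <- tryCatch({
    out <- car::vif(lm_fit)
    if (is.matrix(out)) stats::setNames(out[, 1], rownames(out)) else out
  }, error = function(e) {
    if (grepl("aliased", conditionMessage(e)))
      stats::setNames(rep(Inf, length(terms)), terms)
    else stop(e)
  })
  if (any(!is.finite(v)) && !force)
    stop("perfectly collinear predictor(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "),
         " (use force = TRUE to continue)")
  v
}

ind_fixed <- c("dominance_rank", "dependent_infant", "new_immigrant",
               "tenure", "new_alpha_male", "last_year_in_group",
               "female_number", "group_size", "group_id")
dyad_fixed <- c("rank_average", "dependent_infant_cat", "new_immigrant",
                "new_alpha_male", "female_number", "group_size", "group_id")
ind_cont <- c("dominance_rank", "tenure", "female_number", "group_size")
dyad_cont <- c("rank_average", "female_number", "group_size")

prep_model_table <- function(model_table, model, standardize) {
  d <- as.data.frame(model_table)
  to_yn <- function(x) factor(ifelse(as.logical(x), "yes", "no"),
                              levels = c("no", "yes"))
  for (cl in intersect(c("dependent_infant", "new_immigrant",
                         "new_alpha_male", "last_year_in_group"), names(d)))
    d[[cl]] <- to_yn(d[[cl]])
  if ("dependent_infant_cat" %in% names(d))
    d$dependent_infant_cat <- factor(d$dependent_infant_cat,
                                     levels = c("none", "one", "both"))
  if ("group_id" %in% names(d)) d$group_id <- factor(d$group_id)
  d$year <- factor(d$year)
  for (cl in intersect(c("id", "id1", "id2", "dyad_id"), names(d)))
    d[[cl]] <- factor(d[[cl]])
  fixed <- if (model == "individual") ind_fixed else dyad_fixed
  cont <- if (model == "individual") ind_cont else dyad_cont
  dropped <- character(0)
  for (term in fixed) {
    x <- d[[term]]
    if (is.factor(x) && length(unique(droplevels(x))) < 2) {
      dropped <- c(dropped, term)
    } else if (is.numeric(x) && stats::sd(x) == 0) {
      dropped <- c(dropped, term)
    }
  }
  fixed <- setdiff(fixed, dropped)
  if (standardize)
    for (term in intersect(cont, fixed)) d[[term]] <- gelman_standardize(d[[term]])
  list(data = droplevels(d), fixed = fixed, dropped = dropped)
}

#' Fit a hierarchical model of association strength
#'
#' Fits the individual-year model (response: node strength; predictors:
#' dominance rank, dependent infant, new immigrant, tenure, new alpha male,
#' last year in group, female number, group size, group; random intercepts
#' for individual and year) or the dyad-year model (response: dyadic
#' strength; predictors: average rank, dependent-infant category, new
#' immigrant, new alpha male, female number, group size, group; random
#' intercepts for each dyad member, the dyad, and year).
#'
#' The default backend is a Student-t linear mixed model with identity link
#' (glmmTMB `t_family`), a deterministic maximum-likelihood stand-in for the
#' heavy-tailed Bayesian fit the design calls for; a Gaussian backend is
#' available. Continuous predictors are 2-SD standardized
#' ([gelman_standardize()]); "meaningful" terms are those whose Wald
#' interval at `level` excludes zero. Fixed terms that are constant in the
#' data (e.g. no immigrant in a small study) are dropped and listed in the
#' diagnostics. Two separate member random intercepts approximate the
#' multi-membership structure of the dyadic model.
#'
#' @param model_table `individual` or `dyad` table from
#'   [build_model_tables()].
#' @param model "individual" or "dyadic".
#' @param backend "student" or "gaussian".
#' @param level interval level for the meaningful-effect classification.
#' @param standardize 2-SD standardize continuous predictors.
#' @param check_vif run [vif_screen()] first (halts on perfect collinearity).
#' @param seed optional integer, set before fitting (the backends are
#'   deterministic; the seed is part of the reproducibility contract).
#' @return object of class `strength_fit`: list with `effects` (term,
#'   estimate, se, ci_low, ci_high, meaningful), `r2`
#'   (marginal, conditional), `vif`, `diagnostics`, and the underlying `fit`.
#' @export
fit_hierarchical <- function(model_table, model = c("individual", "dyadic"),
                             backend = c("student", "gaussian"),
                             level = 0.95, standardize = TRUE,
                             check_vif = TRUE, seed = NULL) {
  model <- match.arg(model)
  backend <- match.arg(backend)
  if (is.null(model_table) || !nrow(model_table)) stop("empty model table")
  if (!is.null(seed)) set.seed(seed)
  pr <- prep_model_table(model_table, model, standardize)
  d <- pr$data
  vif <- if (check_vif && length(pr$fixed) >= 2)
    vif_screen(d, "strength", pr$fixed) else NULL
  re <- if (model == "individual") c("(1 | id)", "(1 | year)")
  else c("(1 | id1)", "(1 | id2)", "(1 | dyad_id)", "(1 | year)")
  rhs <- paste(c(pr$fixed, re), collapse = " + ")
  f <- stats::as.formula(paste("strength ~", rhs))
  fam <- if (backend == "student") glmmTMB::t_family(link = "identity")
  else stats::gaussian(link = "identity")
  ctrl <- glmmTMB::glmmTMBControl(optCtrl = list(iter.max = 2000,
                                                 eval.max = 2000))
  fit <- suppressWarnings(glmmTMB::glmmTMB(f, data = d, family = fam,
                                           control = ctrl))
  cf <- summary(fit)$coefficients$cond
  z <- stats::qnorm(1 - (1 - level) / 2)
  effects <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                        ci_low = cf[, 1] - z * cf[, 2],
                        ci_high = cf[, 1] + z * cf[, 2])
  effects$meaningful <- effects$ci_low > 0 | effects$ci_high < 0
  rownames(effects) <- NULL
  vc <- glmmTMB::VarCorr(fit)$cond
  re_sd <- vapply(vc, function(v) attr(v, "stddev"), numeric(1))
  conv <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
  res <- structure(list(
    model_id = model, effects = effects, vif = vif, fit = fit, data = d,
    diagnostics = list(backend = backend,
                       family = if (backend == "student") "student (t_family)"
                       else "gaussian",
                       approximation = "maximum likelihood; Wald intervals in place of credible intervals",
                       converged = conv,
                       singular_re = any(re_sd < 1e-5),
                       re_sd = re_sd, dropped_terms = pr$dropped,
                       level = level, n = nrow(d), seed = seed)),
    class = "strength_fit")
  if (!conv) warning("model did not converge cleanly; summaries flagged")
  res$r2 <- r2_summaries(res)
  res
}

#' @export
print.strength_fit <- function(x, digits = 3, ...) {
  cat("<strength_fit> model:", x$model_id, "| backend:",
      x$diagnostics$backend, "| n =", x$diagnostics$n, "\n")
  eff <- x$effects
  eff$meaningful <- ifelse(eff$meaningful, "*", "")
  print(format(eff, digits = digits), row.names = FALSE)
  cat(sprintf("R2 marginal = %.3f, conditional = %.3f\n",
              x$r2["marginal"], x$r2["conditional"]))
  if (length(x$diagnostics$dropped_terms))
    cat("dropped constant term(s):",
        paste(x$diagnostics$dropped_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Marginal and conditional R-squared
#'
#' Variance-decomposition R2 for a hierarchical fit: marginal is the
#' variance explained by the fixed effects alone,
#' `var_f / (var_f + var_re + var_eps)`; conditional adds the random-effect
#' variance to the numerator, so conditional >= marginal always. For the
#' Student backend the residual variance uses the fitted scale and degrees
#' of freedom (`sigma^2 * nu / (nu - 2)`) when the tail is heavy enough,
#' falling back to the empirical residual variance otherwise.
#'
#' @param fit a `strength_fit` or `event_gam_fit`.
#' @return named numeric: `marginal`, `conditional`.
#' @export
r2_summaries <- function(fit) {
  if (inherits(fit, "event_gam_fit")) return(fit$r2)
  stopifnot(inherits(fit, "strength_fit"))
  m <- fit$fit
  mu_f <- stats::predict(m, re.form = NA)
  var_f <- stats::var(mu_f)
  vc <- glmmTMB::VarCorr(m)$cond
  var_re <- sum(vapply(vc, function(v) attr(v, "stddev")^2, numeric(1)))
  var_eps <- tryCatch({
    if (fit$diagnostics$backend == "student") {
      nu <- unname(glmmTMB::family_params(m))
      if (is.finite(nu) && nu > 2) stats::sigma(m)^2 * nu / (nu - 2)
      else stats::var(stats::residuals(m))
    } else stats::sigma(m)^2
  }, error = function(e) stats::var(stats::residuals(m)))
  tot <- var_f + var_re + var_eps
  c(marginal = var_f / tot, conditional = (var_f + var_re) / tot)
}

#' Fit a time-matched additive model of event-window strength
#'
#' A factor-smooth generalized additive model of the compiled event series:
#' `strength ~ condition + s(offset, by = condition) + s(dyad, re)`, i.e. one
#' penalized spline of the year-relative-to-event per condition level (the
#' condition x year-period interaction), a condition main effect, and a dyad
#' random intercept. The spline basis dimension equals the number of distinct
#' offsets (at most 5). Fitted by REML with mgcv; the "sds" of each smooth -
#' the estimated wigglyness - is the REML smoothing-component standard
#' deviation, and a smooth is classified meaningful when its Wald test at
#' `level` rejects a flat curve.
#'
#' @param event_table `infant` or `immigrant` table from
#'   [compile_event_tables()].
#' @param level classification level.
#' @param family "gaussian" (default) or "scat" (scaled-t, heavy-tailed).
#' @param seed optional integer, set before fitting.
#' @return object of class `event_gam_fit`: `effects` (parametric terms),
#'   `smooths` (term, edf, statistic, p_value, meaningful, sds), `r2`,
#'   `diagnostics`, underlying `fit`.
#' @export
fit_event_gam <- function(event_table, level = 0.95,
                          family = c("gaussian", "scat"), seed = NULL) {
  family <- match.arg(family)
  if (is.null(event_table) || !nrow(event_table)) stop("empty event table")
  if (!is.null(seed)) set.seed(seed)
  d <- as.data.frame(event_table)
  d$condition <- factor(d$condition, levels = c("no", "yes"))
  d$dyad_id <- factor(d$dyad_id)
  if (length(unique(d$condition)) < 2)
    stop("degenerate event table: only one condition level present")
  for (lv in levels(d$condition))
    if (length(unique(d$offset[d$condition == lv])) < 2)
      stop("degenerate event table: fewer than 2 offsets for condition ", lv)
  k <- min(5L, length(unique(d$offset)))
  fam <- if (family == "scat") mgcv::scat(link = "identity")
  else stats::gaussian()
  fit <- mgcv::gam(strength ~ condition + s(offset, by = condition, k = k) +
                     s(dyad_id, bs = "re"),
                   data = d, method = "REML", family = fam)
  sm <- summary(fit)
  z <- stats::qnorm(1 - (1 - level) / 2)
  pt <- sm$p.table
  effects <- data.frame(term = rownames(pt), estimate = pt[, 1], se = pt[, 2],
                        ci_low = pt[, 1] - z * pt[, 2],
                        ci_high = pt[, 1] + z * pt[, 2])
  effects$meaningful <- effects$ci_low > 0 | effects$ci_high < 0
  rownames(effects) <- NULL
  st <- sm$s.table
  vcomp <- tryCatch({
    out <- NULL
    utils::capture.output(out <- mgcv::gam.vcomp(fit))
    out
  }, error = function(e) NULL)
  sds <- if (is.matrix(vcomp)) vcomp[, "std.dev"] else
    stats::setNames(rep(NA_real_, nrow(st)), rownames(st))
  smooths <- data.frame(term = rownames(st), edf = st[, "edf"],
                        statistic = st[, ncol(st) - 1L],
                        p_value = st[, ncol(st)])
  smooths$meaningful <- smooths$p_value < (1 - level)
  smooths$sds <- sds[match(smooths$term, names(sds))]
  rownames(smooths) <- NULL
  # R2 by variance decomposition, with the dyad intercept as the random part
  mu_f <- stats::predict(fit, exclude = "s(dyad_id)", newdata = d)
  var_f <- stats::var(as.numeric(mu_f))
  var_re <- if (!is.null(vcomp) && "s(dyad_id)" %in% rownames(vcomp))
    vcomp["s(dyad_id)", "std.dev"]^2 else 0
  var_eps <- fit$sig2
  r2 <- c(marginal = var_f / (var_f + var_re + var_eps),
          conditional = (var_f + var_re) / (var_f + var_re + var_eps))
  structure(list(effects = effects, smooths = smooths, r2 = r2, fit = fit,
                 data = d,
                 diagnostics = list(backend = "mgcv REML",
                                    family = family,
                                    approximation = "penalized likelihood; smoothing-component sd as wigglyness",
                                    level = level, n = nrow(d), seed = seed,
                                    k = k)),
            class = "event_gam_fit")
}

#' @export
print.event_gam_fit <- function(x, digits = 3, ...) {
  cat("<event_gam_fit> n =", x$diagnostics$n, "| family:",
      x$diagnostics$family, "\n")
  print(format(x$effects, digits = digits), row.names = FALSE)
  print(format(x$smooths, digits = digits), row.names = FALSE)
  cat(sprintf("R2 marginal = %.3f, conditional = %.3f\n",
              x$r2["marginal"], x$r2["conditional"]))
  invisible(x)
}
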