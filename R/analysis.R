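# Pipeline driver and cohort statistics: per-site model predictions,
# squared Pearson correlations against the measured moduli, Tukey group
# comparisons, measured-vs-predicted distribution tests and the Monte Carlo
# sensitivity study of the fibril-array parameters.

#' Per-site virtual-indentation predictions
#'
#' For each site with extracted covariates, builds the fibril-array
#' stiffness at the site's mineral volume fraction and evaluates the
#' indentation modulus along the local fibril direction (`E_pred`) and
#' along the fibril axis (`E_pred0`, fibril angle held at 0). Sites with an
#' infeasible phase partition are flagged and left `NA`.
#'
#' @param sites indent table with `phi_avg` and `theta_avg` columns.
#' @param params a [fibril_array_params()] template.
#' @param predictor optional `f(phi, theta)` evaluator (e.g.
#'   [modulus_interpolator()]); direct evaluation when `NULL`.
#' @return The table with `E_pred` and `E_pred0` columns filled.
#' @export
predict_sites <- function(sites, params = fibril_array_params(),
                          predictor = NULL) {
  stopifnot(all(c("phi_avg", "theta_avg") %in% names(sites)))
  n <- nrow(sites)
  E_pred <- E_pred0 <- rep(NA_real_, n)
  ok <- complete.cases(sites$phi_avg, sites$theta_avg)
  if (is.null(predictor)) {
    for (i in which(ok)) {
      C <- tryCatch(fibril_array_stiffness(params, phi = sites$phi_avg[i]),
                    error = function(e) NULL)
      if (is.null(C)) { ok[i] <- FALSE; next }
      E_pred[i] <- indentation_modulus(C, theta = sites$theta_avg[i])
      E_pred0[i] <- indentation_modulus(C, theta = 0)
    }
  } else {
    E_pred[ok] <- predictor(sites$phi_avg[ok], sites$theta_avg[ok])
    E_pred0[ok] <- predictor(sites$phi_avg[ok], 0)
  }
  sites$E_pred <- E_pred
  sites$E_pred0 <- E_pred0
  sites
}

#' Squared Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length (pairs with missing values
#'   are dropped); at least 3 complete pairs, both nonconstant.
#' @return r^2 of the linear dependence, in `[0, 1]`.
#' @export
pearson_r2 <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  cor(x, y)^2
}

#' Tukey multiple comparison of group means
#'
#' One-way analysis of variance followed by Tukey's honest significant
#' difference test over all group pairs (osteonal / interstitial / mixed
#' region labels in the pipeline), at level `conf_level`.
#'
#' @param values numeric response.
#' @param labels group labels (coerced to factor).
#' @param conf_level confidence level.
#' @return Data frame with one row per pair: difference, interval bounds
#'   and adjusted p-value.
#' @export
compare_groups <- function(values, labels, conf_level = 0.95) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("need at least 2 groups", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2))
    stop("degenerate group(s): ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  fit <- aov(values ~ labels)
  tk <- TukeyHSD(fit, conf.level = conf_level)$labels
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL)
}

#' Rank and t tests between two samples
#'
#' Two-sided Wilcoxon rank test and Welch t-test comparing two
#' distributions (measured vs predicted moduli in the pipeline). The
#' rank-sum (unpaired) variant is the default; `paired = TRUE` switches
#' both tests to their paired forms.
#'
#' @param a,b numeric samples.
#' @param paired logical.
#' @return Named vector `c(p_wilcoxon =, p_t =)`.
#' @export
compare_distributions <- function(a, b, paired = FALSE) {
  if (paired) {
    ok <- complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
  } else {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
  }
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per sample", call. = FALSE)
  pw <- wilcox.test(a, b, paired = paired, exact = FALSE)$p.value
  pt <- t.test(a, b, paired = paired)$p.value
  c(p_wilcoxon = pw, p_t = pt)
}

#' Monte Carlo sensitivity configuration
#'
#' Defaults reproduce the auxiliary sensitivity experiment: mineral volume
#' fraction fixed at 0.34, mineral quota and fibril volume fraction each
#' uniform on [0.25, 0.75], fibril angle uniform on [0°, 90°], 10,000
#' feasible draws.
#'
#' @param phi_fixed fixed mineral volume fraction.
#' @param q_range,f_fibril_range,theta_range sampling ranges.
#' @param n_draws number of feasible draws.
#' @param seed integer seed.
#' @return Object of class `sensitivity_config`.
#' @export
sensitivity_config <- function(phi_fixed = 0.34, q_range = c(0.25, 0.75),
                               f_fibril_range = c(0.25, 0.75),
                               theta_range = c(0, 90), n_draws = 10000,
                               seed = 1L) {
  stopifnot(n_draws >= 1, all(q_range >= 0 & q_range <= 1),
            all(f_fibril_range >= 0 & f_fibril_range <= 1),
            all(theta_range >= 0 & theta_range <= 90))
  structure(as.list(environment()), class = "sensitivity_config")
}

#' Monte Carlo sensitivity study of the fibril-array parameters
#'
#' Draws (mineral quota, fibril volume fraction, fibril angle) uniformly
#' from the configured ranges at fixed mineralization, rejecting and
#' redrawing parameter sets whose phase partition leaves a volume fraction
#' outside [0, 1], and evaluates the virtual indentation modulus for each
#' feasible draw.
#'
#' @param cfg a [sensitivity_config()].
#' @param params a [fibril_array_params()] template supplying all
#'   non-varied parameters.
#' @param n_omega,n_phi quadrature resolution per draw.
#' @return List of class `sensitivity_mc`: `values` (GPa, length
#'   `n_draws`), `draws` (data frame of q, f_fibril, theta), `min`, `max`,
#'   `histogram` (counts over integer-GPa bins), `n_rejected`.
#' @export
sensitivity_mc <- function(cfg = sensitivity_config(),
                           params = fibril_array_params(),
                           n_omega = 90, n_phi = 90) {
  set.seed(cfg$seed)
  n <- cfg$n_draws
  q <- ff <- th <- numeric(n)
  got <- 0L; rejected <- 0L
  while (got < n) {
    m <- n - got
    qq <- runif(m, cfg$q_range[1], cfg$q_range[2])
    fq <- runif(m, cfg$f_fibril_range[1], cfg$f_fibril_range[2])
    tq <- runif(m, cfg$theta_range[1], cfg$theta_range[2])
    fmin <- qq * cfg$phi_fixed / fq
    fvoid <- 1 - (1 - qq) * cfg$phi_fixed / (1 - fq)
    feas <- fmin >= 0 & fmin <= 1 & fvoid >= 0 & fvoid <= 1 &
      fvoid < 1 - 1e-10
    k <- sum(feas)
    if (k == 0 && rejected > 1e6)
      stop("all draws infeasible for this configuration", call. = FALSE)
    rejected <- rejected + (m - k)
    if (k) {
      idx <- got + seq_len(k)
      q[idx] <- qq[feas]; ff[idx] <- fq[feas]; th[idx] <- tq[feas]
      got <- got + k
    }
  }
  vals <- numeric(n)
  for (i in seq_len(n)) {
    p <- fibril_array_params(
      E_collagen = params$E_collagen, nu_collagen = params$nu_collagen,
      E_mineral = params$E_mineral, nu_mineral = params$nu_mineral,
      ar_mineral = params$ar_mineral, ar_void = params$ar_void,
      ar_fibril = params$ar_fibril, f_fibril = ff[i], q_mineral = q[i],
      phi_mineral = cfg$phi_fixed)
    C <- fibril_array_stiffness(p)
    vals[i] <- indentation_modulus(C, theta = th[i], n_omega = n_omega,
                                   n_phi = n_phi)
  }
  brk <- seq(floor(min(vals)), ceiling(max(vals)) + 1) - 0.5
  structure(list(values = vals,
                 draws = data.frame(q = q, f_fibril = ff, theta = th),
                 min = min(vals), max = max(vals),
                 histogram = table(cut(vals, brk)),
                 n_rejected = rejected),
            class = "sensitivity_mc")
}

#' @export
print.sensitivity_mc <- function(x, ...) {
  cat(sprintf(paste0("Monte Carlo sensitivity study: %d draws ",
                     "(%d infeasible rejected)\n"),
              length(x$values), x$n_rejected))
  cat(sprintf("  indentation modulus range: %.2f to %.2f GPa (rounded: %d to %d GPa)\n",
              x$min, x$max, round(x$min), round(x$max)))
  invisible(x)
}

#' Run the full site-matched pipeline
#'
#' Executes, in order: qBEI calibration of the calcium map, rigid
#' registration of the displaced modality rasters to the reference frame,
#' disk-averaged covariate extraction, quality filtering, per-site model
#' prediction, and cohort statistics (means, SDs, squared Pearson
#' correlations against the measured moduli, Tukey region comparisons and
#' measured-vs-predicted distribution tests).
#'
#' @param sim a [simulate_cohort()] result (or an equivalent list with
#'   `ca_map`, `theta_map`, `reference_map`, `sites`, `params`, `cfg`).
#' @param predictor optional `f(phi, theta)` evaluator; defaults to the
#'   generator's evaluator when present (attribute `predictor` of the
#'   sites table), otherwise a fresh [modulus_interpolator()].
#' @param register if `FALSE`, skip registration and use identity
#'   transforms (for perfectly registered inputs).
#' @param dir optional output directory for the per-site CSV and summary
#'   YAML.
#' @return Object of class `lamellar_report`: `sites` (retained, with
#'   covariates and predictions), `correlation_table`, `group_comparison`,
#'   `distribution_tests`, `transform` (recovered), `rejection_log`,
#'   `summary` (named means/SDs).
#' @export
run_pipeline <- function(sim, predictor = NULL, register = TRUE,
                         dir = NULL) {
  phi_field <- calibrate_field(sim$ca_map)
  tr <- if (register) {
    register_rigid(sim$reference_map, phi_field,
                   window = c(dx = 5, dy = 5, alpha = 2))
  } else {
    rigid_transform()
  }
  sites <- extract_covariates(sim$sites, phi_field, sim$theta_map,
                              transforms = list(phi = tr, theta = tr))
  flt <- filter_indents(sites)
  sites <- flt$retained
  if (is.null(predictor))
    predictor <- attr(sim$sites, "predictor")
  sites <- predict_sites(sites, sim$params, predictor)

  used <- sites[complete.cases(sites$E_meas_GPa, sites$phi_avg,
                               sites$theta_avg, sites$E_pred), ]
  msd <- function(v) c(mean = mean(v), sd = sd(v))
  corr <- data.frame(
    variable = c("phi_avg", "theta_avg", "E_pred0", "E_pred", "E_meas"),
    mean = c(mean(used$phi_avg), mean(used$theta_avg), mean(used$E_pred0),
             mean(used$E_pred), mean(used$E_meas_GPa)),
    sd = c(sd(used$phi_avg), sd(used$theta_avg), sd(used$E_pred0),
           sd(used$E_pred), sd(used$E_meas_GPa)),
    r2_vs_E_meas = c(pearson_r2(used$phi_avg, used$E_meas_GPa),
                     pearson_r2(used$theta_avg, used$E_meas_GPa),
                     pearson_r2(used$E_pred0, used$E_meas_GPa),
                     pearson_r2(used$E_pred, used$E_meas_GPa),
                     NA_real_))
  grp <- tryCatch(compare_groups(used$E_meas_GPa, used$region),
                  error = function(e) NULL)
  dist_tests <- compare_distributions(used$E_meas_GPa, used$E_pred)

  report <- structure(list(
    sites = sites,
    correlation_table = corr,
    group_comparison = grp,
    distribution_tests = dist_tests,
    transform = tr,
    rejection_log = flt$log,
    n_performed = nrow(sim$sites),
    n_retained = nrow(sites),
    summary = list(
      n_performed = nrow(sim$sites), n_retained = nrow(sites),
      phi = msd(used$phi_avg), theta = msd(used$theta_avg),
      E_meas = msd(used$E_meas_GPa), E_pred = msd(used$E_pred),
      E_pred0 = msd(used$E_pred0))), class = "lamellar_report")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_indents_csv(sites, file.path(dir, "sites.csv"))
    write.csv(corr, file.path(dir, "correlation_table.csv"),
              row.names = FALSE)
    if (!is.null(grp))
      write.csv(grp, file.path(dir, "group_comparison.csv"),
                row.names = FALSE)
    yaml::write_yaml(lapply(report$summary, function(x)
      if (is.numeric(x)) as.list(x) else x),
      file.path(dir, "summary.yaml"))
  }
  report
}

#' @export
print.lamellar_report <- function(x, ...) {
  cat("Site-matched lamellar bone analysis\n")
  cat(sprintf("  indents: %d performed, %d retained\n",
              x$n_performed, x$n_retained))
  s <- x$summary
  cat(sprintf("  phi_mi,fa: %.3f +/- %.3f   theta: %.1f +/- %.1f deg\n",
              s$phi["mean"], s$phi["sd"], s$theta["mean"], s$theta["sd"]))
  cat(sprintf("  E_meas: %.2f +/- %.2f GPa   E_pred: %.2f +/- %.2f GPa   E_pred0: %.2f +/- %.2f GPa\n",
              s$E_meas["mean"], s$E_meas["sd"], s$E_pred["mean"],
              s$E_pred["sd"], s$E_pred0["mean"], s$E_pred0["sd"]))
  cat(sprintf("  r2(E_meas, E_pred) = %.4f\n",
              x$correlation_table$r2_vs_E_meas[
                x$correlation_table$variable == "E_pred"]))
  invisible(x)
}

#' @export
summary.lamellar_report <- function(object, ...) {
  cat("Correlation table (vs measured indentation modulus):\n")
  print(object$correlation_table, digits = 4)
  if (!is.null(object$group_comparison)) {
    cat("\nTukey comparison of measured moduli between regions:\n")
    print(object$group_comparison, digits = 4)
  }
  cat("\nMeasured vs predicted distribution tests:\n")
  print(object$distribution_tests, digits = 4)
  invisible(object)
}
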