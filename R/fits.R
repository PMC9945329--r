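#' Gas constant in kcal K^-1 mol^-1
#' @export
R_KCAL <- 1.987e-3

#' Default experiment temperature (27 degrees C), Kelvin
#' @export
T_DEFAULT <- 300.15

#' Fit a single-exponential kinetic trace
#'
#' Fits Y(t) = A exp(-t / t1) + Y0, optionally with a linear drift term
#' + d*t, by nonlinear least squares. The observed rate constant is
#' k = 1 / t1.
#'
#' @param trace data.frame with columns `t` (s, strictly increasing,
#'   >= 5 points) and `y` (signal).
#' @param with_drift Include the linear drift term. Default FALSE.
#' @return List of class `trace_fit`: `A`, `t1`, `Y0`, `d` (NA unless
#'   fitted), `k` (= 1/t1), `errors` (named SEs), `degenerate` (TRUE when
#'   the amplitude is indistinguishable from zero), `fitted` values.
#' @export
fit_single_exponential <- function(trace, with_drift = FALSE) {
  stopifnot(is.data.frame(trace), all(c("t", "y") %in% names(trace)))
  t <- trace$t
  y <- trace$y
  if (length(t) < 5L) stop("need at least 5 points")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")

  a0 <- y[1] - y[length(y)]
  y0_0 <- y[length(y)]
  t1_0 <- max(t[length(t)] / 3, diff(range(t)) / 5)
  if (abs(a0) < .Machine$double.eps) a0 <- stats::sd(y) + .Machine$double.eps

  df <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (with_drift) {
      minpack.lm::nlsLM(y ~ A * exp(-t / t1) + Y0 + d * t, data = df,
                        start = list(A = a0, t1 = t1_0, Y0 = y0_0, d = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-t / t1) + Y0, data = df,
                        start = list(A = a0, t1 = t1_0, Y0 = y0_0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) stop("exponential fit failed to converge: ",
                              conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  if (cf[["t1"]] <= 0) stop("fitted relaxation time t1 <= 0")
  degenerate <- (is.finite(se[["A"]]) && abs(cf[["A"]]) < 2 * se[["A"]]) ||
    abs(cf[["A"]]) < 1e-6 * max(abs(y), 1e-12)
  structure(
    list(A = cf[["A"]], t1 = cf[["t1"]], Y0 = cf[["Y0"]],
         d = if (with_drift) cf[["d"]] else NA_real_,
         k = 1 / cf[["t1"]], errors = se, degenerate = degenerate,
         fitted = stats::fitted(fit)),
    class = "trace_fit"
  )
}

# two-state LEM signal: linear baselines mixed by the Boltzmann factor
# K = exp(-(dG - m x) / RT); fraction unfolded = K / (1 + K)
lem_signal <- function(x, y_n, s_n, y_u, s_u, dG, m, RT) {
  K <- exp(-(dG - m * x) / RT)
  ((y_n + s_n * x) + (y_u + s_u * x) * K) / (1 + K)
}

#' Fit a two-state equilibrium denaturation curve
#'
#' Linear extrapolation model (LEM) with linear native and unfolded
#' baselines: the observed signal is the population-weighted mix of the two
#' baselines with equilibrium constant K = exp(-(dG - m*x)/RT).
#'
#' @param curve data.frame with columns `conc` (M denaturant) and `y`
#'   (signal); must span both baselines.
#' @param T Temperature, Kelvin. Default 300.15 (27 C).
#' @return List of class `equilibrium_fit`: baselines `y_n`, `s_n`, `y_u`,
#'   `s_u`; `dG` (kcal/mol), `m_eq` (kcal/mol/M), `c_mid` (= dG/m_eq),
#'   `errors`, `T`, and `fraction_folded` (data.frame `conc`, `ff`).
#' @export
fit_equilibrium <- function(curve, T = T_DEFAULT) {
  stopifnot(is.data.frame(curve), all(c("conc", "y") %in% names(curve)))
  x <- curve$conc
  y <- curve$y
  RT <- R_KCAL * T
  n <- length(x)
  if (n < 8L) stop("need at least 8 points spanning both baselines")

  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  k4 <- max(3L, floor(n / 4))
  lowi <- seq_len(k4)
  highi <- seq(n - k4 + 1L, n)
  bl_n <- stats::coef(stats::lm(y[lowi] ~ x[lowi]))
  bl_u <- stats::coef(stats::lm(y[highi] ~ x[highi]))
  if (abs(bl_n[1] - bl_u[1]) < 1e-12 && abs(bl_n[2] - bl_u[2]) < 1e-12) {
    stop("baselines are collinear: no transition to fit")
  }
  ymid <- (bl_n[1] + bl_u[1]) / 2
  cmid0 <- x[which.min(abs(y - ymid))]
  if (cmid0 <= min(x) || cmid0 >= max(x)) {
    stop("no transition inside the measured concentration range")
  }
  m0 <- 2
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lem_signal(x, y_n, s_n, y_u, s_u, dG, m, RT),
      data = df,
      start = list(y_n = unname(bl_n[1]), s_n = unname(bl_n[2]),
                   y_u = unname(bl_u[1]), s_u = unname(bl_u[2]),
                   dG = m0 * cmid0, m = m0),
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) stop("equilibrium fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  if (cf[["m"]] <= 0) stop("fitted m_eq <= 0: not a cooperative unfolding")
  K <- exp(-(cf[["dG"]] - cf[["m"]] * x) / RT)
  structure(
    list(y_n = cf[["y_n"]], s_n = cf[["s_n"]], y_u = cf[["y_u"]],
         s_u = cf[["s_u"]], dG = cf[["dG"]], m_eq = cf[["m"]],
         c_mid = cf[["dG"]] / cf[["m"]], errors = se, T = T,
         fraction_folded = data.frame(conc = x, ff = 1 / (1 + K))),
    class = "equilibrium_fit"
  )
}

# two-state chevron: ln k_obs(x) for folding + unfolding branches
chevron_lnk <- function(x, ln_kf, ln_ku, mf, mu, RT) {
  log(exp(ln_kf + mf * x / RT) + exp(ln_ku + mu * x / RT))
}

#' Fit a chevron plot
#'
#' Fits ln k_obs = ln[kf_H2O exp(mf x / RT) + ku_H2O exp(mu x / RT)] to
#' observed relaxation rates versus denaturant concentration. Fitting is on
#' ln k_obs (uniform relative error); set `on_log = FALSE` to fit plain k.
#' Data must cover both limbs of the V.
#'
#' @param data data.frame with columns `conc` (M) and `k_obs` (s^-1 > 0).
#' @param T Temperature, Kelvin. Default 300.15.
#' @param on_log Fit on the log scale. Default TRUE.
#' @return List of class `chevron_fit`: `kf_h2o`, `ku_h2o` (s^-1), `mf`
#'   (kcal/mol/M, negative), `mu` (positive), `errors` (SEs of ln_kf,
#'   ln_ku, mf, mu), `T`, `R`.
#' @export
fit_chevron <- function(data, T = T_DEFAULT, on_log = TRUE) {
  stopifnot(is.data.frame(data), all(c("conc", "k_obs") %in% names(data)))
  x <- data$conc
  k <- data$k_obs
  stopifnot(all(x >= 0), all(k > 0))
  RT <- R_KCAL * T

  # both limbs present: the rate minimum must be interior
  i_min <- which.min(log(k))
  if (i_min == which.min(x) || i_min == which.max(x)) {
    stop("data cover a single limb: chevron parameters are unidentifiable")
  }

  x_min <- x[i_min]
  lo <- x < x_min
  hi <- x > x_min
  f_lo <- stats::lm(log(k[lo]) ~ x[lo])
  f_hi <- stats::lm(log(k[hi]) ~ x[hi])
  start <- list(ln_kf = unname(stats::coef(f_lo)[1]),
                ln_ku = unname(stats::coef(f_hi)[1]),
                mf = unname(stats::coef(f_lo)[2]) * RT,
                mu = unname(stats::coef(f_hi)[2]) * RT)

  df <- data.frame(x = x, yk = k, ylog = log(k))
  fit <- tryCatch({
    if (on_log) {
      minpack.lm::nlsLM(ylog ~ chevron_lnk(x, ln_kf, ln_ku, mf, mu, RT),
                        data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 1000))
    } else {
      minpack.lm::nlsLM(yk ~ exp(chevron_lnk(x, ln_kf, ln_ku, mf, mu, RT)),
                        data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 1000))
    }
  }, error = function(e) stop("chevron fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(
    list(kf_h2o = exp(cf[["ln_kf"]]), ku_h2o = exp(cf[["ln_ku"]]),
         mf = cf[["mf"]], mu = cf[["mu"]],
         ln_kf = cf[["ln_kf"]], ln_ku = cf[["ln_ku"]],
         errors = se, T = T, R = R_KCAL),
    class = "chevron_fit"
  )
}

#' Construct a chevron_fit from known parameters
#'
#' Used to carry literature values or generator truths through
#' [derive_stability()] and [synthetic_chevron()].
#'
#' @param kf_h2o,ku_h2o Folding/unfolding rate constants in water, s^-1.
#' @param mf,mu Kinetic m-values, kcal/mol/M (mf negative, mu positive for
#'   a cooperative folder).
#' @param T Temperature, Kelvin.
#' @return A `chevron_fit`.
#' @export
chevron_parameters <- function(kf_h2o, ku_h2o, mf, mu, T = T_DEFAULT) {
  stopifnot(kf_h2o > 0, ku_h2o > 0)
  structure(
    list(kf_h2o = kf_h2o, ku_h2o = ku_h2o, mf = mf, mu = mu,
         ln_kf = log(kf_h2o), ln_ku = log(ku_h2o),
         errors = NULL, T = T, R = R_KCAL),
    class = "chevron_fit"
  )
}

#' Derive stability parameters from a chevron fit
#'
#' Computes the kinetically derived equilibrium quantities:
#' m_eq = mu - mf; beta_T = |mf| / m_eq; dG = -RT ln(ku/kf) (kcal/mol);
#' C_mid = dG / m_eq (M); ku at C_mid = ku_H2O exp(mu C_mid / RT); and the
#' midpoint unfolding half-life ln 2 / ku(C_mid).
#'
#' @param fit A `chevron_fit`.
#' @return List of class `derived_stability` with fields `m_eq_kin`,
#'   `beta_t`, `dG_kin`, `c_mid`, `ku_cmid`, `half_life_cmid_s`,
#'   `half_life_cmid_min`, `T`.
#' @export
derive_stability <- function(fit) {
  stopifnot(inherits(fit, "chevron_fit"))
  RT <- fit$R * fit$T
  m_eq <- fit$mu - fit$mf
  if (m_eq <= 0) stop("m_eq = mu - mf <= 0: not a cooperative folder")
  beta_t <- abs(fit$mf) / m_eq
  dG <- -RT * log(fit$ku_h2o / fit$kf_h2o)
  c_mid <- dG / m_eq
  ku_cmid <- fit$ku_h2o * exp(fit$mu * c_mid / RT)
  structure(
    list(m_eq_kin = m_eq, beta_t = beta_t, dG_kin = dG, c_mid = c_mid,
         ku_cmid = ku_cmid,
         half_life_cmid_s = log(2) / ku_cmid,
         half_life_cmid_min = log(2) / ku_cmid / 60,
         T = fit$T),
    class = "derived_stability"
  )
}

#' @export
print.derived_stability <- function(x, ...) {
  cat(sprintf(
    paste0("derived_stability (T = %.2f K):\n",
           "  m_eq %.3f kcal/mol/M   beta_T %.3f\n",
           "  dG %.3f kcal/mol   C_mid %.3f M\n",
           "  ku(C_mid) %.3e s^-1   half-life %.2f min\n"),
    x$T, x$m_eq_kin, x$beta_t, x$dG_kin, x$c_mid, x$ku_cmid,
    x$half_life_cmid_min))
  invisible(x)
}

#' Write fit results as JSON or a Table-style TSV row
#'
#' @param fits Named list of `chevron_fit` / `derived_stability` /
#'   `equilibrium_fit` objects (one per protein).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fits, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  flat <- lapply(fits, function(f) {
    out <- unclass(f)
    out$errors <- NULL
    out$fraction_folded <- NULL
    out$fitted <- NULL
    out
  })
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- lapply(names(flat), function(nm) {
      vals <- flat[[nm]]
      vals <- vals[vapply(vals, function(v)
        is.numeric(v) && length(v) == 1L, logical(1))]
      cbind(data.frame(id = nm), as.data.frame(vals))
    })
    tab <- Reduce(function(a, b) merge(a, b, all = TRUE), rows)
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a two-column concentration/signal or time/signal table
#'
#' Accepts TSV or CSV with optional header; the first two columns are used.
#'
#' @param path Input file.
#' @param names Column names to assign (e.g. `c("conc", "y")`).
#' @return data.frame with the two named columns.
#' @export
read_xy_table <- function(path, names = c("x", "y")) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- !grepl("^\\s*[-0-9.eE+]+[,\\s]", first)
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           comment.char = "#")
  out <- tab[, 1:2]
  names(out) <- names
  out
}
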