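#' Van Genuchten retention parameters with negligible residual water
#'
#' A unimodal retention curve for the soil matrix:
#' `theta(psi) = phi_mat * (1 + (alpha*|psi|)^n)^(1/n - 1)`.
#' `n` is treated as texture-fixed; `alpha` is the dynamic parameter, tied to
#' the micro/meso pore pools through [alpha_from_pools()].  Macropores are
#' volumetric only and sit outside the curve.
#'
#' @param phi_mat Saturated matrix water content (matrix porosity), cm^3/cm^3.
#' @param alpha Shape parameter, 1/cm (>= 0).
#' @param n Shape parameter (> 1).
#' @return An object of class `retention_params`.
#' @export
retention_params <- function(phi_mat, alpha, n) {
  if (!is.finite(phi_mat) || phi_mat <= 0 || phi_mat >= 1)
    stop("`phi_mat` must lie in (0, 1)", call. = FALSE)
  if (!is.finite(alpha) || alpha < 0)
    stop("`alpha` must be >= 0", call. = FALSE)
  if (!is.finite(n) || n <= 1)
    stop("`n` must be > 1", call. = FALSE)
  structure(list(phi_mat = phi_mat, alpha = alpha, n = n),
            class = "retention_params")
}

#' @export
print.retention_params <- function(x, ...) {
  cat(sprintf("<retention_params> phi_mat = %.4f, alpha = %.4g 1/cm, n = %.4f\n",
              x$phi_mat, x$alpha, x$n))
  invisible(x)
}

#' Evaluate the matrix water retention curve
#'
#' @param psi Pressure head, cm; non-positive (0 = saturation).
#' @param params A [retention_params()].
#' @return Water content theta, cm^3/cm^3; `theta(0) = phi_mat`, monotone
#'   non-increasing in `|psi|`.
#' @examples
#' p <- retention_params(0.588, 0.77, 1.08)
#' vg_theta(c(0, -100), p)
#' @export
vg_theta <- function(psi, params) {
  if (any(psi > 0)) stop("pressure head `psi` must be <= 0", call. = FALSE)
  params$phi_mat * (1 + (params$alpha * abs(psi))^params$n)^(1 / params$n - 1)
}

#' Alpha of the retention curve from the micro/matrix pore pools
#'
#' Inverts the retention curve at the micropore/mesopore boundary head so
#' that `vg_theta(psi_mic_mes) = phi_mic` exactly:
#' `alpha = ((phi_mic/phi_mat)^(-n/(n-1)) - 1)^(1/n) / |psi_mic_mes|`.
#' This is what makes the curve dynamic: as bioturbation or root turnover
#' shifts pore volume between classes, `alpha` follows the pools while `n`
#' stays fixed by texture.
#'
#' @param phi_mic Microporosity, cm^3/cm^3 (pores below the boundary
#'   diameter); must satisfy `0 < phi_mic <= phi_mat`.
#' @param phi_mat Matrix porosity, cm^3/cm^3.
#' @param n Texture-fixed van Genuchten n (> 1).
#' @param psi_mic_mes Pressure head at the micropore/mesopore boundary, cm
#'   (negative; -100 cm corresponds to a 30 micrometre pore diameter).
#' @return alpha in 1/cm; 0 when `phi_mic == phi_mat` (no mesopores).
#' @export
alpha_from_pools <- function(phi_mic, phi_mat, n, psi_mic_mes = -100) {
  if (any(phi_mic <= 0)) stop("`phi_mic` must be positive", call. = FALSE)
  if (any(phi_mic > phi_mat + 1e-12))
    stop("`phi_mic` cannot exceed `phi_mat`", call. = FALSE)
  if (any(psi_mic_mes >= 0)) stop("`psi_mic_mes` must be < 0", call. = FALSE)
  if (any(n <= 1)) stop("`n` must be > 1", call. = FALSE)
  ratio <- pmin(phi_mic / phi_mat, 1)
  (pmax(ratio^(-n / (n - 1)) - 1, 0))^(1 / n) / abs(psi_mic_mes)
}

#' Equivalent pore diameter for a pressure head
#'
#' Capillary rise law `d = C / |psi|` with `C = 3000` micrometre-cm
#' (Young-Laplace with standard surface tension, rounded), so that -100 cm
#' corresponds to 30 micrometres and -30 cm to 100 micrometres: the two
#' class boundaries of the model.
#'
#' @param psi Pressure head, cm (strictly negative).
#' @return Equivalent pore diameter, micrometres.
#' @export
psi_to_diameter <- function(psi) {
  if (any(psi >= 0)) stop("`psi` must be < 0", call. = FALSE)
  3000 / abs(psi)
}

#' Saturated hydraulic conductivity ratio implied by two alpha values
#'
#' Capillary bundle theory predicts `K_sat` proportional to `alpha^2`, so the
#' conductivity ratio between two soils sharing `n` is `(alpha_1/alpha_2)^2`.
#'
#' @param alpha_1,alpha_2 Van Genuchten alpha values, 1/cm (`alpha_2 > 0`).
#' @return The fold ratio `(alpha_1/alpha_2)^2`.
#' @export
ksat_ratio <- function(alpha_1, alpha_2) {
  if (any(alpha_2 <= 0)) stop("`alpha_2` must be > 0", call. = FALSE)
  (alpha_1 / alpha_2)^2
}

#' Fit retention curves jointly with a shared n
#'
#' Joint nonlinear least squares over the concatenated residuals of several
#' measured retention curves, with one `n` shared across curves (either fixed
#' or fitted) and per-curve `(phi_mat, alpha)`.  Measurements at excluded
#' pressure heads (by default -2.5 cm, where water held in structural
#' macropores drains freely and the matrix curve does not apply) are dropped
#' before fitting.  Because the sum of squares is multimodal in `alpha`, the
#' optimizer is restarted from `n_starts` log-spaced alpha values and the
#' best solution kept.
#'
#' @param data A data frame with columns `label`, `psi_cm` (<= 0) and
#'   `theta`; replicate points may simply repeat a head within a label
#'   (pooled-point fitting).  If a `replicate` column is present and
#'   `use_means = TRUE`, replicate means per head are fitted instead.
#' @param n_fixed Shared n to impose (e.g. 1.08), or `NULL` to fit n as a
#'   free shared parameter.
#' @param exclude_psi Pressure heads to exclude, cm (matched to 1e-6 cm).
#' @param n_starts Number of log-spaced alpha multi-starts.
#' @param use_means Fit replicate means instead of pooled points.
#' @return An object of class `vg_shared_fit`: list with `params` (data frame
#'   `label`, `phi_mat`, `alpha`, `rmse`, `n_points`), `n`, `n_fixed`
#'   (logical), `ssr` and `convergence` info.
#' @export
fit_shared_n <- function(data, n_fixed = 1.08, exclude_psi = -2.5,
                         n_starts = 10, use_means = FALSE) {
  stopifnot(all(c("label", "psi_cm", "theta") %in% names(data)))
  keep <- rep(TRUE, nrow(data))
  for (p in exclude_psi) keep <- keep & abs(data$psi_cm - p) > 1e-6
  d <- data[keep, , drop = FALSE]
  if (use_means) {
    agg <- stats::aggregate(theta ~ label + psi_cm, data = d, FUN = mean)
    d <- agg
  }
  labels <- unique(d$label)
  K <- length(labels)
  counts <- table(factor(d$label, levels = labels))
  if (any(counts < 3))
    stop("each curve needs at least 3 retained points after exclusion; got: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  idx <- split(seq_len(nrow(d)), factor(d$label, levels = labels))
  free_n <- is.null(n_fixed)

  resid_fun <- function(par) {
    phi <- par[seq_len(K)]
    alpha <- par[K + seq_len(K)]
    n <- if (free_n) par[2 * K + 1] else n_fixed
    r <- numeric(nrow(d))
    for (k in seq_len(K)) {
      i <- idx[[k]]
      r[i] <- phi[k] * (1 + (alpha[k] * abs(d$psi_cm[i]))^n)^(1 / n - 1) -
        d$theta[i]
    }
    r
  }

  lower <- c(rep(1e-4, K), rep(1e-6, K), if (free_n) 1.001)
  upper <- c(rep(1 - 1e-4, K), rep(10, K), if (free_n) 10)
  phi0 <- vapply(idx, function(i) min(max(d$theta[i]), 0.99), numeric(1))
  alpha_grid <- 10^seq(-4, 0.5, length.out = n_starts)

  best <- NULL
  for (a0 in alpha_grid) {
    start <- c(phi0, rep(a0, K), if (free_n) 1.2)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop("shared-n retention fit failed from every start", call. = FALSE)

  par <- unname(best$fit$par)
  n_hat <- if (free_n) par[2 * K + 1] else n_fixed
  rmse <- vapply(seq_len(K), function(k) {
    i <- idx[[k]]
    p <- retention_params(par[k], par[K + k], n_hat)
    sqrt(mean((vg_theta(d$psi_cm[i], p) - d$theta[i])^2))
  }, numeric(1))
  structure(
    list(params = data.frame(label = labels,
                             phi_mat = par[seq_len(K)],
                             alpha = par[K + seq_len(K)],
                             rmse = rmse,
                             n_points = as.integer(counts),
                             stringsAsFactors = FALSE),
         n = n_hat, n_fixed = !free_n, ssr = best$ssr,
         convergence = best$fit$info, message = best$fit$message),
    class = "vg_shared_fit")
}

#' @export
print.vg_shared_fit <- function(x, ...) {
  cat(sprintf("<vg_shared_fit> shared n = %.4f (%s), SSR = %.4g\n",
              x$n, if (x$n_fixed) "fixed" else "fitted", x$ssr))
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Partition a fitted matrix retention curve into pore classes
#'
#' Splits the fitted matrix porosity into micro- and mesopores at the
#' boundary head (`phi_mic = vg_theta(psi_mic_mes)`), and each class into its
#' textural and structural parts using the minimum matrix porosity and the
#' textural micropore fraction.  Macroporosity is set to zero: matrix-only
#' retention fits carry no information about macropores.
#'
#' @param params A [retention_params()] (or a `vg_shared_fit`; then one row
#'   per fitted curve is returned).
#' @param psi_mic_mes Micropore/mesopore boundary head, cm.
#' @param phi_min Minimum (textural) matrix porosity, cm^3/cm^3.
#' @param f_t_mic Fraction of textural pores in the micropore class.
#' @return A data frame in the column order textural (mic, mes, total),
#'   structural (mic, mes, total), total (mic, mes, mat).
#' @export
classify_pores <- function(params, psi_mic_mes = -100, phi_min, f_t_mic) {
  if (inherits(params, "vg_shared_fit")) {
    rows <- lapply(seq_len(nrow(params$params)), function(k) {
      p <- retention_params(params$params$phi_mat[k],
                            params$params$alpha[k], params$n)
      classify_pores(p, psi_mic_mes, phi_min, f_t_mic)
    })
    out <- do.call(rbind, rows)
    out$label <- params$params$label
    return(out[, c("label", setdiff(names(out), "label"))])
  }
  if (phi_min > params$phi_mat + 1e-12)
    stop("`phi_min` exceeds the fitted matrix porosity", call. = FALSE)
  phi_mic <- vg_theta(psi_mic_mes, params)
  phi_mes <- params$phi_mat - phi_mic
  phi_t_mic <- f_t_mic * phi_min
  phi_t_mes <- (1 - f_t_mic) * phi_min
  s_mic <- phi_mic - phi_t_mic
  s_mes <- phi_mes - phi_t_mes
  tol <- 1e-9
  if (s_mic < -tol || s_mes < -tol) {
    bad <- c("micropore", "mesopore")[c(s_mic < -tol, s_mes < -tol)]
    stop("textural porosity exceeds total in class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(phi_t_mic = phi_t_mic, phi_t_mes = phi_t_mes, phi_t = phi_min,
             phi_s_mic = max(s_mic, 0), phi_s_mes = max(s_mes, 0),
             phi_s = max(s_mic, 0) + max(s_mes, 0),
             phi_mic = phi_mic, phi_mes = phi_mes,
             phi_mat = params$phi_mat)
}

#' Read and write retention data as CSV
#'
#' CSV with columns `label`, `psi_cm`, `theta` (plus any extras such as
#' `replicate`); leading lines starting with `#` are treated as metadata and
#' skipped on read.
#'
#' @param data A retention data frame.
#' @param path File path.
#' @param meta Optional character vector of metadata lines (written with a
#'   leading `# `).
#' @export
write_retention <- function(data, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_retention
#' @export
read_retention <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
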