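#' Pinball (check) loss
#'
#' `rho_tau(u) = u * (tau - 1\{u < 0\})`. Its minimizer over a constant is
#' the `tau`-quantile.
#'
#' @param u numeric residuals.
#' @param tau quantile level in (0, 1).
#' @return numeric vector of losses.
#' @export
pinball_loss <- function(u, tau) {
  stopifnot(tau > 0, tau < 1)
  u * (tau - (u < 0))
}

#' Smallest minimizer of the empirical pinball loss
#'
#' The order statistic at rank `ceiling(tau * n)`: the lower endpoint of the
#' (possibly non-unique) set of empirical `tau`-quantiles.
#'
#' @param y numeric sample.
#' @param tau quantile level in (0, 1).
#' @return single numeric value.
#' @examples
#' pinball_quantile(c(1, 2, 3, 9), 0.5)  # 2: ties broken downward
#' @export
pinball_quantile <- function(y, tau) {
  stopifnot(length(y) > 0, tau > 0, tau < 1)
  sort(y)[max(1L, ceiling(tau * length(y)))]
}

#' Quantile-regression design for recovery estimation
#'
#' Pairs minute- (or hour-) level metric observations with the decay
#' covariate `z = 1/(t + 1)`, where `t` is hours since release. The fitted
#' model is `log Y_tau = beta_ind + alpha_g * z`: a per-animal offset
#' (baseline behaviour) plus a per-group slope that measures the initial
#' multiplicative displacement of the `tau`-quantile, decaying to zero as
#' `t` grows.
#'
#' @param observations data frame with columns `animal_id`, `group`, `t_h`
#'   (hours since release, >= 0) and `y` (positive metric values).
#' @param tau quantile level in (0, 1).
#' @param response name of the response metric (bookkeeping only).
#' @return An object of class `qr_design`.
#' @seealso [fit_quantile_model()]
#' @export
qr_design <- function(observations, tau = 0.5, response = "metric") {
  stopifnot(is.data.frame(observations), tau > 0, tau < 1)
  need <- c("animal_id", "group", "t_h", "y")
  miss <- setdiff(need, names(observations))
  if (length(miss)) stop("observations lack columns: ", paste(miss, collapse = ", "))
  obs <- tibble::as_tibble(observations[need])
  obs <- obs[complete.cases(obs), ]
  if (nrow(obs) == 0) stop("no complete observations")
  if (any(obs$y <= 0)) stop("responses must be positive (log applied internally)")
  if (any(obs$t_h < 0)) stop("times must be nonnegative (hours since release)")
  obs$animal_id <- as.character(obs$animal_id)
  obs$group <- as.character(obs$group)
  obs$z <- 1 / (obs$t_h + 1)
  structure(list(observations = obs, tau = tau, response = response),
            class = "qr_design")
}

#' @export
print.qr_design <- function(x, ...) {
  o <- x$observations
  cat("<qr_design>", x$response, "tau =", x$tau, "-", nrow(o), "obs,",
      length(unique(o$animal_id)), "animals,",
      length(unique(o$group)), "group(s)\n")
  invisible(x)
}

# model matrix: one intercept column per (group, animal), one z column per group
qr_model_matrix <- function(obs) {
  af <- factor(paste(obs$group, obs$animal_id, sep = "/"))
  gf <- factor(obs$group)
  Xa <- vapply(levels(af), function(l) as.numeric(af == l),
               numeric(length(af)))
  Xg <- vapply(levels(gf), function(l) obs$z * (gf == l),
               numeric(length(gf)))
  colnames(Xg) <- paste0("alpha:", levels(gf))
  list(X = cbind(Xa, Xg), animals = levels(af), groups = levels(gf))
}

#' Fit the log-linear quantile recovery model
#'
#' Minimizes the pinball objective
#' `sum rho_tau(log y_i - beta_ind(i) - alpha_g(i) * z_i)` with one offset
#' per animal and one slope per group, using the linear-programming solvers
#' of \pkg{quantreg} (Barrodale-Roberts simplex for small problems, the
#' Frisch-Newton interior-point method for large ones). The fit is
#' deterministic given the data.
#'
#' @param design a [qr_design()].
#' @param tau quantile level; defaults to the design's.
#' @param method `"br"`, `"fn"`, or `NULL` to choose by problem size
#'   (`"br"` up to 20000 observations).
#' @return An object of class `qr_fit` with elements `tau`, `beta_ind`
#'   (named per animal), `alpha` (named per group), `loss` (achieved pinball
#'   objective), `n_obs`, `groups`, `method`.
#' @examples
#' obs <- data.frame(animal_id = "a", group = "g",
#'                   t_h = c(0, 1, 3, 7), y = exp(1 - 2 / (c(0, 1, 3, 7) + 1)))
#' fit <- fit_quantile_model(qr_design(obs, tau = 0.5))
#' fit$alpha  # -2 (exact interpolation)
#' @export
fit_quantile_model <- function(design, tau = NULL, method = NULL) {
  stopifnot(inherits(design, "qr_design"))
  if (is.null(tau)) tau <- design$tau
  obs <- design$observations
  n_t <- tapply(obs$t_h, obs$animal_id, function(t) length(unique(t)))
  if (any(n_t < 2)) {
    stop("each animal needs >= 2 distinct observation times; offending: ",
         paste(names(n_t)[n_t < 2], collapse = ", "))
  }
  nz_g <- tapply(obs$z, obs$group, function(z) length(unique(z)))
  if (any(nz_g < 2)) {
    stop("degenerate design: a group has a single time value, its slope is ",
         "not identified")
  }
  mm <- qr_model_matrix(obs)
  u <- log(obs$y)
  if (is.null(method)) method <- if (nrow(mm$X) <= 20000) "br" else "fn"
  fit <- withCallingHandlers(
    quantreg::rq.fit(mm$X, u, tau = tau, method = method),
    warning = function(w) {
      if (grepl("nonunique", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  cf <- fit$coefficients
  beta <- cf[mm$animals]
  alpha <- cf[paste0("alpha:", mm$groups)]
  names(alpha) <- mm$groups
  loss <- sum(pinball_loss(u - as.numeric(mm$X %*% cf), tau))
  structure(
    list(tau = tau, beta_ind = beta, alpha = alpha, loss = loss,
         n_obs = nrow(obs), groups = mm$groups, method = method,
         response = design$response),
    class = "qr_fit"
  )
}

#' @export
print.qr_fit <- function(x, ...) {
  cat("<qr_fit>", x$response, "tau =", x$tau, "-", x$n_obs, "obs\n")
  cat("  alpha:", paste(names(x$alpha), round(x$alpha, 4), collapse = "; "), "\n")
  cat("  pinball loss:", format(x$loss), "\n")
  invisible(x)
}
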